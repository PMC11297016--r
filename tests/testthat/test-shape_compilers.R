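test_that("the zig-zag compiler maps directions to turning numbers", {
  pth <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 2), c(-1, 2))
  expect_equal(compile_zigzag(pth)$states0, c(0L, 1L, 2L, 3L, 0L))
  # clockwise mirror for negative paths
  nth <- rbind(c(0, 0), c(1, 0), c(2, -1), c(2, -2), c(1, -2))
  expect_equal(compile_zigzag(nth)$states0, c(0L, -1L, -2L, -3L, 0L))
  # straight east line compiles to the already-folded program
  expect_true(all(compile_zigzag(cbind(0:5, 0L))$states0 == 0L))
  expect_error(compile_zigzag(rbind(c(0, 0), c(0, 1), c(0, 0))), "self")
  expect_error(compile_zigzag(rbind(c(1, 0), c(2, 0))), "NotAtOrigin")
  expect_error(compile_zigzag(rbind(c(0, 0), c(0, 1), c(1, 0))),
               "NotZigZag")
})

test_that("compiled zig-zag programs target their path exactly", {
  for (seed in 1:40) {
    pth <- random_zigzag(sample(5:40, 1), seed)
    prog <- compile_zigzag(pth)
    tgt <- target_configuration(prog)
    expect_equal(unname(tgt$positions), unname(pth))
  }
  # small instances verified exhaustively foldable
  for (seed in 41:44) {
    pth <- random_zigzag(10, seed)
    expect_true(explore(compile_zigzag(pth))$foldable)
  }
})

test_that("square paths raster the square boustrophedon", {
  expect_equal(unname(square_path(1)), cbind(0L, 0L))
  expect_equal(unname(square_path(2)),
               rbind(c(0L, 0L), c(1L, 0L), c(1L, 1L), c(0L, 1L)))
  p8 <- square_path(8)
  expect_equal(nrow(p8), 64)
  expect_true(all(p8 >= 0 & p8 < 8))
  expect_false(anyDuplicated(paste(p8[, 1], p8[, 2])) > 0)
})

test_that("squares fold with zero error", {
  for (n in 2:4) {
    prog <- compile_zigzag(square_path(n))
    v <- foldability_verdict(prog, synthesize_shape("square", n = n))
    expect_true(v$foldable)
    expect_equal(v$error, 0)
  }
})

test_that("y-monotone traversals cover the shape within the perimeter bound", {
  sh <- tm_shape(rbind(c(0, 0), c(1, 0), c(2, 0), c(2, 1), c(3, 1)))
  tr <- ymonotone_traversal(sh)
  expect_equal(unname(tr$path + rep(tr$offset, each = nrow(tr$path))),
               rbind(c(0L, 0L), c(1L, 0L), c(2L, 0L), c(3L, 0L),
                     c(3L, 1L), c(2L, 1L)))
  expect_equal(tr$error, 1)
  # a square needs no extensions
  expect_equal(ymonotone_traversal(synthesize_shape("square", n = 4))$error, 0)

  for (seed in 1:60) {
    sh <- synthesize_shape("ymonotone_random", height = 6, maxw = 8,
                           seed = seed)
    expect_true(is_y_monotone(sh))
    tr <- ymonotone_traversal(sh)
    expect_lte(tr$error, nrow(perimeter(sh)))
    # traversal is a valid positive zig-zag path covering the shape
    cm <- compile_ymonotone(sh)
    expect_equal(folding_error(target_configuration(cm$program),
                               cm$target_shape), tr$error)
  }
})

test_that("perimeter uses the six-neighbour adjacency", {
  expect_equal(nrow(perimeter(tm_shape(matrix(c(0L, 0L), 1)))), 1)
  expect_equal(nrow(perimeter(synthesize_shape("square", n = 2))), 4)
  expect_equal(nrow(perimeter(synthesize_shape("square", n = 8))), 28)
})

test_that("shapes scale by replacing points with k x k blocks", {
  s1 <- tm_shape(matrix(c(0L, 0L), 1))
  s2 <- scale_shape(s1, 2)
  expect_setequal(paste(s2$points[, 1], s2$points[, 2]),
                  c("0 0", "1 0", "0 1", "1 1"))
  sh <- synthesize_shape("separator_random", height = 3, maxw = 3, seed = 2)
  expect_equal(nrow(scale_shape(sh, 2)$points), 4 * nrow(sh$points))
  expect_equal(scale_shape(sh, 1)$points, sh$points)
})

test_that("yw-separators are found exactly when they exist", {
  col <- tm_shape(cbind(0L, 0:4))
  expect_equal(find_yw_separator(col), cbind(x = rep(0L, 5), y = 0:4))
  # the top point hangs to the upper right, unreachable by +y/+w steps
  none <- tm_shape(rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 2)))
  expect_null(find_yw_separator(none))
  # a separator may sidestep a dead-end column: (2,0)->(1,1)->(0,2)
  side <- tm_shape(rbind(c(2, 0), c(0, 1), c(1, 1), c(2, 1), c(0, 2)))
  expect_equal(unname(find_yw_separator(side)),
               cbind(c(2L, 1L, 0L), 0:2))
  for (seed in 1:40) {
    sh <- synthesize_shape("separator_random", height = 5, maxw = 5,
                           seed = seed)
    sep <- find_yw_separator(sh)
    expect_false(is.null(sep))
    steps <- diff(sep[, 1])
    expect_true(all(steps %in% c(-1L, 0L)))      # +y or +w only
    expect_true(all(paste(sep[, 1], sep[, 2]) %in%
                      paste(sh$points[, 1], sh$points[, 2])))
  }
})

test_that("scaled shapes fold with zero error via the two-lobe traversal", {
  # smallest instance: exhaustively foldable onto the 2x2 square
  cs <- compile_scaled(tm_shape(matrix(c(0L, 0L), 1)))
  v <- foldability_verdict(cs$program, cs$target_shape)
  expect_true(v$foldable)
  expect_equal(v$error, 0)
  expect_equal(sort(cs$program$states0), sort(c(-2L, 0L, 1L, 0L)))

  for (seed in 1:25) {
    sh <- synthesize_shape("separator_random", height = 4, maxw = 4,
                           seed = seed)
    cs <- compile_scaled(sh)
    # the cut is a yw-chain splitting every scaled row into non-empty parts
    expect_true(all(diff(cs$cut[, 1]) %in% c(-1L, 0L)))
    expect_equal(nrow(cs$path), 4 * nrow(sh$points))
    expect_equal(folding_error(target_configuration(cs$program),
                               cs$target_shape), 0)
    for (s in 1:5) {
      tr <- sample_trajectory(cs$program, seed = s)
      expect_equal(tr$terminal, "target")
      expect_equal(folding_error(tr$final, cs$target_shape), 0)
    }
  }
  expect_error(compile_scaled(tm_shape(rbind(c(0, 0), c(0, 1), c(1, 1),
                                             c(1, 2)))),
               "NoSeparator")
})

test_that("thin crosses are y-monotone but not exactly foldable", {
  cr <- synthesize_shape("cross", arm = 2)
  expect_equal(nrow(cr$points), 9)
  expect_true(is_y_monotone(cr))
  # no Hamiltonian path exists: exhaustive search over all starts
  pts <- cr$points
  keys <- paste(pts[, 1], pts[, 2])
  nbrs <- lapply(seq_len(nrow(pts)), function(i) {
    nb <- t(apply(direction_vectors(), 1, function(d) pts[i, ] + d))
    which(keys %in% paste(nb[, 1], nb[, 2]))
  })
  ham <- function(cur, seen) {
    if (length(seen) == nrow(pts)) return(TRUE)
    for (nx in nbrs[[cur]]) {
      if (!(nx %in% seen) && ham(nx, c(seen, nx))) return(TRUE)
    }
    FALSE
  }
  expect_false(any(vapply(seq_len(nrow(pts)), function(s) ham(s, s),
                          logical(1))))
  # hence every folding of the cross has error >= 1, and the y-monotone
  # compiler achieves a perimeter-bounded error
  tr <- ymonotone_traversal(cr)
  expect_gte(tr$error, 1)
  expect_lte(tr$error, nrow(perimeter(cr)))
})
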