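test_that("direction arithmetic follows the hexagonal tuple", {
  expect_equal(rotate_direction(0, 2), 2)          # +x twice -> +w
  expect_equal(rotate_direction("+x", 2), "+w")
  for (d in 0:5) {
    expect_equal(rotate_direction(d, 0), d)
    expect_equal(rotate_direction(d, 6), d)
    expect_equal(rotate_direction(rotate_direction(d, 4), -4), d)
  }
  expect_equal(unname(direction_vectors()["+x", ] +
                        direction_vectors()["+w", ]),
               unname(direction_vectors()["+y", ]))  # x + w = y
})

test_that("configurations reconstruct from move-count vectors", {
  p <- line_program(4, 1)
  c0 <- tm_configuration(p)
  expect_equal(c0$positions[, 1], 0:3)
  expect_true(all(c0$positions[, 2] == 0))

  cf <- tm_configuration(p, c(1, 1, 1, 0))
  expect_equal(unname(cf$positions),
               cbind(0L, 0:3))                     # rotated onto +y ray
  expect_equal(cf$directions[1:3], rep(1L, 3))

  # blocked witness geometry of the 2*pi line rotation machine
  w <- tm_configuration(line_program(7, 6), c(0, 2, 3, 4, 5, 6, 0))
  expect_equal(unname(w$positions),
               rbind(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(-1L, 1L),
                     c(-1L, 0L), c(0L, -1L), c(1L, -1L)))
  expect_equal(w$states, c(6L, 4L, 3L, 2L, 1L, 0L, 0L))

  expect_error(tm_configuration(p, c(2, 0, 0, 0)), "out of range")
  expect_error(tm_configuration(line_program(7, 6), c(0, 3, 3, 4, 5, 6, 0)),
               "self-intersecting")
})

test_that("rule applicability implements blocking", {
  w <- tm_configuration(line_program(7, 6), c(0, 2, 3, 4, 5, 6, 0))
  expect_false(rule_applicable(w, 1))    # translated head hits the tail
  expect_false(rule_applicable(w, 6))    # state already 0
  expect_true(rule_applicable(tm_configuration(line_program(3, 1)), 1))
  expect_error(rule_applicable(w, 8), "IndexError")
})

test_that("rule application turns, translates the head, and burns one unit", {
  p <- tm_program(c(3, 3, 0))
  c0 <- tm_configuration(p)
  c1 <- apply_rule(c0, 1)
  expect_equal(c1$states, c(2L, 3L, 0L))
  expect_equal(unname(c1$positions[2, ] - c0$positions[2, ]), c(-1L, 1L))
  expect_equal(unname(c1$positions[3, ] - c0$positions[3, ]), c(-1L, 1L))

  # last monomer: empty head, state change only
  cl <- tm_configuration(tm_program(c(0, 1)))
  cl2 <- apply_rule(cl, 2)
  expect_equal(cl2$states, c(0L, 0L))
  expect_equal(cl2$positions, cl$positions)

  expect_error(apply_rule(c1, 3), "BlockedMove")   # state 0
  # progress measure: each step removes exactly one unit of work
  expect_equal(sum(abs(c0$states)) - sum(abs(c1$states)), 1)
})

test_that("turn angles are signed pi/3 multiples matching direction changes", {
  p <- tm_program(c(1, 1, 0))
  expect_equal(turn_angle(tm_configuration(p), 2), 0)          # collinear
  expect_equal(turn_angle(tm_configuration(p, c(0, 1, 0)), 2), 1)  # left
  neg <- tm_program(c(-1, -1, 0))
  expect_equal(turn_angle(tm_configuration(neg, c(0, 1, 0)), 2), -1)
  expect_error(turn_angle(tm_configuration(p), 1), "IndexError")
})

test_that("turn-angle sums equal move-count differences on reachable space", {
  # exhaustive check of the angle-sum identity for the n=5, s=4 line machine
  p <- line_program(5, 4)
  vec <- explore(p, return_vectors = TRUE)$vectors
  for (r in seq_len(nrow(vec))) {
    cf <- tm_configuration(p, vec[r, ])
    for (i in 1:3) {
      for (j in (i + 1):4) {
        angles <- vapply((i + 1):j, function(kk) turn_angle(cf, kk),
                         integer(1))
        expect_equal(cf$moves[j] - cf$moves[i], sum(angles))
      }
    }
  }
})

test_that("permanent blocking is nonzero states with no applicable rule", {
  w <- tm_configuration(line_program(7, 6), c(0, 2, 3, 4, 5, 6, 0))
  expect_true(is_permanently_blocked(w))
  done <- tm_configuration(line_program(4, 1), c(1, 1, 1, 0))
  expect_false(is_permanently_blocked(done))
  expect_true(is_final(done))
  for (s in 1:6) {
    expect_false(is_permanently_blocked(tm_configuration(line_program(5, s))))
  }
})

test_that("folding error is the symmetric difference", {
  p <- tm_program(c(0, 0, 0))
  cf <- tm_configuration(p)
  expect_equal(folding_error(cf, cf$positions), 0)
  sh <- tm_shape(rbind(c(0, 0), c(1, 0), c(1, 1)))
  expect_equal(folding_error(cf, sh), 2)
})

test_that("applicability agrees with the self-intersection oracle", {
  # a move is blocked exactly when the tentative successor self-intersects;
  # checked against the independent oracle over whole reachable spaces of
  # random small programs, including mixed signs
  for (seed in 1:6) {
    p <- random_program(5, 3, seed)
    vecs <- orc_explore(p$states0)
    for (r in seq_len(nrow(vecs))) {
      cf <- tm_configuration(p, vecs[r, ])
      expect_equal(applicable_moves(cf),
                   as.integer(orc_applicable_set(p$states0, vecs[r, ])),
                   info = sprintf("seed %d, row %d", seed, r))
    }
  }
})

test_that("oracle and engine agree on successor geometry", {
  for (seed in 7:10) {
    p <- random_program(6, 2, seed)
    cf <- tm_configuration(p)
    set.seed(seed)
    for (step in 1:20) {
      a <- applicable_moves(cf)
      if (!length(a)) break
      i <- a[sample.int(length(a), 1)]
      cf <- apply_rule(cf, i)
      expect_equal(unname(cf$positions), unname(orc_positions(p$states0,
                                                              cf$moves)))
      expect_true(orc_simple(cf$positions))
    }
  }
})

test_that("head stays above and tail below the monomer line for states <= 3", {
  # half-plane invariant, exhaustive on small uniform machines
  for (s in 1:3) {
    p <- line_program(6, s)
    vec <- explore(p, return_vectors = TRUE)$vectors
    for (r in seq_len(nrow(vec))) {
      pos <- tm_configuration(p, vec[r, ])$positions
      for (i in 1:6) {
        if (i < 6) expect_true(all(pos[(i + 1):6, 2] >= pos[i, 2]))
        expect_true(all(pos[1:i, 2] <= pos[i, 2]))
      }
    }
  }
})

test_that("adjacent move counts never differ by more than two", {
  for (s in c(2, 5)) {
    rep <- explore(line_program(6, s))
    expect_lte(rep$max_adjacent_diff, 2)
  }
})

test_that("scripted replays validate every move", {
  p <- line_program(3, 1)
  cf <- replay_moves(tm_configuration(p), c(1, 2))
  expect_equal(cf$moves, c(1L, 1L, 0L))
  expect_error(replay_moves(tm_configuration(p), c(3, 3)),
               "ScriptInapplicable")
  stopped <- replay_moves(tm_configuration(p), c(1, 1), on_fail = "stop")
  expect_equal(attr(stopped, "fail_at"), 2L)
})
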