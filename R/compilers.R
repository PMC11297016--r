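#' Zig-zag path compiler
#'
#' A positive zig-zag path uses only the step directions
#' \eqn{\pm x, +y, +w} (a negative one \eqn{\pm x, -y, -w}); such paths
#' wind over and back parallel to the x-axis while moving monotonically in
#' y.  The compiler assigns each monomer the number of \eqn{\pi/3} turns
#' from east to its direction in the folded path:
#' \deqn{+x \to 0, \quad +y \to 1, \quad +w \to 2, \quad -x \to 3}
#' for positive paths, and the clockwise mirror
#' \eqn{+x \to 0, -w \to -1, -y \to -2, -x \to -3} for negative ones.  The
#' last monomer gets state 0.  Every such program folds its path on all
#' trajectories, in expected time logarithmic in the path length.
#'
#' @param path n x 2 integer matrix: a self-avoiding unit-step path
#'   starting at the origin.
#' @param name program label.
#' @return a [tm_program()] whose target configuration traces `path`.
#' @examples
#' compile_zigzag(square_path(3))
#' @export
compile_zigzag <- function(path, name = "zigzag") {
  path <- as_point_matrix(path)
  if (path[1L, 1L] != 0L || path[1L, 2L] != 0L)
    stop("NotAtOrigin: zig-zag paths must start at (0,0)")
  if (anyDuplicated(point_keys(path)))
    stop("path is self-intersecting")
  dirs <- path_directions(path)
  pos_map <- c(0L, 1L, 2L, 3L, NA, NA)   # +x +y +w -x | -y -w
  neg_map <- c(0L, NA, NA, -3L, -2L, -1L)
  if (all(dirs %in% c(0L, 1L, 2L, 3L))) {
    states <- pos_map[dirs + 1L]
  } else if (all(dirs %in% c(0L, 3L, 4L, 5L))) {
    states <- neg_map[dirs + 1L]
  } else {
    stop("NotZigZag: path mixes upward and downward steps")
  }
  prog <- tm_program(c(states, 0L), name = name)
  attr(prog, "target_path") <- path
  prog
}

#' Boustrophedon raster path of the n x n square
#'
#' Row 0 west to east, one +y step, row 1 east to west, and so on; a
#' positive zig-zag path covering all \eqn{n^2} points of the square.
#'
#' @param n side length.
#' @return n^2 x 2 integer matrix of points in traversal order.
#' @export
square_path <- function(n) {
  stopifnot(n >= 1L)
  n <- as.integer(n)
  do.call(rbind, lapply(0:(n - 1L), function(y) {
    xs <- if (y %% 2L == 0L) 0:(n - 1L) else (n - 1L):0
    cbind(xs, y)
  }))
}

#' Zig-zag traversal of a y-monotone shape
#'
#' Builds the row-by-row raster: even-indexed rows are traversed west to
#' east and odd rows east to west, with each row segment extended sideways
#' by the points needed to meet the turn of the next row.  The traversal
#' covers every shape point; the extension points fall outside the shape
#' but each is adjacent to a perimeter point, so the folding error is at
#' most the perimeter length of the shape.
#'
#' @param shape a y-monotone, connected [tm_shape()].
#' @return list with `path` (the traversal, anchored so its first point is
#'   the origin), `offset` (translation applied: `original = path + offset`),
#'   `error` (number of traversal points outside the shape), and
#'   `extra_points` (those points, in original coordinates).
#' @export
ymonotone_traversal <- function(shape) {
  stopifnot(inherits(shape, "tm_shape"))
  if (!is_y_monotone(shape)) stop("NotYMonotone")
  rows <- shape_rows(shape)
  H <- nrow(rows)
  segs <- vector("list", H)
  for (i in seq_len(H)) {
    l <- rows$l[i]; r <- rows$r[i]
    if (i %% 2L == 1L) {          # even index in 0-based counting
      if (i < H) r <- max(r, rows$r[i + 1L])
      if (i > 1L) l <- min(l, rows$l[i - 1L])
      xs <- l:r
    } else {                      # odd index: right-to-left
      if (i < H) l <- min(l, rows$l[i + 1L])
      if (i > 1L) r <- max(r, rows$r[i - 1L])
      xs <- r:l
    }
    segs[[i]] <- cbind(xs, rows$y[i])
  }
  path <- do.call(rbind, segs)
  keys <- point_keys(shape$points)
  outside <- !(point_keys(path) %in% keys)
  offset <- path[1L, ]
  list(path = cbind(path[, 1L] - offset[1L], path[, 2L] - offset[2L]),
       offset = offset,
       error = sum(outside),
       extra_points = path[outside, , drop = FALSE])
}

#' Compile a y-monotone shape to a program
#'
#' Convenience wrapper: [ymonotone_traversal()] followed by
#' [compile_zigzag()].
#'
#' @param shape a y-monotone connected [tm_shape()].
#' @param name program label.
#' @return list with `program`, `traversal` (see [ymonotone_traversal()]),
#'   and `target_shape` (the shape translated into the program's frame,
#'   i.e. anchored at the traversal start).
#' @export
compile_ymonotone <- function(shape, name = "ymonotone") {
  tr <- ymonotone_traversal(shape)
  prog <- compile_zigzag(tr$path, name = name)
  anchored <- tm_shape(translate_points(shape$points, -tr$offset[1L],
                                        -tr$offset[2L]), check = FALSE)
  list(program = prog, traversal = tr, target_shape = anchored)
}

#' Find a yw-separator of a y-monotone shape
#'
#' A yw-separator is a chain of shape points from the bottom row to the
#' top row in which every step is +y or +w.  Found by forward marking of
#' the +y/+w-reachable points row by row, then backtracking (leftmost
#' predecessor first).
#'
#' @param shape a y-monotone [tm_shape()].
#' @return k x 2 integer matrix of chain points bottom to top, or `NULL`
#'   if no separator exists.
#' @export
find_yw_separator <- function(shape) {
  stopifnot(inherits(shape, "tm_shape"))
  if (!is_y_monotone(shape)) stop("NotYMonotone")
  rows <- shape_rows(shape)
  H <- nrow(rows)
  # marked interval per row: points reachable from the bottom row
  a <- rows$l[1L]; b <- rows$r[1L]
  A <- integer(H); B <- integer(H)
  A[1L] <- a; B[1L] <- b
  for (i in seq_len(H - 1L)) {
    a2 <- max(rows$l[i + 1L], a - 1L)   # +w reaches one to the left
    b2 <- min(rows$r[i + 1L], b)        # +y keeps x
    if (a2 > b2) return(NULL)
    a <- a2; b <- b2
    A[i + 1L] <- a; B[i + 1L] <- b
  }
  # backtrack from the leftmost marked point of the top row
  xs <- integer(H)
  xs[H] <- A[H]
  for (i in rev(seq_len(H - 1L))) {
    # predecessor of (x, y+1) is (x, y) (+y) or (x+1, y) (+w); leftmost first
    cand <- c(xs[i + 1L], xs[i + 1L] + 1L)
    ok <- cand[cand >= A[i] & cand <= B[i]]
    xs[i] <- ok[1L]
  }
  cbind(x = xs, y = rows$y)
}
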