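#' Compile a factor-2 scaled shape to a zero-error program
#'
#' For an xy-connected y-monotone shape with a yw-separator, the scaled
#' shape \eqn{S_{\times 2}} is foldable with zero error.  The compiler cuts
#' \eqn{S_{\times 2}} along the doubled separator into a left piece
#' \eqn{S'_{\times 2}} and a right piece \eqn{S''_{\times 2}} whose shared
#' boundary columns \eqn{C'} (rightmost of the left piece) and
#' \eqn{C'' = C' + (1,0)} are yw-chains.  The chain is traversed from the
#' topmost point of \eqn{C'} down through the left piece (a negative
#' zig-zag path, clockwise turning numbers), across the bottom row, and
#' back up through the right piece (a positive zig-zag path, anticlockwise
#' turning numbers); the two halves never interfere across the cut, so the
#' fold completes on every trajectory.
#'
#' The per-segment cut placement follows the separator geometry (y-parallel
#' segments split each cell pair 2+2; w-parallel segments split 1+3 or 3+1
#' according to which side of the separator the shape continues on), with
#' a feasibility pass that keeps the cut a yw-chain and both pieces
#' non-empty in every row.
#'
#' @param shape an xy-connected, y-monotone [tm_shape()] admitting a
#'   yw-separator.
#' @param name program label.
#' @return list with `program` (a [tm_program()]), `path` (the traversal,
#'   anchored at the origin), `offset` (original = anchored + offset),
#'   `target_shape` (the scaled shape in the anchored frame), `split`
#'   (index of the last monomer in the left piece), `cut` (the cut chain
#'   C', original coordinates, bottom to top), `c_prime`, `c_second`,
#'   `s_prime`, `s_second` (the two pieces as point matrices).
#' @examples
#' cs <- compile_scaled(tm_shape(matrix(c(0L, 0L), 1)))
#' cs$program$states0   # folds the 2x2 square
#' @export
compile_scaled <- function(shape, name = "scaled") {
  stopifnot(inherits(shape, "tm_shape"))
  if (!is_y_monotone(shape)) stop("NotYMonotone")
  if (!is_xy_connected(shape)) stop("NotXYConnected")
  C <- find_yw_separator(shape)
  if (is.null(C)) stop("NoSeparator: shape admits no yw-separator")
  rows <- shape_rows(shape)
  H <- nrow(rows)
  keys <- point_keys(shape$points)

  ## scaled rows t = 1..2H, bottom to top
  T2 <- 2L * H
  y2 <- 2L * rows$y[1L] + 0:(T2 - 1L)
  L2 <- rep(2L * rows$l, each = 2L)
  R2 <- rep(2L * rows$r + 1L, each = 2L)

  ## candidate cut from the separator case rules
  cand <- integer(T2)
  cand[1L] <- 2L * C[1L, 1L]
  for (i in seq_len(H - 1L)) {
    xi <- C[i, 1L]; xi1 <- C[i + 1L, 1L]
    if (xi1 == xi) {                       # segment parallel to y
      cand[2L * i] <- 2L * xi
      cand[2L * i + 1L] <- 2L * xi
    } else {                               # parallel to w (xi1 == xi - 1)
      caseA <- paste(xi - 1L, C[i, 2L]) %in% keys
      if (caseA) {
        cand[2L * i] <- 2L * xi - 1L
        cand[2L * i + 1L] <- 2L * xi - 2L
      } else {
        cand[2L * i] <- 2L * xi
        cand[2L * i + 1L] <- 2L * xi - 1L
      }
    }
  }
  cand[T2] <- 2L * C[H, 1L]

  ## feasibility pass: the cut must be a yw-chain with both sides
  ## non-empty in every row
  lo <- integer(T2); hi <- integer(T2)
  lo[1L] <- L2[1L]; hi[1L] <- R2[1L] - 1L
  for (t in 2:T2) {
    lo[t] <- max(L2[t], lo[t - 1L] - 1L)
    hi[t] <- min(R2[t] - 1L, hi[t - 1L])
    if (lo[t] > hi[t])
      stop("NoValidCut: no yw-chain cut exists for the scaled shape")
  }
  chi <- integer(T2)
  chi[T2] <- min(max(cand[T2], lo[T2]), hi[T2])
  for (t in rev(seq_len(T2 - 1L))) {
    a <- max(lo[t], chi[t + 1L])
    b <- min(hi[t], chi[t + 1L] + 1L)
    chi[t] <- min(max(cand[t], a), b)
  }

  ## traversal: down the left piece, across the bottom, up the right piece
  seg <- function(x1, x2, y) cbind(x1:x2, y)
  down <- list()
  for (j in H:1) {
    t2 <- 2L * j; t1 <- 2L * j - 1L
    down[[length(down) + 1L]] <- seg(chi[t2], L2[t2], y2[t2])
    down[[length(down) + 1L]] <- seg(L2[t1], chi[t1], y2[t1])
  }
  up <- list()
  for (j in 1:H) {
    t1 <- 2L * j - 1L; t2 <- 2L * j
    up[[length(up) + 1L]] <- seg(chi[t1] + 1L, R2[t1], y2[t1])
    up[[length(up) + 1L]] <- seg(R2[t2], chi[t2] + 1L, y2[t2])
  }
  left <- do.call(rbind, down)
  right <- do.call(rbind, up)
  path <- rbind(left, right)
  split <- nrow(left)

  ## states: clockwise turning numbers on the left piece, anticlockwise on
  ## the right; each monomer turns from east to its folded direction
  dirs <- path_directions(path)
  pos_map <- c(0L, 1L, 2L, 3L, NA, NA)
  neg_map <- c(0L, NA, NA, -3L, -2L, -1L)
  n <- nrow(path)
  states <- integer(n)
  for (i in seq_len(n - 1L)) {
    states[i] <- if (i <= split) neg_map[dirs[i] + 1L] else
      pos_map[dirs[i] + 1L]
    if (is.na(states[i]))
      stop("internal: traversal is not a two-lobe zig-zag path")
  }
  offset <- path[1L, ]
  anchored <- cbind(path[, 1L] - offset[1L], path[, 2L] - offset[2L])
  prog <- tm_program(states, name = name)
  attr(prog, "target_path") <- anchored
  s2 <- scale_shape(shape, 2L)
  list(program = prog,
       path = anchored,
       offset = offset,
       target_shape = tm_shape(translate_points(s2$points, -offset[1L],
                                                -offset[2L]), check = FALSE),
       split = split,
       cut = cbind(x = chi, y = y2),
       c_prime = cbind(x = chi, y = y2),
       c_second = cbind(x = chi + 1L, y = y2),
       s_prime = left,
       s_second = right)
}
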