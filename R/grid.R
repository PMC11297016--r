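#' Triangular-grid direction conventions
#'
#' Positions live on the triangular grid, stored as integer axial pairs
#' \eqn{(x, y)} with basis vectors \eqn{x = (1, 0)}, \eqn{y = (0, 1)} and the
#' derived third axis \eqn{w = (-1, 1)} (so \eqn{x + w = y}).  The six unit
#' directions are indexed 0..5 in the anticlockwise tuple
#' \eqn{(+x, +y, +w, -x, -y, -w)}; index \eqn{i} corresponds to the angle
#' \eqn{i\pi/3} from east.  All model arithmetic stays in integers; the
#' Cartesian projection \eqn{(x + y/2,\; y\sqrt{3}/2)} is used for rendering
#' only.
#'
#' @return `direction_vectors()` returns a 6 x 2 integer matrix of unit
#'   vectors, with row names `"+x", "+y", "+w", "-x", "-y", "-w"`.
#' @examples
#' direction_vectors()
#' rotate_direction(0, 2)   # +x turned twice anticlockwise is +w
#' @export
direction_vectors <- function() {
  m <- matrix(c(1L, 0L,  0L, 1L,  -1L, 1L,  -1L, 0L,  0L, -1L,  1L, -1L),
              ncol = 2L, byrow = TRUE,
              dimnames = list(c("+x", "+y", "+w", "-x", "-y", "-w"),
                              c("x", "y")))
  m
}

.DIRS <- matrix(c(1L, 0L,  0L, 1L,  -1L, 1L,  -1L, 0L,  0L, -1L,  1L, -1L),
                ncol = 2L, byrow = TRUE)
.DIR_NAMES <- c("+x", "+y", "+w", "-x", "-y", "-w")

#' Rotate a grid direction
#'
#' @param d direction index in 0..5 (0 = east, anticlockwise), or one of the
#'   names `"+x", "+y", "+w", "-x", "-y", "-w"`.
#' @param steps signed number of \eqn{\pi/3} rotations; positive is
#'   anticlockwise.
#' @return the rotated direction, in the same representation as `d`.
#' @export
rotate_direction <- function(d, steps) {
  stopifnot(length(steps) == 1L, steps == as.integer(steps))
  if (is.character(d)) {
    idx <- match(d, .DIR_NAMES) - 1L
    if (anyNA(idx)) stop("unknown direction name: ", d)
    return(.DIR_NAMES[(idx + as.integer(steps)) %% 6L + 1L])
  }
  stopifnot(all(d %in% 0:5))
  (as.integer(d) + as.integer(steps)) %% 6L
}

## direction index of each unit step along a path (n-1 values for n points)
path_directions <- function(pos) {
  n <- nrow(pos)
  if (n < 2L) return(integer(0))
  dx <- diff(pos[, 1L])
  dy <- diff(pos[, 2L])
  idx <- integer(n - 1L)
  for (k in seq_len(n - 1L)) {
    hit <- which(.DIRS[, 1L] == dx[k] & .DIRS[, 2L] == dy[k])
    if (length(hit) != 1L)
      stop("not a unit-step path at step ", k, " (offset ",
           dx[k], ",", dy[k], ")")
    idx[k] <- hit - 1L
  }
  idx
}

## Cartesian projection of axial coordinates (for rendering/plots)
axial_to_cartesian <- function(pos) {
  cbind(pos[, 1L] + pos[, 2L] / 2, pos[, 2L] * sqrt(3) / 2)
}

point_keys <- function(pos) paste(pos[, 1L], pos[, 2L])

as_point_matrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.null(dim(points))) {
    stopifnot(length(points) == 2L)
    points <- matrix(points, ncol = 2L)
  }
  storage.mode(points) <- "integer"
  dimnames(points) <- list(NULL, c("x", "y"))
  points
}
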