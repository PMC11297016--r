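#' Grid shapes
#'
#' A shape is a finite set of triangular-grid points whose induced graph,
#' under the six unit directions \eqn{\pm x, \pm y, \pm w}, is connected.
#'
#' @param points n x 2 integer matrix (or data frame) of axial coordinates.
#' @param check if `TRUE` (default), verify connectivity.
#' @return an object of class `tm_shape`; points are stored in canonical
#'   order (by y, then x).
#' @examples
#' tm_shape(rbind(c(0, 0), c(1, 0), c(0, 1)))
#' @export
tm_shape <- function(points, check = TRUE) {
  pts <- as_point_matrix(points)
  if (anyDuplicated(point_keys(pts))) stop("duplicate points in shape")
  pts <- pts[order(pts[, 2L], pts[, 1L]), , drop = FALSE]
  if (check && !.points_connected(pts))
    stop("DisconnectedShape: induced graph is not connected")
  structure(list(points = pts), class = "tm_shape")
}

#' @export
print.tm_shape <- function(x, ...) {
  cat(sprintf("Grid shape: %d points, x in [%d, %d], y in [%d, %d]\n",
              nrow(x$points), min(x$points[, 1L]), max(x$points[, 1L]),
              min(x$points[, 2L]), max(x$points[, 2L])))
  if (is_y_monotone(x)) cat("  y-monotone\n")
  invisible(x)
}

#' @export
length.tm_shape <- function(x) nrow(x$points)

.neighbours6 <- function(p) {
  cbind(p[1L] + .DIRS[, 1L], p[2L] + .DIRS[, 2L])
}

.points_connected <- function(pts) {
  n <- nrow(pts)
  if (n <= 1L) return(TRUE)
  keys <- point_keys(pts)
  idx <- seq_len(n)
  names(idx) <- keys
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    cur <- queue[[1L]]
    queue <- queue[-1L]
    nb <- .neighbours6(pts[cur, ])
    hit <- idx[point_keys(nb)]
    hit <- hit[!is.na(hit)]
    new <- hit[!seen[hit]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

#' Row decomposition of a shape
#'
#' @param shape a [tm_shape()].
#' @return data frame with one row per occupied y-coordinate (ascending):
#'   `y`, leftmost `l`, rightmost `r`, and count `size`.
#' @export
shape_rows <- function(shape) {
  pts <- shape$points
  ys <- sort(unique(pts[, 2L]))
  out <- data.frame(y = ys, l = NA_integer_, r = NA_integer_,
                    size = NA_integer_)
  for (k in seq_along(ys)) {
    xs <- pts[pts[, 2L] == ys[k], 1L]
    out$l[k] <- min(xs)
    out$r[k] <- max(xs)
    out$size[k] <- length(xs)
  }
  out
}

#' y-monotonicity test
#'
#' A shape is y-monotone when the points along each of its y-coordinates
#' form one contiguous segment.
#'
#' @param shape a [tm_shape()].
#' @return logical.
#' @export
is_y_monotone <- function(shape) {
  rows <- shape_rows(shape)
  all(rows$size == rows$r - rows$l + 1L)
}

#' xy-connectivity test
#'
#' A shape is xy-connected when its induced graph remains connected after
#' removing all edges parallel to the w direction.
#'
#' @param shape a [tm_shape()].
#' @return logical.
#' @export
is_xy_connected <- function(shape) {
  pts <- shape$points
  n <- nrow(pts)
  if (n <= 1L) return(TRUE)
  idx <- seq_len(n)
  names(idx) <- point_keys(pts)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  steps <- .DIRS[c(1L, 2L, 4L, 5L), , drop = FALSE]  # +/-x, +/-y only
  while (length(queue)) {
    cur <- queue[[1L]]
    queue <- queue[-1L]
    nb <- cbind(pts[cur, 1L] + steps[, 1L], pts[cur, 2L] + steps[, 2L])
    hit <- idx[point_keys(nb)]
    hit <- hit[!is.na(hit)]
    new <- hit[!seen[hit]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

#' Perimeter of a shape
#'
#' The shape points having at least one of their six grid neighbours
#' outside the shape; the perimeter length is the number of such points.
#'
#' @param shape a [tm_shape()].
#' @return integer matrix of perimeter points (possibly all of the shape).
#' @export
perimeter <- function(shape) {
  pts <- shape$points
  keys <- point_keys(pts)
  on_perim <- vapply(seq_len(nrow(pts)), function(i) {
    nb <- .neighbours6(pts[i, ])
    !all(point_keys(nb) %in% keys)
  }, logical(1L))
  pts[on_perim, , drop = FALSE]
}

#' Scale a shape by an integer factor
#'
#' Every point \eqn{(i, j)} is replaced by the \eqn{k \times k} block
#' \eqn{\{(ki + a, kj + b) : 0 \le a, b < k\}}.
#'
#' @param shape a [tm_shape()].
#' @param k positive integer scale factor.
#' @return a [tm_shape()] with \eqn{k^2} times as many points.
#' @export
scale_shape <- function(shape, k) {
  stopifnot(k >= 1L)
  k <- as.integer(k)
  pts <- shape$points
  offs <- expand.grid(a = 0:(k - 1L), b = 0:(k - 1L))
  out <- do.call(rbind, lapply(seq_len(nrow(offs)), function(m) {
    cbind(k * pts[, 1L] + offs$a[m], k * pts[, 2L] + offs$b[m])
  }))
  tm_shape(out, check = FALSE)
}

translate_points <- function(pts, dx, dy) {
  cbind(pts[, 1L] + as.integer(dx), pts[, 2L] + as.integer(dy))
}

#' Synthetic shape fixtures
#'
#' Generates the shape families used throughout the package tests and
#' examples.
#'
#' \describe{
#'   \item{`square(n)`}{the n x n square `0 <= x, y < n` (n^2 points).}
#'   \item{`cross(arm)`}{width-1 cross with four arms of the given length
#'     (4 arm + 1 points); y-monotone but not Hamiltonian for arm >= 2.}
#'   \item{`ymonotone_random(height, maxw)`}{random y-monotone shape: each
#'     row a random segment of width 1..maxw, consecutive rows constrained
#'     to stay adjacent on the triangular grid.}
#'   \item{`separator_random(height, maxw)`}{as above, additionally
#'     guaranteeing by construction that a yw-separator exists.}
#'   \item{`spiral(k)`}{the k-turn 1-gap spiral (see [spiral_shape()]).}
#' }
#'
#' @param kind one of `"square"`, `"cross"`, `"ymonotone_random"`,
#'   `"separator_random"`, `"spiral"`.
#' @param n,arm,height,maxw,k kind-specific size parameters.
#' @param seed RNG seed for the random kinds.
#' @return a [tm_shape()].
#' @export
synthesize_shape <- function(kind = c("square", "cross", "ymonotone_random",
                                      "separator_random", "spiral"),
                             n = 4L, arm = 2L, height = 6L, maxw = 8L,
                             k = 1L, seed = 1L) {
  kind <- match.arg(kind)
  switch(kind,
    square = {
      stopifnot(n >= 1L)
      g <- expand.grid(x = 0:(n - 1L), y = 0:(n - 1L))
      tm_shape(as.matrix(g), check = FALSE)
    },
    cross = {
      stopifnot(arm >= 1L)
      pts <- rbind(cbind(seq(-arm, arm), 0L),
                   cbind(0L, setdiff(seq(-arm, arm), 0L)))
      tm_shape(pts, check = FALSE)
    },
    ymonotone_random = .random_ymonotone(height, maxw, seed, separator = FALSE),
    separator_random = .random_ymonotone(height, maxw, seed, separator = TRUE),
    spiral = spiral_shape(k)
  )
}

## Random y-monotone shape builder.  Rows are segments [l, r]; consecutive
## rows must be adjacent on the triangular grid, i.e. l' <= r and
## r' >= l - 1 (the +y and +w step patterns).  With separator = TRUE the
## shape is additionally kept xy-connected (consecutive rows share an x)
## and the forward-marked cut interval of the factor-2 scaled shape is
## kept non-empty row by row, so the scaled compiler's yw-chain cut -- and
## hence also a yw-separator of the shape itself -- exists by construction.
.random_ymonotone <- function(height, maxw, seed, separator) {
  stopifnot(height >= 1L, maxw >= 1L)
  set.seed(seed)
  l <- integer(height)
  r <- integer(height)
  w <- sample.int(maxw, 1L)
  l[1L] <- 0L
  r[1L] <- w - 1L
  # scaled cut interval at the top scaled row of the current row pair
  a <- max(2L * l[1L], 2L * l[1L] - 1L)
  b <- 2L * r[1L]
  for (i in seq_len(height - 1L)) {
    w <- sample.int(maxw, 1L)
    cand <- seq.int(l[i] - w, r[i])  # triangular-grid adjacency range
    if (separator) {
      ok <- vapply(cand, function(lp) {
        rp <- lp + w - 1L
        if (max(l[i], lp) > min(r[i], rp)) return(FALSE)  # xy-connectivity
        max(2L * lp, a - 1L) <= min(2L * rp, b)           # cut survives
      }, logical(1L))
      cand <- cand[ok]
      if (!length(cand)) cand <- b %/% 2L  # fall back onto the cut column
    }
    l[i + 1L] <- cand[sample.int(length(cand), 1L)]
    r[i + 1L] <- l[i + 1L] + w - 1L
    if (separator) {
      a1 <- max(2L * l[i + 1L], a - 1L)
      b1 <- min(2L * r[i + 1L], b)
      a <- max(2L * l[i + 1L], a1 - 1L)   # second scaled row of the pair
      b <- b1
      if (a > b) stop("internal: scaled cut interval lost")  # unreachable
    }
  }
  pts <- do.call(rbind, lapply(seq_len(height), function(i) {
    cbind(seq.int(l[i], r[i]), i - 1L)
  }))
  tm_shape(pts, check = FALSE)
}
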