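#' The k-turn 1-gap spiral
#'
#' An anticlockwise spiral of nested "almost rectangles" whose arms keep a
#' gap of exactly one grid unit.  The ring \eqn{R_{k'}} consists of the
#' rectangle frame \eqn{y = \pm 2k'}, \eqn{x \in \{-2k', 2k'-1\}}, plus
#' three joint points and minus one corner point that opens the gap to the
#' next ring.  The spiral has \eqn{8k^2 + 6k + 2} points and exactly two
#' degree-1 points: the inside start \eqn{(0, 0)} and the outside start
#' \eqn{(2k+1, -2k)}.  It has a traversal (in fact two), yet for
#' \eqn{k \ge 2} no Turning Machine folds it on all trajectories.
#'
#' @param k number of turns (>= 1).
#' @return a [tm_shape()] with attributes `inside_start`, `outside_start`.
#' @examples
#' nrow(spiral_shape(1)$points)   # 16
#' @export
spiral_shape <- function(k) {
  stopifnot(k >= 1L)
  k <- as.integer(k)
  pts <- NULL
  for (kp in seq_len(k)) {
    ring <- rbind(
      cbind(seq.int(-2L * kp, 2L * kp - 1L), 2L * kp),
      cbind(seq.int(-2L * kp, 2L * kp - 1L), -2L * kp),
      cbind(-2L * kp, seq.int(-2L * kp, 2L * kp)),
      cbind(2L * kp - 1L, seq.int(-2L * kp, 2L * kp)),
      cbind(c(2L * kp - 2L, 2L * kp, 2L * kp + 1L),
            c(-2L * kp + 2L, -2L * kp, -2L * kp)))
    ring <- ring[!duplicated(point_keys(ring)), , drop = FALSE]
    drop <- point_keys(ring) == paste(2L * kp - 1L, -2L * kp + 1L)
    pts <- rbind(pts, ring[!drop, , drop = FALSE])
  }
  pts <- pts[!duplicated(point_keys(pts)), , drop = FALSE]
  sh <- tm_shape(pts)
  attr(sh, "inside_start") <- c(0L, 0L)
  attr(sh, "outside_start") <- c(2L * k + 1L, -2L * k)
  sh
}

#' Canonical spiral turning numbers
#'
#' The only initial state sequences that can possibly fold the k-turn
#' 1-gap spiral: run-length patterns over base values \eqn{t_0, \ldots,
#' t_{4k}}.  Inside-to-outside sequences require \eqn{t_0 \equiv 0 \pmod
#' 6} and increase by 2 at even and 1 at odd indices; outside-to-inside
#' sequences require \eqn{t_0 \equiv 3 \pmod 6} and decrease by 1 at even
#' and 2 at odd indices.  Both have length \eqn{8k^2 + 6k + 2}, matching
#' the spiral point count.
#'
#' @param k number of spiral turns.
#' @param orientation `"in_to_out"` or `"out_to_in"`.
#' @param t0 base turning number; must satisfy the congruence for the
#'   chosen orientation (error `BadBaseState` otherwise).
#' @return integer vector of initial states.
#' @examples
#' spiral_turning_numbers(1, "in_to_out", 0)
#' @export
spiral_turning_numbers <- function(k, orientation = c("in_to_out",
                                                      "out_to_in"),
                                   t0 = NULL) {
  stopifnot(k >= 1L)
  orientation <- match.arg(orientation)
  if (is.null(t0)) t0 <- if (orientation == "in_to_out") 0L else 3L
  t0 <- as.integer(t0)
  m <- 4L * as.integer(k)
  if (orientation == "in_to_out") {
    if (t0 %% 6L != 0L)
      stop("BadBaseState: inside-to-outside requires t0 = 0 (mod 6)")
    t <- integer(m + 1L)
    t[1L] <- t0
    for (i in seq_len(m))
      t[i + 1L] <- t[i] + if (i %% 2L == 0L) 2L else 1L
    c(rep(t, times = seq_len(m + 1L)), t[m + 1L])
  } else {
    if (t0 %% 6L != 3L && t0 %% 6L != -3L)
      stop("BadBaseState: outside-to-inside requires t0 = 3 (mod 6)")
    t <- integer(m + 1L)
    t[1L] <- t0
    for (i in seq_len(m))
      t[i + 1L] <- t[i] - if (i %% 2L == 0L) 1L else 2L
    # run lengths 4k+1 down to 1 trace the spiral arms from the outside
    # start; the final monomer (no direction) repeats the innermost value,
    # mirroring the inside-to-outside sequence
    c(rep(t, times = rev(seq_len(m + 1L))), t[m + 1L])
  }
}

#' Spiral program on the east line
#'
#' Builds the Turning Machine with [spiral_turning_numbers()] as initial
#' states, all monomers starting on the east line.  Its unique target
#' configuration traces the spiral (anchored at the origin, so for
#' outside-to-inside programs the spiral is translated by minus the
#' outside start point).
#'
#' @inheritParams spiral_turning_numbers
#' @return a [tm_program()] with attribute `target_shape` (anchored
#'   [tm_shape()]).
#' @export
spiral_program <- function(k, orientation = c("in_to_out", "out_to_in"),
                           t0 = NULL) {
  orientation <- match.arg(orientation)
  states <- spiral_turning_numbers(k, orientation, t0)
  prog <- tm_program(states,
                     name = sprintf("spiral(k=%d,%s)", k, orientation))
  sh <- spiral_shape(k)
  anchor <- if (orientation == "in_to_out") attr(sh, "inside_start") else
    attr(sh, "outside_start")
  attr(prog, "target_shape") <-
    tm_shape(translate_points(sh$points, -anchor[1L], -anchor[2L]))
  prog
}

#' Necessity probe for the canonical spiral states
#'
#' Perturbs each directed monomer's initial state in the canonical spiral
#' sequence by plus or minus one and shows that the resulting program
#' cannot fold the spiral: the perturbation rotates that monomer's final
#' direction, so the program's unique all-zero target configuration either
#' self-intersects (no trajectory can complete at all) or traces a point
#' set different from the spiral (positive folding error on every
#' completing trajectory).  The final monomer is excluded: it has no
#' direction, so its counter does not affect the folded geometry.
#'
#' @inheritParams spiral_turning_numbers
#' @return data frame with one row per (monomer, delta) perturbation:
#'   `monomer`, `delta`, `failure` (`"invalid_target"` or
#'   `"wrong_shape"`), and `fails` (logical).
#' @export
spiral_state_necessity <- function(k, orientation = c("in_to_out",
                                                      "out_to_in"),
                                   t0 = NULL) {
  orientation <- match.arg(orientation)
  states <- spiral_turning_numbers(k, orientation, t0)
  sh <- spiral_shape(k)
  anchor <- if (orientation == "in_to_out") attr(sh, "inside_start") else
    attr(sh, "outside_start")
  target <- tm_shape(translate_points(sh$points, -anchor[1L], -anchor[2L]))
  n <- length(states)
  out <- expand.grid(monomer = seq_len(n - 1L), delta = c(-1L, 1L))
  out$failure <- NA_character_
  out$fails <- NA
  for (r in seq_len(nrow(out))) {
    s2 <- states
    s2[out$monomer[r]] <- s2[out$monomer[r]] + out$delta[r]
    p2 <- tm_program(s2)
    tgt <- tryCatch(target_configuration(p2), error = function(e) NULL)
    if (is.null(tgt)) {
      out$failure[r] <- "invalid_target"
      out$fails[r] <- TRUE
    } else {
      err <- folding_error(tgt, target)
      out$failure[r] <- if (err > 0L) "wrong_shape" else "folds"
      out$fails[r] <- err > 0L
    }
  }
  out
}
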