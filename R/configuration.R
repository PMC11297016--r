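#' Configurations as move-count vectors
#'
#' A configuration of a fixed program is canonically encoded by its
#' move-count vector: entry \eqn{i} counts the rule applications monomer
#' \eqn{i} has received, so \eqn{0 \le \Delta s_i \le |s_0(m_i)|} and the
#' current state is \eqn{s_0 - \mathrm{sign}(s_0)\,\Delta s}.  Geometry is
#' derived by prefix sums: each move rotates the monomer's direction by
#' \eqn{\pm\pi/3}, and the reconstructed path must remain self-avoiding.
#'
#' @param program a [tm_program()].
#' @param moves integer move-count vector (default all zeros, the initial
#'   configuration).  An error is raised if a count exceeds the monomer's
#'   initial state magnitude or if the reconstructed chain repeats a point.
#' @return an object of class `tm_configuration` with components
#'   `program`, `moves`, `states`, `directions` (index 0..5 per monomer,
#'   `NA` for the last) and `positions` (n x 2 integer matrix).
#' @examples
#' p <- line_program(4, 1)
#' tm_configuration(p, c(1, 1, 1, 0))  # the rotated line
#' @export
tm_configuration <- function(program, moves = NULL) {
  stopifnot(inherits(program, "tm_program"))
  n <- length(program$states0)
  if (is.null(moves)) moves <- integer(n)
  moves <- as.integer(moves)
  if (length(moves) != n) stop("moves must have one entry per monomer")
  pos <- .eng_positions(program$states0, program$dirs0, moves)
  sgn <- sign(program$states0)
  states <- program$states0 - sgn * moves
  dirs <- (program$dirs0 + sgn * moves) %% 6L
  dirs[n] <- NA_integer_
  colnames(pos) <- c("x", "y")
  structure(
    list(program = program, moves = moves, states = states,
         directions = dirs, positions = pos),
    class = "tm_configuration")
}

#' @export
print.tm_configuration <- function(x, ...) {
  n <- length(x$moves)
  cat(sprintf("Turning Machine configuration (%d monomers, program '%s')\n",
              n, x$program$name))
  cat("  moves : ", paste(utils::head(x$moves, 20L), collapse = " "),
      if (n > 20L) " ..." else "", "\n", sep = "")
  cat("  states: ", paste(utils::head(x$states, 20L), collapse = " "),
      if (n > 20L) " ..." else "", "\n", sep = "")
  if (is_final(x)) {
    cat("  final configuration (all states zero)\n")
  } else if (is_permanently_blocked(x)) {
    cat("  PERMANENTLY BLOCKED: nonzero states, no applicable rule\n")
  } else {
    cat("  applicable rules at monomers: ",
        paste(applicable_moves(x), collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Plot a configuration
#'
#' Draws the chain in Cartesian projection; monomers still holding a
#' nonzero state are filled, and those whose rule is currently blocked are
#' highlighted in red.
#'
#' @param x a [tm_configuration()].
#' @param ... passed to [plot()].
#' @export
plot.tm_configuration <- function(x, ...) {
  xy <- axial_to_cartesian(x$positions)
  plot(xy, type = "l", asp = 1, xlab = "x", ylab = "y", ...)
  active <- x$states != 0L
  blocked <- active
  blocked[applicable_moves(x)] <- FALSE
  graphics::points(xy, pch = ifelse(active, 19, 21),
                   col = ifelse(blocked & active, "red", "black"))
  invisible(x)
}

#' Applicability of the turning rule
#'
#' The rule at monomer \eqn{i} is applicable when its state is nonzero and
#' translating its head (all later monomers) by the unit vector two
#' direction-tuple steps around from the monomer's current direction
#' (anticlockwise for positive states, clockwise for negative) does not
#' collide with its tail (itself and all earlier monomers).  The last
#' monomer has an empty head and is applicable whenever its state is
#' nonzero.
#'
#' @param config a [tm_configuration()].
#' @param i monomer index, 1-based.
#' @return `TRUE` if the rule can fire.
#' @export
rule_applicable <- function(config, i) {
  stopifnot(inherits(config, "tm_configuration"))
  n <- length(config$moves)
  if (i < 1L || i > n) stop("IndexError: monomer index out of range")
  .eng_rule_applicable(config$program$states0, config$program$dirs0,
                       config$moves, as.integer(i))
}

#' Indices of all applicable rules
#' @param config a [tm_configuration()].
#' @return integer vector of monomer indices (1-based) whose rule can fire.
#' @export
applicable_moves <- function(config) {
  stopifnot(inherits(config, "tm_configuration"))
  .eng_applicable_set(config$program$states0, config$program$dirs0,
                      config$moves)
}

#' Apply one turning rule
#'
#' Fires the rule at monomer `i`: the move count increments, the monomer's
#' direction rotates by \eqn{\pi/3} (anticlockwise for positive states),
#' and all later monomers translate rigidly by the corresponding unit
#' vector.  Total remaining work \eqn{\sum_i |s(m_i)|} drops by exactly 1.
#'
#' @inheritParams rule_applicable
#' @return the successor [tm_configuration()].
#' @export
apply_rule <- function(config, i) {
  stopifnot(inherits(config, "tm_configuration"))
  n <- length(config$moves)
  if (i < 1L || i > n) stop("IndexError: monomer index out of range")
  mv <- .eng_apply(config$program$states0, config$program$dirs0,
                   config$moves, as.integer(i))
  tm_configuration(config$program, mv)
}

#' Replay a scripted move sequence
#'
#' Applies the given monomer indices in order, validating each move.
#'
#' @param config starting [tm_configuration()].
#' @param seq integer vector of monomer indices (1-based).
#' @param on_fail `"error"` raises `ScriptInapplicable`; `"stop"` returns
#'   the configuration reached before the failing move.
#' @return the final [tm_configuration()], with attribute `fail_at` (0 if
#'   the whole sequence applied).
#' @export
replay_moves <- function(config, seq, on_fail = c("error", "stop")) {
  stopifnot(inherits(config, "tm_configuration"))
  on_fail <- match.arg(on_fail)
  res <- .eng_replay(config$program$states0, config$program$dirs0,
                     config$moves, as.integer(seq))
  if (res$fail_at > 0L && on_fail == "error")
    stop(sprintf("ScriptInapplicable: move %d (monomer %d) is not applicable",
                 res$fail_at, seq[res$fail_at]))
  out <- tm_configuration(config$program, res$moves)
  attr(out, "fail_at") <- res$fail_at
  out
}

#' Turn angle at a monomer
#'
#' The signed angle, in units of \eqn{\pi/3}, between the chain edge coming
#' into monomer `i` and the edge leaving it; positive when the three points
#' make a left (anticlockwise) turn.  Defined for interior monomers
#' \eqn{2 \le i \le n-1}; simplicity of the chain rules out magnitude 3.
#'
#' @inheritParams rule_applicable
#' @return integer in -2..2.
#' @export
turn_angle <- function(config, i) {
  stopifnot(inherits(config, "tm_configuration"))
  n <- length(config$moves)
  if (i < 2L || i > n - 1L)
    stop("IndexError: turn angle is defined for interior monomers only")
  d <- (config$directions[i] - config$directions[i - 1L]) %% 6L
  if (d > 3L) d <- d - 6L
  if (d == 3L)
    stop("degenerate turn angle (reversal) in a simple chain")  # unreachable
  as.integer(d)
}

#' Is a configuration final?
#' @param config a [tm_configuration()].
#' @return `TRUE` when every state is zero.
#' @export
is_final <- function(config) all(config$states == 0L)

#' Is a configuration permanently blocked?
#'
#' A configuration is permanently blocked when at least one state is
#' nonzero yet no monomer has an applicable rule.  (Temporary blocking of
#' an individual monomer is a trajectory-level notion; see [explore()].)
#'
#' @param config a [tm_configuration()].
#' @return logical.
#' @export
is_permanently_blocked <- function(config) {
  any(config$states != 0L) && length(applicable_moves(config)) == 0L
}

#' Folding error against a target shape
#'
#' The size of the symmetric difference between the configuration's
#' occupied points and the shape's points: positions outside the shape plus
#' shape points left uncovered.
#'
#' @param config a [tm_configuration()].
#' @param shape a [tm_shape()] or an n x 2 matrix of points.
#' @return non-negative integer.
#' @export
folding_error <- function(config, shape) {
  pts <- if (inherits(shape, "tm_shape")) shape$points else
    as_point_matrix(shape)
  a <- point_keys(config$positions)
  b <- point_keys(pts)
  length(setdiff(a, b)) + length(setdiff(b, a))
}
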