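#' Turning Machine programs
#'
#' A Turning Machine instance is an initial configuration: a self-avoiding
#' chain of monomers, each carrying an integer turning number (its state).
#' A monomer in positive state wants to turn anticlockwise by \eqn{\pi/3}
#' that many times, decrementing as it goes; a negative state turns
#' clockwise and increments.  By default the chain starts as the east line
#' \eqn{(0,0), (1,0), \ldots, (n-1,0)}, the canonical initial geometry.
#'
#' @param states integer vector of initial turning numbers, one per monomer.
#'   The last monomer has no successor and therefore no direction; its rule
#'   applications change only its state.
#' @param positions optional n x 2 integer matrix of initial positions; must
#'   be a self-avoiding unit-step path starting at the origin.  Default is
#'   the east line.
#' @param name label used in printing and file output.
#' @return an object of class `tm_program`.
#' @seealso [line_program()], [tm_configuration()], [explore()]
#' @examples
#' p <- tm_program(c(1, 1, 1, 0))
#' p
#' @export
tm_program <- function(states, positions = NULL, name = "program") {
  states <- as.integer(states)
  n <- length(states)
  stopifnot(n >= 1L)
  if (is.null(positions)) {
    positions <- cbind(x = 0:(n - 1L), y = integer(n))
  } else {
    positions <- as_point_matrix(positions)
    if (nrow(positions) != n)
      stop("positions must have one row per monomer")
    if (positions[1L, 1L] != 0L || positions[1L, 2L] != 0L)
      stop("NotAtOrigin: the first monomer must sit at (0,0)")
    if (anyDuplicated(point_keys(positions)))
      stop("SelfIntersection: initial positions repeat a point")
  }
  dirs <- c(path_directions(positions), 0L)  # last entry is a placeholder
  structure(
    list(states0 = states, dirs0 = dirs, positions0 = positions, name = name),
    class = "tm_program")
}

#' @export
print.tm_program <- function(x, ...) {
  n <- length(x$states0)
  cat(sprintf("Turning Machine program '%s': %d monomers\n", x$name, n))
  cat("  initial states: ",
      paste(utils::head(x$states0, 20L), collapse = " "),
      if (n > 20L) " ..." else "", "\n", sep = "")
  cat(sprintf("  total turning work sum(|s0|) = %d\n", sum(abs(x$states0))))
  invisible(x)
}

#' @export
length.tm_program <- function(x) length(x$states0)

#' Line-rotation machine
#'
#' The machine \eqn{L_n^s}: \eqn{n} monomers on the east line, the first
#' \eqn{n-1} all in state \eqn{s}, the last in state 0.  Its target
#' configuration is the straight line rotated anticlockwise by
#' \eqn{s\pi/3} about the origin.  Rotations up to \eqn{5\pi/3} (s = 1..5)
#' complete on every trajectory; \eqn{2\pi} (s = 6) permanently blocks for
#' chains of seven or more monomers.
#'
#' @param n number of monomers (>= 1).
#' @param s common initial state of monomers 1..n-1 (may be negative for
#'   clockwise rotation).
#' @return a [tm_program()]; the fully rotated line is available via
#'   [target_configuration()].
#' @examples
#' line_program(5, 3)
#' @export
line_program <- function(n, s) {
  stopifnot(n >= 1L)
  states <- c(rep.int(as.integer(s), n - 1L), 0L)
  tm_program(states, name = sprintf("L(%d,%d)", n, s))
}

#' Target configuration of a program
#'
#' The configuration in which every monomer has exhausted its turning
#' number (all states zero).  It is uniquely determined by the initial
#' states and geometry; an error is raised if that final geometry
#' self-intersects, in which case no trajectory can complete.
#'
#' @param program a [tm_program()].
#' @return a [tm_configuration()] with all states zero.
#' @export
target_configuration <- function(program) {
  tm_configuration(program, abs(program$states0))
}
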