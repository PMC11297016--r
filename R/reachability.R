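#' Exhaustive reachability analysis
#'
#' Breadth-first search over all reachable move-count vectors, starting
#' from the initial configuration.  Every maximal trajectory is finite
#' (each rule application removes one unit of remaining turning work), so
#' a program folds on *all* trajectories -- "computes its target
#' configuration" -- exactly when the target is reachable and no reachable
#' configuration is permanently blocked.
#'
#' @param program a [tm_program()].
#' @param state_cap abort (with `truncated = TRUE` and the verdict
#'   withheld) once more than this many vectors have been enumerated.
#' @param want_path if `TRUE`, also return a move sequence from the
#'   initial configuration to the first (shortest) blocked witness.
#' @param return_vectors if `TRUE`, return the full matrix of reachable
#'   move-count vectors (rows in BFS order).
#' @return an object of class `tm_reachability`: `reachable_count`,
#'   `target_reachable`, `blocked_witnesses` (matrix of move-count
#'   vectors, BFS order, so the first witness has fewest total moves),
#'   `foldable`, `truncated`, `max_adjacent_diff` (the largest
#'   \eqn{|\Delta s_i - \Delta s_{i+1}|} seen anywhere in the reachable
#'   space), and optionally `witness_path`, `vectors`.
#' @examples
#' explore(line_program(4, 1))$reachable_count  # 8
#' @export
explore <- function(program, state_cap = 5e6, want_path = FALSE,
                    return_vectors = FALSE) {
  stopifnot(inherits(program, "tm_program"))
  res <- .eng_explore(program$states0, program$dirs0, state_cap,
                      want_path, return_vectors)
  foldable <- if (res$truncated) NA else
    res$target_reachable && nrow(res$witnesses) == 0L
  structure(
    list(program = program,
         reachable_count = res$reachable_count,
         target_reachable = res$target_reachable,
         blocked_witnesses = res$witnesses,
         witness_path = res$witness_path,
         foldable = foldable,
         truncated = res$truncated,
         max_adjacent_diff = res$max_adjacent_diff,
         vectors = if (return_vectors) res$vectors else NULL),
    class = "tm_reachability")
}

#' @export
print.tm_reachability <- function(x, ...) {
  cat(sprintf("Reachability of '%s': %s reachable configurations%s\n",
              x$program$name, format(x$reachable_count, big.mark = ","),
              if (x$truncated) " (TRUNCATED at state cap)" else ""))
  if (x$truncated) {
    cat("  verdict withheld: state cap exceeded\n")
  } else {
    cat(sprintf("  target reachable: %s; permanently blocked witnesses: %d\n",
                x$target_reachable, nrow(x$blocked_witnesses)))
    cat(sprintf("  foldable on all trajectories: %s\n", x$foldable))
  }
  invisible(x)
}

#' Foldability verdict against a target shape
#'
#' Combines [explore()] with the folding error of the program's unique
#' target configuration against a shape: a target structure is foldable
#' when every trajectory reaches it.
#'
#' @param program a [tm_program()].
#' @param shape optional [tm_shape()]; if supplied, `error` is the
#'   symmetric difference between the target configuration and the shape.
#' @param state_cap passed to [explore()].
#' @return list with `foldable`, `error` (NA if no shape given),
#'   `witnesses`, `report` (the full `tm_reachability`).
#' @export
foldability_verdict <- function(program, shape = NULL, state_cap = 5e6) {
  rep <- explore(program, state_cap = state_cap)
  err <- NA_integer_
  if (!is.null(shape)) {
    tgt <- tryCatch(target_configuration(program), error = function(e) NULL)
    err <- if (is.null(tgt)) NA_integer_ else folding_error(tgt, shape)
  }
  list(foldable = rep$foldable, error = err,
       witnesses = rep$blocked_witnesses, report = rep)
}
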