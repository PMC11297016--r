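#' Scripted blocking trajectories for the k-turn spiral
#'
#' For \eqn{k \ge 2} the k-turn 1-gap spiral is not foldable: the only
#' candidate programs are the canonical turning-number sequences (see
#' [spiral_turning_numbers()]), and each of the six sign cases admits a
#' reachable permanently blocked configuration.  This function plays a
#' deterministic scripted trajectory for the chosen case and verifies the
#' blocking at the end:
#'
#' \describe{
#'   \item{`in_pos`}{inside-to-outside, all states positive
#'     (\eqn{t_0 = 0}).  The innermost coil folds first, creating a small
#'     pocket; the high-state tail then rolls itself prematurely into the
#'     pocket and the whole chain jams.}
#'   \item{`in_neg`}{inside-to-outside, all states negative
#'     (\eqn{t_0 = -6k}).  The outer arms fold into place first; the inner
#'     coil, which needs the most clockwise turning, wedges into a tight
#'     permanently blocked cluster (the clockwise analogue of the blocked
#'     \eqn{2\pi} line rotation).}
#'   \item{`in_mixed`}{inside-to-outside with both signs
#'     (\eqn{t_0 = -6}).  The canonical sequence contains a contiguous
#'     zero-state run; the negative side before it folds clockwise and the
#'     positive side after it anticlockwise, closing a pincer.}
#'   \item{`out_pos`}{outside-to-inside, all positive
#'     (\eqn{t_0 = 6k + 3}); mirror of `in_neg`, starting from the
#'     monomers that form the shorter arms.}
#'   \item{`out_neg`}{outside-to-inside, all negative (\eqn{t_0 = -3}).
#'     Sweeps fold the outermost arms into a C shape; the remaining arm
#'     can only wrap clockwise around the blocked region and jams.}
#'   \item{`out_mixed`}{outside-to-inside with both signs
#'     (\eqn{t_0 = 3}); the zero-run pincer, mirrored.}
#' }
#'
#' Each script is a sequence of phases.  Strict phases (the proofs'
#' prescribed segment sweeps) must apply in full, otherwise a
#' `ScriptInapplicable` error is raised.  Closing phases intentionally run
#' until no further scripted move applies -- the jam forming is the point.
#' The end configuration is then checked: exhaustive reachability from it
#' must show that no continuation ever reaches the all-zero target and
#' that the designated (still nonzero) monomers never move again.
#'
#' @param k number of spiral turns, at least 2.
#' @param case one of `"in_pos"`, `"in_neg"`, `"in_mixed"`, `"out_pos"`,
#'   `"out_neg"`, `"out_mixed"`.
#' @param state_cap cap for the verification search from the end
#'   configuration.
#' @return list with `program`, `moves` (the full scripted move sequence),
#'   `final` (end [tm_configuration()]), `blocked_monomers` (indices with
#'   nonzero state at the end), and `verdict` (`TRUE` when the designated
#'   monomers are permanently blocked on every continuation).
#' @examples
#' spiral_blocking_trajectory(2, "in_pos")$verdict
#' @export
spiral_blocking_trajectory <- function(k,
                                       case = c("in_pos", "in_neg",
                                                "in_mixed", "out_pos",
                                                "out_neg", "out_mixed"),
                                       state_cap = 1e6) {
  case <- match.arg(case)
  if (k < 2) stop("spiral blocking requires k >= 2 (the 1-turn case is open)")
  k <- as.integer(k)

  prog <- switch(case,
    in_pos = spiral_program(k, "in_to_out", 0L),
    in_neg = spiral_program(k, "in_to_out", -6L * k),
    in_mixed = spiral_program(k, "in_to_out", -6L),
    out_pos = spiral_program(k, "out_to_in", 6L * k + 3L),
    out_neg = spiral_program(k, "out_to_in", -3L),
    out_mixed = spiral_program(k, "out_to_in", 3L))
  n <- length(prog)
  cfg <- tm_configuration(prog)
  all_moves <- integer(0)

  strict <- function(sq) {
    cfg2 <- replay_moves(cfg, sq, on_fail = "error")
    all_moves <<- c(all_moves, sq)
    cfg <<- cfg2
  }
  tolerant <- function(sq) {
    cfg2 <- replay_moves(cfg, sq, on_fail = "stop")
    fail <- attr(cfg2, "fail_at")
    all_moves <<- c(all_moves,
                    if (fail == 0L) sq else sq[seq_len(fail - 1L)])
    cfg <<- cfg2
  }
  ## fold greedily, always moving the chosen end of the applicable set,
  ## until the configuration offers no move at all
  closing_fold <- function(pick) {
    repeat {
      a <- applicable_moves(cfg)
      if (!length(a)) break
      i <- pick(a)
      cfg <<- apply_rule(cfg, i)
      all_moves <<- c(all_moves, i)
    }
  }
  ## 1-based start index of inside-to-outside run i (runs [t_i]^{i+1})
  run_in <- function(i) 1L + (i * (i + 1L)) %/% 2L
  ## 1-based start of outside-to-inside run i (runs [t_i]^{4k+1-i})
  run_out <- function(i) {
    if (i == 0L) 1L else 1L + sum((4L * k + 1L) - 0:(i - 1L))
  }

  switch(case,
    in_pos = {
      # fold the innermost coil, creating the pocket ...
      strict(2:n)                      # rotate monomers 2..n by pi/3
      strict(rep(4:n, 2L))             # rotate monomers 4..n by 2pi/3
      strict(rep(n, cfg$states[n]))    # retire the last monomer's counter
      strict(n - 1L)
      # ... then roll the high-state tail into the pocket until it jams
      roll <- integer(0)
      for (j in seq(n, 4L, by = -1L)) roll <- c(roll, j - 2L, j - 1L,
                                                j - 2L)
      tolerant(roll)
      closing_fold(max)
    },
    in_neg = closing_fold(max),
    in_mixed = {
      # zero run is run i = 4 (t_4 = t_0 + 6 = 0); fold the flanks onto it
      i0 <- run_in(3L); i1 <- run_in(4L) - 1L   # segment before the zeros
      j0 <- run_in(5L); j1 <- run_in(6L) - 1L   # segment after the zeros
      strict(rep(i0:i1, 2L))
      strict(j0:j1)
      strict(rep((j1 + 1L):n, 3L))
      closing_fold(max)
    },
    out_pos = closing_fold(max),
    out_neg = {
      strict(rep(1:n, 3L))                   # |t0| full-line sweeps
      strict(rep(run_out(1L):n, 2L))         # two sweeps of the rest
      strict(run_out(2L):n)                  # one more sweep
      tolerant(rep((12L * k + 4L):n, 2L))    # wrap the remaining arm
      closing_fold(max)
    },
    out_mixed = {
      # zero run is run i = 2 (t_2 = t_0 - 3 = 0); fold the flanks onto it
      strict(run_out(1L):(run_out(2L) - 1L))
      strict(rep(run_out(3L):(run_out(4L) - 1L), 2L))
      tolerant(rep(run_out(4L):n, 3L))
      closing_fold(min)
    })

  blocked_monomers <- which(cfg$states != 0L)
  verdict <- .verify_blocked_subset(cfg, blocked_monomers, state_cap)
  list(program = prog, moves = all_moves, final = cfg,
       blocked_monomers = blocked_monomers, verdict = verdict)
}

## A configuration is a fresh Turning Machine instance (the model is
## memoryless): reachability from it is reachability of this program.
continuation_program <- function(config) {
  tm_program(config$states, positions = config$positions,
             name = "continuation")
}

## TRUE iff, over the whole reachable space from `config`, the target is
## never reached and none of the designated monomers ever has an
## applicable rule (their move counts stay 0 in every reachable vector).
.verify_blocked_subset <- function(config, monomers, state_cap) {
  if (!length(monomers)) return(FALSE)
  cont <- continuation_program(config)
  rep <- explore(cont, state_cap = state_cap, return_vectors = TRUE)
  if (rep$truncated) return(NA)
  !rep$target_reachable && all(rep$vectors[, monomers] == 0L)
}
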