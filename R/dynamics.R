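#' Sample one stochastic folding trajectory
#'
#' The system evolves as a continuous-time Markov chain: every applicable
#' rule fires at rate 1, so a configuration with k applicable moves holds
#' for an Exp(k) time and then applies one of them uniformly at random.
#' A trajectory ends at the target configuration (all states zero), at a
#' permanently blocked configuration, or when the step cap is reached.
#'
#' @param program a [tm_program()].
#' @param seed integer seed; identical seeds reproduce identical
#'   trajectories.
#' @param step_cap maximum number of rule applications; defaults to
#'   `sum(abs(states))`, the exact length of every completing trajectory.
#' @param record if `TRUE` (default) keep the per-step log (monomer index
#'   and waiting time); set `FALSE` to save memory on large runs.
#' @return an object of class `tm_trajectory`: list with `program`,
#'   `steps` (monomer indices), `waits` (exponential holding times),
#'   `n_steps`, `total_time`, `terminal` (one of `"target"`,
#'   `"permanently_blocked"`, `"cap_reached"`), and `final`
#'   (the end [tm_configuration()]).
#' @examples
#' tr <- sample_trajectory(line_program(5, 1), seed = 42)
#' tr$terminal
#' @export
sample_trajectory <- function(program, seed = 1L, step_cap = NULL,
                              record = TRUE) {
  stopifnot(inherits(program, "tm_program"))
  if (is.null(step_cap)) step_cap <- sum(abs(program$states0))
  set.seed(as.integer(seed))
  res <- .eng_sample_trajectory(program$states0, program$dirs0,
                                as.integer(step_cap), record)
  structure(
    list(program = program, steps = res$steps, waits = res$waits,
         n_steps = res$n_steps, total_time = res$total_time,
         terminal = c("target", "permanently_blocked",
                      "cap_reached")[res$terminal + 1L],
         final = tm_configuration(program, res$moves)),
    class = "tm_trajectory")
}

#' @export
print.tm_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory of '%s': %d steps, time %.4f, terminal = %s\n",
              x$program$name, x$n_steps, x$total_time, x$terminal))
  invisible(x)
}

#' Completion-time statistics over independent trajectories
#'
#' Aggregates [sample_trajectory()] over `n_samples` independent runs; the
#' per-trajectory RNG streams are derived from the master seed by counter.
#'
#' @param program a [tm_program()].
#' @param n_samples number of independent trajectories.
#' @param seed master seed.
#' @param step_cap per-trajectory step cap (default `sum(abs(states))`).
#' @return an object of class `tm_completion_stats`: `samples`,
#'   `mean_time`, `sd_time`, `mean_steps`, `fraction_reaching_target`, and
#'   the raw vectors `times`, `steps`, `reached`.
#' @examples
#' completion_time_stats(line_program(5, 1), n_samples = 200, seed = 7)
#' @export
completion_time_stats <- function(program, n_samples, seed = 1L,
                                  step_cap = NULL) {
  stopifnot(inherits(program, "tm_program"), n_samples >= 1L)
  if (is.null(step_cap)) step_cap <- sum(abs(program$states0))
  base <- as.integer(seed) %% 1000000000L
  times <- numeric(n_samples)
  steps <- integer(n_samples)
  reached <- logical(n_samples)
  for (k in seq_len(n_samples)) {
    set.seed(base + k)
    res <- .eng_sample_trajectory(program$states0, program$dirs0,
                                  as.integer(step_cap), FALSE)
    times[k] <- res$total_time
    steps[k] <- res$n_steps
    reached[k] <- res$terminal == 0L
  }
  structure(
    list(samples = n_samples, mean_time = mean(times),
         sd_time = stats::sd(times), mean_steps = mean(steps),
         fraction_reaching_target = mean(reached),
         times = times, steps = steps, reached = reached),
    class = "tm_completion_stats")
}

#' @export
print.tm_completion_stats <- function(x, ...) {
  cat(sprintf(paste0("Completion over %d trajectories: mean time %.4f ",
                     "(sd %.4f), mean steps %.1f, target fraction %.3f\n"),
              x$samples, x$mean_time, x$sd_time, x$mean_steps,
              x$fraction_reaching_target))
  invisible(x)
}

#' Exact expected absorption time
#'
#' Enumerates the reachable configuration space and solves the first-step
#' equations \eqn{E[c] = (1 + \sum_{c'} E[c'])/k(c)} by a backward sweep
#' over the reachable DAG (total move count strictly increases along every
#' step, which yields a topological order).  When permanently blocked
#' configurations are reachable, the returned value is the expected time
#' to absorption (target or blocked) and `p_target` gives the probability
#' of reaching the target.
#'
#' @param program a [tm_program()].
#' @param state_cap maximum number of reachable move-count vectors to
#'   enumerate; exceeding it raises `StateCapExceeded`.
#' @return list with `expected_time`, `p_target`, `reachable_count`,
#'   `has_blocked`.
#' @examples
#' exact_expected_time(line_program(5, 1))$expected_time  # 25/12
#' @export
exact_expected_time <- function(program, state_cap = 1e6) {
  stopifnot(inherits(program, "tm_program"))
  .eng_expected_absorption(program$states0, program$dirs0, state_cap)
}

#' Write a trajectory log
#'
#' One line-delimited record per step: step index, monomer, waiting time,
#' and the move-count vector after the step.
#'
#' @param trajectory a `tm_trajectory` (recorded).
#' @param path output file.
#' @export
write_trajectory_log <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "tm_trajectory"))
  mv <- integer(length(trajectory$program$states0))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(trajectory$steps)) {
    mv[trajectory$steps[k]] <- mv[trajectory$steps[k]] + 1L
    writeLines(sprintf("%d\t%d\t%.6f\t%s", k, trajectory$steps[k],
                       trajectory$waits[k], paste(mv, collapse = ",")),
               con)
  }
  invisible(path)
}
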