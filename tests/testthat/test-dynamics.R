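test_that("trajectories are reproducible and respect the progress measure", {
  p <- line_program(8, 3)
  t1 <- sample_trajectory(p, seed = 11)
  t2 <- sample_trajectory(p, seed = 11)
  expect_identical(t1$steps, t2$steps)
  expect_identical(t1$total_time, t2$total_time)
  expect_equal(t1$terminal, "target")
  expect_equal(t1$n_steps, 21)                 # exactly sum(s0)
  expect_true(all(t1$waits > 0))
  expect_equal(sum(t1$waits), t1$total_time)

  # two-monomer machine: a single step
  t3 <- sample_trajectory(line_program(2, 1), seed = 1)
  expect_equal(t3$n_steps, 1)
  expect_equal(t3$terminal, "target")
})

test_that("the 2*pi rotation machine blocks on some seeded trajectory", {
  # blocking is rare (absorption probability about 0.35%); seed 489 is a
  # trajectory that reaches a permanently blocked configuration
  tr <- sample_trajectory(line_program(7, 6), seed = 489)
  expect_equal(tr$terminal, "permanently_blocked")
  expect_true(is_permanently_blocked(tr$final))
  expect_lt(tr$n_steps, sum(abs(tr$program$states0)))
  hits <- vapply(1:50, function(s) {
    sample_trajectory(line_program(7, 6), seed = s)$terminal
  }, character(1))
  expect_true("target" %in% hits)
})

test_that("completion statistics match closed forms", {
  # one monomer, nothing to do
  st0 <- completion_time_stats(line_program(1, 0), 10, seed = 1)
  expect_equal(st0$mean_time, 0)
  expect_equal(st0$fraction_reaching_target, 1)

  # L(5,1): four independent unit-rate clocks; mean completion H_4 = 25/12
  st <- completion_time_stats(line_program(5, 1), 4000, seed = 5)
  se <- st$sd_time / sqrt(st$samples)
  expect_lt(abs(st$mean_time - 25 / 12), 3 * se)
  expect_equal(st$fraction_reaching_target, 1)
  expect_equal(st$mean_steps, 4)
})

test_that("exact expected absorption times are correct on small machines", {
  expect_equal(exact_expected_time(line_program(2, 1))$expected_time, 1)
  expect_equal(exact_expected_time(line_program(5, 1))$expected_time,
               25 / 12)
  expect_equal(exact_expected_time(line_program(3, 2))$expected_time, 2.75)
  # harmonic numbers for single-turn lines
  for (n in c(4, 7, 9)) {
    expect_equal(exact_expected_time(line_program(n, 1))$expected_time,
                 sum(1 / seq_len(n - 1)))
  }
})

test_that("exact and sampled expectations agree within three sigma", {
  for (p in list(line_program(5, 2), line_program(4, 3))) {
    ex <- exact_expected_time(p)
    expect_equal(ex$p_target, 1)
    st <- completion_time_stats(p, 3000, seed = 17)
    se <- st$sd_time / sqrt(st$samples)
    expect_lt(abs(st$mean_time - ex$expected_time), 3 * se)
  }
})

test_that("blocked machines report absorption and blocking probability", {
  ex <- exact_expected_time(line_program(7, 6))
  expect_true(ex$has_blocked)
  expect_lt(ex$p_target, 1)
  expect_gt(ex$p_target, 0)
  expect_gt(ex$expected_time, 0)
})

test_that("mean completion time of triple-turn lines grows with length", {
  means <- vapply(c(4, 8, 16, 32), function(n) {
    completion_time_stats(line_program(n, 3), 400, seed = 23)$mean_time
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("trajectory logs hold one record per step", {
  tr <- sample_trajectory(line_program(6, 2), seed = 3)
  f <- tempfile(fileext = ".tsv")
  write_trajectory_log(tr, f)
  lines <- readLines(f)
  expect_equal(length(lines), tr$n_steps)
  last <- strsplit(lines[length(lines)], "\t")[[1]]
  expect_equal(as.integer(strsplit(last[4], ",")[[1]]),
               tr$final$moves)
})
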