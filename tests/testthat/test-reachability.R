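test_that("exhaustive search enumerates the single-turn line exactly", {
  rep <- explore(line_program(4, 1), return_vectors = TRUE)
  expect_equal(rep$reachable_count, 8)   # {0,1}^3 x {0}, none blocked
  expect_true(rep$foldable)
  expect_equal(nrow(rep$blocked_witnesses), 0)
  expect_equal(nrow(rep$vectors), 8)
  expect_true(all(rep$vectors[, 4] == 0))
})

test_that("reachability agrees with the independent oracle", {
  for (p in list(line_program(5, 2), random_program(5, 3, 31))) {
    rep <- explore(p, return_vectors = TRUE)
    orc <- orc_explore(p$states0)
    expect_equal(rep$reachable_count, nrow(orc))
    expect_setequal(apply(rep$vectors, 1, paste, collapse = ","),
                    apply(orc, 1, paste, collapse = ","))
  }
})

test_that("line rotations up to 5*pi/3 fold; 2*pi does not", {
  for (n in 3:7) {
    for (s in 1:5) {
      expect_true(explore(line_program(n, s))$foldable,
                  info = sprintf("L(%d,%d)", n, s))
    }
  }
  r6 <- explore(line_program(7, 6))
  expect_false(r6$foldable)
  expect_true(r6$target_reachable)   # some trajectories do complete
  # smaller 2*pi machines still fold
  for (n in 2:6) expect_true(explore(line_program(n, 6))$foldable)
})

test_that("the blocked 2*pi witness matches the known configuration", {
  r6 <- explore(line_program(7, 6), want_path = TRUE)
  w <- r6$blocked_witnesses
  known <- c(0, 2, 3, 4, 5, 6, 0)
  expect_true(any(apply(w, 1, function(z) all(z == known))))
  # every witness re-validates as permanently blocked
  for (r in seq_len(nrow(w))) {
    cf <- tm_configuration(line_program(7, 6), w[r, ])
    expect_true(is_permanently_blocked(cf))
  }
  # the witness path replays from the initial configuration to a blocked state
  cf <- replay_moves(tm_configuration(line_program(7, 6)), r6$witness_path)
  expect_true(is_permanently_blocked(cf))
})

test_that("foldable verdicts agree with seeded sampling", {
  for (p in list(line_program(6, 4), compile_zigzag(square_path(3)))) {
    expect_true(explore(p)$foldable)
    for (s in 1:50) {
      tr <- sample_trajectory(p, seed = s)
      expect_equal(tr$terminal, "target")
    }
  }
})

test_that("foldability verdicts combine reachability and folding error", {
  p4 <- compile_zigzag(square_path(4))
  sq4 <- synthesize_shape("square", n = 4)
  v <- foldability_verdict(p4, sq4)
  expect_true(v$foldable)
  expect_equal(v$error, 0)

  v6 <- foldability_verdict(line_program(7, 6),
                            target_configuration(line_program(7, 6))$positions)
  expect_false(v6$foldable)

  done <- tm_program(c(0, 0, 0))
  v0 <- foldability_verdict(done, tm_configuration(done)$positions)
  expect_true(v0$foldable)
  expect_equal(v0$error, 0)
})

test_that("the state cap truncates with an explicit unknown verdict", {
  rep <- explore(line_program(7, 5), state_cap = 100)
  expect_true(rep$truncated)
  expect_true(is.na(rep$foldable))
})
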