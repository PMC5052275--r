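test_that("simulated curves are reproducible from the master seed", {
  r <- rate_set(50, 50, 10)
  sim <- sim_config(2000, seq(-90, 120, 30), seed = 123)
  a <- simulate_curve(r, 80, sim)
  b <- simulate_curve(r, 80, sim)
  expect_identical(a, b)
  c <- simulate_curve(r, 80, sim_config(2000, seq(-90, 120, 30),
                                        seed = 124))
  expect_false(identical(a, c))
})

test_that("a near-instant probe wins almost every race", {
  set.seed(5)
  r <- rate_set(v_p = 1e6, v_r = 50, v_cp = 0)
  tr <- simulate_trials(r, trial_condition(-50, 40), 1e4)
  expect_gte(mean(tr$judgment == "probe_first"), 0.999)
})

test_that("symmetric racers hit one half within Monte Carlo error", {
  set.seed(6)
  r <- rate_set(45, 45, 0)
  tr <- simulate_trials(r, trial_condition(0, 40), 1e5)
  expect_lt(abs(mean(tr$judgment == "probe_first") - 0.5),
            4 * sqrt(0.25 / 1e5))
})

test_that("empirical frequencies agree with the closed form at every SOA", {
  r <- rate_set(40, 90, 12, v_neutral = 25)
  sim <- sim_config(1e5, c(-80, -20, 0, 30, 60, 100, 170), seed = 77)
  cur <- simulate_curve(r, 80, sim)
  p <- probe_first_probability(r, trial_condition(cur$soa_ms, 80))
  se <- sqrt(pmax(p * (1 - p), 1e-9) / cur$n)
  expect_true(all(abs(cur$k_probe_first / cur$n - p) < 4 * se + 1e-4))
})

test_that("no cue-caused percepts occur without a confusion rate", {
  r <- rate_set(50, 50, 0)
  cur <- simulate_curve(r, 140, sim_config(5000, c(-30, 0, 30), seed = 3))
  expect_true(all(cur$k_via_cue == 0))
})

test_that("Monte Carlo error shrinks roughly as the square root of the trial count", {
  r <- rate_set(50, 70, 8)
  p <- probe_first_probability(r, trial_condition(20, 80))
  errs <- vapply(c(1e3, 1e4, 1e5), function(n) {
    cur <- simulate_curve(r, 80, sim_config(n, 20, seed = 42))
    abs(cur$k_probe_first / cur$n - p)
  }, 0)
  se <- sqrt(p * (1 - p) / c(1e3, 1e4, 1e5))
  expect_true(all(errs < 4 * se))
})

test_that("refinements-off mode lets the cue fire after probe onset", {
  # an unwinnable probe isolates the cue route: censoring at probe onset
  # caps the capture probability at 1 - exp(-v_cp * coa), the uncensored
  # race exceeds it by the post-mask wins
  r <- rate_set(v_p = 0, v_r = 50, v_cp = 10, v_neutral = 25)
  set.seed(8)
  on <- mean(simulate_trials(r, trial_condition(0, 140), 3e4,
                             refinements_on = TRUE)$judgment ==
               "probe_first")
  set.seed(8)
  off <- mean(simulate_trials(r, trial_condition(0, 140), 3e4,
                              refinements_on = FALSE)$judgment ==
                "probe_first")
  expect_equal(on, cue_capture_probability(10, 140), tolerance = 0.02)
  expect_gt(off, on + 0.02)
})
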