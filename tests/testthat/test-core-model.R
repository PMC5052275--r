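test_that("symmetric racers give probability one half at zero SOA", {
  r <- rate_set(v_p = 50, v_r = 50, v_cp = 0)
  expect_equal(probe_first_probability(r, trial_condition(0, 140)), 0.5)
  expect_equal(probe_first_probability(r, trial_condition(0)), 0.5)
})

test_that("closed form reproduces the derived decomposition oracle", {
  # cue wins with 1 - exp(-v_cp * coa); otherwise the symmetric targets
  # split the remainder; verified independently by Monte Carlo below
  r <- rate_set(v_p = 50, v_r = 50, v_cp = 10)
  cond <- trial_condition(0, 140)
  expect_equal(probe_first_probability(r, cond), 0.8767, tolerance = 1e-3)
  d <- decompose_contributions(r, cond)
  expect_equal(d$p_via_cue, 0.7534, tolerance = 1e-3)
  expect_equal(d$p_via_probe, 0.1233, tolerance = 1e-3)
  set.seed(1)
  tr <- simulate_trials(r, cond, 1e6)
  expect_equal(mean(tr$judgment == "probe_first"), 0.8767,
               tolerance = 4 * sqrt(0.88 * 0.12 / 1e6) / 0.8767)
  expect_equal(mean(tr$cause == "cue"), 0.7534, tolerance = 3e-3)
})

test_that("extreme SOAs drive the probability to its limits", {
  r <- rate_set(v_p = 35, v_r = 55, v_cp = 0)
  expect_equal(probe_first_probability(r, trial_condition(-5000, 40)), 1,
               tolerance = 1e-6)
  expect_equal(probe_first_probability(r, trial_condition(5000, 40)), 0,
               tolerance = 1e-6)
})

test_that("cue capture probability follows the censored-window form", {
  expect_equal(cue_capture_probability(10, 140), 1 - exp(-1.4))
  expect_equal(cue_capture_probability(5, 0), 0)
  expect_equal(cue_capture_probability(0, 140), 0)
  # t0 shortens the window; monotone in rate and interval
  expect_lt(cue_capture_probability(10, 140, t0 = 15),
            cue_capture_probability(10, 140))
  expect_true(all(diff(cue_capture_probability(c(1, 5, 10, 20), 140)) > 0))
  expect_true(all(diff(cue_capture_probability(10, c(20, 60, 140))) > 0))
  expect_error(cue_capture_probability(-1, 100), "nonnegative")
})

test_that("overall rate sums concurrent race rates", {
  expect_equal(overall_rate(rate_set(29, 29, 0, v_neutral = 29),
                            no_cue = TRUE), 58)
  expect_equal(overall_rate(rate_set(58, 113, 10)), 181)
  expect_equal(overall_rate(rate_set(0, 0, 0)), 0)
  set.seed(3)
  for (i in 1:10) {
    v <- runif(3, 0, 150)
    expect_equal(overall_rate(rate_set(v[1], v[2], v[3])), sum(v))
  }
})

test_that("invalid rates, conditions, and arguments are rejected", {
  expect_error(rate_set(-1, 50, 0), "nonnegative")
  expect_error(rate_set(Inf, 50, 0), "finite")
  expect_error(rate_set(50, NA, 0), "finite")
  expect_error(trial_condition(0, coa = -5), "nonnegative")
  expect_error(trial_condition(NaN, 40), "finite")
  expect_error(trial_condition(0, 40, cld = -1), "nonnegative")
})

test_that("probability is bounded, monotone in SOA, and continuous at the regime boundaries", {
  set.seed(11)
  for (i in 1:15) {
    r <- rate_set(runif(1, 1, 120), runif(1, 1, 120), runif(1, 0, 25),
                  runif(1, 5, 60))
    coa <- runif(1, 0, 160)
    s <- seq(-250, 300, 2.5)
    p <- probe_first_probability(r, trial_condition(s, coa))
    expect_true(all(p >= 0 & p <= 1))
    expect_true(all(diff(p) <= 1e-12))
    # no discontinuity at the regime boundaries soa = 0 and soa = coa
    for (b in c(0, coa)) {
      gap <- diff(probe_first_probability(
        r, trial_condition(b + c(-1e-7, 1e-7), coa)))
      expect_lt(abs(gap), 1e-6)
    }
  }
})

test_that("a zero confusion rate with neutral target rates reproduces the no-cue curve", {
  vn <- 31
  r <- rate_set(v_p = vn, v_r = vn, v_cp = 0, v_neutral = vn)
  s <- seq(-180, 220, 7)
  expect_equal(probe_first_probability(r, trial_condition(s, 80)),
               probe_first_probability(r, trial_condition(s)),
               tolerance = 1e-12)
})

test_that("decomposition sums exactly to the total probability", {
  set.seed(21)
  for (i in 1:20) {
    r <- rate_set(runif(1, 1, 120), runif(1, 1, 120), runif(1, 0, 25),
                  runif(1, 5, 60), t0 = sample(c(0, 15), 1))
    cond <- trial_condition(runif(1, -200, 250), runif(1, 0, 160))
    d <- decompose_contributions(r, cond)
    expect_lt(abs(d$p_via_cue + d$p_via_probe -
                    probe_first_probability(r, cond)), 1e-10)
  }
})

test_that("the half-probability SOA shifts rightward with the cueing interval", {
  r <- rate_set(50, 50, 10)
  pss <- vapply(c(40, 80, 140), function(coa)
    pss_dl_from_rates(r, coa)$pss_ms, 0)
  expect_true(all(diff(pss) > 0))
})

test_that("the reference-regime config switch changes only reference-leads-cue trials", {
  r <- rate_set(60, 35, 8, v_neutral = 20)
  s <- seq(-100, 200, 10)
  p_switch <- probe_first_probability(r, trial_condition(s, 80),
                                      toj_config(reference_regime = "switch"))
  p_neutral <- probe_first_probability(r, trial_condition(s, 80),
                                       toj_config(reference_regime = "neutral"))
  expect_equal(p_switch[s <= 80], p_neutral[s <= 80])
  expect_false(isTRUE(all.equal(p_switch[s > 90], p_neutral[s > 90])))
})

test_that("model configuration survives a JSON round trip", {
  cfg <- toj_config(t0 = 15, reference_regime = "neutral")
  back <- toj_config_from_json(toj_config_json(cfg))
  expect_equal(back$t0, 15)
  expect_equal(back$reference_regime, "neutral")
  cfg0 <- toj_config_from_json(toj_config_json(toj_config()))
  expect_null(cfg0$t0)
})
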