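test_that("symmetric rates put the point of subjective simultaneity at zero", {
  out <- pss_dl_from_rates(rate_set(50, 50, 0))
  expect_equal(out$pss_ms, 0, tolerance = 1e-3)
  expect_gt(out$dl_ms, 0)
})

test_that("model-curve PSS matches a Monte Carlo bisection within two milliseconds", {
  r <- rate_set(50, 50, 10)
  pss <- pss_dl_from_rates(r, coa = 140)$pss_ms
  grid <- seq(floor(pss) - 10, ceiling(pss) + 10, 2)
  cur <- simulate_curve(r, 140, sim_config(2e4, grid, seed = 17))
  emp <- fit_classic_curve(data.frame(soa_ms = cur$soa_ms,
                                      n_trials = cur$n,
                                      n_probe_first = cur$k_probe_first))
  expect_lt(abs(emp$pss_ms - pss), 2)
})

test_that("a curve that never crosses one half is flagged, not guessed", {
  # overwhelming confusion rate: probability stays above 0.5 everywhere
  out <- pss_dl_from_rates(rate_set(5, 200, 200), coa = 500,
                           soa_range = c(-400, 400))
  expect_false(out$ok)
  expect_true(is.na(out$pss_ms))
})

test_that("the logistic fit recovers parameters of logistic-generated counts", {
  set.seed(23)
  soa <- seq(-120, 180, 30)
  pss0 <- 42; slope0 <- -0.035
  p <- plogis(slope0 * (soa - pss0))
  counts <- data.frame(soa_ms = soa, n_trials = 2000,
                       n_probe_first = rbinom(length(soa), 2000, p))
  fit <- fit_classic_curve(counts)
  expect_true(fit$ok)
  expect_lt(abs(fit$pss_ms - pss0), 4)
  expect_lt(abs(fit$dl_ms - log(3) / abs(slope0)) / (log(3) / abs(slope0)),
            0.1)
  # symmetric counts give a PSS near zero
  p2 <- plogis(-0.03 * soa)
  sym <- data.frame(soa_ms = soa, n_trials = 2000,
                    n_probe_first = rbinom(length(soa), 2000, p2))
  expect_lt(abs(fit_classic_curve(sym)$pss_ms), 5)
})

test_that("degenerate count patterns are flagged failures", {
  soa <- c(-30, 0, 30)
  allzero <- data.frame(soa_ms = soa, n_trials = 20, n_probe_first = 0)
  expect_false(fit_classic_curve(allzero)$ok)
  allone <- data.frame(soa_ms = soa, n_trials = 20, n_probe_first = 20)
  expect_false(fit_classic_curve(allone)$ok)
  expect_error(fit_classic_curve(allzero[1:2, ]), "3 SOA")
})

test_that("a reference-rate advantage is concealed by cue-probe confusions in the classic analysis", {
  # generate-and-fit: v_r > v_p yet the classic curve shifts rightward
  set.seed(29)
  r <- rate_set(58, 113, 10, v_neutral = 29)
  soa <- seq(-60, 180, 30)
  p <- probe_first_probability(r, trial_condition(soa, 140))
  counts <- data.frame(soa_ms = soa, n_trials = 1500,
                       n_probe_first = rbinom(length(soa), 1500, p))
  fit <- fit_classic_curve(counts)
  expect_true(fit$ok)
  expect_gt(fit$pss_ms, 0)
})

test_that("the decomposition is consistent with the censored two-racer reduction", {
  # the probe-route term must equal (1 - capture) times the probability
  # of the same race with the confusion rate removed
  r <- rate_set(58, 113, 10, v_neutral = 29)
  r0 <- rate_set(58, 113, 0, v_neutral = 29)
  s <- seq(-150, 200, 5)
  d <- decompose_contributions(r, trial_condition(s, 140))
  kap <- cue_capture_probability(10, 140)
  p0 <- probe_first_probability(r0, trial_condition(s, 140))
  expect_equal(d$p_via_probe, (1 - kap) * p0, tolerance = 1e-10)
})

test_that("report rendering writes figures and tables, and rejects missing fits", {
  fit <- cached_small_fit()$fit
  dir <- file.path(tempdir(), "toj_reports")
  files <- render_reports(fit, dir, ndraws = 60)
  expect_true(all(file.exists(files)))
  expect_true(all(file.size(files) > 0))
  expect_true(any(grepl("\\.pdf$", files)))
  expect_true(any(grepl("\\.csv$", files)))
  unlink(dir, recursive = TRUE)
  expect_error(render_reports(NULL, dir), "toj_fit")
})
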