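bad_dataset <- function(k, n) {
  tibble::tibble(subject_id = 1L, condition_label = "no_cue",
                 soa_ms = c(-30, 30), coa_ms = NA_real_, cld_px = NA_real_,
                 n_trials = n, n_probe_first = k)
}

test_that("datasets violating the count and identifiability invariants are rejected", {
  expect_error(validate_toj_dataset(bad_dataset(k = c(5, 12), n = 10)),
               "k <= n")
  expect_error(fit_toj(bad_dataset(k = c(5, 12), n = 10)), "k <= n")
  expect_error(validate_toj_dataset(bad_dataset(k = 1, n = 10)[0, ]),
               "empty")
  one_soa <- bad_dataset(k = c(5, 5), n = 10)
  one_soa$soa_ms <- c(0, 0)
  expect_error(validate_toj_dataset(one_soa), "2 distinct SOAs")
  two_nocue <- rbind(bad_dataset(5, 10),
                     transform(bad_dataset(5, 10),
                               condition_label = "no_cue_b"))
  expect_error(validate_toj_dataset(two_nocue), "one no-cue")
})

test_that("the hierarchical fit returns coherent summaries and diagnostics", {
  cf <- cached_small_fit()
  fit <- cf$fit
  s <- summary(fit)
  expect_equal(nrow(s), 4)  # v_neutral + three cued families
  expect_true(all(is.finite(s$mean_hz)))
  expect_true(all(s$hdi_lower <= s$mean_hz & s$mean_hz <= s$hdi_upper))
  expect_true(all(s$mean_hz > 0))
  expect_true(all(is.finite(fit$diagnostics$rhat)))
  expect_true(all(fit$diagnostics$ess > 0))
  # subject draws strictly positive on the rate scale
  expect_true(all(subject_rate_draws(fit, "v_p", 1, "cued") > 0))
  # summaries recomputable from stored draws
  dr <- group_rate_draws(fit, "v_neutral")
  expect_equal(mean(dr), s$mean_hz[s$family == "v_neutral"])
})

test_that("contrasts are zero against themselves and antisymmetric", {
  fit <- cached_small_fit()$fit
  self <- contrast(fit, "v_p", "v_p", condition = "cued")
  expect_equal(self$mean, 0)
  expect_equal(self$hdi_lower, 0)
  expect_equal(self$hdi_upper, 0)
  ab <- contrast(fit, "v_p", "v_r", condition = "cued")
  ba <- contrast(fit, "v_r", "v_p", condition = "cued")
  expect_equal(ab$mean, -ba$mean)
  expect_equal(ab$hdi_lower, -ba$hdi_upper)
  expect_error(contrast(fit, "v_p", "v_q", condition = "cued"), "unknown")
})

test_that("posterior predictive bands are proper count bands", {
  fit <- cached_small_fit()$fit
  pp <- posterior_predict(fit, ndraws = 120)
  expect_true(all(pp$k_lower >= 0))
  expect_true(all(pp$k_upper <= pp$n_trials))
  expect_true(all(pp$k_lower <= pp$k_median & pp$k_median <= pp$k_upper))
  expect_true(all(pp$p_mean >= 0 & pp$p_mean <= 1))
  # bands generally contain the observations that generated the fit
  inside <- mean(pp$n_probe_first >= pp$k_lower &
                   pp$n_probe_first <= pp$k_upper)
  expect_gt(inside, 0.9)
})

test_that("subject-level neutral rates shrink from their no-pooling estimates toward the group mean", {
  cf <- cached_small_fit()
  fit <- cf$fit
  dat <- cf$fixture$data
  group <- mean(group_rate_draws(fit, "v_neutral"))
  subjects <- sort(unique(dat$subject_id))
  closer <- vapply(subjects, function(id) {
    rows <- dat[dat$subject_id == id & is.na(dat$coa_ms), ]
    nll <- function(v) {
      p <- probe_first_probability(rate_set(v, v, 0, v_neutral = v),
                                   trial_condition(rows$soa_ms))
      p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
      -sum(rows$n_probe_first * log(p) +
             (rows$n_trials - rows$n_probe_first) * log(1 - p))
    }
    mle <- optimize(nll, c(1, 200))$minimum
    post <- mean(subject_rate_draws(fit, "v_neutral", id))
    abs(post - group) <= abs(mle - group) + 0.5
  }, TRUE)
  expect_gte(mean(closer), 5 / 6)
})

test_that("symmetric generating rates leave the probe-reference contrast centred on zero", {
  fx <- small_toj_dataset(v_p = 40, v_r = 40, v_cp = 5, n_subjects = 6,
                          seed = 31)
  fit <- suppressWarnings(fit_toj(
    fx$data, "full",
    mcmc = mcmc_control(chains = 3, warmup = 800, iter = 800, seed = 13)))
  ct <- contrast(fit, "v_p", "v_r", condition = "cued")
  expect_true(ct$hdi_lower < 0 && ct$hdi_upper > 0)
})

test_that("the posterior couples the rate difference and the confusion rate negatively", {
  fit <- cached_small_fit()$fit
  dvp <- group_rate_draws(fit, "v_p", "cued") -
    group_rate_draws(fit, "v_r", "cued")
  dvcp <- group_rate_draws(fit, "v_cp", "cued")
  expect_lt(cor(dvp, dvcp), 0)
})

test_that("an under-sampled fit is flagged rather than silently accepted", {
  fx <- small_toj_dataset(n_subjects = 4, seed = 55)
  expect_warning(
    fit <- fit_toj(fx$data, "full",
                   mcmc = mcmc_control(chains = 3, warmup = 10, iter = 20,
                                       seed = 2)),
    "R-hat")
  expect_false(fit$converged)
})

test_that("the disadvantageous cueing phenotype is identified from the fit", {
  d <- two_condition_design("coa_140", 140, n_subjects = 10)
  spec <- population_spec(
    rates = data.frame(condition = "coa_140", v_p = 58, v_r = 113,
                       v_cp = 10),
    v_neutral = 29, sdlog = 0.15,
    phenotype_weights = c(beneficial = 0.5, disadvantageous = 0.5))
  pop <- sample_population(spec, 10, seed = 41)
  dat <- generate_dataset(d, pop, seed = 42)
  fit <- suppressWarnings(fit_toj(
    dat, "full",
    mcmc = mcmc_control(chains = 2, warmup = 800, iter = 800, seed = 6)))
  cls <- classify_subjects(fit)
  truth <- unique(as.data.frame(pop)[c("subject_id", "phenotype")])
  truth <- truth[order(truth$subject_id), ]
  agree <- mean(cls$disadvantageous ==
                  (truth$phenotype == "disadvantageous"))
  expect_gte(agree, 0.8)
  expect_error(classify_subjects(
    suppressWarnings(fit_toj(dat, "rates_only",
                             mcmc = mcmc_control(chains = 2, warmup = 200,
                                                 iter = 200, seed = 1)))),
    "full variant")
})
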