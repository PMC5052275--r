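test_that("a degenerate hierarchy collapses all subjects onto the group rates", {
  spec <- population_preset("exp1", sdlog = 0,
                            phenotype_weights = c(beneficial = 1,
                                                  disadvantageous = 0))
  pop <- sample_population(spec, 5, seed = 1)
  expect_true(all(pop$v_neutral == 29))
  expect_equal(unique(pop$v_p[pop$condition == "coa_80"]), 69)
  expect_equal(unique(pop$v_r[pop$condition == "coa_140"]), 113)
})

test_that("population sampling is seed-reproducible and validated", {
  spec <- population_preset("exp1")
  expect_identical(sample_population(spec, 8, seed = 4),
                   sample_population(spec, 8, seed = 4))
  expect_error(population_spec(
    rates = data.frame(condition = "a", v_p = 30, v_r = 30, v_cp = 2),
    phenotype_weights = c(beneficial = 0.7, disadvantageous = 0.7)),
    "sum to 1")
  expect_error(population_spec(
    rates = data.frame(condition = "a", v_p = -3, v_r = 30, v_cp = 2)),
    "nonnegative")
})

test_that("generated counts satisfy the dataset invariants and track the generating curve", {
  d <- make_design("exp1")
  spec <- population_preset("exp1", sdlog = 0,
                            phenotype_weights = c(beneficial = 1,
                                                  disadvantageous = 0))
  pop <- sample_population(spec, 12, seed = 2)
  dat <- generate_dataset(d, pop, seed = 3)
  expect_s3_class(dat, "toj_dataset")
  expect_true(all(dat$n_probe_first >= 0 & dat$n_probe_first <= dat$n_trials))
  expect_silent(validate_toj_dataset(dat))
  # with zero spread the pooled frequency per cell is binomial around the
  # closed-form probability
  r <- rate_set(69, 19, 8, v_neutral = 29)
  cell <- dat[dat$condition_label == "coa_80", ]
  agg <- aggregate(cbind(n_trials, n_probe_first) ~ soa_ms, cell, sum)
  p <- probe_first_probability(r, trial_condition(agg$soa_ms, 80))
  se <- sqrt(pmax(p * (1 - p), 1e-9) / agg$n_trials)
  expect_true(all(abs(agg$n_probe_first / agg$n_trials - p) < 4 * se + 1e-3))
})

test_that("datasets survive a CSV round trip with provenance", {
  fx <- small_toj_dataset(n_subjects = 3, seed = 10)
  path <- tempfile(fileext = ".csv")
  write_toj_dataset(fx$data, path, provenance = list(seed = 10))
  back <- read_toj_dataset(path)
  expect_equal(as.data.frame(back), as.data.frame(fx$data))
  expect_true(file.exists(paste0(path, ".json")))
  expect_equal(jsonlite::fromJSON(paste0(path, ".json"))$seed, 10)
  unlink(c(path, paste0(path, ".json")))
})

test_that("zero-repetition cells yield zero counts", {
  conds <- data.frame(condition = c("no_cue", "c1"), coa_ms = c(NA, 80),
                      cld_px = c(NA, 0))
  reps <- data.frame(condition = rep(c("no_cue", "c1"), each = 3),
                     soa_ms = rep(c(-30, 0, 30), 2),
                     n_trials = c(5, 0, 5, 5, 5, 5))
  d <- make_design("custom", conditions = conds, repetitions = reps,
                   n_subjects = 2)
  spec <- population_spec(rates = data.frame(condition = "c1", v_p = 40,
                                             v_r = 40, v_cp = 5))
  pop <- sample_population(spec, 2, seed = 1)
  dat <- generate_dataset(d, pop, seed = 1)
  zero <- dat[dat$condition_label == "no_cue" & dat$soa_ms == 0, ]
  expect_true(all(zero$n_probe_first == 0L))
})

test_that("phenotypes shift the classic psychometric curve in opposite directions", {
  d <- make_design("exp1")
  pooled_pss <- function(weights, seed) {
    spec <- population_preset("exp1", sdlog = 0.1,
                              phenotype_weights = weights)
    pop <- sample_population(spec, 12, seed = seed)
    dat <- generate_dataset(d, pop, seed = seed + 1)
    vapply(c("no_cue", "coa_40", "coa_80", "coa_140"), function(cn) {
      agg <- aggregate(cbind(n_trials, n_probe_first) ~ soa_ms,
                       dat[dat$condition_label == cn, ], sum)
      fit_classic_curve(agg)$pss_ms
    }, 0)
  }
  ben <- pooled_pss(c(beneficial = 1, disadvantageous = 0), 20)
  dis <- pooled_pss(c(beneficial = 0, disadvantageous = 1), 30)
  # beneficial phenotype: PSS grows with COA (rightward shifts);
  # disadvantageous: cued PSS at or left of the neutral PSS
  expect_true(all(diff(ben) > 0))
  expect_true(all(dis[c("coa_80", "coa_140")] < dis["no_cue"]))
})
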