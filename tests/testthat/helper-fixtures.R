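# Shared fixtures: small synthetic designs and a cached hierarchical fit
# so that several test files can reuse one MCMC run.

two_condition_design <- function(cond, coa_ms, cld_px = 0, n_subjects = 8,
                                 reps_row = cond) {
  base <- as.data.frame(make_design("exp1")$trials)
  reps <- base[base$condition %in% c("no_cue", reps_row), ]
  reps$condition[reps$condition == reps_row] <- cond
  make_design("custom",
              conditions = data.frame(condition = c("no_cue", cond),
                                      coa_ms = c(NA, coa_ms),
                                      cld_px = c(NA, cld_px)),
              repetitions = reps, n_subjects = n_subjects)
}

small_toj_dataset <- function(v_p = 60, v_r = 30, v_cp = 6, v_neutral = 29,
                              n_subjects = 6, coa = 80, seed = 42,
                              sdlog = 0.2) {
  d <- two_condition_design("cued", coa, n_subjects = n_subjects,
                            reps_row = sprintf("coa_%d", coa))
  spec <- population_spec(
    rates = data.frame(condition = "cued", v_p = v_p, v_r = v_r,
                       v_cp = v_cp),
    v_neutral = v_neutral, sdlog = sdlog,
    phenotype_weights = c(beneficial = 1, disadvantageous = 0))
  pop <- sample_population(spec, n_subjects, seed = seed)
  list(design = d, population = pop,
       data = generate_dataset(d, pop, seed = seed + 1))
}

.fit_cache <- new.env(parent = emptyenv())

# one modest hierarchical fit shared by the inference / reporting tests
cached_small_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    fx <- small_toj_dataset(n_subjects = 6, seed = 7)
    .fit_cache$fixture <- fx
    .fit_cache$fit <- suppressWarnings(fit_toj(
      fx$data, "full",
      mcmc = mcmc_control(chains = 3, warmup = 800, iter = 800,
                          seed = 99)))
  }
  list(fit = .fit_cache$fit, fixture = .fit_cache$fixture)
}
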