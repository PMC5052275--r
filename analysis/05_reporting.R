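#!/usr/bin/env Rscript
# Figures and psychometric summaries for the fitted COA experiment (runs
# 02 and 03 are prerequisites only for the dataset; the fit is redone
# here at reduced length for the figure set): posterior density panels,
# normalized posterior predictive curves, the cue-contribution
# decomposition, and the concealment comparison of classic PSS shifts
# versus fitted rate contrasts.

suppressMessages({library(cuedtoj); library(dplyr)})

dat <- read_toj_dataset("results/data_exp1.csv")
fit <- fit_toj(dat, "full",
               mcmc = mcmc_control(chains = 3, warmup = 1500, iter = 1500,
                                   seed = 55))
files <- render_reports(fit, "results/figures", ndraws = 200)
cat("wrote:\n"); cat(paste(" ", files, collapse = "\n"), "\n")

# classic psychometric summaries per condition (pooled over subjects)
classic <- bind_rows(lapply(unique(dat$condition_label), function(cn) {
  agg <- dat %>% filter(condition_label == cn) %>% group_by(soa_ms) %>%
    summarise(n_trials = sum(n_trials),
              n_probe_first = sum(n_probe_first), .groups = "drop")
  mutate(fit_classic_curve(agg), condition = cn)
}))
write.csv(as.data.frame(classic), "results/classic_pss_dl.csv",
          row.names = FALSE)
cat("\nclassic logistic PSS/DL per condition (pooled):\n")
print(classic %>% select(condition, pss_ms, dl_ms, ok))

ct <- contrast(fit, "v_r", "v_p", condition = "coa_140")
cat(sprintf(
  "\nConcealment: classic PSS at COA 140 is %+.0f ms (rightward) while\n",
  classic$pss_ms[classic$condition == "coa_140"]))
cat(sprintf(
  "the fitted reference-probe contrast is %+.0f Hz [%.0f, %.0f] —\n",
  ct$mean, ct$hdi_lower, ct$hdi_upper))
cat("the cue's inhibition-of-return disadvantage for the probe is\n")
cat("invisible in the classic analysis because cue-probe confusions\n")
cat("overcompensate it.\n")
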