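#!/usr/bin/env Rscript
# Closed-form and simulated psychometric curves of the cued-TOJ race
# model: equal target rates (50 Hz), a 10 Hz cue-as-probe rate, and three
# cue onset asynchronies. The rightward shift of the curves — growing
# with COA although every rate is constant — comes entirely from trials
# in which the cue is encoded as the probe. Also tabulates the capture
# probabilities behind that shift.

suppressMessages({library(cuedtoj); library(dplyr)})
dir.create("results", showWarnings = FALSE)

r <- rate_set(v_p = 50, v_r = 50, v_cp = 10)
grid <- seq(-150, 200, 2)

curves <- bind_rows(lapply(c(NA, 40, 80, 140), function(coa) {
  lab <- if (is.na(coa)) "no_cue" else sprintf("coa_%d", coa)
  d <- decompose_contributions(r, trial_condition(grid, coa))
  d$condition <- lab
  d$p_probe_first <- d$p_via_cue + d$p_via_probe
  d
}))
write.csv(curves, "results/model_curves.csv", row.names = FALSE)

sim <- bind_rows(lapply(c(40, 80, 140), function(coa) {
  cur <- simulate_curve(r, coa,
                        sim_config(1e4, seq(-150, 150, 5), seed = 7))
  cur$condition <- sprintf("coa_%d", coa)
  cur
}))
write.csv(sim, "results/simulated_curves.csv", row.names = FALSE)

pss <- bind_rows(lapply(c(40, 80, 140), function(coa)
  mutate(pss_dl_from_rates(r, coa), coa_ms = coa)))
cap <- tibble(v_cp = c(10, 10, 10, 20), coa_ms = c(40, 80, 140, 140),
              capture = cue_capture_probability(v_cp, coa_ms))
write.csv(pss, "results/model_pss.csv", row.names = FALSE)
write.csv(cap, "results/capture_probabilities.csv", row.names = FALSE)

cat("PSS by COA (ms):\n"); print(pss)
cat(sprintf(
  "capture probability at 10 Hz over 140 ms: %.1f%%; at 20 Hz: %.1f%%\n",
  100 * cue_capture_probability(10, 140),
  100 * cue_capture_probability(20, 140)))
cat("Curves shift rightward with COA at constant rates: the shift is",
    "carried by cue-as-probe categorizations (p_via_cue).\n")
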