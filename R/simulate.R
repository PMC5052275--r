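#' Simulation configuration
#'
#' @param n_per_soa trials to simulate at each SOA (positive integer).
#' @param soa_grid SOA values in ms.
#' @param seed master seed; each SOA uses an independent substream derived
#'   from it, so results do not depend on how the grid is chunked.
#' @param refinements_on if `TRUE` (default) the cue race is censored at
#'   probe onset and the reference uses the pre-cue neutral-rate regime;
#'   `FALSE` reproduces the plain illustrative race algorithm (uncensored
#'   cue, reference always at `v_r`).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_per_soa, soa_grid, seed = 1L,
                       refinements_on = TRUE) {
  stopifnot(length(n_per_soa) == 1L, is.finite(n_per_soa), n_per_soa >= 1,
            length(soa_grid) >= 1L, all(is.finite(soa_grid)),
            length(seed) == 1L, is.finite(seed))
  structure(list(n_per_soa = as.integer(n_per_soa),
                 soa_grid = as.numeric(soa_grid), seed = as.integer(seed),
                 refinements_on = isTRUE(refinements_on)),
            class = "sim_config")
}

rexp_or_inf <- function(n, rate) {
  if (rate <= 0) rep(Inf, n) else rexp(n, rate)
}

# substream seed for the i-th SOA of a curve (kept below 2^31)
substream_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483629 + 7919 * i) %% 2147483629 + 1)
}

#' Simulate trial-level races
#'
#' Draws encoding times `T_r ~ Exp(v_r)` (piecewise `v_neutral`/`v_r` under
#' the refinement regime), `T_p ~ Exp(v_p)`, `T_cp ~ Exp(v_cp)` and counts
#' a "probe first" percept when the probe or a (non-censored) cue-as-probe
#' categorization completes before the reference. Uses the current R RNG
#' stream; call `set.seed()` first for reproducibility.
#'
#' @param rates a [rate_set()].
#' @param cond a [trial_condition()] with scalar `soa`.
#' @param n number of trials.
#' @param refinements_on see [sim_config()].
#' @param config a [toj_config()].
#' @return A tibble with one row per trial: `judgment`
#'   (`"probe_first"`/`"reference_first"`) and `cause`
#'   (`"probe"`, `"cue"`, or `"none"` — the earliest racer responsible for
#'   a probe-first percept).
#' @export
simulate_trials <- function(rates, cond, n, refinements_on = TRUE,
                            config = toj_config()) {
  stopifnot(inherits(rates, "rate_set"), inherits(cond, "trial_condition"),
            length(cond$soa) == 1L, n >= 1)
  nocue <- is.na(cond$coa)
  t0 <- (config$t0 %||% rates$t0) / 1000
  soa <- cond$soa / 1000
  coa <- if (nocue) 0 else cond$coa / 1000
  vp <- if (nocue) rates$v_neutral else rates$v_p
  vr <- if (nocue) rates$v_neutral else rates$v_r
  vcp <- if (nocue) 0 else rates$v_cp

  # reference encoding time in its race time (starts t0 after onset)
  if (refinements_on && !nocue) {
    d <- if (config$reference_regime == "switch") {
      max(soa - coa - t0, 0)
    } else if (soa > coa) Inf else 0
    if (d > 0) {
      t1 <- rexp_or_inf(n, rates$v_neutral)
      t_r <- ifelse(t1 < d, t1, d + rexp_or_inf(n, vr))
    } else {
      t_r <- rexp_or_inf(n, vr)
    }
  } else {
    t_r <- rexp_or_inf(n, vr)
  }
  t_p <- soa + rexp_or_inf(n, vp)
  t_cp_raw <- rexp_or_inf(n, vcp)
  cue_valid <- if (refinements_on) t_cp_raw < pmax(coa - t0, 0) else
    rep(TRUE, n)
  t_cp <- ifelse(cue_valid, soa - coa + t_cp_raw, Inf)

  cue_wins <- t_cp < t_r
  probe_wins <- t_p < t_r
  p1st <- cue_wins | probe_wins
  cause <- ifelse(!p1st, "none",
                  ifelse(cue_wins & (!probe_wins | t_cp < t_p),
                         "cue", "probe"))
  tibble::tibble(
    judgment = ifelse(p1st, "probe_first", "reference_first"),
    cause = cause)
}

#' Simulate an empirical psychometric curve
#'
#' Runs [simulate_trials()] at every SOA of the grid with independent,
#' seed-derived substreams and tabulates "probe first" counts and the
#' number of those caused by cue-as-probe categorizations.
#'
#' @param rates a [rate_set()].
#' @param coa cue onset asynchrony in ms (`NA` for the no-cue condition).
#' @param sim a [sim_config()].
#' @param config a [toj_config()].
#' @return A tibble with columns `soa_ms`, `n`, `k_probe_first`,
#'   `k_via_cue`.
#' @export
simulate_curve <- function(rates, coa, sim, config = toj_config()) {
  stopifnot(inherits(sim, "sim_config"))
  if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
  res <- lapply(seq_along(sim$soa_grid), function(i) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(substream_seed(sim$seed, i))
    tr <- simulate_trials(rates, trial_condition(sim$soa_grid[i], coa),
                          sim$n_per_soa, sim$refinements_on, config)
    tibble::tibble(soa_ms = sim$soa_grid[i], n = sim$n_per_soa,
                   k_probe_first = sum(tr$judgment == "probe_first"),
                   k_via_cue = sum(tr$cause == "cue"))
  })
  dplyr::bind_rows(res)
}
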