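#' Point of subjective simultaneity and difference limen from model rates
#'
#' Root-finds the closed-form psychometric curve: the PSS is the SOA at
#' which the "probe first" probability crosses 0.5, the DL half the
#' distance between two configurable quantile SOAs (default the 25% and
#' 75% points).
#'
#' @param rates a [rate_set()].
#' @param coa cue onset asynchrony in ms (`NA` for no cue).
#' @param config a [toj_config()].
#' @param quantiles probability levels defining the DL interval.
#' @param soa_range search interval in ms.
#' @return A one-row tibble: `pss_ms`, `dl_ms`, `ok`, `source`. When the
#'   curve does not cross a level inside `soa_range`, the corresponding
#'   value is `NA` and `ok` is `FALSE`.
#' @export
pss_dl_from_rates <- function(rates, coa = NA_real_,
                              config = toj_config(),
                              quantiles = c(0.25, 0.75),
                              soa_range = c(-1000, 1000)) {
  f <- function(s) probe_first_probability(
    rates, trial_condition(s, coa), config)
  solve_level <- function(q) {
    lo <- f(soa_range[1]); hi <- f(soa_range[2])
    if (lo < q || hi > q) return(NA_real_)
    uniroot(function(s) f(s) - q, soa_range, tol = 1e-6)$root
  }
  pss <- solve_level(0.5)
  s_hi <- solve_level(min(quantiles))  # lower prob -> larger SOA
  s_lo <- solve_level(max(quantiles))
  dl <- if (is.na(s_hi) || is.na(s_lo)) NA_real_ else (s_hi - s_lo) / 2
  tibble::tibble(pss_ms = pss, dl_ms = dl,
                 ok = !is.na(pss), source = "model_rates")
}

#' Classic logistic psychometric fit to "probe first" counts
#'
#' Maximum-likelihood logistic (binomial GLM) fit of the psychometric
#' function, the traditional analysis the race model replaces. Summary
#' parameters: `pss_ms` (SOA of the 0.5 crossing) and `dl_ms` (half the
#' interquantile SOA spread).
#'
#' @param counts a data frame with columns `soa_ms`, `n_trials`,
#'   `n_probe_first` (at least three SOA levels with trials).
#' @param quantiles probability levels defining the DL interval.
#' @return A one-row tibble: `pss_ms`, `dl_ms`, `slope`, `intercept`,
#'   `ok`, `source`. Degenerate data (all responses 0 or all at ceiling)
#'   yield a flagged failure (`ok = FALSE`).
#' @export
fit_classic_curve <- function(counts, quantiles = c(0.25, 0.75)) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("soa_ms", "n_trials", "n_probe_first") %in%
                  names(counts)))
  counts <- dplyr::filter(counts, .data$n_trials > 0)
  if (dplyr::n_distinct(counts$soa_ms) < 3) {
    stop("need >= 3 SOA levels with trials", call. = FALSE)
  }
  fail <- tibble::tibble(pss_ms = NA_real_, dl_ms = NA_real_,
                         slope = NA_real_, intercept = NA_real_,
                         ok = FALSE, source = "logistic_fit")
  if (all(counts$n_probe_first == 0) ||
      all(counts$n_probe_first == counts$n_trials)) {
    return(fail)
  }
  m <- tryCatch(
    glm(cbind(n_probe_first, n_trials - n_probe_first) ~ soa_ms,
        family = binomial(), data = counts),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(m)) {
    m <- suppressWarnings(
      glm(cbind(n_probe_first, n_trials - n_probe_first) ~ soa_ms,
          family = binomial(), data = counts))
  }
  b <- coef(m)
  if (any(!is.finite(b)) || abs(b[2]) < 1e-12) return(fail)
  pss <- -b[1] / b[2]
  dl <- abs(qlogis(max(quantiles)) - qlogis(min(quantiles))) /
    (2 * abs(b[2]))
  tibble::tibble(pss_ms = pss, dl_ms = dl, slope = unname(b[2]),
                 intercept = unname(b[1]), ok = TRUE,
                 source = "logistic_fit")
}

#' Render figure and table reports for a fitted model
#'
#' Writes (1) group-level posterior density panels with 95% HDI brackets,
#' (2) subject-level posterior predictive curves over the raw data,
#' normalized into the range zero to one, (3) model psychometric curves
#' with the cue-as-probe contribution as a shaded area, and (4) CSV
#' summary tables.
#'
#' @param fit a [fit_toj()] result.
#' @param dir output directory (created if missing).
#' @param subjects subject ids for the predictive panels (default: up to
#'   four).
#' @param ndraws posterior draws for the predictive bands.
#' @return Character vector of the files written, invisibly.
#' @export
render_reports <- function(fit, dir, subjects = NULL, ndraws = 200) {
  if (!inherits(fit, "toj_fit")) {
    stop("`fit` must be a toj_fit", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()

  # 1. group-level posterior densities
  g <- fit$groups
  dens <- dplyr::bind_rows(lapply(seq_len(nrow(g)), function(i) {
    tibble::tibble(
      family = g$family[i],
      condition = ifelse(is.na(g$condition[i]), "no_cue", g$condition[i]),
      rate_hz = group_rate_draws(fit, g$family[i],
                                 if (is.na(g$condition[i])) NULL else
                                   g$condition[i]))
  }))
  hdis <- dplyr::bind_rows(lapply(split(dens,
                                        dens[c("family", "condition")]),
                                  function(d) {
    if (nrow(d) == 0) return(NULL)
    h <- hdi(d$rate_hz)
    tibble::tibble(family = d$family[1], condition = d$condition[1],
                   lower = h[["lower"]], upper = h[["upper"]])
  }))
  p1 <- ggplot2::ggplot(dens, ggplot2::aes(x = .data$rate_hz)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::geom_segment(data = hdis,
                          ggplot2::aes(x = .data$lower, xend = .data$upper,
                                       y = 0, yend = 0),
                          linewidth = 1.2, colour = "black") +
    ggplot2::facet_grid(condition ~ family, scales = "free") +
    ggplot2::labs(x = "rate (Hz)", y = "posterior density")
  f <- file.path(dir, "group_rate_densities.pdf")
  ggplot2::ggsave(f, p1, width = 9, height = 7)
  files <- c(files, f)

  # 2. posterior predictive curves, normalized to [0, 1]
  pp <- posterior_predict(fit, ndraws = ndraws)
  subjects <- subjects %||% utils::head(sort(unique(pp$subject_id)), 4)
  pps <- dplyr::filter(pp, .data$subject_id %in% subjects,
                       .data$n_trials > 0)
  p2 <- ggplot2::ggplot(pps, ggplot2::aes(x = .data$soa_ms)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$k_lower / .data$n_trials,
      ymax = .data$k_upper / .data$n_trials), fill = "grey75") +
    ggplot2::geom_line(ggplot2::aes(y = .data$p_mean)) +
    ggplot2::geom_point(ggplot2::aes(
      y = .data$n_probe_first / .data$n_trials), size = 0.8) +
    ggplot2::facet_grid(subject_id ~ condition_label) +
    ggplot2::labs(x = "SOA (ms)", y = "p(probe first)") +
    ggplot2::coord_cartesian(ylim = c(0, 1))
  f <- file.path(dir, "posterior_predictive.pdf")
  ggplot2::ggsave(f, p2, width = 9, height = 7)
  files <- c(files, f)

  # 3. decomposition of the group-mean model curves
  smry <- summary(fit)
  cued <- dplyr::filter(smry, !is.na(.data$condition))
  vn <- smry$mean_hz[smry$family == "v_neutral"][1]
  soa_grid <- seq(-150, 200, by = 2)
  cond_meta <- dplyr::distinct(
    fit$row_meta[c("condition_label", "coa_ms")])
  dec <- dplyr::bind_rows(lapply(unique(cued$condition), function(cn) {
    get_rate <- function(fam, default) {
      v <- cued$mean_hz[cued$condition == cn & cued$family == fam]
      if (length(v) == 0) default else v
    }
    r <- rate_set(v_p = get_rate("v_p", vn), v_r = get_rate("v_r", vn),
                  v_cp = get_rate("v_cp", 0), v_neutral = vn,
                  t0 = fit$t0_s * 1000)
    coa <- cond_meta$coa_ms[cond_meta$condition_label == cn][1]
    d <- decompose_contributions(r, trial_condition(soa_grid, coa),
                                 fit$config)
    d$condition <- cn
    d
  }))
  p3 <- ggplot2::ggplot(dec, ggplot2::aes(x = .data$soa_ms)) +
    ggplot2::geom_area(ggplot2::aes(y = .data$p_via_cue),
                       fill = "grey40") +
    ggplot2::geom_line(ggplot2::aes(
      y = .data$p_via_cue + .data$p_via_probe)) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "SOA (ms)", y = "p(probe first)",
                  subtitle = "shaded: contribution of cue-as-probe categorizations")
  f <- file.path(dir, "confusion_decomposition.pdf")
  ggplot2::ggsave(f, p3, width = 9, height = 5)
  files <- c(files, f)

  # 4. tables
  f <- file.path(dir, "group_rate_summary.csv")
  utils::write.csv(as.data.frame(smry), f, row.names = FALSE)
  files <- c(files, f)
  classic <- dplyr::bind_rows(lapply(
    split(fit$row_meta, fit$row_meta$condition_label), function(d) {
      agg <- dplyr::summarise(
        dplyr::group_by(d, .data$soa_ms),
        n_trials = sum(.data$n_trials),
        n_probe_first = sum(.data$n_probe_first), .groups = "drop")
      out <- fit_classic_curve(agg)
      out$condition <- d$condition_label[1]
      out
    }))
  f <- file.path(dir, "classic_psychometric_fits.csv")
  utils::write.csv(as.data.frame(classic), f, row.names = FALSE)
  files <- c(files, f)

  invisible(files)
}
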