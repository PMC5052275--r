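#' Sampler control settings
#'
#' @param chains number of MCMC chains (run sequentially).
#' @param warmup adaptation iterations discarded per chain.
#' @param iter retained iterations per chain.
#' @param seed integer seed; chain `c` uses `seed + c`.
#' @param rhat_threshold split-chain convergence threshold; a fit whose
#'   group-level parameters exceed it is flagged (not silently accepted).
#' @param prior weakly-informative prior settings: normal priors on the
#'   group-mean log rates (location/scale for target rates and for the
#'   cue-as-probe rate, i.e. log-normal with heavy right tails on the Hz
#'   scale) and a half-normal scale for the group spreads.
#' @return An object of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 3, warmup = 1500, iter = 1500,
                         seed = 1L, rhat_threshold = 1.01,
                         prior = list(mu_target = log(30), sd_target = 1.5,
                                      mu_vcp = log(5), sd_vcp = 1.5,
                                      sigma_scale = 1)) {
  stopifnot(chains >= 1, warmup >= 10, iter >= 10)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter), seed = as.integer(seed),
                 rhat_threshold = rhat_threshold, prior = prior),
            class = "mcmc_control")
}

variant_families <- function(variant) {
  switch(variant,
         full = c("v_p", "v_r", "v_cp"),
         rates_only = c("v_p", "v_r"),
         confusion_only = "v_cp")
}

# Build the parameter/group/row index maps the C++ sampler consumes.
build_model_frame <- function(dataset, variant, config, prior) {
  data <- validate_toj_dataset(dataset)
  data <- dplyr::filter(data, .data$n_trials > 0)
  subjects <- sort(unique(data$subject_id))
  cond_tab <- dplyr::distinct(data[c("condition_label", "coa_ms")])
  cued <- sort(cond_tab$condition_label[!is.na(cond_tab$coa_ms)])
  fams <- variant_families(variant)

  # groups: v_neutral plus one per (family, cued condition)
  groups <- tibble::tibble(family = "v_neutral",
                           condition = NA_character_)
  for (cn in cued) {
    groups <- dplyr::bind_rows(groups,
      tibble::tibble(family = fams, condition = cn))
  }
  groups$m0 <- ifelse(groups$family == "v_cp", prior$mu_vcp,
                      prior$mu_target)
  groups$s0 <- ifelse(groups$family == "v_cp", prior$sd_vcp,
                      prior$sd_target)
  groups$sig_scale <- prior$sigma_scale
  groups$gidx <- seq_len(nrow(groups)) - 1L

  # subject-level parameters
  par <- dplyr::cross_join(tibble::tibble(subject_id = subjects),
                           groups[c("family", "condition", "gidx")])
  par$idx <- seq_len(nrow(par)) - 1L
  par$name <- ifelse(
    is.na(par$condition),
    sprintf("%s[%d]", par$family, par$subject_id),
    sprintf("%s[%d,%s]", par$family, par$subject_id, par$condition))

  lookup <- function(subj, fam, cond) {
    if (fam == "v_neutral") {
      hit <- par$subject_id == subj & par$family == "v_neutral"
    } else {
      hit <- par$subject_id == subj & par$family == fam &
        !is.na(par$condition) & par$condition == cond
    }
    par$idx[hit][1]
  }

  n <- nrow(data)
  ivp <- ivr <- ivcp <- ivn <- integer(n)
  for (i in seq_len(n)) {
    subj <- data$subject_id[i]
    cn <- data$condition_label[i]
    ineu <- lookup(subj, "v_neutral", NA)
    if (is.na(data$coa_ms[i])) {
      ivp[i] <- ivr[i] <- ivn[i] <- ineu
      ivcp[i] <- -1L
    } else {
      ivn[i] <- ineu
      ivp[i] <- if ("v_p" %in% fams) lookup(subj, "v_p", cn) else ineu
      ivr[i] <- if ("v_r" %in% fams) lookup(subj, "v_r", cn) else ineu
      ivcp[i] <- if ("v_cp" %in% fams) lookup(subj, "v_cp", cn) else -1L
    }
  }

  rows <- list(n = as.integer(data$n_trials),
               k = as.integer(data$n_probe_first),
               ivp = as.integer(ivp), ivr = as.integer(ivr),
               ivcp = as.integer(ivcp), ivn = as.integer(ivn),
               nocue = as.integer(is.na(data$coa_ms)),
               soa_s = data$soa_ms / 1000,
               coa_s = ifelse(is.na(data$coa_ms), 0, data$coa_ms) / 1000)

  # rows affected by each parameter; the neutral rate only touches cued
  # rows through the regime once the reference leads the cue (soa > coa)
  vn_relevant <- rows$nocue == 1L | data$soa_ms > dplyr::coalesce(
    data$coa_ms, Inf)
  par_hits <- lapply(par$idx, function(j) {
    which(ivp == j | ivr == j | ivcp == j | (ivn == j & vn_relevant)) - 1L
  })
  group_members <- lapply(groups$gidx, function(g) {
    par$idx[par$gidx == g]
  })

  # update blocks: each subject's neutral rate alone, and each subject x
  # cued-condition parameter set jointly (the within-condition rates are
  # strongly correlated a posteriori)
  block_key <- paste(par$subject_id,
                     ifelse(is.na(par$condition), ".neutral",
                            par$condition))
  blocks <- lapply(split(par$idx, block_key), as.integer)
  block_rows <- lapply(blocks, function(members) {
    sort(unique(unlist(par_hits[members + 1L])))
  })

  # translation blocks: the groups of one condition move jointly
  hb_key <- ifelse(is.na(groups$condition), ".neutral", groups$condition)
  hblocks <- lapply(split(groups$gidx, hb_key), as.integer)
  hblock_rows <- lapply(hblocks, function(gs) {
    members <- unlist(group_members[gs + 1L])
    sort(unique(unlist(par_hits[members + 1L])))
  })

  list(data = data, rows = rows, par = par, groups = groups,
       blocks = unname(blocks), block_rows = unname(block_rows),
       group_members = group_members, hblocks = unname(hblocks),
       hblock_rows = unname(hblock_rows),
       t0_s = (config$t0 %||% 0) / 1000, regime = regime_code(config))
}

#' Fit the hierarchical Bayesian race model to TOJ data
#'
#' Subject-level log rates are partially pooled toward condition-specific
#' group means (normal hierarchy on the log scale); the likelihood is
#' binomial with success probability from the closed-form race model at
#' each record's SOA/COA. Sampling uses adaptive Metropolis-within-Gibbs
#' (scalar random walks on log rates, conjugate updates for group means).
#' The neutral rate is one parameter per subject shared across conditions;
#' cued-condition rates are condition-specific.
#'
#' @param dataset a `toj_dataset` (see [generate_dataset()],
#'   [read_toj_dataset()]).
#' @param variant which mechanisms are free: `"full"` (rate changes and
#'   cue-as-probe confusions), `"rates_only"` (`v_cp` pinned at 0), or
#'   `"confusion_only"` (both targets race at the subject's neutral rate;
#'   only `v_cp` free).
#' @param config a [toj_config()].
#' @param mcmc an [mcmc_control()].
#' @return An object of class `toj_fit` with draws, parameter tables,
#'   split-chain convergence diagnostics and a `converged` flag.
#' @export
fit_toj <- function(dataset, variant = c("full", "rates_only",
                                         "confusion_only"),
                    config = toj_config(), mcmc = mcmc_control()) {
  variant <- match.arg(variant)
  mf <- build_model_frame(dataset, variant, config, mcmc$prior)
  np <- nrow(mf$par)
  ng <- nrow(mf$groups)

  par_names <- mf$par$name
  mu_names <- ifelse(is.na(mf$groups$condition),
                     sprintf("mu_%s", mf$groups$family),
                     sprintf("mu_%s[%s]", mf$groups$family,
                             mf$groups$condition))
  sig_names <- sub("^mu_", "sigma_", mu_names)
  cn <- c(par_names, mu_names, sig_names)

  draws_list <- vector("list", mcmc$chains)
  for (ch in seq_len(mcmc$chains)) {
    set.seed(mcmc$seed + ch)
    m0 <- mf$groups$m0
    theta0 <- m0[mf$par$gidx + 1L] + rnorm(np, 0, 0.4)
    mu0 <- m0 + rnorm(ng, 0, 0.3)
    sigma0 <- exp(log(0.4) + rnorm(ng, 0, 0.2))
    res <- run_mwg_chain(mf$rows, mf$blocks, mf$block_rows, mf$par$gidx,
                         mf$group_members, mf$hblocks, mf$hblock_rows,
                         mf$groups$m0, mf$groups$s0,
                         mf$groups$sig_scale, theta0, mu0, sigma0,
                         mcmc$warmup, mcmc$iter, mf$t0_s, mf$regime)
    colnames(res$draws) <- cn
    draws_list[[ch]] <- res$draws
  }

  diag <- tibble::tibble(
    parameter = cn,
    rhat = vapply(cn, function(p) rhat(lapply(draws_list, function(d)
      d[, p])), 0),
    ess = vapply(cn, function(p) ess(lapply(draws_list, function(d)
      d[, p])), 0))
  group_cols <- c(mu_names, sig_names)
  worst <- max(diag$rhat[diag$parameter %in% group_cols], na.rm = TRUE)
  converged <- is.finite(worst) && worst <= mcmc$rhat_threshold

  fit <- structure(list(
    draws = draws_list, par = mf$par, groups = mf$groups, np = np,
    ng = ng, rowdata = mf$rows, row_meta = mf$data, t0_s = mf$t0_s,
    regime = mf$regime, variant = variant, config = config, mcmc = mcmc,
    diagnostics = diag, converged = converged, max_rhat_group = worst),
    class = "toj_fit")
  if (!converged) {
    warning(sprintf(
      "group-level split R-hat %.3f exceeds %.3f; treat estimates with caution",
      worst, mcmc$rhat_threshold), call. = FALSE)
  }
  fit
}

#' @export
print.toj_fit <- function(x, ...) {
  cat(sprintf(
    "<toj_fit> variant = %s, %d subjects, %d records, %d chains x %d draws\n",
    x$variant, length(unique(x$par$subject_id)), length(x$rowdata$n),
    length(x$draws), nrow(x$draws[[1]])))
  cat(sprintf("max group-level R-hat: %.3f (%s)\n", x$max_rhat_group,
              if (x$converged) "converged" else "NOT converged"))
  print(summary(x))
  invisible(x)
}

pooled_draws <- function(fit, column) {
  unlist(lapply(fit$draws, function(d) d[, column]), use.names = FALSE)
}

#' Posterior draws of a group-level rate
#'
#' Group-level rates are reported as `exp(mu)` of the log-scale hierarchy
#' location (the population median rate).
#'
#' @param fit a [fit_toj()] result.
#' @param family `"v_p"`, `"v_r"`, `"v_cp"`, or `"v_neutral"`.
#' @param condition condition label (ignored for `v_neutral`).
#' @return Numeric vector of pooled posterior draws (Hz).
#' @export
group_rate_draws <- function(fit, family, condition = NULL) {
  stopifnot(inherits(fit, "toj_fit"))
  col <- if (family == "v_neutral") "mu_v_neutral" else {
    if (is.null(condition)) {
      stop("condition required for cued-condition families", call. = FALSE)
    }
    sprintf("mu_%s[%s]", family, condition)
  }
  if (!col %in% colnames(fit$draws[[1]])) {
    stop("unknown parameter: ", col, call. = FALSE)
  }
  exp(pooled_draws(fit, col))
}

#' Posterior draws of a subject-level rate
#' @inheritParams group_rate_draws
#' @param subject subject id.
#' @return Numeric vector of pooled posterior draws (Hz).
#' @export
subject_rate_draws <- function(fit, family, subject, condition = NULL) {
  stopifnot(inherits(fit, "toj_fit"))
  col <- if (family == "v_neutral") sprintf("v_neutral[%d]", subject) else
    sprintf("%s[%d,%s]", family, subject, condition)
  if (!col %in% colnames(fit$draws[[1]])) {
    stop("unknown parameter: ", col, call. = FALSE)
  }
  exp(pooled_draws(fit, col))
}

#' Summarize group-level posterior estimates
#'
#' @param object a [fit_toj()] result.
#' @param prob HDI mass.
#' @param ... unused.
#' @return A tibble with one row per group-level rate: posterior mean, sd,
#'   HDI bounds (Hz), the between-subject spread (log scale), and
#'   diagnostics.
#' @export
summary.toj_fit <- function(object, prob = 0.95, ...) {
  g <- object$groups
  rows <- lapply(seq_len(nrow(g)), function(i) {
    dr <- group_rate_draws(object, g$family[i],
                           if (is.na(g$condition[i])) NULL else
                             g$condition[i])
    h <- hdi(dr, prob)
    mu_col <- if (is.na(g$condition[i])) sprintf("mu_%s", g$family[i]) else
      sprintf("mu_%s[%s]", g$family[i], g$condition[i])
    sig_col <- sub("^mu_", "sigma_", mu_col)
    d <- object$diagnostics
    tibble::tibble(
      family = g$family[i], condition = g$condition[i],
      mean_hz = mean(dr), sd_hz = sd(dr),
      hdi_lower = h[["lower"]], hdi_upper = h[["upper"]],
      sigma_log = mean(pooled_draws(object, sig_col)),
      rhat = d$rhat[d$parameter == mu_col],
      ess = d$ess[d$parameter == mu_col])
  })
  dplyr::bind_rows(rows)
}

#' Posterior contrast between two group-level rates
#'
#' Draw-wise difference `a - b` on the Hz scale, e.g. the probe-minus-
#' reference rate difference whose 95% HDI excluding zero indicates a
#' reliable cueing effect on processing speed.
#'
#' @param fit a [fit_toj()] result.
#' @param a,b parameter families (`"v_p"`, `"v_r"`, `"v_cp"`,
#'   `"v_neutral"`).
#' @param condition condition label for `a` (and for `b` unless
#'   `condition_b` is given).
#' @param condition_b optional condition label for `b`.
#' @param prob HDI mass.
#' @return A one-row tibble: `mean`, `hdi_lower`, `hdi_upper`,
#'   `prob_positive`.
#' @export
contrast <- function(fit, a, b, condition = NULL, condition_b = condition,
                     prob = 0.95) {
  da <- group_rate_draws(fit, a, condition)
  db <- group_rate_draws(fit, b, condition_b)
  d <- da - db
  h <- hdi(d, prob)
  tibble::tibble(contrast = sprintf("%s - %s", a, b),
                 condition = condition %||% NA_character_,
                 mean = mean(d), hdi_lower = h[["lower"]],
                 hdi_upper = h[["upper"]], prob_positive = mean(d > 0))
}

#' Classify subjects by their cueing phenotype
#'
#' Labels a subject "disadvantageous" when the posterior mean of
#' `v_p - v_r` is negative in every cued condition and the posterior
#' mass of `v_cp` concentrates near zero (its posterior mean stays below
#' `vcp_threshold`) in every cued condition — the pattern of observers
#' for whom the cue only hurts. The classification is an explicit,
#' optional filter for group summaries; nothing applies it by default.
#'
#' @param fit a [fit_toj()] result from the `"full"` variant.
#' @param vcp_threshold cue-as-probe rate (Hz) below which the confusion
#'   mechanism counts as absent.
#' @return A tibble with `subject_id` and logical `disadvantageous`.
#' @export
classify_subjects <- function(fit, vcp_threshold = 2) {
  stopifnot(inherits(fit, "toj_fit"))
  if (fit$variant != "full") {
    stop("phenotype classification needs the full variant", call. = FALSE)
  }
  cued <- unique(fit$par$condition[!is.na(fit$par$condition)])
  subjects <- sort(unique(fit$par$subject_id))
  flag <- vapply(subjects, function(id) {
    all(vapply(cued, function(cn) {
      dvp <- mean(subject_rate_draws(fit, "v_p", id, cn)) -
        mean(subject_rate_draws(fit, "v_r", id, cn))
      vcp <- mean(subject_rate_draws(fit, "v_cp", id, cn))
      dvp < 0 && vcp < vcp_threshold
    }, TRUE))
  }, TRUE)
  tibble::tibble(subject_id = subjects, disadvantageous = flag)
}

#' Posterior predictive "probe first" counts
#'
#' Draws replicate response counts for each record of the fitted dataset
#' (or a compatible new one) from randomly selected posterior draws, and
#' summarizes them as central predictive bands.
#'
#' @param fit a [fit_toj()] result.
#' @param ndraws number of posterior draws to use.
#' @param prob central band mass.
#' @param seed seed for the predictive draws.
#' @return A tibble: the record columns plus `p_mean`, `k_lower`,
#'   `k_median`, `k_upper`. Records with `n_trials = 0` keep empty (NA)
#'   bands.
#' @export
posterior_predict <- function(fit, ndraws = 200, prob = 0.95, seed = 1L) {
  stopifnot(inherits(fit, "toj_fit"))
  set.seed(as.integer(seed))
  all_draws <- do.call(rbind, fit$draws)
  S <- nrow(all_draws)
  take <- sample.int(S, min(ndraws, S))
  rows <- fit$rowdata
  nr <- length(rows$n)
  pm <- matrix(0, length(take), nr)
  km <- matrix(0L, length(take), nr)
  for (s in seq_along(take)) {
    th <- all_draws[take[s], seq_len(fit$np)]
    vp <- exp(th[rows$ivp + 1L])
    vr <- exp(th[rows$ivr + 1L])
    vcp <- ifelse(rows$ivcp < 0, 0, exp(th[pmax(rows$ivcp, 0) + 1L]))
    vn <- exp(th[rows$ivn + 1L])
    m <- race_decompose_cpp(vp, vr, vcp, vn, fit$t0_s * 1000,
                            rows$soa_s * 1000, rows$coa_s * 1000,
                            rows$nocue == 1L, fit$regime)
    p <- pmin(pmax(m[, 1] + m[, 2], 0), 1)
    pm[s, ] <- p
    km[s, ] <- rbinom(nr, rows$n, p)
  }
  alpha <- (1 - prob) / 2
  out <- fit$row_meta
  out$p_mean <- colMeans(pm)
  out$k_lower <- apply(km, 2, quantile, alpha)
  out$k_median <- apply(km, 2, quantile, 0.5)
  out$k_upper <- apply(km, 2, quantile, 1 - alpha)
  zero <- out$n_trials == 0
  out$k_lower[zero] <- out$k_median[zero] <- out$k_upper[zero] <- NA_real_
  out
}
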