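log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Generalized Pareto fit to sample exceedances (profile-likelihood method
# of Zhang & Stephens 2009); returns the shape k and scale sigma.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  m <- 30 + floor(sqrt(n))
  j <- seq_len(m)
  quart <- x[max(1, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (j - 0.5))) / (3 * quart)
  k_j <- vapply(theta, function(b) -mean(log1p(-b * x)), 0)
  l_j <- n * (log(theta / k_j) + k_j - 1)
  w_j <- 1 / vapply(l_j, function(l) sum(exp(l_j - l)), 0)
  theta_hat <- sum(theta * w_j)
  k <- -mean(log1p(-theta_hat * x))
  list(k = k, sigma = k / theta_hat)
}

# Pareto-smoothed importance weights (log scale, normalized to max 0):
# the largest weights are replaced by expected order statistics of a
# generalized Pareto distribution fitted to the weight tail.
psis_weights <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5) return(lw)
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1):S]
  cut <- exp(lw[ord[S - M]])
  exceed <- exp(lw[tail_ids]) - cut
  if (max(exceed) <= 0) return(lw)
  fit <- gpd_fit(exceed)
  if (!is.finite(fit$k)) return(lw)
  p <- (seq_len(M) - 0.5) / M
  qgpd <- if (abs(fit$k) < 1e-12) -fit$sigma * log1p(-p) else
    fit$sigma / fit$k * ((1 - p)^(-fit$k) - 1)
  smoothed <- log(cut + qgpd)
  smoothed <- pmin(smoothed, 0)
  lw[tail_ids[order(lw[tail_ids])]] <- smoothed
  lw
}

# Approximate leave-one-out expected log predictive density per record,
# using Pareto-smoothed importance sampling over the posterior draws.
loo_pointwise <- function(ll) {
  apply(ll, 2, function(l) {
    lw <- psis_weights(-l)
    log_sum_exp(lw + l) - log_sum_exp(lw)
  })
}

#' Compare nested variants of the race model
#'
#' Fits each variant to the dataset and scores it by approximate
#' leave-one-out cross-validated predictive density (truncated importance
#' sampling over the posterior draws), with standard errors on scores and
#' on pairwise score differences. Scoring is per condition by default
#' (summing the pointwise predictive densities of each condition's
#' records) or joint over the whole dataset.
#'
#' @param dataset a `toj_dataset`.
#' @param variants model variants to compare (at least two, unless a
#'   single-variant trivial report is wanted).
#' @param config a [toj_config()].
#' @param mcmc an [mcmc_control()].
#' @param scope `"per_condition"` or `"joint"`.
#' @param on_nonconvergence `"warn"` flags non-converged fits in the
#'   report; `"abort"` raises an error instead.
#' @return An object of class `toj_comparison`: tibbles `scores`
#'   (condition, variant, elpd, se, rank) and `pairwise` (score
#'   differences with their SE), plus the fitted objects.
#' @export
compare_toj_models <- function(dataset,
                               variants = c("full", "rates_only",
                                            "confusion_only"),
                               config = toj_config(),
                               mcmc = mcmc_control(),
                               scope = c("per_condition", "joint"),
                               on_nonconvergence = c("warn", "abort")) {
  scope <- match.arg(scope)
  on_nonconvergence <- match.arg(on_nonconvergence)
  stopifnot(length(variants) >= 1)
  fits <- lapply(variants, function(v) {
    withCallingHandlers(
      fit_toj(dataset, variant = v, config = config, mcmc = mcmc),
      warning = function(w) {
        if (on_nonconvergence == "warn") invokeRestart("muffleWarning")
      })
  })
  names(fits) <- variants
  bad <- variants[!vapply(fits, function(f) f$converged, TRUE)]
  if (length(bad) > 0 && on_nonconvergence == "abort") {
    stop("non-converged fits: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  point <- lapply(fits, function(f) {
    dr <- do.call(rbind, f$draws)
    ll <- loglik_matrix_cpp(dr, f$np, f$rowdata, f$t0_s, f$regime)
    loo_pointwise(ll)
  })
  cond <- if (scope == "joint") {
    rep("all", length(point[[1]]))
  } else {
    fits[[1]]$row_meta$condition_label
  }

  scores <- dplyr::bind_rows(lapply(variants, function(v) {
    tibble::tibble(condition = cond, variant = v, elpd_i = point[[v]])
  }))
  scores <- dplyr::summarise(
    dplyr::group_by(scores, .data$condition, .data$variant),
    elpd = sum(.data$elpd_i),
    se = sqrt(dplyr::n() * var(.data$elpd_i)), .groups = "drop")
  scores <- dplyr::mutate(
    dplyr::group_by(scores, .data$condition),
    rank = rank(-.data$elpd, ties.method = "first"))
  scores <- dplyr::ungroup(scores)
  scores$converged <- !(scores$variant %in% bad)

  pw <- NULL
  if (length(variants) >= 2) {
    n_mech <- c(full = 3, rates_only = 2, confusion_only = 1)
    combs <- utils::combn(variants, 2, simplify = FALSE)
    pw <- dplyr::bind_rows(lapply(combs, function(ab) {
      d <- point[[ab[1]]] - point[[ab[2]]]
      agg <- dplyr::summarise(
        dplyr::group_by(tibble::tibble(condition = cond, d = d),
                        .data$condition),
        delta_elpd = sum(.data$d),
        se_delta = sqrt(dplyr::n() * var(.data$d)), .groups = "drop")
      agg$variant_a <- ab[1]
      agg$variant_b <- ab[2]
      agg[c("condition", "variant_a", "variant_b", "delta_elpd",
            "se_delta")]
    }))

    # standard-error-aware ranking with a one-SE parsimony tie-break:
    # when a variant with more free mechanisms leads a simpler one by
    # less than the standard error of their score difference, the models
    # are indistinguishable and the simpler one is ranked first
    se_of <- function(cn, a, b) {
      hit <- pw$condition == cn &
        ((pw$variant_a == a & pw$variant_b == b) |
         (pw$variant_a == b & pw$variant_b == a))
      pw$se_delta[hit][1]
    }
    for (cn in unique(scores$condition)) {
      sc <- scores[scores$condition == cn, ]
      sc <- sc[order(sc$rank), ]
      repeat {
        swapped <- FALSE
        for (i in seq_len(nrow(sc) - 1)) {
          a <- sc$variant[i]; b <- sc$variant[i + 1]
          closer <- (sc$elpd[i] - sc$elpd[i + 1]) < se_of(cn, a, b)
          if (n_mech[[a]] > n_mech[[b]] && closer) {
            sc[c(i, i + 1), ] <- sc[c(i + 1, i), ]
            swapped <- TRUE
          }
        }
        if (!swapped) break
      }
      sc$rank <- seq_len(nrow(sc))
      idx <- scores$condition == cn
      scores$rank[idx] <- sc$rank[match(scores$variant[idx], sc$variant)]
    }
  }

  structure(list(scores = scores, pairwise = pw, fits = fits,
                 scope = scope,
                 criterion = "approximate LOO (truncated importance sampling)",
                 nonconverged = bad),
            class = "toj_comparison")
}

#' @export
print.toj_comparison <- function(x, ...) {
  cat(sprintf("<toj_comparison> criterion: %s; scope: %s\n", x$criterion,
              x$scope))
  if (length(x$nonconverged) > 0) {
    cat("non-converged variants:", paste(x$nonconverged, collapse = ", "),
        "\n")
  }
  print(dplyr::arrange(x$scores, .data$condition, .data$rank))
  invisible(x)
}

#' Variant ranked first in a condition
#' @param comparison a [compare_toj_models()] report.
#' @param condition condition label (or `"all"` for joint scope).
#' @return The winning variant name.
#' @export
top_variant <- function(comparison, condition) {
  s <- comparison$scores
  s$variant[s$condition == condition & s$rank == 1][1]
}
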