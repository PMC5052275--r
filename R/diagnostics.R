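# Split-chain convergence and effective-sample-size diagnostics.
# Standard formulations: potential scale reduction on split half-chains,
# ESS from the pooled autocorrelation sequence truncated by Geyer's
# initial-positive-sequence rule.

split_chains <- function(draws_list) {
  out <- list()
  for (ch in draws_list) {
    n <- length(ch)
    h <- floor(n / 2)
    out <- c(out, list(ch[seq_len(h)], ch[(n - h + 1):n]))
  }
  out
}

#' Split-chain potential scale reduction factor
#' @param draws_list list of numeric vectors, one per chain.
#' @return Scalar R-hat (NA for constant chains).
#' @export
rhat <- function(draws_list) {
  chains <- split_chains(draws_list)
  n <- length(chains[[1]])
  m <- length(chains)
  if (n < 2) return(NA_real_)
  means <- vapply(chains, mean, 0)
  vars <- vapply(chains, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size
#' @param draws_list list of numeric vectors, one per chain.
#' @return Scalar effective sample size estimate.
#' @export
ess <- function(draws_list) {
  m <- length(draws_list)
  n <- length(draws_list[[1]])
  if (n < 4) return(NA_real_)
  W <- mean(vapply(draws_list, var, 0))
  if (!is.finite(W) || W <= 0) return(NA_real_)
  # chain-averaged autocorrelations
  max_lag <- min(n - 1, 1000)
  acfs <- vapply(draws_list, function(x) {
    as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
                          demean = TRUE)$acf)
  }, numeric(max_lag + 1))
  rho <- rowMeans(acfs)
  # Geyer initial positive sequence on paired sums
  s <- 0
  t <- 1
  while (t + 1 <= length(rho) - 1) {
    pair <- rho[t + 1] + rho[t + 2]
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  max(m * n / (1 + 2 * s), 1)
}

#' Highest density interval of a sample
#' @param x numeric draws.
#' @param prob mass of the interval.
#' @return Named vector `c(lower, upper)` of the shortest interval holding
#'   `prob` of the draws.
#' @export
hdi <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0) return(c(lower = NA_real_, upper = NA_real_))
  k <- max(1, ceiling(prob * n))
  if (k >= n) return(c(lower = x[1], upper = x[n]))
  starts <- seq_len(n - k)
  widths <- x[starts + k] - x[starts]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k])
}
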