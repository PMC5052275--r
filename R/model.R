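#' Encoding-rate set for one cueing condition
#'
#' Bundles the exponential encoding rates of the racers on a cued
#' temporal-order judgment (TOJ) trial: the cued target ("probe"), the
#' uncued target ("reference"), the cue racing to be categorized as the
#' probe, and the per-target rate of the neutral no-cue condition. Rates
#' are expressed in Hz; time arguments at the package interface are in
#' milliseconds (internal arithmetic uses seconds).
#'
#' @param v_p probe encoding rate (Hz).
#' @param v_r reference encoding rate (Hz).
#' @param v_cp rate of "cue is the probe" categorizations (Hz); 0 recovers
#'   a plain two-racer TOJ model.
#' @param v_neutral per-target encoding rate of the no-cue condition (Hz).
#'   Defaults to the mean of `v_p` and `v_r`. It is the rate at which both
#'   targets race on no-cue trials and the pre-cue rate of the reference
#'   when the reference appears before the cue.
#' @param t0 encoding threshold (ms): each racer starts its exponential
#'   clock `t0` after its own onset. Because the cue is masked at the
#'   physical probe onset, a positive `t0` shortens the cue's racing
#'   window to `coa - t0`.
#' @return An object of class `rate_set`.
#' @examples
#' rate_set(v_p = 50, v_r = 50, v_cp = 10)
#' @export
rate_set <- function(v_p, v_r, v_cp = 0, v_neutral = (v_p + v_r) / 2,
                     t0 = 0) {
  vals <- c(v_p = v_p, v_r = v_r, v_cp = v_cp, v_neutral = v_neutral,
            t0 = t0)
  if (length(vals) != 5L || !is.numeric(vals)) {
    stop("all rate_set fields must be numeric scalars", call. = FALSE)
  }
  if (any(!is.finite(vals))) {
    stop("rate_set fields must be finite", call. = FALSE)
  }
  if (any(vals < 0)) {
    stop("rates and t0 must be nonnegative", call. = FALSE)
  }
  structure(as.list(vals), class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat(sprintf(
    "<rate_set> v_p = %g Hz, v_r = %g Hz, v_cp = %g Hz, v_neutral = %g Hz, t0 = %g ms\n",
    x$v_p, x$v_r, x$v_cp, x$v_neutral, x$t0))
  invisible(x)
}

#' Presentation timing of one TOJ trial regime
#'
#' Timeline convention: the reference target appears at virtual time zero,
#' the probe at `soa`, and the cue at `soa - coa`. Negative SOAs mean the
#' probe leads.
#'
#' @param soa stimulus onset asynchrony in ms (probe onset minus reference
#'   onset); may be a vector to describe an SOA grid under one cueing
#'   regime.
#' @param coa cue onset asynchrony in ms (probe onset minus cue onset),
#'   a nonnegative scalar; `NA` (default) denotes the no-cue condition.
#' @param cld cue location displacement in px. Condition metadata only; it
#'   does not enter the race model.
#' @return An object of class `trial_condition`.
#' @examples
#' trial_condition(soa = seq(-120, 180, 30), coa = 140)
#' trial_condition(soa = 0) # no cue
#' @export
trial_condition <- function(soa, coa = NA_real_, cld = 0) {
  if (!is.numeric(soa) || length(soa) < 1L || any(!is.finite(soa))) {
    stop("soa must be finite numeric", call. = FALSE)
  }
  if (length(coa) != 1L) stop("coa must be a scalar", call. = FALSE)
  if (!is.na(coa) && (!is.finite(coa) || coa < 0)) {
    stop("coa must be nonnegative and finite (or NA for no cue)",
         call. = FALSE)
  }
  if (length(cld) != 1L || is.na(cld) || cld < 0) {
    stop("cld must be a nonnegative scalar", call. = FALSE)
  }
  structure(list(soa = as.numeric(soa), coa = as.numeric(coa),
                 cld = as.numeric(cld)),
            class = "trial_condition")
}

#' Model configuration
#'
#' @param t0 optional encoding threshold in ms; when supplied it overrides
#'   the `t0` stored in a [rate_set()] (and is the threshold used by
#'   [fit_toj()], where no rate set exists yet).
#' @param reference_regime behaviour of the reference racer when it is
#'   shown before the cue (`soa > coa`): `"switch"` (default) races it at
#'   `v_neutral` until cue onset and at `v_r` afterwards (piecewise
#'   hazard); `"neutral"` keeps it at `v_neutral` for the whole trial.
#' @return An object of class `toj_config`.
#' @seealso [toj_config_json()]
#' @export
toj_config <- function(t0 = NULL, reference_regime = c("switch", "neutral")) {
  reference_regime <- match.arg(reference_regime)
  if (!is.null(t0)) {
    stopifnot(is.numeric(t0), length(t0) == 1L, is.finite(t0), t0 >= 0)
  }
  structure(list(t0 = t0, reference_regime = reference_regime),
            class = "toj_config")
}

#' Serialize / restore a model configuration as JSON
#'
#' @param config a [toj_config()].
#' @param json a JSON string produced by `toj_config_json()`.
#' @return `toj_config_json()` returns a JSON string;
#'   `toj_config_from_json()` returns a `toj_config`.
#' @export
toj_config_json <- function(config) {
  jsonlite::toJSON(unclass(config), auto_unbox = TRUE, null = "null")
}

#' @rdname toj_config_json
#' @export
toj_config_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  toj_config(t0 = x$t0, reference_regime = x$reference_regime)
}

regime_code <- function(config) {
  if (config$reference_regime == "switch") 0L else 1L
}

# internal: vectorized decomposition on the (ms, Hz) interface
race_decompose <- function(rates, cond, config = toj_config()) {
  stopifnot(inherits(rates, "rate_set"), inherits(cond, "trial_condition"))
  n <- length(cond$soa)
  nocue <- is.na(cond$coa)
  t0 <- config$t0 %||% rates$t0
  m <- race_decompose_cpp(
    rep(rates$v_p, n), rep(rates$v_r, n), rep(rates$v_cp, n),
    rep(rates$v_neutral, n), t0, cond$soa,
    rep(if (nocue) 0 else cond$coa, n), rep(nocue, n),
    regime_code(config))
  m
}

#' Probability of a "probe first" judgment
#'
#' Closed-form probability that the cued target is perceived first, under
#' independent exponential races started at each stimulus's onset (plus the
#' threshold `t0`). A "probe first" percept arises when the probe or the
#' cue-as-probe categorization completes before the reference. Two
#' refinements apply: the cue race is censored at the physical probe onset
#' (the probe masks the cue), and when the reference is shown before the
#' cue it races at the neutral-condition rate until cue onset (see
#' [toj_config()]). In the no-cue condition both targets race at
#' `v_neutral` and `v_cp` is ignored.
#'
#' @param rates a [rate_set()].
#' @param cond a [trial_condition()]; its `soa` may be a vector.
#' @param config a [toj_config()].
#' @return A numeric vector of probabilities, one per SOA, monotonically
#'   nonincreasing in SOA.
#' @examples
#' r <- rate_set(v_p = 50, v_r = 50, v_cp = 10)
#' probe_first_probability(r, trial_condition(soa = 0, coa = 140))
#' @export
probe_first_probability <- function(rates, cond, config = toj_config()) {
  m <- race_decompose(rates, cond, config)
  unname(pmin(pmax(m[, 1] + m[, 2], 0), 1))
}

#' Split the "probe first" probability into cue and probe contributions
#'
#' `p_via_cue` is the probability that the cue-as-probe categorization
#' completes before both its censoring time (probe onset) and the
#' reference; `p_via_probe` is the probability that the probe itself beats
#' the reference when no such cue event occurred. The two sum exactly to
#' [probe_first_probability()].
#'
#' @inheritParams probe_first_probability
#' @return A tibble with columns `soa_ms`, `p_via_cue`, `p_via_probe`.
#' @export
decompose_contributions <- function(rates, cond, config = toj_config()) {
  m <- race_decompose(rates, cond, config)
  tibble::tibble(soa_ms = cond$soa, p_via_cue = unname(m[, 1]),
                 p_via_probe = unname(m[, 2]))
}

#' Probability that the cue is encoded as the probe before being masked
#'
#' Completion probability of the cue-as-probe race inside its uncensored
#' window. The window runs from the start of the cue's race (`t0` after cue
#' onset) to the physical probe onset, hence has length
#' `max(coa - t0, 0)` ms; with `t0 = 0` the probability is
#' `1 - exp(-v_cp * coa)`.
#'
#' @param v_cp cue-as-probe categorization rate (Hz).
#' @param coa cue onset asynchrony (ms).
#' @param t0 encoding threshold (ms).
#' @return Capture probability in `[0, 1]`; vectorized over its arguments.
#' @examples
#' cue_capture_probability(v_cp = 10, coa = 140) # ~0.75
#' @export
cue_capture_probability <- function(v_cp, coa, t0 = 0) {
  if (any(!is.finite(v_cp)) || any(!is.finite(coa)) || any(!is.finite(t0))) {
    stop("arguments must be finite", call. = FALSE)
  }
  if (any(v_cp < 0) || any(coa < 0) || any(t0 < 0)) {
    stop("arguments must be nonnegative", call. = FALSE)
  }
  -expm1(-v_cp * pmax(coa - t0, 0) / 1000)
}

#' Overall processing rate C
#'
#' The total encoding capacity deployed in a condition, obtained by summing
#' all concurrent race rates: `v_p + v_r + v_cp` in a cued condition and
#' `2 * v_neutral` in the no-cue condition.
#'
#' @param rates a [rate_set()].
#' @param no_cue if `TRUE`, the no-cue condition's overall rate.
#' @return Rate in Hz.
#' @export
overall_rate <- function(rates, no_cue = FALSE) {
  stopifnot(inherits(rates, "rate_set"))
  if (no_cue) 2 * rates$v_neutral else rates$v_p + rates$v_r + rates$v_cp
}
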