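# SOA repetition table of the two cueing experiments: rows are conditions,
# columns the nine-to-eleven SOAs; repetitions are biased toward the
# (condition-dependent) region of the point of subjective simultaneity.
repetition_table <- function() {
  soas <- c(-120, -90, -60, -30, 0, 30, 60, 90, 120, 150, 180)
  m <- rbind(
    "no_cue"    = c(4, 12, 20, 28, 32, 28, 20, 12, 4, 0, 0),
    "coa_40"    = c(0, 4, 12, 20, 28, 32, 32, 20, 8, 4, 0),
    "coa_80"    = c(0, 4, 8, 12, 20, 28, 32, 28, 20, 8, 0),
    "coa_140"   = c(0, 0, 4, 4, 12, 16, 24, 32, 32, 24, 12))
  colnames(m) <- soas
  m
}

design_row_trials <- function(label, row) {
  soas <- as.numeric(names(row))
  keep <- row > 0
  tibble::tibble(condition = label, soa_ms = soas[keep],
                 n_trials = as.integer(row[keep]))
}

#' Build an experiment design
#'
#' The `"exp1"` preset is a 30-subject design with a no-cue condition and
#' three cue onset asynchronies (COA 40, 80, 140 ms), 160 trials per
#' condition distributed over nine SOAs each. The `"exp2"` preset is a
#' 26-subject design with COA fixed at 80 ms and the cue displaced by 0,
#' 15, or 60 px (CLD), plus a no-cue condition; its cued conditions reuse
#' the COA = 80 ms repetition row.
#'
#' @param preset `"exp1"`, `"exp2"`, or `"custom"`.
#' @param conditions for `"custom"`: a data frame with columns `condition`,
#'   `coa_ms` (`NA` for no cue), `cld_px`.
#' @param repetitions for `"custom"`: a data frame with columns
#'   `condition`, `soa_ms`, `n_trials` (nonnegative integers).
#' @param n_subjects number of subjects (overrides the preset's).
#' @return An object of class `toj_design`: a list with tibbles
#'   `conditions` and `trials`, and `n_subjects`.
#' @examples
#' d <- make_design("exp1")
#' design_trial_totals(d)
#' @export
make_design <- function(preset = c("exp1", "exp2", "custom"),
                        conditions = NULL, repetitions = NULL,
                        n_subjects = NULL) {
  preset <- match.arg(preset)
  tab <- repetition_table()
  if (preset == "exp1") {
    conditions <- tibble::tibble(
      condition = c("no_cue", "coa_40", "coa_80", "coa_140"),
      coa_ms = c(NA, 40, 80, 140),
      cld_px = c(NA, 0, 0, 0))
    trials <- dplyr::bind_rows(lapply(conditions$condition, function(cn)
      design_row_trials(cn, tab[cn, ])))
    n_subjects <- n_subjects %||% 30L
  } else if (preset == "exp2") {
    conditions <- tibble::tibble(
      condition = c("no_cue", "cld_0", "cld_15", "cld_60"),
      coa_ms = c(NA, 80, 80, 80),
      cld_px = c(NA, 0, 15, 60))
    rows <- c(no_cue = "no_cue", cld_0 = "coa_80", cld_15 = "coa_80",
              cld_60 = "coa_80")
    trials <- dplyr::bind_rows(lapply(names(rows), function(cn)
      design_row_trials(cn, tab[rows[[cn]], ])))
    n_subjects <- n_subjects %||% 26L
  } else {
    if (is.null(conditions) || is.null(repetitions)) {
      stop("custom designs need `conditions` and `repetitions`",
           call. = FALSE)
    }
    conditions <- tibble::as_tibble(conditions)
    trials <- tibble::as_tibble(repetitions)
    need_c <- c("condition", "coa_ms", "cld_px")
    need_t <- c("condition", "soa_ms", "n_trials")
    if (!all(need_c %in% names(conditions)) ||
        !all(need_t %in% names(trials))) {
      stop("custom design tables are missing required columns",
           call. = FALSE)
    }
    if (anyNA(trials$n_trials) || any(trials$n_trials < 0) ||
        any(trials$n_trials != round(trials$n_trials))) {
      stop("repetition counts must be nonnegative integers", call. = FALSE)
    }
    if (!all(trials$condition %in% conditions$condition)) {
      stop("repetitions reference unknown conditions", call. = FALSE)
    }
    if (anyDuplicated(conditions$condition) ||
        anyDuplicated(trials[c("condition", "soa_ms")])) {
      stop("duplicate condition or (condition, soa) entries", call. = FALSE)
    }
    trials$n_trials <- as.integer(trials$n_trials)
    n_subjects <- n_subjects %||% 1L
  }
  structure(list(conditions = conditions, trials = trials,
                 n_subjects = as.integer(n_subjects)),
            class = "toj_design")
}

#' Trials per condition of a design
#' @param design a [make_design()] object.
#' @return A tibble with `condition` and `total` trial counts.
#' @export
design_trial_totals <- function(design) {
  stopifnot(inherits(design, "toj_design"))
  dplyr::summarise(dplyr::group_by(design$trials, .data$condition),
                   total = sum(.data$n_trials), .groups = "drop")
}

#' @export
print.toj_design <- function(x, ...) {
  cat(sprintf("<toj_design> %d subjects, %d conditions, %d trials/subject\n",
              x$n_subjects, nrow(x$conditions), sum(x$trials$n_trials)))
  print(x$conditions)
  invisible(x)
}
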