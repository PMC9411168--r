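# Exposure-series reduction: one value per peptide per sample.
#
# Each spot is imaged at several camera exposure times; its fluorescence is
# assumed linear in exposure. The per-spot OLS slope of signal on exposure,
# multiplied by 100 and log2-transformed, is the single reduced value used
# by all downstream kinase statistics.

#' Transform a fitted slope to the reduced per-peptide value
#'
#' `value = log2(100 * slope)` when the slope is positive; a non-positive
#' slope has no defined value and is returned as `NA` (never clamped), which
#' downstream QC treats as a failure.
#'
#' @param slope Numeric vector of fitted slopes (signal units per ms).
#' @return Numeric vector of reduced values (dimensionless, log2 scale).
#' @export
#' @examples
#' reduce_to_value(c(0.01, 0.1, -0.05))
reduce_to_value <- function(slope) {
  if (!is.numeric(slope)) abort("`slope` must be numeric")
  out <- rep(NA_real_, length(slope))
  ok <- is.finite(slope) & slope > 0
  out[ok] <- log2(100 * slope[ok])
  out
}

#' Fit per-spot exposure slopes and reduce to values
#'
#' For every (sample, peptide) series, fits ordinary least squares of signal
#' on exposure time and records the slope, the coefficient of determination
#' of that fit, and the reduced value `log2(100 * slope)`. The default model
#' includes an intercept, which absorbs constant optical background; a
#' through-origin fit is available. A series with zero signal variance gets
#' slope 0 and r2 reported as 0 (it will fail any positive-signal QC).
#'
#' If a `spot_id` column is present, replicate spots of the same peptide on
#' an array are fitted individually and their slopes, r2 and values averaged
#' per (sample, peptide), with a message.
#'
#' @param signals Long tibble with columns `sample_id`, `group`,
#'   `peptide_id`, `exposure_ms`, `signal` (and optionally `spot_id`).
#' @param model `"with_intercept"` (default) or `"through_origin"`.
#' @return A tibble with one row per (sample, peptide): `sample_id`,
#'   `group`, `peptide_id`, `slope`, `r2`, `value`.
#' @export
#' @examples
#' sig <- tibble::tibble(
#'   sample_id = "S1", group = "condition", peptide_id = "P001",
#'   exposure_ms = c(10, 20, 50, 100, 200),
#'   signal = 0.1 * c(10, 20, 50, 100, 200)
#' )
#' fit_exposure_slopes(sig)
fit_exposure_slopes <- function(signals,
                                model = c("with_intercept", "through_origin")) {
  model <- match.arg(model)
  check_columns(signals, c("sample_id", "group", "peptide_id",
                           "exposure_ms", "signal"), "`signals`")
  if (any(!is.finite(signals$signal))) {
    bad <- signals[!is.finite(signals$signal), ]
    abort(sprintf("non-finite signal for sample %s, peptide %s",
                  bad$sample_id[1], bad$peptide_id[1]))
  }
  if (any(signals$exposure_ms <= 0)) {
    abort("`exposure_ms` must be strictly positive")
  }

  has_spots <- "spot_id" %in% names(signals)
  keys <- if (has_spots) {
    c("sample_id", "group", "peptide_id", "spot_id")
  } else {
    c("sample_id", "group", "peptide_id")
  }

  few <- signals %>%
    group_by(dplyr::across(dplyr::all_of(keys))) %>%
    summarise(n_exp = n_distinct(.data$exposure_ms), .groups = "drop") %>%
    filter(.data$n_exp < 2L)
  if (nrow(few) > 0L) {
    abort(sprintf(
      "series for sample %s, peptide %s has < 2 distinct exposure times",
      few$sample_id[1], few$peptide_id[1]
    ))
  }

  fits <- signals %>%
    group_by(dplyr::across(dplyr::all_of(keys))) %>%
    summarise(
      slope = ols_slope(.data$exposure_ms, .data$signal, model),
      r2 = ols_r2(.data$exposure_ms, .data$signal, model),
      .groups = "drop"
    )

  if (has_spots) {
    n_rep <- fits %>%
      count(.data$sample_id, .data$peptide_id) %>%
      filter(.data$n > 1L)
    if (nrow(n_rep) > 0L) {
      inform(sprintf(
        "averaging replicate spots for %d (sample, peptide) pairs",
        nrow(n_rep)
      ))
    }
    fits <- fits %>%
      group_by(.data$sample_id, .data$group, .data$peptide_id) %>%
      summarise(slope = mean(.data$slope), r2 = mean(.data$r2),
                .groups = "drop")
  }

  fits %>%
    mutate(value = reduce_to_value(.data$slope)) %>%
    arrange(.data$sample_id, .data$peptide_id)
}

# OLS slope of y on x; zero-variance y yields slope 0 under both models'
# least-squares solutions (with intercept: covariance is 0; through origin
# only when y is identically 0 — a constant nonzero y keeps its LS slope).
ols_slope <- function(x, y, model) {
  if (model == "with_intercept") {
    sxx <- sum((x - mean(x))^2)
    sum((x - mean(x)) * (y - mean(y))) / sxx
  } else {
    sum(x * y) / sum(x^2)
  }
}

# Coefficient of determination; a zero-variance response has no defined r2
# and is reported as 0 so it cannot pass a curve-fit threshold.
ols_r2 <- function(x, y, model) {
  if (model == "with_intercept") {
    syy <- sum((y - mean(y))^2)
    if (syy == 0) return(0)
    sxx <- sum((x - mean(x))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    sxy^2 / (sxx * syy)
  } else {
    syy <- sum(y^2) # uncentered total sum of squares for a no-intercept fit
    if (syy == 0) return(0)
    b <- sum(x * y) / sum(x^2)
    1 - sum((y - b * x)^2) / syy
  }
}

#' Flag peptides by curve-fit and signal quality
#'
#' A peptide passes QC only if in *every* sample its fit has
#' `r2 >= r2_min`, its slope exceeds `min_slope` (strict, so the default 0
#' also excludes flat and negative spots), and its reduced value is defined.
#' QC is deliberately per-peptide across all samples so that every retained
#' peptide contributes a complete, balanced set of group means and
#' variances downstream; a peptide failing in one sample is excluded
#' everywhere.
#'
#' @param values Output of [fit_exposure_slopes()].
#' @param r2_min Minimum coefficient of determination, in `[0, 1]`
#'   (default 0.90).
#' @param min_slope Exclusive lower bound on the slope (default 0).
#' @return The input tibble with a logical `qc_pass` column added (same
#'   value for all rows of a peptide).
#' @export
qc_filter <- function(values, r2_min = 0.90, min_slope = 0) {
  check_columns(values, c("sample_id", "peptide_id", "slope", "r2", "value"),
                "`values`")
  r2_min <- check_number(r2_min, "r2_min", 0, 1)
  min_slope <- check_number(min_slope, "min_slope")
  flags <- values %>%
    group_by(.data$peptide_id) %>%
    summarise(
      qc_pass = all(is.finite(.data$r2) & .data$r2 >= r2_min &
                      .data$slope > min_slope & !is.na(.data$value)),
      .groups = "drop"
    )
  values %>% left_join(flags, by = "peptide_id")
}

#' Peptides passing QC
#'
#' @param values Output of [qc_filter()].
#' @return Character vector of QC-passing peptide ids.
#' @export
qc_passing <- function(values) {
  check_columns(values, c("peptide_id", "qc_pass"), "`values`")
  sort(unique(values$peptide_id[values$qc_pass]))
}
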