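#' Net change in percent length myelinated
#'
#' `delta PLM = recovery PLM - baseline PLM`, in percentage points:
#' -100 is an axon going from fully myelinated to bare, +100 the reverse.
#' Lost axons (not refound at the recovery timepoint) are excluded.
#'
#' @param records Longitudinal data frame (see [read_longitudinal()]).
#' @return Numeric vector of delta-PLM values, one per non-lost record, in
#'   input order.
#' @export
delta_plm <- function(records) {
  if (any(records$status == "lost")) {
    stop_myelo("lost axons have no recovery PLM; filter them out first",
               "myelo_excluded_record_error")
  }
  records$plm_recovery - records$plm_baseline
}

#' Fit a linear model of recovery PLM on baseline PLM
#'
#' Two forms are supported. `simple` is ordinary least squares of
#' `recovery ~ 1 + baseline`. `adjusted` is
#' `recovery ~ 1 + baseline + baseline:delta`, which augments the simple
#' model with an interaction between baseline PLM and the realized
#' delta-PLM of each axon. Note the adjusted form is near-circular --
#' delta-PLM is a function of the response -- and is provided because it
#' is how remodeling-adjusted recovery fits are reported in this
#' literature; interpret its R-squared accordingly (see the methods
#' vignette).
#'
#' Lost axons and axons unmyelinated at both timepoints
#' (`excluded_always_unmyelinated`) are dropped before fitting so that
#' trends of myelin replacement are not biased by axons that were never
#' candidates for remyelination.
#'
#' @param records Longitudinal data frame (see [read_longitudinal()]).
#' @param form `"simple"` or `"adjusted"`.
#' @return An object of class `remyelination_fit`: list with `model_form`,
#'   `coefficients`, `r_squared`, `p_value` (overall F test), `n`, and the
#'   underlying `lm` object as `model`.
#' @export
fit_recovery_model <- function(records, form = c("simple", "adjusted")) {
  form <- match.arg(form)
  keep <- records$status == "present"
  df <- records[keep, , drop = FALSE]
  if (nrow(df) < 3L) {
    stop_myelo("need at least 3 included records to fit (have %d)",
               "myelo_empty_data_error", nrow(df))
  }
  df$delta <- df$plm_recovery - df$plm_baseline
  fml <- if (form == "simple") {
    plm_recovery ~ plm_baseline
  } else {
    plm_recovery ~ plm_baseline + plm_baseline:delta
  }
  fit <- stats::lm(fml, data = df)
  s <- summary(fit)
  pval <- if (is.null(s$fstatistic)) NA_real_ else {
    unname(stats::pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
                     lower.tail = FALSE))
  }
  cf <- stats::coef(fit)
  names(cf) <- sub("plm_baseline:delta", "baseline:delta_plm", names(cf))
  names(cf) <- sub("^plm_baseline$", "baseline", names(cf))
  structure(list(model_form = form, coefficients = cf,
                 r_squared = s$r.squared, p_value = pval, n = nrow(df),
                 model = fit),
            class = "remyelination_fit")
}

#' @export
print.remyelination_fit <- function(x, ...) {
  cat(sprintf("<remyelination_fit (%s): n = %d, R^2 = %.3f, p = %.3g>\n",
              x$model_form, x$n, x$r_squared, x$p_value))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Where the recovery-vs-baseline fit crosses the identity line
#'
#' Solves `intercept + slope * x = x` for the simple model:
#' `x = intercept / (1 - slope)`. Axons with baseline PLM below the
#' crossing tend to gain myelin during recovery; axons above it tend to
#' lose myelin. A slope of exactly 1 leaves the crossing undefined.
#'
#' @param fit A simple-form [fit_recovery_model()] result.
#' @param tol Slopes within `tol` of 1 are treated as parallel. Default
#'   1e-8.
#' @return Crossing point in PLM percent.
#' @export
identity_crossing <- function(fit, tol = 1e-8) {
  stopifnot(inherits(fit, "remyelination_fit"))
  if (fit$model_form != "simple") {
    stop_myelo("identity crossing is defined for the simple model form",
               "myelo_argument_error")
  }
  slope <- fit$coefficients[["baseline"]]
  if (abs(1 - slope) < tol) {
    stop_myelo("fit is parallel to (or on) the identity line: no unique crossing",
               "myelo_no_crossing_error")
  }
  fit$coefficients[["(Intercept)"]] / (1 - slope)
}

#' Tracing-error band from control animals
#'
#' Repeated tracing of unchanged axons in control animals yields small
#' spurious negative delta-PLM values; their mean (a non-positive number)
#' and its mirror define a symmetric band around 0 within which a
#' longitudinal delta-PLM cannot be distinguished from tracing error.
#'
#' @param control_records Longitudinal data frame from control animals.
#' @return Non-negative half-width of the band, in PLM percentage points
#'   (0 when no control delta-PLM is negative).
#' @export
tracing_error_band <- function(control_records) {
  d <- delta_plm(control_records)
  neg <- d[d < 0]
  if (length(neg) == 0L) return(0)
  abs(mean(neg))
}

#' Fraction of traced sheaths surrounding PV axons within ROIs
#'
#' For each region of interest at a timepoint, computes
#' `100 * n_pv / (n_pv + n_other)` and summarizes across ROIs as mean and
#' standard error, together with the mean total sheath count per ROI.
#' ROIs with zero sheaths are excluded with a warning.
#'
#' @param rois ROI sheath-count data frame (see [read_roi_sheaths()]).
#' @param timepoint `"baseline"` or `"recovery"`.
#' @return List with `per_roi` (data frame `roi_id`, `fraction_pct`,
#'   `total`), `mean_fraction`, `sem_fraction`, `mean_total`, `n_rois`.
#' @export
pv_sheath_fraction <- function(rois, timepoint = c("baseline", "recovery")) {
  timepoint <- match.arg(timepoint)
  df <- rois[rois$timepoint == timepoint, , drop = FALSE]
  if (nrow(df) == 0L) {
    stop_myelo("no ROIs at timepoint %s", "myelo_empty_data_error", timepoint)
  }
  total <- df$n_pv + df$n_other
  if (any(total == 0)) {
    warning(sprintf("excluding %d ROI(s) with zero sheaths", sum(total == 0)))
    df <- df[total > 0, , drop = FALSE]
    total <- df$n_pv + df$n_other
    if (nrow(df) == 0L) {
      stop_myelo("all ROIs at timepoint %s have zero sheaths",
                 "myelo_empty_data_error", timepoint)
    }
  }
  frac <- 100 * df$n_pv / total
  list(per_roi = data.frame(roi_id = df$roi_id, fraction_pct = frac,
                            total = total),
       mean_fraction = mean(frac),
       sem_fraction = if (length(frac) > 1L) sem(frac) else NA_real_,
       mean_total = mean(total), n_rois = nrow(df))
}
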