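#' Construct a logistic myelination fit from known coefficients
#'
#' Builds a `logistic_fit` object directly from a coefficient set, e.g. a
#' published table of estimates for the diameter + subtype model, so that
#' [d50()] and [predict_probability()] can be applied without refitting.
#'
#' Coefficient names follow the model
#' `P(myelinated) ~ 1 + diameter + subtype` under treatment coding:
#' `"(Intercept)"`, `"diam"` and one `"type_<subtype>"` per non-reference
#' subtype (the reference carries no coefficient).
#'
#' @param coefficients Named numeric vector (see above).
#' @param standard_errors Optional named numeric vector, same names.
#' @param covariance Optional covariance matrix over the same terms.
#' @param loglik Optional log-likelihood of the fit.
#' @param converged Logical convergence flag.
#' @param separation_flags Character vector of terms flagged as separated.
#' @param reference Reference subtype of the treatment coding.
#' @return An object of class `logistic_fit`.
#' @export
logistic_fit <- function(coefficients, standard_errors = NULL,
                         covariance = NULL, loglik = NA_real_,
                         converged = TRUE, separation_flags = character(),
                         reference = "PV") {
  check_subtype(reference)
  nm <- names(coefficients)
  if (is.null(nm) || !all(c("(Intercept)", "diam") %in% nm)) {
    stop_myelo("coefficients must be named and include \"(Intercept)\" and \"diam\"",
               "myelo_argument_error")
  }
  type_terms <- grep("^type_", nm, value = TRUE)
  check_subtype(sub("^type_", "", type_terms))
  if (paste0("type_", reference) %in% nm) {
    stop_myelo("reference subtype %s must not carry a coefficient",
               "myelo_argument_error", reference)
  }
  structure(list(coefficients = coefficients,
                 standard_errors = standard_errors,
                 covariance = covariance, loglik = loglik,
                 converged = converged,
                 separation_flags = separation_flags,
                 reference = reference),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit: reference %s%s%s>\n", x$reference,
              if (x$converged) "" else ", NOT converged",
              if (length(x$separation_flags) > 0L)
                paste0(", separated: ", paste(x$separation_flags, collapse = ", "))
              else ""))
  tab <- data.frame(estimate = x$coefficients)
  if (!is.null(x$standard_errors)) tab$se <- x$standard_errors[names(x$coefficients)]
  print(tab, digits = 4)
  invisible(x)
}

#' Fit the binomial GLM of myelination probability
#'
#' Fits `P(myelinated) ~ 1 + diameter + subtype` by maximum likelihood
#' with a logit link and treatment coding relative to `reference`.
#' Responses may be 0/1 myelination status or per-axon site fractions
#' (1/3, 2/3, ...), in which case the site count enters as a binomial
#' weight. Subtypes with no myelinated (or no unmyelinated) axons produce
#' complete separation: the coefficient diverges during the capped
#' iterative fit and the term is flagged rather than regularized, since
#' the divergent estimate is itself informative (a subtype essentially
#' never myelinated).
#'
#' @param data Data frame with columns `mean_diameter_um` (or `diameter`),
#'   `subtype`, `myelination_fraction` (or `response`), and optionally
#'   `n_sites` (weights; default 1).
#' @param reference Reference subtype for the dummy coding. Default "PV".
#' @param max_iter IWLS iteration budget. Default 100.
#' @param coef_threshold,se_threshold A term with `|coefficient|` above
#'   `coef_threshold` or standard error above `se_threshold` after the
#'   iteration budget is added to `separation_flags`. Defaults 10 and 100.
#' @return A [logistic_fit()].
#' @export
fit_myelination_glm <- function(data, reference = "PV", max_iter = 100L,
                                coef_threshold = 10, se_threshold = 100) {
  diam <- data[["mean_diameter_um"]]
  if (is.null(diam)) diam <- data[["diameter"]]
  resp <- data[["myelination_fraction"]]
  if (is.null(resp)) resp <- data[["response"]]
  if (is.null(diam) || is.null(resp)) {
    stop_myelo("data needs diameter and response columns", "myelo_argument_error")
  }
  w <- data[["n_sites"]]
  if (is.null(w)) w <- rep(1, length(diam))
  subtype <- check_subtype(data[["subtype"]])
  if (any(diam <= 0)) stop_myelo("diameters must be > 0", "myelo_argument_error")
  if (any(resp < 0 | resp > 1)) {
    stop_myelo("responses must lie in [0, 1]", "myelo_argument_error")
  }
  present <- unique(subtype)
  if (length(present) < 2L) {
    stop_myelo("at least 2 subtypes are required", "myelo_argument_error")
  }
  if (!reference %in% present) {
    stop_myelo("reference subtype %s absent from data", "myelo_argument_error",
               reference)
  }
  if (all(resp == 0) || all(resp == 1)) {
    stop_myelo("response is single-class: no information to fit",
               "myelo_no_information_error")
  }
  lev <- c(reference, MYELO_SUBTYPES[MYELO_SUBTYPES %in% setdiff(present, reference)])
  df <- data.frame(resp = resp, diam = diam,
                   subtype = factor(subtype, levels = lev), w = w)
  fit <- withCallingHandlers(
    stats::glm(resp ~ diam + subtype, family = stats::binomial(),
               weights = w, data = df,
               control = stats::glm.control(maxit = max_iter)),
    warning = function(cnd) {
      # site-fraction responses legitimately yield non-integer successes;
      # divergence under separation is detected and flagged below
      if (grepl("non-integer|fitted probabilities numerically 0 or 1",
                conditionMessage(cnd))) {
        invokeRestart("muffleWarning")
      }
    })
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop_myelo("design is rank-deficient (collinear predictors)",
               "myelo_rank_error")
  }
  names(cf) <- sub("^subtype", "type_", names(cf))
  V <- stats::vcov(fit)
  dimnames(V) <- list(names(cf), names(cf))
  se <- sqrt(diag(V))
  flags <- names(cf)[abs(cf) > coef_threshold | se > se_threshold]
  flags <- setdiff(flags, "diam")  # diameter slope is never a class indicator
  logistic_fit(cf, standard_errors = se, covariance = V,
               loglik = as.numeric(stats::logLik(fit)),
               converged = fit$converged, separation_flags = flags,
               reference = reference)
}

#' Diameter at 50% myelination probability
#'
#' For a subtype with type offset `b_t` (0 for the reference), the modeled
#' probability crosses one half at `d50 = -(b_0 + b_t) / b_d`. When the fit
#' carries a covariance matrix, a 95% interval is attached by the delta
#' method on this ratio.
#'
#' @param fit A [logistic_fit()].
#' @param subtype Subtype to evaluate.
#' @param level Interval coverage; default 0.95.
#' @return An object of class `d50_estimate`: list with `subtype`, `d50`,
#'   `lower`, `upper` (the last two `NA` without a covariance).
#' @examples
#' f <- logistic_fit(c("(Intercept)" = -3.044, diam = 5.836))
#' d50(f, "PV")$d50  # 0.522
#' @export
d50 <- function(fit, subtype, level = 0.95) {
  stopifnot(inherits(fit, "logistic_fit"))
  check_subtype(subtype)
  term <- paste0("type_", subtype)
  if (term %in% fit$separation_flags || "(Intercept)" %in% fit$separation_flags) {
    stop_myelo("d50 is undefined for separation-flagged subtype %s",
               "myelo_separation_error", subtype)
  }
  b0 <- fit$coefficients[["(Intercept)"]]
  bd <- fit$coefficients[["diam"]]
  bt <- if (subtype == fit$reference) 0 else {
    if (!term %in% names(fit$coefficients)) {
      stop_myelo("subtype %s has no coefficient in this fit",
                 "myelo_argument_error", subtype)
    }
    fit$coefficients[[term]]
  }
  if (bd == 0) stop_myelo("diameter coefficient is zero; d50 undefined",
                          "myelo_argument_error")
  if (bd < 0) warning("diameter coefficient is negative: model is non-monotone ",
                      "increasing; d50 is a downward crossing")
  est <- -(b0 + bt) / bd
  lower <- upper <- NA_real_
  V <- fit$covariance
  if (!is.null(V)) {
    terms <- c("(Intercept)", "diam", if (subtype != fit$reference) term)
    if (all(terms %in% rownames(V))) {
      # delta method: gradient of -(b0+bt)/bd w.r.t. (b0, bd[, bt])
      grad <- c(-1 / bd, (b0 + bt) / bd^2,
                if (subtype != fit$reference) -1 / bd)
      v <- drop(t(grad) %*% V[terms, terms] %*% grad)
      z <- stats::qnorm(1 - (1 - level) / 2)
      lower <- est - z * sqrt(v)
      upper <- est + z * sqrt(v)
    }
  }
  structure(list(subtype = subtype, d50 = est, lower = lower, upper = upper),
            class = "d50_estimate")
}

#' @export
print.d50_estimate <- function(x, ...) {
  cat(sprintf("<d50 %s: %.3f um%s>\n", x$subtype, x$d50,
              if (is.na(x$lower)) "" else
                sprintf(" [%.3f, %.3f]", x$lower, x$upper)))
  invisible(x)
}

#' Predicted myelination probability
#'
#' Evaluates `logistic(b_0 + b_d * diameter + b_type)` for a subtype.
#'
#' @param fit A [logistic_fit()].
#' @param diameter Axon diameter(s) in um (vectorized).
#' @param subtype Subtype to evaluate.
#' @return Probabilities in (0, 1).
#' @export
predict_probability <- function(fit, diameter, subtype) {
  stopifnot(inherits(fit, "logistic_fit"))
  check_subtype(subtype)
  term <- paste0("type_", subtype)
  bt <- if (subtype == fit$reference) 0 else {
    if (!term %in% names(fit$coefficients)) {
      stop_myelo("subtype %s has no coefficient in this fit",
                 "myelo_argument_error", subtype)
    }
    fit$coefficients[[term]]
  }
  stats::plogis(fit$coefficients[["(Intercept)"]] +
                  fit$coefficients[["diam"]] * diameter + bt)
}

#' Tabulate d50 estimates for every subtype in a fit
#'
#' @param fit A [logistic_fit()].
#' @return Data frame `subtype d50_um lower_um upper_um`; separation-flagged
#'   subtypes are omitted.
#' @export
d50_table <- function(fit) {
  subs <- c(fit$reference,
            sub("^type_", "", grep("^type_", names(fit$coefficients), value = TRUE)))
  subs <- subs[!paste0("type_", subs) %in% fit$separation_flags]
  do.call(rbind, lapply(subs, function(s) {
    est <- d50(fit, s)
    data.frame(subtype = s, d50_um = est$d50, lower_um = est$lower,
               upper_um = est$upper)
  }))
}
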