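#' Default reference levels for the covariate models
#'
#' Male gender, the 0-44 age band, and the VEGFRi drug class.
#' @return named character vector.
#' @export
default_reference_levels <- function() {
  c(gender = "male", age_band = "0-44", drug_class = "VEGFRi")
}

#' Logistic regression of event occurrence on report covariates
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via [stats::glm()], tight convergence tolerance, at most 100
#' iterations) of a binary outcome on categorical covariates.  In
#' `"univariate"` mode one model is fitted per covariate; in
#' `"multivariate"` mode a single model includes them all.  Complete
#' separation is reported as a non-converged fit with a diagnostic, never as
#' silent output.  Missing covariate values are handled by complete-case
#' analysis.
#'
#' @param data data.frame holding the covariate columns.
#' @param outcome binary (0/1 or logical) vector, one per row of `data`.
#' @param covariates character vector of column names; all are treated as
#'   factors.
#' @param mode `"univariate"` or `"multivariate"`.
#' @param reference_levels named character vector of reference levels per
#'   factor (defaults: [default_reference_levels()]).
#' @return for `"multivariate"`, one object of class `tma_logit`; for
#'   `"univariate"`, a named list of them (one per covariate).
#' @export
fit_logistic <- function(data, outcome, covariates,
                         mode = c("multivariate", "univariate"),
                         reference_levels = default_reference_levels()) {
  mode <- match.arg(mode)
  outcome <- as.numeric(outcome)
  if (!all(outcome %in% c(0, 1)))
    stopf("outcome must be binary 0/1")
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov) > 0)
    stopf("covariate column(s) not in data: %s",
          paste(missing_cov, collapse = ", "))

  df <- data[, covariates, drop = FALSE]
  for (v in covariates) {
    f <- factor(df[[v]])
    ref <- reference_levels[[v]]
    if (!is.null(ref) && !is.na(ref) && ref %in% levels(f))
      f <- stats::relevel(f, ref = ref)
    df[[v]] <- f
  }
  df$.y <- outcome

  fit_one <- function(vars) {
    keep <- stats::complete.cases(df[, c(vars, ".y"), drop = FALSE])
    d <- df[keep, , drop = FALSE]
    form <- stats::as.formula(paste(".y ~", paste(vars, collapse = " + ")))
    g <- suppressWarnings(
      stats::glm(form, family = stats::binomial(), data = d,
                 control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
    coefs <- stats::coef(g)
    vc <- suppressWarnings(stats::vcov(g))
    se <- sqrt(diag(vc))
    separated <- !g$converged || g$boundary ||
      any(abs(coefs[-1]) > 15, na.rm = TRUE) || any(se > 100, na.rm = TRUE)
    structure(list(
      coefficients = coefs,
      standard_errors = se,
      covariance = vc,
      converged = !separated,
      diagnostic = if (separated)
        "possible complete separation or non-convergence" else NA_character_,
      n_obs = nrow(d),
      reference_levels = vapply(vars, function(v) levels(d[[v]])[1],
                                character(1)),
      factors = vars,
      xlevels = g$xlevels,
      glm = g
    ), class = "tma_logit")
  }

  if (mode == "multivariate") fit_one(covariates)
  else stats::setNames(lapply(covariates, fit_one), covariates)
}

#' Odds-ratio table with Wald confidence intervals
#'
#' For every non-reference factor level of one or more converged logistic
#' fits: `OR = exp(beta)`, Wald CI `exp(beta +/- z * SE)` and the two-sided
#' Wald p-value.
#'
#' @param fit a `tma_logit`, or a named list of them (as returned by
#'   univariate mode); lists are labelled `ULR`, single fits `MLR`.
#' @param alpha two-sided level (default 0.05).
#' @return data.frame with columns `factor, level, model, or, ci_low,
#'   ci_high, p`.
#' @export
odds_ratio_table <- function(fit, alpha = 0.05) {
  if (inherits(fit, "tma_logit")) {
    fits <- list(fit)
    model_label <- "MLR"
  } else {
    fits <- fit
    model_label <- "ULR"
  }
  z <- stats::qnorm(1 - alpha / 2)
  rows <- list()
  for (f in fits) {
    if (!isTRUE(f$converged))
      stopf("odds_ratio_table() requires a converged fit (%s)",
            f$diagnostic %||% "non-converged")
    for (v in f$factors) {
      lv <- f$xlevels[[v]]
      for (level in lv[-1]) {
        term <- paste0(v, level)
        b <- f$coefficients[[term]]
        se <- f$standard_errors[[term]]
        rows[[length(rows) + 1]] <- data.frame(
          factor = v, level = level, model = model_label,
          or = exp(b), ci_low = exp(b - z * se), ci_high = exp(b + z * se),
          p = 2 * stats::pnorm(abs(b / se), lower.tail = FALSE),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.tma_logit <- function(x, ...) {
  cat(sprintf("logistic fit (%s): n=%d, %s\n",
              paste(x$factors, collapse = " + "), x$n_obs,
              if (isTRUE(x$converged)) "converged" else x$diagnostic))
  print(round(x$coefficients, 4))
  invisible(x)
}
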