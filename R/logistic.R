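#' Fit a binomial logistic regression
#'
#' Maximum-likelihood fit by iteratively reweighted least squares
#' ([stats::glm()], binomial family, convergence tolerance 1e-8, at most
#' 100 iterations), returning a tidy coefficient table with odds ratios and
#' 95% Wald intervals. Complete separation is flagged (huge coefficients /
#' degenerate fitted probabilities) rather than raised.
#'
#' @param formula model formula; the response must be binary (logical, 0/1,
#'   or two-level factor).
#' @param data data frame.
#' @return an object of class `logistic_fit`: a list with `tidy` (tibble:
#'   term, beta, se, or, or_low, or_high, p), `n_obs`, `converged`,
#'   `separation`, `n_iter`, `loglik`, and the underlying `glm` object.
#' @export
#' @examples
#' d <- data.frame(y = c(1, 1, 1, 0, 1, 0, 0, 0),
#'                 x = c(1, 1, 1, 1, 0, 0, 0, 0))
#' fit_logistic(y ~ x, d)$tidy
fit_logistic <- function(formula, data) {
  data <- prepare_model_data(data)
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (length(unique(y)) < 2) {
    rlang::abort("outcome must contain both classes.",
                 class = "pvsignal_degenerate_error")
  }
  mm <- stats::model.matrix(formula, mf)
  pred_cols <- setdiff(colnames(mm), "(Intercept)")
  sds <- apply(mm[, pred_cols, drop = FALSE], 2, stats::sd)
  if (any(sds == 0)) {
    rlang::abort(
      sprintf("constant predictor(s): %s.",
              paste(pred_cols[sds == 0], collapse = ", ")),
      class = "pvsignal_degenerate_error"
    )
  }

  fit <- suppressWarnings(stats::glm(
    formula, data = data, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 100)
  ))
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  fitted <- stats::fitted(fit)
  separation <- any(abs(beta) > 15) &&
    (any(fitted < 1e-8) || any(fitted > 1 - 1e-8))
  z <- beta / se
  tidy <- tibble::tibble(
    term = names(beta),
    beta = unname(beta),
    se = unname(se),
    or = exp(unname(beta)),
    or_low = exp(unname(beta - 1.96 * se)),
    or_high = exp(unname(beta + 1.96 * se)),
    p = unname(2 * stats::pnorm(-abs(z)))
  )
  structure(
    list(
      tidy = tidy,
      n_obs = length(fit$y),
      converged = fit$converged && !separation,
      separation = separation,
      n_iter = fit$iter,
      loglik = as.numeric(stats::logLik(fit)),
      glm = fit
    ),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n=%d | logLik=%.3f | iter=%d | converged=%s%s\n",
              x$n_obs, x$loglik, x$n_iter, x$converged,
              if (x$separation) " (separation)" else ""))
  print(x$tidy)
  invisible(x)
}

#' Predicted probabilities from a logistic fit
#'
#' @param object a `logistic_fit`.
#' @param newdata data frame (default: training data).
#' @param ... unused.
#' @return numeric vector of predicted event probabilities.
#' @export
predict.logistic_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    as.numeric(stats::fitted(object$glm))
  } else {
    as.numeric(stats::predict(object$glm,
                              newdata = prepare_model_data(newdata),
                              type = "response"))
  }
}

# Uniform covariate coding across fit and prediction: logical columns enter
# as 0/1 numerics, character columns as factors (alphabetical reference
# level, e.g. canagliflozin for the SGLT-2i type).
prepare_model_data <- function(data) {
  for (nm in names(data)) {
    if (is.logical(data[[nm]])) data[[nm]] <- as.numeric(data[[nm]])
    else if (is.character(data[[nm]])) data[[nm]] <- factor(data[[nm]])
  }
  data
}

# Joint Wald test for all coefficients of one (possibly multi-level)
# predictor: beta' V^{-1} beta ~ chi^2_k under the null.
wald_joint_p <- function(fit, terms) {
  beta <- stats::coef(fit$glm)[terms]
  v <- stats::vcov(fit$glm)[terms, terms, drop = FALSE]
  stat <- as.numeric(t(beta) %*% solve(v) %*% beta)
  stats::pchisq(stat, df = length(terms), lower.tail = FALSE)
}

#' Adjusted odds ratio for one co-medication class
#'
#' Within the target-drug cohort, fits
#' `event ~ class flag + adjusters` (event = acute-pancreatitis flag) and
#' returns the exposure-term odds ratio with its 95% Wald interval: the
#' contrast of target drug + co-medication versus target-drug monotherapy
#' with respect to that class. Each class is fitted in its own model.
#'
#' @param cohort a cohort tibble from [extract_cohort()].
#' @param class_label name of the co-medication flag column (e.g.
#'   `"glp1ra"`).
#' @param adjusters covariate column names entered additively (default sex,
#'   age group, reporting year; pass `character(0)` for the crude odds
#'   ratio).
#' @return a one-row tibble `(class, or, or_low, or_high, p, n)` with the
#'   full `logistic_fit` in attribute `fit`.
#' @export
combo_adjusted_or <- function(cohort, class_label,
                              adjusters = c("sex", "age_group", "year")) {
  if (!class_label %in% names(cohort)) {
    rlang::abort(sprintf("class '%s' is absent from the cohort.", class_label),
                 class = "pvsignal_config_error")
  }
  missing_adj <- setdiff(adjusters, names(cohort))
  if (length(missing_adj) > 0) {
    rlang::abort(sprintf("adjuster(s) absent from the cohort: %s.",
                         paste(missing_adj, collapse = ", ")),
                 class = "pvsignal_config_error")
  }
  d <- cohort
  d$.exposure <- as.numeric(d[[class_label]])
  if ("year" %in% adjusters) d$year <- factor(d$year)
  rhs <- paste(c(".exposure", adjusters), collapse = " + ")
  fit <- fit_logistic(stats::as.formula(paste("ap ~", rhs)), d)
  row <- fit$tidy[fit$tidy$term == ".exposure", ]
  out <- tibble::tibble(
    class = class_label, or = row$or, or_low = row$or_low,
    or_high = row$or_high, p = row$p, n = fit$n_obs
  )
  attr(out, "fit") <- fit
  out
}

#' Adjusted odds ratios for several co-medication classes
#'
#' @param cohort a cohort tibble from [extract_cohort()].
#' @param classes co-medication flag columns (default: all eight classes).
#' @param adjusters as in [combo_adjusted_or()].
#' @return a forest-plot-ready tibble, one row per class.
#' @export
combo_risk_table <- function(cohort,
                             classes = c("dpp4i", "glp1ra", "metformin",
                                         "insulin", "glinide", "acei",
                                         "ppi", "statin"),
                             adjusters = c("sex", "age_group", "year")) {
  purrr::map_dfr(classes, function(cl) {
    combo_adjusted_or(cohort, cl, adjusters = adjusters)
  })
}
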