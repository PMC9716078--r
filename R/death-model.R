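# Death-risk modelling: split, univariate screen, multivariate fit,
# point-scale nomogram, and validation (ROC/AUC, bootstrap calibration,
# decision-curve analysis).

#' Random 1:1 split into training and validation sets
#'
#' @param cohort a cohort tibble (>= 2 rows).
#' @param seed integer seed; the split is reproducible.
#' @param stratify stratify on the death flag so the event rate is equal
#'   across halves (off by default; the simple random split mirrors a plain
#'   1:1 randomization).
#' @return list `(train, valid)`; sizes differ by at most 1 (training gets
#'   the larger half).
#' @export
split_cohort <- function(cohort, seed = 1L, stratify = FALSE) {
  n <- nrow(cohort)
  if (n < 2) {
    rlang::abort("need at least 2 rows to split.",
                 class = "pvsignal_degenerate_error")
  }
  withr::with_seed(seed, {
    if (stratify) {
      idx_valid <- unlist(lapply(split(seq_len(n), cohort$death), function(g) {
        sample(g, floor(length(g) / 2))
      }), use.names = FALSE)
    } else {
      idx_valid <- sample.int(n, floor(n / 2))
    }
    list(
      train = cohort[-idx_valid, , drop = FALSE],
      valid = cohort[idx_valid, , drop = FALSE]
    )
  })
}

#' Univariate screen of death-risk candidates
#'
#' One-predictor logistic fit per candidate; a candidate is retained when
#' its joint Wald test (all levels of a categorical predictor at once) has
#' p below the entry threshold.
#'
#' @param train training cohort.
#' @param candidates candidate column names.
#' @param outcome binary outcome column (default `"death"`).
#' @param alpha entry threshold (default 0.05).
#' @return tibble `(candidate, df, p, retained)`; the retained names are in
#'   attribute `retained`.
#' @export
univariate_screen <- function(train, candidates, outcome = "death",
                              alpha = 0.05) {
  if (length(candidates) == 0) {
    rows <- tibble::tibble(candidate = character(), df = integer(),
                           p = numeric(), retained = logical())
    attr(rows, "retained") <- character(0)
    return(rows)
  }
  rows <- purrr::map_dfr(candidates, function(cand) {
    d <- train
    fit <- tryCatch(
      fit_logistic(stats::as.formula(paste(outcome, "~", cand)), d),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(tibble::tibble(candidate = cand, df = NA_integer_,
                            p = NA_real_, retained = FALSE))
    }
    terms <- setdiff(fit$tidy$term, "(Intercept)")
    p <- wald_joint_p(fit, terms)
    tibble::tibble(candidate = cand, df = length(terms), p = p,
                   retained = is.finite(p) && p < alpha)
  })
  attr(rows, "retained") <- rows$candidate[rows$retained]
  rows
}

#' Multivariate death-risk fit with forced age
#'
#' Joint logistic fit of the retained risk factors; age is always forced
#' into the model regardless of its univariate p-value (switch off by
#' passing `force = character(0)`).
#'
#' @param train training cohort.
#' @param retained predictor column names retained by the screen.
#' @param force columns forced into the model (default `"age_years"`).
#' @param outcome binary outcome column (default `"death"`).
#' @return a `logistic_fit`.
#' @export
multivariate_fit <- function(train, retained, force = "age_years",
                             outcome = "death") {
  predictors <- union(retained, force)
  if (length(predictors) == 0) {
    rlang::abort("no predictors: retention empty and nothing forced.",
                 class = "pvsignal_degenerate_error")
  }
  rhs <- paste(predictors, collapse = " + ")
  fit_logistic(stats::as.formula(paste(outcome, "~", rhs)), train)
}

#' Build a point-scale nomogram from a logistic fit
#'
#' Rescales each model term's contribution to points: the predictor with
#' the largest coefficient-times-range span covers 0-100 points, every
#' term's reference value maps to 0 points, and the total-points-to-
#' probability map goes through the reconstructed linear predictor and the
#' logistic link, so nomogram probabilities reproduce model probabilities
#' exactly.
#'
#' @param fit a converged `logistic_fit`.
#' @param data data frame defining the observed range of each model-matrix
#'   column (typically the training set).
#' @return an object of class `nomogram_spec`: per-term table (`term`,
#'   `beta`, `x_min`, `x_max`, `x_ref`, `max_points`), `intercept`,
#'   `base_lp` (linear predictor at all-reference), and `lp_per_point`.
#' @export
build_nomogram <- function(fit, data) {
  if (!fit$converged) {
    rlang::abort("nomogram requires a converged fit.",
                 class = "pvsignal_config_error")
  }
  mm <- stats::model.matrix(stats::formula(fit$glm),
                            prepare_model_data(data))
  beta <- stats::coef(fit$glm)
  terms <- setdiff(colnames(mm), "(Intercept)")
  x_min <- apply(mm[, terms, drop = FALSE], 2, min)
  x_max <- apply(mm[, terms, drop = FALSE], 2, max)
  span <- abs(beta[terms]) * (x_max - x_min)
  if (all(span == 0)) {
    rlang::abort("all predictors have zero range in `data`.",
                 class = "pvsignal_config_error")
  }
  max_span <- max(span)
  # Reference value of a term: the end of its observed range with the
  # smaller contribution beta*x, so points are nonnegative.
  x_ref <- ifelse(beta[terms] >= 0, x_min, x_max)
  scale <- 100 / max_span
  spec <- tibble::tibble(
    term = terms,
    beta = unname(beta[terms]),
    x_min = unname(x_min), x_max = unname(x_max),
    x_ref = unname(x_ref),
    max_points = unname(span * scale)
  )
  structure(
    list(
      table = spec,
      intercept = unname(beta["(Intercept)"]),
      base_lp = unname(beta["(Intercept)"] + sum(beta[terms] * x_ref)),
      lp_per_point = max_span / 100,
      formula = stats::formula(fit$glm),
      xlevels = fit$glm$xlevels
    ),
    class = "nomogram_spec"
  )
}

#' @export
print.nomogram_spec <- function(x, ...) {
  cat(sprintf("<nomogram_spec> %d terms | base lp %.4f | lp per point %.5f\n",
              nrow(x$table), x$base_lp, x$lp_per_point))
  print(x$table)
  invisible(x)
}

#' Total nomogram points for new observations
#'
#' @param nomogram a `nomogram_spec`.
#' @param newdata data frame of covariate rows.
#' @return numeric vector of total points (reference-level rows score 0).
#' @export
nomogram_points <- function(nomogram, newdata) {
  tt <- stats::delete.response(stats::terms(nomogram$formula))
  mf <- stats::model.frame(tt, prepare_model_data(newdata),
                           xlev = nomogram$xlevels)
  mm <- stats::model.matrix(tt, mf)
  tb <- nomogram$table
  contrib <- sweep(mm[, tb$term, drop = FALSE], 2, tb$x_ref) %*% tb$beta
  as.numeric(contrib) / nomogram$lp_per_point
}

#' Probability from total nomogram points
#'
#' Strictly increasing in total points.
#'
#' @param nomogram a `nomogram_spec`.
#' @param total_points numeric vector of total points.
#' @return predicted death probabilities.
#' @export
nomogram_prob <- function(nomogram, total_points) {
  stats::plogis(nomogram$base_lp + nomogram$lp_per_point * total_points)
}

#' Area under the ROC curve
#'
#' The Mann-Whitney statistic: the probability a random event score exceeds
#' a random non-event score, ties counting one half. Computed from mean
#' ranks, equivalent to the trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric risk scores.
#' @param labels binary labels (logical or 0/1).
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)) # 1
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    rlang::abort("both classes must be present.",
                 class = "pvsignal_degenerate_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve points
#'
#' @param scores numeric risk scores.
#' @param labels binary labels.
#' @return tibble `(threshold, tpr, fpr)` over the unique scores.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  purrr::map_dfr(th, function(t) {
    pos <- scores >= t
    tibble::tibble(
      threshold = t,
      tpr = sum(pos & labels) / sum(labels),
      fpr = sum(pos & !labels) / sum(!labels)
    )
  })
}

#' Bootstrap calibration curve and mean absolute error
#'
#' Refits the model on bootstrap resamples, scores the original data with
#' each refit, bins the original observations by deciles of the original
#' predictions (empty bins are merged by using unique quantile breaks), and
#' compares bin-averaged predicted risk against the observed event
#' fraction. The calibration MAE is the mean absolute predicted-observed
#' difference over bins, averaged over resamples.
#'
#' @param fit a converged `logistic_fit`.
#' @param data the data the fit was built on.
#' @param n_boot number of bootstrap resamples (default 2000).
#' @param bins number of risk bins (default 10, i.e. deciles).
#' @param seed integer seed.
#' @param outcome outcome column name (default `"death"`).
#' @return list of class `calibration_report`: `mae`, `curve` (tibble
#'   `bin`, `mean_predicted`, `observed`, `n`), `n_boot`, `n_failed`.
#' @export
bootstrap_calibration <- function(fit, data, n_boot = 2000, bins = 10,
                                  seed = 1L, outcome = "death") {
  if (!fit$converged) {
    rlang::abort("calibration requires a converged fit.",
                 class = "pvsignal_config_error")
  }
  data <- prepare_model_data(data)
  p0 <- predict(fit, data)
  y <- as.numeric(data[[outcome]])
  breaks <- unique(stats::quantile(p0, probs = seq(0, 1, length.out = bins + 1),
                                   type = 7))
  if (length(breaks) < 3) breaks <- c(-Inf, stats::median(p0), Inf)
  bin <- cut(p0, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  observed <- tapply(y, bin, mean)
  fml <- stats::formula(fit$glm)
  n <- nrow(data)

  withr::with_seed(seed, {
    n_failed <- 0L
    pred_sum <- numeric(length(observed))
    mae_sum <- 0
    done <- 0L
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, replace = TRUE)
      refit <- tryCatch(
        suppressWarnings(stats::glm(
          fml, data = data[idx, , drop = FALSE],
          family = stats::binomial(),
          control = stats::glm.control(epsilon = 1e-8, maxit = 100)
        )),
        error = function(e) NULL
      )
      if (is.null(refit) || !refit$converged) {
        n_failed <- n_failed + 1L
        next
      }
      pb <- as.numeric(stats::predict(refit, newdata = data,
                                      type = "response"))
      mp <- tapply(pb, bin, mean)
      pred_sum <- pred_sum + mp
      mae_sum <- mae_sum + mean(abs(mp - observed))
      done <- done + 1L
    }
    if (done == 0L) {
      rlang::abort("all bootstrap refits failed.",
                   class = "pvsignal_degenerate_error")
    }
    structure(
      list(
        mae = mae_sum / done,
        curve = tibble::tibble(
          bin = seq_along(observed),
          mean_predicted = as.numeric(pred_sum / done),
          observed = as.numeric(observed),
          n = as.integer(table(bin))
        ),
        n_boot = done,
        n_failed = n_failed
      ),
      class = "calibration_report"
    )
  })
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration_report> MAE %.4f over %d bins, %d resamples\n",
              x$mae, nrow(x$curve), x$n_boot))
  invisible(x)
}

#' Decision-curve analysis
#'
#' Net benefit of acting on the model at each threshold probability
#' `p_t`: `NB(p_t) = TP/N - FP/N x p_t/(1 - p_t)`, alongside the treat-all
#' and treat-none reference strategies. Thresholds at or above 1 are
#' excluded from the grid.
#'
#' @param probabilities predicted probabilities in `[0, 1]`.
#' @param labels binary outcome labels.
#' @param thresholds threshold grid (default 0.001 to 0.5 step 0.001).
#' @return tibble `(threshold, nb_model, nb_all, nb_none)`.
#' @export
decision_curve <- function(probabilities, labels,
                           thresholds = seq(0.001, 0.5, by = 0.001)) {
  if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE)) {
    rlang::abort("probabilities must lie in [0, 1].",
                 class = "pvsignal_config_error")
  }
  labels <- as.logical(labels)
  thresholds <- thresholds[thresholds < 1]
  n <- length(labels)
  prev <- mean(labels)
  purrr::map_dfr(thresholds, function(pt) {
    pos <- probabilities >= pt
    tp <- sum(pos & labels)
    fp <- sum(pos & !labels)
    w <- pt / (1 - pt)
    tibble::tibble(
      threshold = pt,
      nb_model = tp / n - fp / n * w,
      nb_all = prev - (1 - prev) * w,
      nb_none = 0
    )
  })
}
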