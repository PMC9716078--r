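# Cohort of known death-risk structure used across the tests below.
death_fixture <- function(n, seed) {
  withr::with_seed(seed, {
    d <- tibble::tibble(
      row_id = seq_len(n),
      statin = stats::rbinom(n, 1, 0.3) == 1,
      heart_failure = stats::rbinom(n, 1, 0.1) == 1,
      age_years = round(stats::runif(n, 20, 90)),
      sglt2i = sample(c("canagliflozin", "dapagliflozin", "empagliflozin"),
                      n, TRUE, prob = c(0.45, 0.25, 0.3))
    )
    lp <- -4.8 + 0.9 * d$statin + 0.6 * d$heart_failure +
      0.02 * d$age_years + 0.7 * (d$sglt2i == "dapagliflozin") +
      0.3 * (d$sglt2i == "empagliflozin")
    d$true_p <- stats::plogis(lp)
    d$death <- stats::rbinom(n, 1, d$true_p) == 1
    d
  })
}

test_that("the 1:1 split is disjoint, exhaustive, near-equal and seeded", {
  cohort <- death_fixture(711, seed = 60)
  halves <- split_cohort(cohort, seed = 9)
  expect_equal(sort(c(nrow(halves$train), nrow(halves$valid))), c(355, 356))
  expect_equal(nrow(halves$train) + nrow(halves$valid), 711)
  expect_length(intersect(halves$train$row_id, halves$valid$row_id), 0)
  again <- split_cohort(cohort, seed = 9)
  expect_identical(halves, again)
  expect_false(identical(halves$train, split_cohort(cohort, seed = 10)$train))
  expect_error(split_cohort(cohort[1, ], seed = 1),
               class = "pvsignal_degenerate_error")
})

test_that("stratified splitting balances the event count across halves", {
  cohort <- death_fixture(1000, seed = 61)
  cohort$death <- c(rep(TRUE, 100), rep(FALSE, 900))
  halves <- split_cohort(cohort, seed = 2, stratify = TRUE)
  expect_lte(abs(sum(halves$train$death) - sum(halves$valid$death)), 1)
})

test_that("univariate screening has power for real effects and holds its size", {
  # power: true OR 3 at n = 500, event rate ~0.2
  withr::with_seed(62, {
    power_hits <- vapply(seq_len(50), function(i) {
      d <- tibble::tibble(x = stats::rbinom(500, 1, 0.4))
      d$death <- stats::rbinom(500, 1,
                               stats::plogis(-1.8 + log(3) * d$x)) == 1
      scr <- univariate_screen(d, "x")
      scr$retained[1]
    }, logical(1))
    expect_gte(mean(power_hits), 0.9)
    # size: pure-noise predictor retained at about the entry level
    null_hits <- vapply(seq_len(200), function(i) {
      d <- tibble::tibble(x = stats::rbinom(400, 1, 0.5))
      d$death <- stats::rbinom(400, 1, 0.15) == 1
      univariate_screen(d, "x")$retained[1]
    }, logical(1))
    expect_lte(mean(null_hits), 0.10)
    expect_gte(mean(null_hits), 0.01)
  })
  expect_equal(nrow(univariate_screen(death_fixture(100, 1), character(0))), 0)
})

test_that("the multivariate fit recovers the true coefficients", {
  cohort <- death_fixture(50000, seed = 63)
  fit <- multivariate_fit(cohort, c("statin", "heart_failure", "sglt2i"))
  b <- fit$tidy$beta
  names(b) <- fit$tidy$term
  expect_equal(unname(b["statin"]), 0.9, tolerance = 0.15)
  expect_equal(unname(b["sglt2idapagliflozin"]), 0.7, tolerance = 0.15)
  expect_equal(unname(b["age_years"]), 0.02, tolerance = 0.15)
  # age is forced in even when not listed as retained
  expect_true("age_years" %in% fit$tidy$term)
  # refitting on identical data is deterministic
  fit2 <- multivariate_fit(cohort, c("statin", "heart_failure", "sglt2i"))
  expect_identical(fit$tidy, fit2$tidy)
  # an age-only model reduces to the single-predictor fit
  solo <- multivariate_fit(cohort, character(0))
  expect_equal(setdiff(solo$tidy$term, "(Intercept)"), "age_years")
})

test_that("the nomogram point scale reproduces model probabilities", {
  cohort <- death_fixture(4000, seed = 64)
  fit <- multivariate_fit(cohort, c("statin", "heart_failure", "sglt2i"))
  nom <- build_nomogram(fit, cohort)
  expect_equal(max(nom$table$max_points), 100)
  # reference-level rows score zero points and the base probability
  ref <- tibble::tibble(statin = FALSE, heart_failure = FALSE,
                        age_years = min(cohort$age_years),
                        sglt2i = "canagliflozin")
  expect_equal(nomogram_points(nom, ref), 0, tolerance = 1e-12)
  expect_equal(nomogram_prob(nom, 0), stats::plogis(nom$base_lp))
  # round trip on random covariate rows
  idx <- withr::with_seed(1, sample.int(nrow(cohort), 50))
  rows <- cohort[idx, ]
  pts <- nomogram_points(nom, rows)
  expect_true(all(pts >= -1e-9))
  expect_equal(nomogram_prob(nom, pts), predict(fit, rows),
               tolerance = 1e-9)
  # probability is strictly increasing in total points
  expect_true(all(diff(nomogram_prob(nom, seq(0, 200, 10))) > 0))
})

test_that("AUC equals the pairwise Mann-Whitney comparison", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 10), c(rep(1, 4), rep(0, 6))), 0.5)
  expect_error(roc_auc(1:5, rep(1, 5)), class = "pvsignal_degenerate_error")
  withr::with_seed(65, {
    scores <- round(stats::runif(20), 1) # ties on purpose
    labels <- stats::rbinom(20, 1, 0.4)
  })
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  oracle <- mean(outer(s1, s0, ">") + 0.5 * outer(s1, s0, "=="))
  expect_equal(roc_auc(scores, labels), oracle)
  # invariant under strictly increasing transforms
  expect_equal(roc_auc(qlogis(pmin(pmax(scores, 0.01), 0.99)), labels),
               roc_auc(pmin(pmax(scores, 0.01), 0.99), labels))
})

test_that("bootstrap calibration is small for well-specified data and ordered", {
  cohort <- death_fixture(4000, seed = 66)
  fit <- multivariate_fit(cohort, c("statin", "sglt2i"))
  cal <- bootstrap_calibration(fit, cohort, n_boot = 100, seed = 5)
  expect_lt(cal$mae, 0.02)
  expect_equal(nrow(cal$curve) <= 10, TRUE)
  # reproducible given the seed, even at a single resample
  c1 <- bootstrap_calibration(fit, cohort, n_boot = 1, seed = 7)
  c2 <- bootstrap_calibration(fit, cohort, n_boot = 1, seed = 7)
  expect_identical(c1$curve, c2$curve)
  # a deliberately miscalibrated score sheet scores worse
  p <- predict(fit, cohort)
  y <- as.numeric(cohort$death)
  bins <- cut(p, unique(stats::quantile(p, 0:10 / 10)),
              include.lowest = TRUE, labels = FALSE)
  mae_of <- function(pred) {
    mean(abs(tapply(pred, bins, mean) - tapply(y, bins, mean)))
  }
  expect_gt(mae_of(p^2), mae_of(p))
})

test_that("net benefit follows its defining formula and reference curves", {
  withr::with_seed(67, {
    p <- stats::runif(1000)
    y <- stats::rbinom(1000, 1, p) # informative scores
  })
  prev <- mean(y)
  dc <- decision_curve(p, y, thresholds = c(0, 0.1, 0.25, 0.999))
  expect_equal(dc$nb_none, rep(0, 4))
  expect_equal(dc$nb_model[1], prev)  # threshold 0 classifies everyone
  expect_equal(dc$nb_all[1], prev)
  # direct formula check at one threshold
  pt <- 0.25
  tp <- sum(p >= pt & y == 1); fp <- sum(p >= pt & y == 0)
  expect_equal(dc$nb_model[3], tp / 1000 - fp / 1000 * pt / (1 - pt))
  expect_true(all(dc$nb_model <= prev + 1e-12))
  expect_true(all(dc$nb_model >= dc$nb_all - 1e-12))
  # classify-all at fixed prevalence: closed-form reference value
  y2 <- c(rep(1, 200), rep(0, 800))
  dc2 <- decision_curve(rep(1, 1000), y2, thresholds = 0.25)
  expect_equal(dc2$nb_all, 0.2 - 0.8 * (0.25 / 0.75), tolerance = 1e-12)
  expect_error(decision_curve(c(-0.1, 0.5), c(0, 1)),
               class = "pvsignal_config_error")
})
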