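#' Configuration for the synthetic spontaneous-report generator
#'
#' Defines the ground truth of a simulated FAERS-like dataset: how many
#' reports, how prevalent the target drug class is, how strongly the target
#' event is associated with it (as an odds multiplier), the demographic
#' marginals, the onset-time law, co-medication prevalences and their odds
#' multipliers, and the coefficients of the true logistic death model.
#'
#' Demographic strata default to the observed marginals of the acute
#' pancreatitis / SGLT-2i reporting cohort (sex, age group, reporting year,
#' reporter occupation, country, per-drug share); they are sampled
#' independently across fields since only marginals are available. Age is
#' drawn from a normal law (mean 56.2, sd 12.1) truncated within the sampled
#' age-group bounds, so both the group marginals and the cohort mean age are
#' reproduced.
#'
#' The onset-time law defaults to a lognormal with median 54 days and
#' `sdlog` 1.2618, calibrated so that the median is 54 days and 83% of the
#' mass lies within 180 days.
#'
#' @param n_reports number of distinct cases to simulate (>= 1).
#' @param target_drug_names generic names of the target drug class.
#' @param target_prevalence probability a report's suspect drug is a target
#'   drug.
#' @param background_event_rate probability a non-target report carries the
#'   target event.
#' @param injected_ror odds multiplier for the target event on target-drug
#'   reports (class-level reporting odds ratio to inject; must be > 0).
#' @param demographic_mix named list of probability vectors for `sex`,
#'   `age_group`, `country`, `reporter`, `year`, and `drug_share`; each must
#'   sum to 1 (tolerance 1e-9).
#' @param age_mean,age_sd parameters of the truncated-normal age law (years).
#' @param weight_mean,weight_sd,weight_missing body-weight law (kg) and its
#'   missingness fraction.
#' @param tto_law list `(family = "lognormal", meanlog, sdlog)` for
#'   days-to-onset on event-positive target-drug reports.
#' @param comed_prevalence named probabilities of carrying each co-medication
#'   class.
#' @param comed_or named odds multipliers each co-medication applies to the
#'   target-event odds on target-drug reports (1 = no effect).
#' @param hf_prevalence probability of a heart-failure indication.
#' @param death_model_beta named coefficients of the true logistic death
#'   model on target-drug reports: `intercept`, `age` (per year), `statin`,
#'   `heart_failure`, and per-type contrasts `dapagliflozin`,
#'   `empagliflozin`, `ertugliflozin` (canagliflozin is reference).
#' @param background_death_rate death probability on non-target reports.
#' @param missing named list of missingness probabilities injected per field
#'   (`sex`, `age`, `therapy_start`); default 0.
#' @param dup_fraction fraction of cases additionally emitted as a
#'   second case version (exercises deduplication); default 0.
#' @param seed integer seed; every simulation is reproducible given the seed.
#' @return an object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_reports = 1000, injected_ror = 5, seed = 1)
sim_config <- function(n_reports,
                       target_drug_names = sglt2i_generics(),
                       target_prevalence = 0.01,
                       background_event_rate = 0.01,
                       injected_ror = 1,
                       demographic_mix = default_demographic_mix(),
                       age_mean = 56.2, age_sd = 12.1,
                       weight_mean = 95.8, weight_sd = 24.4,
                       weight_missing = 0.559,
                       tto_law = default_tto_law(),
                       comed_prevalence = default_comed_prevalence(),
                       comed_or = default_comed_or(),
                       hf_prevalence = 0.08,
                       death_model_beta = default_death_model_beta(),
                       background_death_rate = 0.03,
                       missing = list(sex = 0, age = 0, therapy_start = 0),
                       dup_fraction = 0,
                       seed = 1L) {
  if (!is.numeric(n_reports) || length(n_reports) != 1 || n_reports < 1 ||
      n_reports != floor(n_reports)) {
    rlang::abort("`n_reports` must be a positive integer.",
                 class = "pvsignal_config_error")
  }
  if (!is.numeric(injected_ror) || injected_ror <= 0) {
    rlang::abort("`injected_ror` must be a positive real.",
                 class = "pvsignal_config_error")
  }
  probs <- c(target_prevalence, background_event_rate, hf_prevalence,
             background_death_rate, weight_missing, dup_fraction,
             unlist(missing), unlist(comed_prevalence))
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    rlang::abort("all probabilities must lie in [0, 1].",
                 class = "pvsignal_config_error")
  }
  for (nm in names(demographic_mix)) {
    s <- sum(demographic_mix[[nm]])
    if (abs(s - 1) > 1e-9) {
      rlang::abort(
        sprintf("demographic_mix$%s must sum to 1 (got %.12f).", nm, s),
        class = "pvsignal_config_error"
      )
    }
  }
  if (any(unlist(comed_or) <= 0)) {
    rlang::abort("co-medication odds multipliers must be positive.",
                 class = "pvsignal_config_error")
  }
  structure(
    list(
      n_reports = as.integer(n_reports),
      target_drug_names = target_drug_names,
      target_prevalence = target_prevalence,
      background_event_rate = background_event_rate,
      injected_ror = injected_ror,
      demographic_mix = demographic_mix,
      age_mean = age_mean, age_sd = age_sd,
      weight_mean = weight_mean, weight_sd = weight_sd,
      weight_missing = weight_missing,
      tto_law = tto_law,
      comed_prevalence = comed_prevalence,
      comed_or = comed_or,
      hf_prevalence = hf_prevalence,
      death_model_beta = death_model_beta,
      background_death_rate = background_death_rate,
      missing = missing,
      dup_fraction = dup_fraction,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @export
default_demographic_mix <- function() {
  list(
    sex = c(M = 429, F = 328) / 757,
    age_group = c(`<18` = 1, `18-64` = 568, `65-80` = 176, `>80` = 12) / 757,
    country = c(US = 499, CA = 47, GB = 35, JP = 11, BR = 14, DE = 18,
                ES = 10, OTHER = 123) / 757,
    reporter = c(physician = 308, pharmacist = 83,
                 `other health professional` = 117, lawyer = 3,
                 consumer = 205, unknown = 41) / 757,
    year = c(`2013` = 2, `2014` = 28, `2015` = 111, `2016` = 124,
             `2017` = 106, `2018` = 110, `2019` = 106, `2020` = 82,
             `2021` = 88) / 757,
    drug_share = c(canagliflozin = 317, dapagliflozin = 150,
                   empagliflozin = 287, ertugliflozin = 3) / 757
  )
}

#' @rdname sim_config
#' @export
default_tto_law <- function() {
  # median 54 d; sdlog solves P(X <= 180) = 0.83
  list(family = "lognormal", meanlog = log(54),
       sdlog = log(180 / 54) / stats::qnorm(0.83))
}

#' @rdname sim_config
#' @export
default_comed_prevalence <- function() {
  c(dpp4i = 0.08, glp1ra = 0.08, metformin = 0.35, insulin = 0.25,
    glinide = 0.02, acei = 0.20, ppi = 0.18, statin = 0.30)
}

#' @rdname sim_config
#' @export
default_comed_or <- function() {
  c(dpp4i = 1.39, glp1ra = 1.97, metformin = 1.29, insulin = 1.21,
    glinide = 2.55, acei = 1.34, ppi = 1.32, statin = 1.0)
}

#' @rdname sim_config
#' @export
default_death_model_beta <- function() {
  c(intercept = -5.0, age = 0.02, statin = 0.9, heart_failure = 0.6,
    dapagliflozin = 0.7, empagliflozin = 0.3, ertugliflozin = 1.5)
}

#' Draw onset-to-event intervals from an onset-time law
#'
#' @param n number of draws.
#' @param tto_law list as in [sim_config()] (`family` currently
#'   `"lognormal"`).
#' @return integer days (rounded, floored at 0).
#' @export
draw_onset_days <- function(n, tto_law = default_tto_law()) {
  if (!identical(tto_law$family, "lognormal")) {
    rlang::abort("only the lognormal onset-time family is implemented.",
                 class = "pvsignal_config_error")
  }
  pmax(0L, as.integer(round(stats::rlnorm(n, tto_law$meanlog, tto_law$sdlog))))
}
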