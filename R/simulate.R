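#' Simulate a FAERS-like spontaneous-report dataset with known ground truth
#'
#' Generates `n_reports` cases following the relational structure of a
#' quarterly extract (see [faers_reports()]). Each case receives a suspect
#' drug (a target-class member with probability `target_prevalence`,
#' otherwise a background drug), independent demographic draws from the
#' configured marginals, co-medication flags, and reaction terms. The target
#' event is assigned by the odds model
#' `odds(event | target drug) = injected_ror x odds(event | other drug)`,
#' with co-medication odds multipliers applied on target-drug reports and
#' renormalized so the class-level odds ratio stays at `injected_ror`. Death
#' is drawn from the configured logistic model on target-drug reports (and a
#' constant background rate elsewhere); days-to-onset for event-positive
#' target reports follow the configured onset-time law and are materialized
#' as therapy start dates relative to the event date.
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_dataset`: a list with `reports` (a
#'   [faers_reports()] set) and `truth` (the config plus a `latent` tibble of
#'   per-report ground truth: target membership, event and death indicators,
#'   true death probability, true onset day, co-medication flags).
#' @export
#' @examples
#' sim <- simulate_reports(sim_config(n_reports = 200, seed = 7))
#' sim$reports
simulate_reports <- function(config) {
  if (!inherits(config, "sim_config")) {
    rlang::abort("`config` must be built with sim_config().",
                 class = "pvsignal_config_error")
  }
  withr::with_seed(config$seed, simulate_reports_impl(config))
}

simulate_reports_impl <- function(config) {
  n <- config$n_reports
  mix <- config$demographic_mix
  sample_levels <- function(p) sample(names(p), n, replace = TRUE, prob = p)

  case_id <- as.character(10000000 + seq_len(n))
  case_version <- rep(1L, n)
  primary_id <- paste0(case_id, case_version)

  is_target <- stats::runif(n) < config$target_prevalence
  sglt2i_type <- rep(NA_character_, n)
  sglt2i_type[is_target] <- sample(
    names(mix$drug_share), sum(is_target), replace = TRUE,
    prob = mix$drug_share
  )

  sex <- sample_levels(mix$sex)
  age_group <- sample_levels(mix$age_group)
  bounds <- list(`<18` = c(5, 17.9), `18-64` = c(18, 64.9),
                 `65-80` = c(65, 80.9), `>80` = c(81, 95))
  lo <- vapply(bounds, `[`, numeric(1), 1)[age_group]
  hi <- vapply(bounds, `[`, numeric(1), 2)[age_group]
  age <- round(rtruncnorm(n, config$age_mean, config$age_sd, lo, hi))
  weight <- round(rtruncnorm(n, config$weight_mean, config$weight_sd, 40, 200), 1)
  weight[stats::runif(n) < config$weight_missing] <- NA_real_
  country <- sample_levels(mix$country)
  reporter <- sample_levels(mix$reporter)
  year <- as.integer(sample_levels(mix$year))

  report_date <- as.Date(paste0(year, "-01-01")) +
    floor(stats::runif(n) * 365)
  event_date <- report_date - sample(0:60, n, replace = TRUE)

  comed_names <- names(config$comed_prevalence)
  comed <- vapply(
    comed_names,
    function(cl) stats::runif(n) < config$comed_prevalence[[cl]],
    logical(n)
  )
  if (n == 1) comed <- matrix(comed, nrow = 1, dimnames = list(NULL, comed_names))
  heart_failure <- stats::runif(n) < config$hf_prevalence

  # Target-event assignment. Co-medication multipliers act on the
  # within-target odds; because odds ratios are non-collapsible, the
  # target-arm odds are calibrated exactly (enumerating all co-medication
  # patterns) so the marginal class-level odds ratio equals `injected_ror`.
  p_bg <- config$background_event_rate
  odds_bg <- p_bg / (1 - p_bg)
  or_vec <- unlist(config$comed_or)[comed_names]
  log_or <- log(or_vec)
  comed_mult <- exp(as.vector(comed %*% log_or))
  k <- calibrate_target_odds(odds_bg * config$injected_ror,
                             config$comed_prevalence[comed_names], or_vec)
  odds <- ifelse(is_target, k * comed_mult, odds_bg)
  p_event <- odds / (1 + odds)
  event <- stats::runif(n) < p_event

  # Death: true logistic model on target reports, constant elsewhere.
  b <- config$death_model_beta
  lp <- b[["intercept"]] + b[["age"]] * age +
    b[["statin"]] * comed[, "statin"] +
    b[["heart_failure"]] * heart_failure +
    b[["dapagliflozin"]] * (sglt2i_type %in% "dapagliflozin") +
    b[["empagliflozin"]] * (sglt2i_type %in% "empagliflozin") +
    b[["ertugliflozin"]] * (sglt2i_type %in% "ertugliflozin")
  true_death_prob <- ifelse(is_target, stats::plogis(lp),
                            config$background_death_rate)
  death <- stats::runif(n) < true_death_prob

  # Onset day and therapy start (suspect drug only, drug_seq 1).
  true_onset_day <- rep(NA_integer_, n)
  onset_idx <- which(is_target & event)
  true_onset_day[onset_idx] <- draw_onset_days(length(onset_idx),
                                               config$tto_law)
  start_date <- event_date - sample(30:1000, n, replace = TRUE)
  start_date[onset_idx] <- event_date[onset_idx] - true_onset_day[onset_idx]
  start_date[stats::runif(n) < config$missing$therapy_start] <- NA

  # Injected missingness on exclusion-rule fields (after the latent truth
  # is fixed, so the truth keeps complete values).
  sex_obs <- sex
  sex_obs[stats::runif(n) < config$missing$sex] <- NA_character_
  age_obs <- age
  age_obs[stats::runif(n) < config$missing$age] <- NA_real_

  demo <- tibble::tibble(
    primary_id = primary_id, case_id = case_id, case_version = case_version,
    event_date = event_date, event_date_precision = "day",
    report_date = report_date, report_date_precision = "day",
    sex = sex_obs, age_years = age_obs, weight_kg = weight,
    reporter = reporter, country = country
  )

  # Suspect drug row (+ indication carrying the heart-failure flag), then
  # one concomitant row per flagged co-medication class.
  brand <- c(canagliflozin = "INVOKANA", dapagliflozin = "FARXIGA",
             empagliflozin = "JARDIANCE", ertugliflozin = "STEGLATRO")
  background_drugs <- c("AMLODIPINE", "LEVOTHYROXINE", "ASPIRIN",
                        "IBUPROFEN", "SERTRALINE", "ALBUTEROL", "WARFARIN",
                        "GABAPENTIN", "ADALIMUMAB", "METHOTREXATE",
                        "PREDNISONE", "HYDROCHLOROTHIAZIDE")
  use_brand <- stats::runif(n) < 0.3
  suspect_name <- ifelse(
    is_target,
    ifelse(use_brand, brand[sglt2i_type], toupper(sglt2i_type)),
    sample(background_drugs, n, replace = TRUE)
  )
  suspect <- tibble::tibble(
    primary_id = primary_id, drug_seq = 1L, role = "PS",
    drugname = suspect_name,
    indication = ifelse(heart_failure, "Cardiac failure",
                        "Type 2 diabetes mellitus")
  )
  comed_ingredient <- c(
    dpp4i = "SITAGLIPTIN", glp1ra = "LIRAGLUTIDE", metformin = "METFORMIN",
    insulin = "INSULIN GLARGINE", glinide = "REPAGLINIDE",
    acei = "LISINOPRIL", ppi = "OMEPRAZOLE", statin = "ATORVASTATIN"
  )
  hit <- which(comed, arr.ind = TRUE)
  comed_rows <- tibble::tibble(
    primary_id = primary_id[hit[, 1]],
    drug_seq = 1L + hit[, 2],
    role = "C",
    drugname = unname(comed_ingredient[comed_names[hit[, 2]]]),
    indication = NA_character_
  )
  drug <- dplyr::arrange(dplyr::bind_rows(suspect, comed_rows),
                         .data$primary_id, .data$drug_seq)

  # Reactions: the target event PT where assigned, a background PT
  # otherwise; ~30% of reports carry a second background PT.
  ap_weights <- c(0.05, 0.60, 0.25, 0.02, 0.01, 0.02, 0.01, 0.03, 0.01)
  background_pts <- c(
    "Nausea", "Headache", "Diarrhoea", "Dizziness", "Fatigue", "Rash",
    "Vomiting", "Pruritus", "Arthralgia", "Urinary tract infection",
    "Hypoglycaemia", "Dehydration", "Renal impairment", "Weight decreased",
    "Diabetic ketoacidosis", "Fall", "Myalgia", "Insomnia", "Cough",
    "Oedema peripheral"
  )
  primary_pt <- sample(background_pts, n, replace = TRUE)
  primary_pt[event] <- sample(ap_term_cluster(), sum(event), replace = TRUE,
                              prob = ap_weights)
  second <- which(stats::runif(n) < 0.3)
  reac <- tibble::tibble(
    primary_id = c(primary_id, primary_id[second]),
    pt = c(primary_pt, sample(background_pts, length(second), replace = TRUE))
  )

  outc_flags <- cbind(
    DE = death,
    HO = stats::runif(n) < 0.70,
    LT = stats::runif(n) < 0.107,
    DS = stats::runif(n) < 0.026,
    OT = stats::runif(n) < 0.15
  )
  oh <- which(outc_flags, arr.ind = TRUE)
  outc <- tibble::tibble(
    primary_id = primary_id[oh[, 1]],
    outcome = colnames(outc_flags)[oh[, 2]]
  )

  ther <- tibble::tibble(
    primary_id = primary_id, drug_seq = 1L,
    start_date = start_date,
    start_date_precision = ifelse(is.na(start_date), NA_character_, "day")
  )
  ther <- dplyr::filter(ther, !is.na(.data$start_date))

  reports <- faers_reports(demo, drug, reac, outc, ther)

  # Optional duplicate case versions for deduplication exercises.
  if (config$dup_fraction > 0) {
    k <- which(stats::runif(n) < config$dup_fraction)
    if (length(k) > 0) {
      dup_ids <- primary_id[k]
      new_ids <- paste0(case_id[k], 2L)
      remap <- function(tb) {
        d <- dplyr::filter(tb, .data$primary_id %in% dup_ids)
        d$primary_id <- new_ids[match(d$primary_id, dup_ids)]
        d
      }
      demo2 <- remap(demo)
      demo2$case_version <- 2L
      reports <- faers_reports(
        demo = dplyr::bind_rows(demo, demo2),
        drug = dplyr::bind_rows(drug, remap(drug)),
        reac = dplyr::bind_rows(reac, remap(reac)),
        outc = dplyr::bind_rows(outc, remap(outc)),
        ther = dplyr::bind_rows(ther, remap(ther))
      )
    }
  }

  latent <- tibble::tibble(
    primary_id = primary_id,
    is_target = is_target,
    sglt2i_type = sglt2i_type,
    event = event,
    true_event_prob = p_event,
    death = death,
    true_death_prob = true_death_prob,
    true_onset_day = true_onset_day,
    age_years = age, sex = sex,
    heart_failure = heart_failure
  )
  latent <- dplyr::bind_cols(latent, tibble::as_tibble(comed))

  structure(
    list(reports = reports, truth = list(config = config, latent = latent)),
    class = "sim_dataset"
  )
}

# Baseline odds k for the target arm such that the pooled event
# probability over the co-medication pattern distribution equals
# target_odds/(1 + target_odds). With all multipliers at 1 this reduces to
# k = target_odds.
calibrate_target_odds <- function(target_odds, prevalence, or_vec) {
  if (all(or_vec == 1)) return(target_odds)
  patterns <- as.matrix(expand.grid(rep(list(c(0, 1)), length(or_vec))))
  w <- apply(patterns, 1, function(g) {
    prod(ifelse(g == 1, prevalence, 1 - prevalence))
  })
  m <- exp(as.vector(patterns %*% log(or_vec)))
  target_p <- target_odds / (1 + target_odds)
  f <- function(k) sum(w * (k * m) / (1 + k * m)) - target_p
  stats::uniroot(f, lower = 1e-12, upper = 1e9, tol = 1e-12)$root
}

#' @export
print.sim_dataset <- function(x, ...) {
  lat <- x$truth$latent
  cat(sprintf(
    "<sim_dataset> %d reports | %d target-drug | %d target-event | injected ROR %.3g | seed %d\n",
    nrow(lat), sum(lat$is_target), sum(lat$event),
    x$truth$config$injected_ror, x$truth$config$seed
  ))
  invisible(x)
}
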