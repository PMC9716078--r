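#' Extract the target-drug cohort against the event cluster
#'
#' Restricts a deduplicated report set to reports where at least one target
#' drug (SGLT-2i class member) appears in a suspect role (`PS` or `SS` by
#' default; pass `roles = c("PS", "SS", "C", "I")` to relax), and derives
#' one analysis row per report: the event flag (any reaction PT in the
#' acute-pancreatitis cluster), the SGLT-2i type, per-class co-medication
#' flags (any role), a heart-failure flag from indication strings,
#' demographics, outcome flags, a death flag (`DE` outcome), and the
#' therapy-start-to-event interval in days where computable.
#'
#' @param reports a deduplicated `faers_reports` set.
#' @param dictionary an [event_dictionary()].
#' @param require_demographics drop rows missing sex or age (the drop count
#'   is recorded in the `attrition` attribute).
#' @param drop_multi_sglt2i drop rows listing two or more distinct SGLT-2i
#'   (required for the death-model path).
#' @param roles drug roles that qualify a report for cohort membership.
#' @return a tibble, one row per cohort report, with attribute `attrition`
#'   (named counts at each filter step).
#' @export
extract_cohort <- function(reports, dictionary = event_dictionary(),
                           require_demographics = FALSE,
                           drop_multi_sglt2i = FALSE,
                           roles = c("PS", "SS")) {
  if (!inherits(dictionary, "event_dictionary") ||
      length(dictionary$ap_terms) == 0) {
    rlang::abort("a non-empty event_dictionary is required.",
                 class = "pvsignal_config_error")
  }
  n_input <- n_reports(reports)

  # Suspect-role SGLT-2i rows; the type is the generic whose name patterns
  # matched. Reports matching several generics get all types recorded.
  drug <- reports$drug
  suspect <- drug[drug$role %in% roles, , drop = FALSE]
  type_rows <- purrr::map_dfr(sglt2i_generics(), function(g) {
    hit <- matches_any_substring(suspect$drugname, sglt2i_patterns(g))
    tibble::tibble(primary_id = unique(suspect$primary_id[hit]), sglt2i = g)
  })
  if (nrow(type_rows) == 0) {
    cohort <- empty_cohort()
    attr(cohort, "attrition") <- c(n_input = n_input, n_sglt2i = 0L,
                                   dropped_demographics = 0L,
                                   dropped_multi_sglt2i = 0L, n_final = 0L)
    return(cohort)
  }
  types <- type_rows |>
    dplyr::group_by(.data$primary_id) |>
    dplyr::summarise(
      n_sglt2i_types = dplyr::n_distinct(.data$sglt2i),
      sglt2i = .data$sglt2i[1],
      .groups = "drop"
    )

  ids <- types$primary_id
  ap_ids <- unique(reports$reac$primary_id[
    is_ap_term(reports$reac$pt, dictionary)
  ])
  death_ids <- unique(reports$outc$primary_id[reports$outc$outcome == "DE"])
  outc_flag <- function(code) {
    ids %in% unique(reports$outc$primary_id[reports$outc$outcome == code])
  }

  comed_classes <- setdiff(names(dictionary$drug_classes), "sglt2i")
  comed_flags <- lapply(comed_classes, function(cl) {
    hit <- matches_any_substring(drug$drugname,
                                 dictionary$drug_classes[[cl]])
    ids %in% unique(drug$primary_id[hit])
  })
  names(comed_flags) <- comed_classes

  hf_ids <- unique(drug$primary_id[
    !is.na(drug$indication) &
      stringr::str_detect(normalize_term(drug$indication),
                          "cardiac failure|heart failure")
  ])

  demo <- reports$demo[match(ids, reports$demo$primary_id), , drop = FALSE]
  onset <- onset_days(reports, dictionary, roles = roles)

  cohort <- tibble::tibble(
    primary_id = ids,
    case_id = demo$case_id,
    sglt2i = types$sglt2i,
    n_sglt2i_types = types$n_sglt2i_types,
    ap = ids %in% ap_ids,
    death = ids %in% death_ids,
    hospitalization = outc_flag("HO"),
    life_threatening = outc_flag("LT"),
    disabling = outc_flag("DS"),
    sex = demo$sex,
    age_years = demo$age_years,
    age_group = age_group_of(demo$age_years),
    weight_kg = demo$weight_kg,
    country = demo$country,
    reporter = demo$reporter,
    year = as.integer(format(demo$report_date, "%Y")),
    heart_failure = ids %in% hf_ids,
    onset_days = onset$onset_days[match(ids, onset$primary_id)]
  )
  cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(comed_flags))

  n_sglt2i <- nrow(cohort)
  dropped_demo <- 0L
  if (require_demographics) {
    ok <- !is.na(cohort$sex) & !is.na(cohort$age_years)
    dropped_demo <- sum(!ok)
    cohort <- cohort[ok, , drop = FALSE]
  }
  dropped_multi <- 0L
  if (drop_multi_sglt2i) {
    ok <- cohort$n_sglt2i_types < 2
    dropped_multi <- sum(!ok)
    cohort <- cohort[ok, , drop = FALSE]
  }
  cohort <- dplyr::arrange(cohort, .data$primary_id)
  attr(cohort, "attrition") <- c(
    n_input = n_input, n_sglt2i = n_sglt2i,
    dropped_demographics = dropped_demo,
    dropped_multi_sglt2i = dropped_multi,
    n_final = nrow(cohort)
  )
  cohort
}

empty_cohort <- function() {
  tibble::tibble(
    primary_id = character(), case_id = character(), sglt2i = character(),
    n_sglt2i_types = integer(), ap = logical(), death = logical(),
    hospitalization = logical(), life_threatening = logical(),
    disabling = logical(), sex = character(), age_years = numeric(),
    age_group = character(), weight_kg = numeric(), country = character(),
    reporter = character(), year = integer(), heart_failure = logical(),
    onset_days = integer()
  )
}

# Age banding used throughout the cohort summaries.
age_group_of <- function(age) {
  cut(age, breaks = c(-Inf, 18, 65, 81, Inf),
      labels = c("<18", "18-64", "65-80", ">80"), right = FALSE) |>
    as.character()
}

#' Stratified cohort summary
#'
#' Per-drug and pooled counts/percentages for sex, age group, reporting
#' year, reporter occupation, country and outcome flags, plus per-drug and
#' pooled mean age. The pooled mean age is the count-weighted mean of the
#' per-stratum means, and every percentage is rounded half-up to one
#' decimal.
#'
#' @param cohort a cohort tibble from [extract_cohort()].
#' @return a list of class `cohort_summary` with elements `counts` (long
#'   tibble: characteristic, level, drug, n, total, pct) and `age` (per-drug
#'   mean/sd plus the pooled row).
#' @export
summarize_cohort <- function(cohort) {
  if (nrow(cohort) == 0) {
    rlang::abort("cannot summarize an empty cohort.",
                 class = "pvsignal_degenerate_error")
  }
  drugs <- intersect(sglt2i_generics(), unique(cohort$sglt2i))
  totals <- c(
    stats::setNames(
      vapply(drugs, function(d) sum(cohort$sglt2i == d), integer(1)), drugs),
    pooled = nrow(cohort)
  )

  level_counts <- function(values, characteristic) {
    lv <- sort(unique(values[!is.na(values)]))
    purrr::map_dfr(lv, function(l) {
      purrr::map_dfr(names(totals), function(d) {
        in_drug <- if (d == "pooled") rep(TRUE, nrow(cohort)) else cohort$sglt2i == d
        n <- sum(in_drug & !is.na(values) & values == l)
        tibble::tibble(
          characteristic = characteristic, level = as.character(l),
          drug = d, n = n, total = unname(totals[d]),
          pct = unname(round_half_up(100 * n / totals[d], 1))
        )
      })
    })
  }

  counts <- dplyr::bind_rows(
    level_counts(cohort$sex, "sex"),
    level_counts(cohort$age_group, "age_group"),
    level_counts(cohort$year, "year"),
    level_counts(cohort$reporter, "reporter"),
    level_counts(cohort$country, "country"),
    level_counts(ifelse(cohort$death, "yes", "no"), "death"),
    level_counts(ifelse(cohort$hospitalization, "yes", "no"), "hospitalization"),
    level_counts(ifelse(cohort$life_threatening, "yes", "no"), "life_threatening"),
    level_counts(ifelse(cohort$disabling, "yes", "no"), "disabling")
  )

  per_drug_age <- purrr::map_dfr(drugs, function(d) {
    a <- cohort$age_years[cohort$sglt2i == d & !is.na(cohort$age_years)]
    tibble::tibble(
      drug = d, n = length(a),
      mean_age = round_half_up(mean(a), 1),
      sd_age = round_half_up(stats::sd(a), 1)
    )
  })
  pooled_age <- tibble::tibble(
    drug = "pooled", n = sum(per_drug_age$n),
    mean_age = pooled_mean(per_drug_age$mean_age, per_drug_age$n),
    sd_age = NA_real_
  )

  structure(
    list(counts = counts, age = dplyr::bind_rows(per_drug_age, pooled_age)),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  print(x$age)
  print(x$counts, n = 20)
  invisible(x)
}
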