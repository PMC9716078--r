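# Hand-built report sets for unit tests. Each report is a list:
#   list(id, case = id, version = 1, sex, age, drugs = list(c(name, role)),
#        pts = character(), outcomes = character(),
#        event_date, start_date, rept_date)
make_reports <- function(specs) {
  demo <- purrr::map_dfr(specs, function(s) {
    tibble::tibble(
      primary_id = s$id,
      case_id = s$case %||% s$id,
      case_version = as.integer(s$version %||% 1L),
      event_date = as.Date(s$event_date %||% NA),
      event_date_precision = s$event_precision %||%
        (if (is.null(s$event_date)) NA_character_ else "day"),
      report_date = as.Date(s$rept_date %||% "2018-06-01"),
      report_date_precision = "day",
      sex = s$sex %||% "M",
      age_years = s$age %||% 55,
      weight_kg = s$weight %||% NA_real_,
      reporter = s$reporter %||% "physician",
      country = s$country %||% "US"
    )
  })
  drug <- purrr::map_dfr(specs, function(s) {
    purrr::imap_dfr(s$drugs, function(d, i) {
      tibble::tibble(primary_id = s$id, drug_seq = as.integer(i),
                     role = d[[2]], drugname = d[[1]],
                     indication = if (length(d) > 2) d[[3]] else NA_character_)
    })
  })
  reac <- purrr::map_dfr(specs, function(s) {
    tibble::tibble(primary_id = s$id, pt = s$pts %||% "Nausea")
  })
  outc <- purrr::map_dfr(specs, function(s) {
    if (length(s$outcomes %||% character()) == 0) return(NULL)
    tibble::tibble(primary_id = s$id, outcome = s$outcomes)
  })
  if (nrow(outc %||% tibble::tibble()) == 0) {
    outc <- tibble::tibble(primary_id = character(), outcome = character())
  }
  ther <- purrr::map_dfr(specs, function(s) {
    if (is.null(s$start_date)) return(NULL)
    tibble::tibble(primary_id = s$id, drug_seq = 1L,
                   start_date = as.Date(s$start_date),
                   start_date_precision = s$start_precision %||% "day")
  })
  if (is.null(ther) || nrow(ther) == 0) {
    ther <- tibble::tibble(primary_id = character(), drug_seq = integer(),
                           start_date = as.Date(character()),
                           start_date_precision = character())
  }
  faers_reports(demo, drug, reac, outc, ther)
}

`%||%` <- rlang::`%||%`

# Independent brute-force evaluation of the three statistics from their
# printed closed forms, kept deliberately separate from the package path.
brute_force_stats <- function(a, b, c, d) {
  n <- a + b + c + d
  v <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ror <- (a / c) / (b / d)
  ic <- log2(a * n / ((a + b) * (a + c)))
  ebgm <- a * n / ((a + c) * (a + b))
  list(
    ror = ror,
    ror025 = ror * exp(-1.96 * v),
    ror975 = ror * exp(1.96 * v),
    ic = ic,
    ic025 = if (ic > 0) ic * exp(-1.96 * v) else ic - 1.96 * v,
    ebgm = ebgm,
    ebgm05 = ebgm * exp(-1.64 * v)
  )
}

# Simulated logistic cohort with a single binary exposure, used by the
# coverage and oracle tests.
simulate_binary_cohort <- function(n, beta0, beta1, p_exposed = 0.5) {
  x <- stats::rbinom(n, 1, p_exposed)
  y <- stats::rbinom(n, 1, stats::plogis(beta0 + beta1 * x))
  data.frame(y = y, x = x)
}
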