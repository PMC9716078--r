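# Parsing of quarterly-extract tables back into a faers_reports set, with
# the field conventions of the source system: coded age units, partial
# dates, occupation codes.

# Age unit codes -> multiplier into years. Out-of-range results are treated
# as missing rather than propagated.
age_unit_factor <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.18,
                     DY = 1 / 365.25)

convert_age_years <- function(age, cod) {
  v <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(cod))
  cod[is.na(cod) | cod == ""] <- "YR"
  f <- unname(age_unit_factor[cod])
  out <- v * f
  out[!is.na(out) & (out < 0 | out > 120)] <- NA_real_
  out
}

# Partial-date convention: YYYYMMDD is day precision, YYYYMM month
# precision (anchored to the first of the month), YYYY year precision
# (anchored to 1 January). The precision flag is carried so day-resolved
# arithmetic can refuse coarser dates.
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x)] <- ""
  n <- nchar(x)
  date <- rep(as.Date(NA), length(x))
  precision <- rep(NA_character_, length(x))
  d8 <- n == 8 & grepl("^[0-9]{8}$", x)
  d6 <- n == 6 & grepl("^[0-9]{6}$", x)
  d4 <- n == 4 & grepl("^[0-9]{4}$", x)
  date[d8] <- as.Date(x[d8], format = "%Y%m%d")
  date[d6] <- as.Date(paste0(x[d6], "01"), format = "%Y%m%d")
  date[d4] <- as.Date(paste0(x[d4], "0101"), format = "%Y%m%d")
  precision[d8 & !is.na(date)] <- "day"
  precision[d6 & !is.na(date)] <- "month"
  precision[d4 & !is.na(date)] <- "year"
  precision[is.na(date)] <- NA_character_
  list(date = date, precision = precision)
}

read_faers_table <- function(directory, name, dialect) {
  path <- if (dialect == "faers_ascii") {
    file.path(directory, paste0(name, ".txt"))
  } else {
    file.path(directory, paste0(tolower(name), ".csv"))
  }
  if (!file.exists(path)) return(NULL)
  if (dialect == "faers_ascii") {
    tb <- suppressWarnings(readr::read_delim(
      path, delim = "$", col_types = readr::cols(.default = "c"),
      quote = "", na = character(), progress = FALSE,
      show_col_types = FALSE
    ))
  } else {
    tb <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          na = character(), progress = FALSE,
                          show_col_types = FALSE)
  }
  names(tb) <- tolower(names(tb))
  if (!"primaryid" %in% names(tb)) {
    rlang::abort(sprintf("'%s' has no primaryid column (bad header?).", path),
                 class = "pvsignal_format_error")
  }
  tb
}

#' Parse a quarterly extract into a report set
#'
#' Reads the `DEMO`/`DRUG`/`REAC`/`OUTC`/`THER` tables of one directory in
#' either the `$`-delimited ASCII dialect or the CSV mirror, applying the
#' source system's conventions: coded age units (`DEC` x10, `YR`, `MON`/12,
#' `WK`/52.18, `DY`/365.25; out-of-range ages become missing), partial dates
#' with carried precision, and occupation codes. Rows without a usable
#' `primaryid` are skipped; the skip count is reported via a message and an
#' attribute.
#'
#' @param directory path containing the table files.
#' @param dialect `"faers_ascii"` or `"csv"`.
#' @return a [faers_reports()] set with attribute `n_skipped`.
#' @export
parse_quarter <- function(directory, dialect = c("faers_ascii", "csv")) {
  dialect <- match.arg(dialect)
  if (!dir.exists(directory)) {
    rlang::abort(sprintf("directory '%s' does not exist.", directory),
                 class = "pvsignal_io_error")
  }
  raw <- lapply(
    stats::setNames(nm = c("DEMO", "DRUG", "REAC", "OUTC", "THER")),
    function(nm) read_faers_table(directory, nm, dialect)
  )
  for (nm in c("DEMO", "DRUG", "REAC")) {
    if (is.null(raw[[nm]])) {
      rlang::abort(sprintf("mandatory table %s is missing from '%s'.",
                           nm, directory),
                   class = "pvsignal_io_error")
    }
  }

  n_skipped <- 0L
  d <- raw$DEMO
  bad <- is.na(d$primaryid) | trimws(d$primaryid) == ""
  bad <- bad | duplicated(d$primaryid)
  n_skipped <- n_skipped + sum(bad)
  d <- d[!bad, , drop = FALSE]
  ev <- parse_faers_date(d$event_dt)
  rp <- parse_faers_date(d$rept_dt)
  reporter_lookup <- c(MD = "physician", PH = "pharmacist",
                       HP = "other health professional", LW = "lawyer",
                       CN = "consumer")
  occ <- toupper(trimws(d$occp_cod))
  reporter <- unname(reporter_lookup[occ])
  reporter[is.na(reporter)] <- "unknown"
  sex <- toupper(trimws(d$sex))
  sex[!sex %in% c("M", "F")] <- NA_character_
  demo <- tibble::tibble(
    primary_id = d$primaryid,
    case_id = d$caseid,
    case_version = suppressWarnings(as.integer(d$caseversion)),
    event_date = ev$date, event_date_precision = ev$precision,
    report_date = rp$date, report_date_precision = rp$precision,
    sex = sex,
    age_years = convert_age_years(d$age, d$age_cod),
    weight_kg = suppressWarnings(as.numeric(d$wt)),
    reporter = reporter,
    country = dplyr::na_if(trimws(d$reporter_country), "")
  )
  demo$case_version[is.na(demo$case_version)] <- 1L

  g <- raw$DRUG
  bad <- is.na(g$primaryid) | trimws(g$primaryid) == "" |
    is.na(g$drugname) | trimws(g$drugname) == ""
  n_skipped <- n_skipped + sum(bad)
  g <- g[!bad, , drop = FALSE]
  drug <- tibble::tibble(
    primary_id = g$primaryid,
    drug_seq = suppressWarnings(as.integer(g$drug_seq)),
    role = toupper(trimws(g$role_cod)),
    drugname = g$drugname,
    indication = dplyr::na_if(trimws(g$indi_pt %||% ""), "")
  )

  r <- raw$REAC
  bad <- is.na(r$primaryid) | trimws(r$primaryid) == "" |
    is.na(r$pt) | trimws(r$pt) == ""
  n_skipped <- n_skipped + sum(bad)
  r <- r[!bad, , drop = FALSE]
  reac <- tibble::tibble(primary_id = r$primaryid, pt = r$pt)

  if (!is.null(raw$OUTC)) {
    o <- raw$OUTC
    bad <- is.na(o$primaryid) | trimws(o$primaryid) == ""
    n_skipped <- n_skipped + sum(bad)
    o <- o[!bad, , drop = FALSE]
    outc <- tibble::tibble(primary_id = o$primaryid,
                           outcome = toupper(trimws(o$outc_cod)))
  } else {
    outc <- tibble::tibble(primary_id = character(), outcome = character())
  }

  if (!is.null(raw$THER)) {
    t <- raw$THER
    bad <- is.na(t$primaryid) | trimws(t$primaryid) == ""
    n_skipped <- n_skipped + sum(bad)
    t <- t[!bad, , drop = FALSE]
    st <- parse_faers_date(t$start_dt)
    ther <- tibble::tibble(
      primary_id = t$primaryid,
      drug_seq = suppressWarnings(as.integer(t$dsg_drug_seq)),
      start_date = st$date, start_date_precision = st$precision
    )
    ther <- dplyr::filter(ther, !is.na(.data$start_date))
  } else {
    ther <- tibble::tibble(primary_id = character(), drug_seq = integer(),
                           start_date = as.Date(character()),
                           start_date_precision = character())
  }

  if (n_skipped > 0) {
    rlang::inform(sprintf("parse_quarter: skipped %d malformed row(s).",
                          n_skipped))
  }
  out <- faers_reports(demo, drug, reac, outc, ther)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Deduplicate a report set by case
#'
#' Spontaneous-report databases carry several versions of the same case.
#' Keeps one record per `case_id`: the highest `case_version` wins; ties are
#' broken by the latest report date, then by the lexicographically largest
#' `primary_id`. Idempotent.
#'
#' @param reports a `faers_reports` set.
#' @return the deduplicated `faers_reports` set.
#' @export
deduplicate <- function(reports) {
  demo <- reports$demo
  keep <- demo |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$case_id) |>
    dplyr::arrange(
      dplyr::desc(.data$case_version),
      dplyr::desc(.data$report_date),
      dplyr::desc(.data$primary_id),
      .by_group = TRUE
    ) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  filter_reports(reports, keep$primary_id)
}
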