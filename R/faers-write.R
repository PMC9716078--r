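# Serialization of a report set in the quarterly-extract dialect:
# $-delimited text files DEMO/DRUG/REAC/OUTC/THER (plus a CSV mirror).

occp_codes <- c(physician = "MD", pharmacist = "PH",
                `other health professional` = "HP", lawyer = "LW",
                consumer = "CN", unknown = "")

format_faers_date <- function(date, precision) {
  out <- rep("", length(date))
  ok <- !is.na(date)
  fmt <- c(day = "%Y%m%d", month = "%Y%m", year = "%Y")
  out[ok] <- vapply(which(ok), function(i) {
    format(date[i], fmt[[precision[i]]])
  }, character(1))
  out
}

blank_na <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x
}

faers_tables <- function(reports) {
  demo <- reports$demo
  list(
    DEMO = tibble::tibble(
      primaryid = demo$primary_id,
      caseid = demo$case_id,
      caseversion = demo$case_version,
      event_dt = format_faers_date(demo$event_date, demo$event_date_precision),
      rept_dt = format_faers_date(demo$report_date, demo$report_date_precision),
      age = blank_na(demo$age_years),
      age_cod = ifelse(is.na(demo$age_years), "", "YR"),
      sex = blank_na(demo$sex),
      wt = blank_na(demo$weight_kg),
      wt_cod = ifelse(is.na(demo$weight_kg), "", "KG"),
      occp_cod = unname(occp_codes[demo$reporter]),
      reporter_country = blank_na(demo$country)
    ),
    DRUG = tibble::tibble(
      primaryid = reports$drug$primary_id,
      drug_seq = reports$drug$drug_seq,
      role_cod = reports$drug$role,
      drugname = reports$drug$drugname,
      indi_pt = blank_na(reports$drug$indication)
    ),
    REAC = tibble::tibble(
      primaryid = reports$reac$primary_id,
      pt = reports$reac$pt
    ),
    OUTC = tibble::tibble(
      primaryid = reports$outc$primary_id,
      outc_cod = reports$outc$outcome
    ),
    THER = tibble::tibble(
      primaryid = reports$ther$primary_id,
      dsg_drug_seq = reports$ther$drug_seq,
      start_dt = format_faers_date(reports$ther$start_date,
                                   reports$ther$start_date_precision)
    )
  )
}

#' Write a report set as quarterly-extract files
#'
#' Emits the five `$`-delimited tables (`DEMO.txt`, `DRUG.txt`, `REAC.txt`,
#' `OUTC.txt`, `THER.txt`) with a header line each, or a CSV mirror
#' (`demo.csv`, ...). [parse_quarter()] reads either dialect back to an
#' equivalent report set (round-trip identity on all modeled fields).
#'
#' @param x a `faers_reports` set or a `sim_dataset` (its `reports` are
#'   written).
#' @param directory output directory (created if absent).
#' @param dialect `"faers_ascii"` (`$`-delimited) or `"csv"`.
#' @return invisibly, the written file paths.
#' @export
write_faers_ascii <- function(x, directory, dialect = c("faers_ascii", "csv")) {
  dialect <- match.arg(dialect)
  if (inherits(x, "sim_dataset")) x <- x$reports
  if (!inherits(x, "faers_reports")) {
    rlang::abort("`x` must be a faers_reports set or sim_dataset.",
                 class = "pvsignal_config_error")
  }
  if (n_reports(x) == 0) {
    rlang::abort("refusing to write an empty report set.",
                 class = "pvsignal_degenerate_error")
  }
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) {
      rlang::abort(sprintf("cannot create directory '%s'.", directory),
                   class = "pvsignal_io_error")
    }
  }
  tabs <- faers_tables(x)
  paths <- character(0)
  for (nm in names(tabs)) {
    if (dialect == "faers_ascii") {
      path <- file.path(directory, paste0(nm, ".txt"))
      lines <- c(
        paste(names(tabs[[nm]]), collapse = "$"),
        do.call(paste, c(lapply(tabs[[nm]], as.character), sep = "$"))
      )
      writeLines(lines, path)
    } else {
      path <- file.path(directory, paste0(tolower(nm), ".csv"))
      readr::write_csv(tabs[[nm]], path, progress = FALSE)
    }
    paths <- c(paths, path)
  }
  invisible(paths)
}
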