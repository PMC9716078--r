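#' Relational container for a set of safety reports
#'
#' Mirrors the quarterly-extract structure of a spontaneous reporting system:
#' five linked tibbles keyed by `primary_id` — demographics (`demo`), drug
#' rows (`drug`), reaction preferred terms (`reac`), outcome codes (`outc`)
#' and therapy start dates (`ther`). One case may span several drug,
#' reaction, outcome and therapy rows.
#'
#' `demo` columns: `primary_id`, `case_id`, `case_version`, `event_date`,
#' `event_date_precision`, `report_date`, `report_date_precision`, `sex`
#' (`"M"/"F"/NA`), `age_years`, `weight_kg`, `reporter`, `country`.
#' `drug`: `primary_id`, `drug_seq`, `role` (`PS`/`SS`/`C`/`I`), `drugname`,
#' `indication`. `reac`: `primary_id`, `pt`. `outc`: `primary_id`, `outcome`
#' (`DE`/`HO`/`LT`/`DS`/`OT`). `ther`: `primary_id`, `drug_seq`,
#' `start_date`, `start_date_precision`. Date-precision columns take values
#' `"day"`, `"month"` or `"year"`; intervals in days are only computed from
#' day-precision dates.
#'
#' @param demo,drug,reac,outc,ther tibbles as described above.
#' @return an object of class `faers_reports`.
#' @export
faers_reports <- function(demo, drug, reac, outc, ther) {
  demo <- tibble::as_tibble(demo)
  if (anyDuplicated(demo$primary_id)) {
    rlang::abort("`primary_id` must be unique within a report set.",
                 class = "pvsignal_format_error")
  }
  structure(
    list(
      demo = demo,
      drug = tibble::as_tibble(drug),
      reac = tibble::as_tibble(reac),
      outc = tibble::as_tibble(outc),
      ther = tibble::as_tibble(ther)
    ),
    class = "faers_reports"
  )
}

#' @export
print.faers_reports <- function(x, ...) {
  cat(sprintf(
    "<faers_reports> %d reports | %d drug rows | %d reactions | %d outcomes | %d therapy rows\n",
    nrow(x$demo), nrow(x$drug), nrow(x$reac), nrow(x$outc), nrow(x$ther)
  ))
  invisible(x)
}

#' Number of reports in a report set
#'
#' @param reports a `faers_reports` object.
#' @return integer count of demographic rows (one per report).
#' @export
n_reports <- function(reports) {
  nrow(reports$demo)
}

# Restrict all five tables to the given primary ids, preserving demo order.
filter_reports <- function(reports, keep_ids) {
  faers_reports(
    demo = dplyr::filter(reports$demo, .data$primary_id %in% keep_ids),
    drug = dplyr::filter(reports$drug, .data$primary_id %in% keep_ids),
    reac = dplyr::filter(reports$reac, .data$primary_id %in% keep_ids),
    outc = dplyr::filter(reports$outc, .data$primary_id %in% keep_ids),
    ther = dplyr::filter(reports$ther, .data$primary_id %in% keep_ids)
  )
}
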