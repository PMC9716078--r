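#' Therapy-start-to-event intervals
#'
#' For each report, the interval in days from the earliest day-precision
#' therapy start of a target-class drug (suspect role) to the day-precision
#' event date. The interval is missing when either date is absent or coarser
#' than day precision; negative intervals (event before therapy start) are
#' treated as missing and counted as anomalies.
#'
#' @param reports a `faers_reports` set.
#' @param dictionary an [event_dictionary()]; the target class is its
#'   `sglt2i` entry.
#' @param roles drug roles whose therapy rows are eligible.
#' @return a tibble `(primary_id, onset_days)` with attribute `n_anomalies`
#'   (count of negative intervals suppressed).
#' @export
onset_days <- function(reports, dictionary = event_dictionary(),
                       roles = c("PS", "SS")) {
  drug <- reports$drug
  target <- drug[
    drug$role %in% roles &
      matches_any_substring(drug$drugname, dictionary$drug_classes$sglt2i),
    c("primary_id", "drug_seq")
  ]
  ther <- dplyr::inner_join(reports$ther, target,
                            by = c("primary_id", "drug_seq"))
  ther <- ther[!is.na(ther$start_date) &
                 ther$start_date_precision %in% "day", , drop = FALSE]
  starts <- if (nrow(ther) == 0) {
    tibble::tibble(primary_id = character(), start = as.Date(character()))
  } else {
    ther |>
      dplyr::group_by(.data$primary_id) |>
      dplyr::summarise(start = min(.data$start_date), .groups = "drop")
  }

  demo <- reports$demo
  out <- tibble::tibble(primary_id = demo$primary_id,
                        onset_days = NA_integer_)
  idx <- match(starts$primary_id, demo$primary_id)
  ok <- !is.na(idx) & !is.na(demo$event_date[idx]) &
    demo$event_date_precision[idx] %in% "day"
  days <- as.integer(demo$event_date[idx][ok] - starts$start[ok])
  neg <- days < 0
  if (any(neg)) {
    rlang::inform(sprintf(
      "onset_days: %d report(s) with event before therapy start treated as missing.",
      sum(neg)
    ))
  }
  days[neg] <- NA_integer_
  out$onset_days[idx[ok]] <- days
  attr(out, "n_anomalies") <- sum(neg)
  out
}

#' Summarize onset intervals
#'
#' Median and quartiles by linear interpolation between order statistics
#' ([stats::quantile()] type 7), plus the fraction of intervals within 180
#' days (six months at day resolution).
#'
#' @param intervals numeric vector of onset days; missing values are
#'   dropped.
#' @return a list of class `tto_summary`: `n_evaluable`, `median_days`,
#'   `q1_days`, `q3_days`, `prop_within_180d`.
#' @export
#' @examples
#' summarize_tto(c(10, 20, 30, 40))
summarize_tto <- function(intervals) {
  x <- intervals[!is.na(intervals)]
  if (length(x) == 0) {
    rlang::abort("no evaluable onset intervals.",
                 class = "pvsignal_degenerate_error")
  }
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
  structure(
    list(
      n_evaluable = length(x),
      median_days = q[2],
      q1_days = q[1],
      q3_days = q[3],
      prop_within_180d = mean(x <= 180)
    ),
    class = "tto_summary"
  )
}

#' @export
print.tto_summary <- function(x, ...) {
  cat(sprintf(
    "<tto_summary> n=%d | median %.1f d (IQR %.1f-%.1f) | %.1f%% within 180 d\n",
    x$n_evaluable, x$median_days, x$q1_days, x$q3_days,
    100 * x$prop_within_180d
  ))
  invisible(x)
}
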