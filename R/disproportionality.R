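#' Contingency table for one drug-event pair
#'
#' The 2x2 table of report counts underlying every disproportionality
#' statistic: `a` reports with the target drug and the target event, `b`
#' with the target drug and other events, `c` with other drugs and the
#' target event, `d` with other drugs and other events. Counting is at the
#' report level: a report listing the target drug twice still contributes
#' once.
#'
#' @param a,b,c,d nonnegative integer cell counts; `a+b+c+d >= 1`.
#' @return an object of class `contingency_table`.
#' @export
#' @examples
#' contingency_table(10, 90, 100, 9900)
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) ||
      any(cells != floor(cells))) {
    rlang::abort("cells must be nonnegative integers.",
                 class = "pvsignal_config_error")
  }
  if (sum(cells) < 1) {
    rlang::abort("a+b+c+d must be at least 1.",
                 class = "pvsignal_degenerate_error")
  }
  structure(as.list(cells), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> a=%d b=%d c=%d d=%d (N=%d)\n",
              x$a, x$b, x$c, x$d, x$a + x$b + x$c + x$d))
  invisible(x)
}

#' Build the 2x2 table from a report set
#'
#' @param reports a deduplicated `faers_reports` set.
#' @param drug_names character patterns identifying the target drug
#'   (substring match, case-insensitive).
#' @param event_terms preferred terms of the target event cluster (exact
#'   match after case/whitespace normalization).
#' @param roles drug roles that count as exposure (suspect-only by
#'   default).
#' @return a [contingency_table()].
#' @export
build_table <- function(reports, drug_names, event_terms,
                        roles = c("PS", "SS")) {
  if (n_reports(reports) == 0) {
    rlang::abort("empty report set.", class = "pvsignal_degenerate_error")
  }
  drug <- reports$drug
  drug_ids <- unique(drug$primary_id[
    drug$role %in% roles & matches_any_substring(drug$drugname, drug_names)
  ])
  event_ids <- unique(reports$reac$primary_id[
    normalize_term(reports$reac$pt) %in% normalize_term(event_terms)
  ])
  ids <- reports$demo$primary_id
  in_drug <- ids %in% drug_ids
  in_event <- ids %in% event_ids
  contingency_table(
    a = sum(in_drug & in_event),
    b = sum(in_drug & !in_event),
    c = sum(!in_drug & in_event),
    d = sum(!in_drug & !in_event)
  )
}

# Haldane-Anscombe continuity correction: when any of b, c, d is zero the
# point estimates and variance terms are computed on all four cells + 0.5.
# a = 0 is not corrected away; it yields an explicit undefined result.
corrected_cells <- function(t) {
  corr <- (t$b == 0 || t$c == 0 || t$d == 0)
  cells <- c(t$a, t$b, t$c, t$d) + if (corr) 0.5 else 0
  list(a = cells[1], b = cells[2], c = cells[3], d = cells[4],
       corrected = corr)
}

log_var_term <- function(k) {
  sqrt(1 / k$a + 1 / k$b + 1 / k$c + 1 / k$d)
}

#' Reporting odds ratio with Wald interval
#'
#' `ROR = (a d)/(b c)` with the lognormal 95% interval
#' `ROR x exp(+/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. Zero cells in `b`,
#' `c`, `d` trigger the Haldane-Anscombe 0.5 correction on all cells;
#' `a = 0` returns an undefined (all-`NA`) result flagged via `defined`.
#'
#' @param t a [contingency_table()].
#' @return list `(ror, ror025, ror975, defined, corrected)`.
#' @export
#' @examples
#' ror_with_ci(contingency_table(10, 90, 100, 9900))
ror_with_ci <- function(t) {
  if (t$a == 0) {
    return(list(ror = NA_real_, ror025 = NA_real_, ror975 = NA_real_,
                defined = FALSE, corrected = FALSE))
  }
  k <- corrected_cells(t)
  ror <- (k$a * k$d) / (k$b * k$c)
  half <- 1.96 * log_var_term(k)
  list(ror = ror, ror025 = ror * exp(-half), ror975 = ror * exp(half),
       defined = TRUE, corrected = k$corrected)
}

#' Information component with lower bound
#'
#' `IC = log2( a N / ((a+b)(a+c)) )`, the base-2 log of observed over
#' expected co-reporting. The default lower bound is the multiplicative
#' form `IC x exp(-1.96 sqrt(1/a + 1/b + 1/c + 1/d))`, which is only
#' meaningful for positive IC; for `IC <= 0` the additive fallback
#' `IC - 1.96 sqrt(V)` is used. `method = "credible"` instead applies the
#' standard BCPNN credible-interval approximation
#' `IC - 3.3 a^(-1/2) - 2 a^(-3/2)`.
#'
#' @param t a [contingency_table()].
#' @param method `"multiplicative"` (default) or `"credible"`.
#' @return list `(ic, ic025, defined, method)`.
#' @export
ic_with_bound <- function(t, method = c("multiplicative", "credible")) {
  method <- match.arg(method)
  if (t$a == 0) {
    return(list(ic = NA_real_, ic025 = NA_real_, defined = FALSE,
                method = method))
  }
  k <- corrected_cells(t)
  n_tot <- k$a + k$b + k$c + k$d
  ic <- log2(k$a * n_tot / ((k$a + k$b) * (k$a + k$c)))
  ic025 <- if (method == "credible") {
    ic - 3.3 * k$a^(-0.5) - 2 * k$a^(-1.5)
  } else if (ic > 0) {
    ic * exp(-1.96 * log_var_term(k))
  } else {
    ic - 1.96 * log_var_term(k)
  }
  list(ic = ic, ic025 = ic025, defined = TRUE, method = method)
}

#' Simplified empirical Bayes geometric mean with lower bound
#'
#' The relative-reporting-ratio form `EBGM = a N / ((a+c)(a+b))` (so that
#' `EBGM = 2^IC` exactly) with the one-sided 90% lower bound
#' `EBGM x exp(-1.64 sqrt(1/a + 1/b + 1/c + 1/d))`. No gamma-Poisson
#' shrinkage is applied.
#'
#' @param t a [contingency_table()].
#' @return list `(ebgm, ebgm05, defined)`.
#' @export
ebgm_with_bound <- function(t) {
  if (t$a == 0) {
    return(list(ebgm = NA_real_, ebgm05 = NA_real_, defined = FALSE))
  }
  k <- corrected_cells(t)
  n_tot <- k$a + k$b + k$c + k$d
  ebgm <- k$a * n_tot / ((k$a + k$c) * (k$a + k$b))
  list(ebgm = ebgm, ebgm05 = ebgm * exp(-1.64 * log_var_term(k)),
       defined = TRUE)
}

#' Evaluate the triple signal criterion
#'
#' A drug-event pair is a signal when all three statistics agree:
#' `a >= 3` and `ROR025 > 1`, `IC025 > 0`, and `EBGM05 > 1`.
#'
#' @param t a [contingency_table()].
#' @param ic_method forwarded to [ic_with_bound()].
#' @return a list of class `signal_result` with the three point estimates,
#'   their bounds, `n_a` (cell `a`) and the combined `is_signal` flag.
#' @export
#' @examples
#' evaluate_signal(contingency_table(10, 90, 100, 9900))
evaluate_signal <- function(t, ic_method = "multiplicative") {
  r <- ror_with_ci(t)
  i <- ic_with_bound(t, method = ic_method)
  e <- ebgm_with_bound(t)
  is_signal <- isTRUE(t$a >= 3) &&
    isTRUE(r$defined) && isTRUE(r$ror025 > 1) &&
    isTRUE(i$ic025 > 0) && isTRUE(e$ebgm05 > 1)
  structure(
    list(
      n_a = t$a,
      ror = r$ror, ror025 = r$ror025, ror975 = r$ror975,
      ic = i$ic, ic025 = i$ic025,
      ebgm = e$ebgm, ebgm05 = e$ebgm05,
      defined = r$defined,
      is_signal = is_signal
    ),
    class = "signal_result"
  )
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf(
    "<signal_result> a=%d ROR %.2f (%.2f-%.2f) IC %.2f (%.2f) EBGM %.2f (%.2f) signal=%s\n",
    x$n_a, x$ror, x$ror025, x$ror975, x$ic, x$ic025, x$ebgm, x$ebgm05,
    x$is_signal
  ))
  invisible(x)
}

#' Screen the drug class and each member against the event cluster
#'
#' One row per SGLT-2i member plus the pooled class row, sorted by the
#' case count `a` descending; deterministic for a given report set.
#'
#' @param reports a deduplicated `faers_reports` set.
#' @param dictionary an [event_dictionary()].
#' @param roles exposure roles (suspect-only by default).
#' @param ic_method forwarded to [ic_with_bound()].
#' @return a tibble: drug, a, b, c, d, ror, ror025, ror975, ic, ic025,
#'   ebgm, ebgm05, is_signal.
#' @export
screen_all <- function(reports, dictionary = event_dictionary(),
                       roles = c("PS", "SS"),
                       ic_method = "multiplicative") {
  selectors <- c(
    list(`SGLT-2i` = dictionary$drug_classes$sglt2i),
    stats::setNames(lapply(sglt2i_generics(), sglt2i_patterns),
                    sglt2i_generics())
  )
  rows <- purrr::imap_dfr(selectors, function(patterns, label) {
    t <- build_table(reports, patterns, dictionary$ap_terms, roles = roles)
    s <- evaluate_signal(t, ic_method = ic_method)
    tibble::tibble(
      drug = label, a = t$a, b = t$b, c = t$c, d = t$d,
      ror = s$ror, ror025 = s$ror025, ror975 = s$ror975,
      ic = s$ic, ic025 = s$ic025, ebgm = s$ebgm, ebgm05 = s$ebgm05,
      is_signal = s$is_signal
    )
  })
  dplyr::arrange(rows, dplyr::desc(.data$a), .data$drug)
}
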