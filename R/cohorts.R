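#' Label positive drugs from disproportionality signals
#'
#' A drug is positive for the target event class when it has at least
#' `min_reports` reports in the class (inclusive), RRR strictly greater
#' than `rrr_gt`, and p-value strictly below `p_lt`. Defaults are the
#' hepatobiliary-disorder rule: >= 13 reports, RRR > 1, p < 0.05.
#'
#' @param signals data.frame from [detect_signals()].
#' @param min_reports inclusive report floor.
#' @param rrr_gt strict RRR threshold.
#' @param p_lt strict p-value threshold.
#' @return character vector of positive drug ids (sorted).
#' @export
label_positives <- function(signals, min_reports = 13, rrr_gt = 1.0,
                            p_lt = 0.05) {
  keep <- signals$reports >= min_reports & signals$rrr > rrr_gt &
    signals$pvalue < p_lt
  sort(unique(signals$drug[keep]))
}

#' Label negative drugs from the count matrix and market history
#'
#' A drug is negative when it has exactly zero reports in the target event
#' class and has been on the market for at least `min_years` years — drugs
#' that stayed clean for a decade or more. Drugs absent from the
#' market-years table cannot be assessed and are excluded with a logged
#' count.
#'
#' @param matrix a `drug_event_matrix` (candidates are all its drugs).
#' @param event_class target event key.
#' @param market_years data.frame with columns `drug`, `years`, or a named
#'   numeric vector.
#' @param min_years inclusive market-age floor.
#' @return character vector of negative drug ids (sorted).
#' @export
label_negatives <- function(matrix, event_class, market_years,
                            min_years = 10) {
  if (is.data.frame(market_years)) {
    if (!all(c("drug", "years") %in% names(market_years)))
      stop("market_years needs columns drug, years")
    years <- setNames(as.numeric(market_years$years), market_years$drug)
  } else years <- market_years
  drugs <- names(matrix$drug_marginals)
  target <- matrix$counts[matrix$counts$event == event_class, , drop = FALSE]
  has_reports <- setNames(rep(FALSE, length(drugs)), drugs)
  has_reports[target$drug[target$count > 0]] <- TRUE
  clean <- drugs[!has_reports]
  unknown <- clean[!clean %in% names(years)]
  if (length(unknown) > 0)
    message("label_negatives: ", length(unknown),
            " clean drug(s) missing from market-years table, excluded")
  clean <- setdiff(clean, unknown)
  sort(clean[years[clean] >= min_years])
}

#' Bundle cohort labels with the rule parameters that produced them
#'
#' @param positives,negatives drug id vectors (must be disjoint).
#' @param rule_params named list recording `min_reports`, `rrr_threshold`,
#'   `p_threshold`, `min_market_years`.
#' @return object of class `cohort_labels`.
#' @export
cohort_labels <- function(positives, negatives, rule_params = list()) {
  if (length(intersect(positives, negatives)) > 0)
    stop("positives and negatives must be disjoint")
  structure(list(positives = sort(unique(positives)),
                 negatives = sort(unique(negatives)),
                 rule_params = rule_params),
            class = "cohort_labels")
}

#' @export
print.cohort_labels <- function(x, ...) {
  cat("cohort_labels:", length(x$positives), "positives,",
      length(x$negatives), "negatives\n")
  invisible(x)
}
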