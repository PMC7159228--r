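#' Two-by-two contingency table for a drug-event pair
#'
#' Cell `a` counts reports of the drug of interest with the event of
#' interest, `b` its reports with all other events, `c` the event's reports
#' under all other drugs, and `d` everything else; `N = a+b+c+d` is the
#' grand total of the summarized matrix.
#'
#' @param matrix a `drug_event_matrix`.
#' @param drug canonical drug id (must be present in the matrix).
#' @param event_class event key at the matrix's aggregation level.
#' @return list of class `contingency_table` with integers `a`, `b`, `c`,
#'   `d` and `N`.
#' @export
contingency_table <- function(matrix, drug, event_class) {
  if (!drug %in% names(matrix$drug_marginals))
    stop("drug not present in matrix: ", drug)
  a <- matrix_count(matrix, drug, event_class)
  b <- matrix$drug_marginals[[drug]] - a
  ev <- if (event_class %in% names(matrix$event_marginals))
    matrix$event_marginals[[event_class]] else 0L
  c_ <- ev - a
  d <- matrix$grand_total - a - b - c_
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c_),
                 d = as.integer(d), N = as.integer(matrix$grand_total)),
            class = "contingency_table")
}

#' Relative Reporting Ratio
#'
#' Disproportionality statistic `RRR = a N / ((a + c)(a + b))`: the observed
#' reporting rate of the pair relative to the rate expected if drug and
#' event were reported independently. RRR = 1 under independence, > 1 when
#' the pair is reported more often than expected.
#'
#' @param table a `contingency_table` (or list with `a`,`b`,`c`,`d`).
#' @return nonnegative real. A zero row or column marginal is an error, not
#'   a silent 0/0.
#' @export
rrr <- function(table) {
  a <- table$a; b <- table$b; c_ <- table$c; d <- table$d
  N <- a + b + c_ + d
  if ((a + c_) <= 0 || (a + b) <= 0)
    stop("RRR undefined: zero marginal (a+c or a+b)")
  a * N / ((a + c_) * (a + b))
}

#' Fisher exact p-value for a 2x2 table
#'
#' Exact hypergeometric tail probability with all margins fixed. The
#' one-sided `greater` alternative (default) tests enrichment of the
#' drug-event pair, matching the direction of the RRR > 1 rule; `two_sided`
#' uses the usual sum of all tables at most as probable as the observed one.
#'
#' @param table a `contingency_table`.
#' @param sidedness `"greater"` or `"two_sided"`.
#' @return p-value in \[0, 1\].
#' @export
fisher_pvalue <- function(table, sidedness = c("greater", "two_sided")) {
  sidedness <- match.arg(sidedness)
  a <- table$a; b <- table$b; c_ <- table$c; d <- table$d
  m <- a + b       # drug margin (white balls drawn from)
  k <- a + c_      # event margin
  N <- a + b + c_ + d
  if (N <= 0) stop("empty table")
  if (sidedness == "greater")
    return(phyper(a - 1, m, N - m, k, lower.tail = FALSE))
  lo <- max(0L, k - (N - m)); hi <- min(k, m)
  dens <- dhyper(lo:hi, m, N - m, k)
  obs <- dhyper(a, m, N - m, k)
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

#' Disproportionality signals for one event class
#'
#' For every drug with at least one report in the target event class,
#' computes the report count (cell `a`), the relative reporting ratio and
#' the Fisher exact p-value. Drugs with zero reports in the class are not
#' emitted; they are the candidate pool for negative labeling and are read
#' off the matrix directly.
#'
#' @param matrix a `drug_event_matrix`.
#' @param event_class target event key; must exist in the matrix.
#' @param sidedness passed to [fisher_pvalue()].
#' @param p_adjust `"none"` (default, raw p-values as in the labeling rule)
#'   or `"BH"` for Benjamini-Hochberg.
#' @return data.frame with columns `drug`, `reports`, `rrr`, `pvalue`,
#'   sorted by decreasing `rrr`.
#' @export
detect_signals <- function(matrix, event_class,
                           sidedness = c("greater", "two_sided"),
                           p_adjust = c("none", "BH")) {
  sidedness <- match.arg(sidedness)
  p_adjust <- match.arg(p_adjust)
  if (!event_class %in% names(matrix$event_marginals))
    stop("event class not present in matrix: ", event_class)
  sub <- matrix$counts[matrix$counts$event == event_class &
                         matrix$counts$count > 0, , drop = FALSE]
  if (nrow(sub) == 0)
    return(data.frame(drug = character(), reports = integer(),
                      rrr = numeric(), pvalue = numeric()))
  rows <- lapply(sub$drug, function(d) {
    ct <- contingency_table(matrix, d, event_class)
    data.frame(drug = d, reports = ct$a, rrr = rrr(ct),
               pvalue = fisher_pvalue(ct, sidedness),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (p_adjust == "BH") out$pvalue <- stats::p.adjust(out$pvalue, "BH")
  out <- out[order(-out$rrr, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}
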