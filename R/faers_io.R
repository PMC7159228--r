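#' Read adverse-event report tables
#'
#' Parses spontaneous-report files into the package's standard report frame.
#' Two dialects are supported:
#'
#' * `simple_csv`: comma-separated with header
#'   `report_id,drug_name,role,event_pt,date`; `role` is one of
#'   `primary_suspect` / `other`.
#' * `faers_dollar`: FAERS ASCII style, `$`-separated with header
#'   `primaryid$drugname$role_cod$pt$quarter`; `role_cod` `"PS"` marks the
#'   primary suspect, any other code becomes `other`.
#'
#' Rows with an empty report id or event term, or an unrecognized role, are
#' rejected; the rejection count is reported via [message()] and attached as
#' attribute `n_rejected`, never silently dropped.
#'
#' @param path file path.
#' @param dialect `"simple_csv"` or `"faers_dollar"`.
#' @return data.frame with columns `report_id`, `drug_name_raw`, `role`,
#'   `event_pt`, `event_soc` (NA until mapped), `date`.
#' @export
read_reports <- function(path, dialect = c("simple_csv", "faers_dollar")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read report file: ", path)
  if (dialect == "simple_csv") {
    raw <- read.csv(path, colClasses = "character", strip.white = TRUE)
    need <- c("report_id", "drug_name", "role", "event_pt", "date")
    if (!all(need %in% names(raw)))
      stop("simple_csv requires columns: ", paste(need, collapse = ", "))
    df <- data.frame(report_id = raw$report_id,
                     drug_name_raw = raw$drug_name,
                     role = raw$role,
                     event_pt = raw$event_pt,
                     date = raw$date,
                     stringsAsFactors = FALSE)
  } else {
    raw <- read.csv(path, sep = "$", colClasses = "character",
                    strip.white = TRUE)
    need <- c("primaryid", "drugname", "role_cod", "pt", "quarter")
    if (!all(need %in% names(raw)))
      stop("faers_dollar requires columns: ", paste(need, collapse = ", "))
    df <- data.frame(report_id = raw$primaryid,
                     drug_name_raw = raw$drugname,
                     role = ifelse(toupper(raw$role_cod) == "PS",
                                   "primary_suspect", "other"),
                     event_pt = raw$pt,
                     date = raw$quarter,
                     stringsAsFactors = FALSE)
  }
  ok <- nzchar(trimws(df$report_id)) & nzchar(trimws(df$event_pt)) &
    df$role %in% c("primary_suspect", "other")
  n_rej <- sum(!ok)
  if (n_rej > 0)
    message("read_reports: rejected ", n_rej, " malformed row(s)")
  out <- df[ok, , drop = FALSE]
  out$event_soc <- rep(NA_character_, nrow(out))
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rej
  out
}

#' Keep only primary-suspect drug records
#'
#' Reports name one drug as the most likely cause of their events; all
#' events of a report are attributed to that drug and records for
#' concomitant drugs are discarded.
#'
#' @param records report frame from [read_reports()].
#' @return the subset with `role == "primary_suspect"`, order preserved.
#' @export
filter_primary_suspect <- function(records) {
  out <- records[records$role == "primary_suspect", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map free-text drug names to canonical identifiers
#'
#' Matching is exact after case-folding and whitespace trimming only; names
#' carrying extra dose or formulation text do not match (no fuzzy matching).
#' Unmatched records are returned separately and must not feed downstream
#' counting.
#'
#' @param records report frame.
#' @param synonyms data.frame with columns `raw_name`, `canonical_id`.
#' @return list with elements `matched` (records plus a `drug` column of
#'   canonical ids) and `unmatched`.
#' @export
normalize_drug_names <- function(records, synonyms) {
  if (!all(c("raw_name", "canonical_id") %in% names(synonyms)))
    stop("synonyms needs columns raw_name, canonical_id")
  key <- canonical_name(synonyms$raw_name)
  if (anyDuplicated(key))
    stop("synonym raw names must be unique after case-folding/trimming")
  if (any(!nzchar(synonyms$canonical_id)))
    stop("synonym canonical ids must be non-empty")
  lut <- setNames(as.character(synonyms$canonical_id), key)
  hit <- lut[canonical_name(records$drug_name_raw)]
  ok <- !is.na(hit)
  matched <- records[ok, , drop = FALSE]
  matched$drug <- unname(hit[ok])
  unmatched <- records[!ok, , drop = FALSE]
  rownames(matched) <- rownames(unmatched) <- NULL
  if (nrow(unmatched) > 0)
    message("normalize_drug_names: ", nrow(unmatched),
            " record(s) had no exact synonym match")
  list(matched = matched, unmatched = unmatched)
}

#' Annotate preferred terms with their System Organ Class
#'
#' MedDRA Preferred Terms (PTs) are rolled up to their organ-level System
#' Organ Class (SOC) so counts can be accumulated per end-organ. Records
#' whose PT has no mapping keep `event_soc = NA` and are flagged via the
#' `soc_unmapped` column; SOC-level aggregation excludes them.
#'
#' @param records report frame.
#' @param ptsoc data.frame with columns `pt`, `soc` (each PT maps to exactly
#'   one SOC).
#' @return records with `event_soc` populated and logical `soc_unmapped`.
#' @export
map_pt_to_soc <- function(records, ptsoc) {
  if (!all(c("pt", "soc") %in% names(ptsoc)))
    stop("ptsoc needs columns pt, soc")
  key <- canonical_name(ptsoc$pt)
  if (anyDuplicated(key)) stop("each PT must map to exactly one SOC")
  lut <- setNames(as.character(ptsoc$soc), key)
  soc <- lut[canonical_name(records$event_pt)]
  records$event_soc <- unname(soc)
  records$soc_unmapped <- is.na(soc)
  if (any(records$soc_unmapped))
    message("map_pt_to_soc: ", sum(records$soc_unmapped),
            " record(s) with unmapped PT excluded from SOC rollup")
  records
}

#' Aggregate reports into a drug-event count matrix
#'
#' Consolidates unique drug-event combinations by summing their report
#' numbers: the summarized matrix downstream disproportionality statistics
#' operate on. A report contributing k events for its primary-suspect drug
#' contributes k drug-event pairs.
#'
#' @param records normalized report frame (must carry a `drug` column); when
#'   `event_level = "SOC"`, [map_pt_to_soc()] must have been applied and
#'   unmapped records are excluded.
#' @param event_level count events at MedDRA `"PT"` or `"SOC"` level.
#' @return object of class `drug_event_matrix`: a triplet table plus
#'   marginals and grand total.
#' @export
build_drug_event_matrix <- function(records, event_level = c("PT", "SOC")) {
  event_level <- match.arg(event_level)
  if (is.null(records$drug))
    stop("records must be normalized first (missing `drug` column)")
  if (event_level == "SOC") {
    if (all(is.na(records$event_soc)))
      stop("SOC-level aggregation requires map_pt_to_soc() first")
    records <- records[!is.na(records$event_soc), , drop = FALSE]
    ev <- records$event_soc
  } else {
    ev <- records$event_pt
  }
  if (nrow(records) == 0) stop("no records to aggregate")
  agg <- aggregate(list(count = rep(1L, nrow(records))),
                   by = list(drug = records$drug, event = ev), FUN = sum)
  agg <- agg[order(agg$drug, agg$event), , drop = FALSE]
  rownames(agg) <- NULL
  new_drug_event_matrix(agg, event_level)
}

new_drug_event_matrix <- function(counts, event_level) {
  stopifnot(all(c("drug", "event", "count") %in% names(counts)),
            all(counts$count >= 0))
  counts$count <- as.integer(counts$count)
  dm <- tapply(counts$count, counts$drug, sum)
  em <- tapply(counts$count, counts$event, sum)
  structure(list(counts = counts,
                 drug_marginals = setNames(as.integer(dm), names(dm)),
                 event_marginals = setNames(as.integer(em), names(em)),
                 grand_total = sum(counts$count),
                 event_level = event_level),
            class = "drug_event_matrix")
}

#' @export
print.drug_event_matrix <- function(x, ...) {
  cat("drug_event_matrix (", x$event_level, " level): ",
      length(x$drug_marginals), " drugs x ", length(x$event_marginals),
      " events, ", x$grand_total, " reports\n", sep = "")
  invisible(x)
}

#' Look up one drug-event count
#' @param matrix a `drug_event_matrix`.
#' @param drug,event identifiers; a missing pair counts 0.
#' @return integer count.
#' @export
matrix_count <- function(matrix, drug, event) {
  i <- matrix$counts$drug == drug & matrix$counts$event == event
  if (any(i)) matrix$counts$count[i][1] else 0L
}

#' Serialize / read a drug-event matrix as CSV triplets
#'
#' @param matrix a `drug_event_matrix`.
#' @param path CSV path; header `drug,event,count`.
#' @export
write_matrix <- function(matrix, path) {
  write.csv(matrix$counts, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_matrix
#' @param event_level event level recorded on the read-back matrix.
#' @export
read_matrix <- function(path, event_level = c("PT", "SOC")) {
  event_level <- match.arg(event_level)
  counts <- read.csv(path, colClasses = c("character", "character", "integer"))
  new_drug_event_matrix(counts, event_level)
}
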