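#' Configuration for the FAERS-like report generator
#'
#' Each simulated report names one primary-suspect drug (drawn from
#' `drug_weights`, uniform by default) and one event drawn from that drug's
#' event distribution. The event distribution starts from the shared
#' `event_probs` background; planted drug-event pairs have their event
#' probability multiplied by a relative-risk factor and the distribution is
#' renormalized, so a multiplier of 1 everywhere is the exact independence
#' null.
#'
#' @param n_drugs,n_events,n_reports scene dimensions. Defaults give a
#'   desk-scale reporting system (50 drugs, 20 event terms, 20000 reports)
#'   in which a moderately reported drug accumulates a few hundred reports,
#'   comparable per-drug depth to the real database at a fraction of its
#'   width.
#' @param event_probs background event probabilities (recycled/normalized);
#'   default uniform.
#' @param drug_weights drug reporting weights; default uniform.
#' @param planted_pairs data.frame with columns `drug`, `event`,
#'   `multiplier` (relative-risk multipliers, all >= 1), indices into the
#'   simulated drugs/events.
#' @param seed RNG seed.
#' @return validated list of class `report_sim_config`.
#' @export
report_sim_config <- function(n_drugs = 50, n_events = 20,
                              n_reports = 20000, event_probs = NULL,
                              drug_weights = NULL, planted_pairs = NULL,
                              seed = 1) {
  if (n_drugs < 2 || n_events < 2 || n_reports < 1)
    stop("degenerate simulation dimensions")
  event_probs <- event_probs %||% rep(1 / n_events, n_events)
  if (length(event_probs) != n_events || any(event_probs < 0) ||
      sum(event_probs) <= 0)
    stop("invalid event probabilities")
  event_probs <- event_probs / sum(event_probs)
  drug_weights <- drug_weights %||% rep(1 / n_drugs, n_drugs)
  if (length(drug_weights) != n_drugs || any(drug_weights < 0) ||
      sum(drug_weights) <= 0)
    stop("invalid drug weights")
  drug_weights <- drug_weights / sum(drug_weights)
  if (!is.null(planted_pairs)) {
    stopifnot(all(c("drug", "event", "multiplier") %in%
                    names(planted_pairs)))
    if (any(planted_pairs$multiplier < 1))
      stop("relative-risk multipliers must be >= 1")
    if (any(planted_pairs$drug > n_drugs | planted_pairs$event > n_events))
      stop("planted pair index out of range")
  }
  structure(list(n_drugs = n_drugs, n_events = n_events,
                 n_reports = n_reports, event_probs = event_probs,
                 drug_weights = drug_weights,
                 planted_pairs = planted_pairs, seed = seed),
            class = "report_sim_config")
}

#' Generate a synthetic spontaneous-report set with known ground truth
#'
#' @param config a [report_sim_config()].
#' @return list with `records` (a report frame ready for
#'   [build_drug_event_matrix()]; drug names are already canonical) and
#'   `truth`, a data.frame of exact expected counts per drug-event cell for
#'   the planted pairs plus the per-drug event distributions actually used.
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "report_sim_config"))
  drugs <- sprintf("drug%03d", seq_len(config$n_drugs))
  events <- sprintf("event%03d", seq_len(config$n_events))
  # per-drug event distributions with planted up-weighting
  pmat <- matrix(rep(config$event_probs, each = config$n_drugs),
                 nrow = config$n_drugs)
  if (!is.null(config$planted_pairs)) {
    for (i in seq_len(nrow(config$planted_pairs))) {
      d <- config$planted_pairs$drug[i]; e <- config$planted_pairs$event[i]
      pmat[d, e] <- pmat[d, e] * config$planted_pairs$multiplier[i]
    }
    pmat <- pmat / rowSums(pmat)
  }
  recs <- with_seed(config$seed, {
    di <- sample.int(config$n_drugs, config$n_reports, replace = TRUE,
                     prob = config$drug_weights)
    ei <- integer(config$n_reports)
    for (d in unique(di)) {
      idx <- which(di == d)
      ei[idx] <- sample.int(config$n_events, length(idx), replace = TRUE,
                            prob = pmat[d, ])
    }
    data.frame(report_id = sprintf("R%07d", seq_len(config$n_reports)),
               drug_name_raw = drugs[di],
               role = "primary_suspect",
               event_pt = events[ei],
               event_soc = NA_character_,
               date = paste0(2004 + (seq_len(config$n_reports) %% 12),
                             "Q", 1 + (seq_len(config$n_reports) %% 4)),
               drug = drugs[di],
               stringsAsFactors = FALSE)
  })
  truth <- if (!is.null(config$planted_pairs)) {
    data.frame(drug = drugs[config$planted_pairs$drug],
               event = events[config$planted_pairs$event],
               multiplier = config$planted_pairs$multiplier,
               expected_count = config$n_reports *
                 config$drug_weights[config$planted_pairs$drug] *
                 pmat[cbind(config$planted_pairs$drug,
                            config$planted_pairs$event)],
               stringsAsFactors = FALSE)
  } else data.frame(drug = character(), event = character(),
                    multiplier = numeric(), expected_count = numeric())
  list(records = recs,
       truth = list(planted = truth, event_probs = pmat,
                    drugs = drugs, events = events,
                    expected_cell = function(d, e)
                      config$n_reports * config$drug_weights[d] * pmat[d, e]))
}

#' Configuration for the labeled descriptor-matrix generator
#'
#' Emulates a compound descriptor table with planted class structure:
#' features are drawn from a block-correlated Gaussian (pairwise
#' correlation `rho` inside blocks of `block_size`, mimicking the heavy
#' redundancy of large descriptor panels) with unit variance, and the first
#' `n_informative` features are shifted by `effect_size` standard
#' deviations between the positive and negative class. Defaults mirror the
#' reference cohort scale: 155 positives, 164 negatives, 818 features.
#'
#' @param n_pos,n_neg class sizes.
#' @param n_features,n_informative panel width and number of truly
#'   class-separating features.
#' @param effect_size standardized between-class mean shift per informative
#'   feature.
#' @param rho within-block correlation in \[0, 1).
#' @param block_size features per correlation block.
#' @param missing_rate fraction of cells masked as missing.
#' @param seed RNG seed.
#' @return validated list of class `descriptor_sim_config`.
#' @export
descriptor_sim_config <- function(n_pos = 155, n_neg = 164,
                                  n_features = 818, n_informative = 15,
                                  effect_size = 1, rho = 0.3,
                                  block_size = 10, missing_rate = 0,
                                  seed = 1) {
  if (n_informative > n_features) stop("n_informative exceeds n_features")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1) stop("invalid missing_rate")
  structure(list(n_pos = n_pos, n_neg = n_neg, n_features = n_features,
                 n_informative = n_informative, effect_size = effect_size,
                 rho = rho, block_size = block_size,
                 missing_rate = missing_rate, seed = seed),
            class = "descriptor_sim_config")
}

#' Generate a labeled descriptor matrix with planted informative features
#'
#' @param config a [descriptor_sim_config()].
#' @return list with `x` (descriptor matrix, rownames = compound ids),
#'   `labels` (named `"pos"`/`"neg"` vector) and `informative` (names of
#'   the planted class-separating features).
#' @export
generate_descriptors <- function(config) {
  stopifnot(inherits(config, "descriptor_sim_config"))
  n <- config$n_pos + config$n_neg
  p <- config$n_features
  feat <- sprintf("F%04d", seq_len(p))
  ids <- c(sprintf("P%04d", seq_len(config$n_pos)),
           sprintf("N%04d", seq_len(config$n_neg)))
  labels <- setNames(rep(c("pos", "neg"), c(config$n_pos, config$n_neg)),
                     ids)
  # Planted informative features are drawn independently so the ground
  # truth is well-defined: a noise feature correlated with a shifted one
  # would itself carry class information in the multivariate sense. The
  # block redundancy therefore lives in the noise panel only.
  n_inf <- config$n_informative
  n_noise <- p - n_inf
  block <- if (n_noise > 0) ceiling(seq_len(n_noise) / config$block_size)
           else integer()
  x <- with_seed(config$seed, {
    m <- matrix(rnorm(n * p), n, p)
    if (n_noise > 0 && config$rho > 0) {
      g <- matrix(rnorm(n * max(block)), n, max(block))  # block factors
      m[, n_inf + seq_len(n_noise)] <-
        sqrt(config$rho) * g[, block, drop = FALSE] +
        sqrt(1 - config$rho) * m[, n_inf + seq_len(n_noise), drop = FALSE]
    }
    if (n_inf > 0 && config$effect_size > 0) {
      shift <- ifelse(labels == "pos", config$effect_size / 2,
                      -config$effect_size / 2)
      m[, seq_len(n_inf)] <- m[, seq_len(n_inf)] + shift
    }
    if (config$missing_rate > 0) {
      mask <- matrix(runif(n * p) < config$missing_rate, n, p)
      m[mask] <- NA_real_
    }
    m
  })
  dimnames(x) <- list(ids, feat)
  list(x = x, labels = labels,
       informative = feat[seq_len(config$n_informative)])
}
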