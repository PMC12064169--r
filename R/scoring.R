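# Composite interaction scoring. The upstream predictor emits several
# partially redundant confidence metrics per model (pi-score, ipTM_pTM,
# pDockQ); each alone misclassifies near its own threshold, so they are
# combined into a single 0-100 composite:
#
#   iQ  = ((pi + 2.63) / 5.26) * 40 + iptm_ptm * 30 + pdockq * 30
#   hiQ = ((mean(pi_interfaces) + 2.63) / 5.26) * 60 + iptm_ptm * 40
#
# pi-score is normalized from its native [-2.63, 2.63] range onto [0, 1].
# Evaluating the composites at the constituent scores' published individual
# thresholds (pi = 0.05, ipTM_pTM = 0.5, pDockQ = 0.5) gives 50.38 and
# 50.57, which motivates the operational retention rule: composite > 50.
# Scoring is applied only to the best model of each job (highest ipTM) and
# only when the complex shows at least one confident inter-chain region
# (minimum inter-chain PAE at or below 10 Angstrom by default).

PI_SCORE_HALF_RANGE <- 2.63

clamp_pi <- function(pi_score, what = "pi-score") {
  out_of_range <- abs(pi_score) > PI_SCORE_HALF_RANGE
  if (any(out_of_range, na.rm = TRUE)) {
    warning(what, " outside [-2.63, 2.63] clamped for ",
            sum(out_of_range, na.rm = TRUE), " value(s)")
  }
  pmin(pmax(pi_score, -PI_SCORE_HALF_RANGE), PI_SCORE_HALF_RANGE)
}

#' Composite iQ-score for a hetero interaction
#'
#' Weighted combination of the normalized pi-score (40%), ipTM_pTM (30%)
#' and pDockQ (30%) of the best model, on a 0-100 scale. pi-scores outside
#' \[-2.63, 2.63\] are clamped with a warning; the other two inputs are
#' bounded by construction upstream and are rejected outside \[0, 1\].
#'
#' @param pi_score interface-quality pi-score (dimensionless).
#' @param iptm_ptm weighted ipTM/pTM score in \[0, 1\].
#' @param pdockq pDockQ docking-quality score in \[0, 1\].
#' @return iQ-score in \[0, 100\]. Vectorized over its arguments.
#' @examples
#' compute_iq_score(0.05, 0.5, 0.5) # 50.38: the constituent-threshold point
#' @export
compute_iq_score <- function(pi_score, iptm_ptm, pdockq) {
  if (any(is.na(iptm_ptm)) || any(iptm_ptm < 0 | iptm_ptm > 1)) {
    stop("iptm_ptm must lie in [0, 1]")
  }
  if (any(is.na(pdockq)) || any(pdockq < 0 | pdockq > 1)) {
    stop("pdockq must lie in [0, 1] (and is required for hetero jobs)")
  }
  pi_score <- clamp_pi(pi_score)
  ((pi_score + PI_SCORE_HALF_RANGE) / (2 * PI_SCORE_HALF_RANGE)) * 40 +
    iptm_ptm * 30 + pdockq * 30
}

#' Composite hiQ-score for a homo-oligomer
#'
#' Weighted combination of the mean per-interface pi-score (normalized,
#' 60%) and ipTM_pTM (40%) of the best model, on a 0-100 scale. One
#' pi-score is expected per distinct chain-pair interface; the mean is
#' clamped to \[-2.63, 2.63\] before normalization.
#'
#' @param interface_pi_scores numeric vector, one pi-score per distinct
#'   interface of the oligomer.
#' @param iptm_ptm weighted ipTM/pTM score in \[0, 1\].
#' @return hiQ-score in \[0, 100\].
#' @examples
#' compute_hiq_score(0.05, 0.5) # 50.57: the constituent-threshold point
#' @export
compute_hiq_score <- function(interface_pi_scores, iptm_ptm) {
  if (length(interface_pi_scores) == 0L) {
    stop("at least one interface pi-score is required")
  }
  if (any(is.na(iptm_ptm)) || any(iptm_ptm < 0 | iptm_ptm > 1)) {
    stop("iptm_ptm must lie in [0, 1]")
  }
  mean_pi <- clamp_pi(mean(interface_pi_scores), "mean interface pi-score")
  ((mean_pi + PI_SCORE_HALF_RANGE) / (2 * PI_SCORE_HALF_RANGE)) * 60 +
    iptm_ptm * 40
}

#' Select the best model of a job
#'
#' Models are ranked by ipTM; only the highest-ranked model undergoes
#' composite scoring. Ties break to the lowest model index so selection is
#' deterministic.
#'
#' @param models non-empty list of [model_result()] objects for one job.
#' @return the winning `model_result`.
#' @export
select_best_model <- function(models) {
  if (length(models) == 0L) stop("no models to select from")
  iptm <- vapply(models, `[[`, numeric(1), "iptm")
  idx <- vapply(models, `[[`, integer(1), "model_index")
  best <- order(-iptm, idx)[1L]
  models[[best]]
}

#' PAE gate over inter-chain residue pairs
#'
#' Aggregates the predicted aligned error over all residue pairs that sit
#' on different chains (both orientations of the asymmetric PAE matrix) and
#' passes the model when the aggregate is at or below the threshold. The
#' default aggregate is the minimum: a single confident inter-chain region
#' is what evidences a physical interface. `median` and `mean` are offered
#' for sensitivity analysis.
#'
#' @param model a [model_result()] carrying a PAE matrix and chain ranges.
#' @param pae_threshold gate threshold in Angstrom (default 10).
#' @param stat aggregation statistic over inter-chain PAE cells.
#' @return list with `passed` (logical) and `min_interchain_pae` (the
#'   aggregated value, named for the default statistic).
#' @export
pae_gate <- function(model, pae_threshold = 10, stat = c("min", "median", "mean")) {
  stat <- match.arg(stat)
  if (is.null(model$pae)) stop("model ", model$job_id, " has no PAE matrix")
  cr <- model$chain_ranges
  if (length(cr) < 2L) {
    stop("PAE gate needs >= 2 chains; job ", model$job_id,
         " has a single-chain matrix")
  }
  n <- nrow(model$pae)
  chain_of <- integer(n)
  for (k in seq_along(cr)) {
    chain_of[(cr[[k]][1L] + 1L):cr[[k]][2L]] <- k
  }
  inter <- outer(chain_of, chain_of, `!=`)
  value <- switch(stat,
                  min = min(model$pae[inter]),
                  median = stats::median(model$pae[inter]),
                  mean = mean(model$pae[inter]))
  list(passed = value <= pae_threshold, min_interchain_pae = value)
}

#' Score and filter a cohort of best models
#'
#' For each job, the best model's PAE gate is applied first; only gated
#' models get a composite score (gate failures are kept in the output with
#' a reason but no composite). An interaction is retained when its
#' composite strictly exceeds the cutoff AND the gate passed. Interactions
#' involving shallow-MSA proteins are annotated `unreliable_msa` whatever
#' their retention status. The full table — retained and rejected, with all
#' constituent scores — is returned for transparency.
#'
#' @param best_models named list of best [model_result()]s, keyed by job id.
#' @param score_table assembled score table (see [read_score_table()]);
#'   rows are matched to each best model by job id and model index.
#'   Homo-oligomer jobs may carry one row per distinct interface.
#' @param shallow_ids protein ids flagged by [flag_shallow()].
#' @param iq_cutoff retention cutoff for hetero iQ-scores (default 50).
#' @param hiq_cutoff retention cutoff for homo hiQ-scores (default 50).
#' @param pae_threshold PAE gate threshold in Angstrom (default 10).
#' @param pae_stat PAE aggregation statistic, see [pae_gate()].
#' @return list with `interactions` (hetero `data.frame`, retained rows
#'   sorted by iQ-score descending, then rejected rows) and
#'   `homo_oligomers` (analogous for hiQ-scores).
#' @export
score_and_filter <- function(best_models, score_table,
                             shallow_ids = character(),
                             iq_cutoff = 50, hiq_cutoff = 50,
                             pae_threshold = 10, pae_stat = "min") {
  het <- list()
  hom <- list()
  for (job_id in names(best_models)) {
    model <- best_models[[job_id]]
    info <- parse_job_id(job_id)
    rows <- score_table[score_table$job_id == job_id &
                          score_table$model_index == model$model_index, ,
                        drop = FALSE]
    if (nrow(rows) == 0L) {
      stop("no score record for best model ", model$model_index,
           " of job ", job_id)
    }
    gate <- pae_gate(model, pae_threshold, pae_stat)
    unreliable <- any(info$members %in% shallow_ids)
    if (info$kind == "hetero") {
      if (nrow(rows) != 1L) stop("expected one score record for hetero job ", job_id)
      if (is.na(rows$pdockq)) {
        stop("pdockq is required for hetero job ", job_id)
      }
      iq <- NA_real_
      reason <- ""
      if (gate$passed) {
        iq <- compute_iq_score(rows$pi_score, rows$iptm_ptm, rows$pdockq)
        if (iq <= iq_cutoff) reason <- sprintf("iQ-score <= %g", iq_cutoff)
      } else {
        reason <- sprintf("PAE gate (min inter-chain PAE %.2f > %.2f)",
                          gate$min_interchain_pae, pae_threshold)
      }
      het[[length(het) + 1L]] <- data.frame(
        job_id = job_id,
        protein_a = min(info$members), protein_b = max(info$members),
        pi_score = rows$pi_score, iptm = rows$iptm,
        iptm_ptm = rows$iptm_ptm, pdockq = rows$pdockq,
        min_interchain_pae = gate$min_interchain_pae,
        pae_gate_passed = gate$passed,
        iq_score = iq,
        retained = gate$passed && !is.na(iq) && iq > iq_cutoff,
        unreliable_msa = unreliable,
        reason = reason, stringsAsFactors = FALSE)
    } else {
      n_if <- nrow(rows)
      hiq <- NA_real_
      reason <- ""
      if (gate$passed) {
        hiq <- compute_hiq_score(rows$pi_score, rows$iptm_ptm[1L])
        if (hiq <= hiq_cutoff) reason <- sprintf("hiQ-score <= %g", hiq_cutoff)
      } else {
        reason <- sprintf("PAE gate (min inter-chain PAE %.2f > %.2f)",
                          gate$min_interchain_pae, pae_threshold)
      }
      hom[[length(hom) + 1L]] <- data.frame(
        job_id = job_id,
        protein = info$members, n_copies = info$copies,
        n_interfaces = n_if,
        mean_interface_pi = mean(rows$pi_score),
        iptm = rows$iptm[1L], iptm_ptm = rows$iptm_ptm[1L],
        min_interchain_pae = gate$min_interchain_pae,
        pae_gate_passed = gate$passed,
        hiq_score = hiq,
        retained = gate$passed && !is.na(hiq) && hiq > hiq_cutoff,
        unreliable_msa = unreliable,
        reason = reason, stringsAsFactors = FALSE)
    }
  }
  interactions <- if (length(het)) do.call(rbind, het) else
    empty_interactions_table()
  homo <- if (length(hom)) do.call(rbind, hom) else empty_homo_table()
  list(interactions = sort_scored(interactions, "iq_score"),
       homo_oligomers = sort_scored(homo, "hiq_score"))
}

empty_interactions_table <- function() {
  data.frame(job_id = character(), protein_a = character(),
             protein_b = character(), pi_score = numeric(),
             iptm = numeric(), iptm_ptm = numeric(), pdockq = numeric(),
             min_interchain_pae = numeric(), pae_gate_passed = logical(),
             iq_score = numeric(), retained = logical(),
             unreliable_msa = logical(), reason = character(),
             stringsAsFactors = FALSE)
}

empty_homo_table <- function() {
  data.frame(job_id = character(), protein = character(),
             n_copies = integer(), n_interfaces = integer(),
             mean_interface_pi = numeric(), iptm = numeric(),
             iptm_ptm = numeric(), min_interchain_pae = numeric(),
             pae_gate_passed = logical(), hiq_score = numeric(),
             retained = logical(), unreliable_msa = logical(),
             reason = character(), stringsAsFactors = FALSE)
}

# retained first, by composite score descending; rejected after, stable
sort_scored <- function(tab, score_col) {
  if (nrow(tab) == 0L) return(tab)
  key <- ifelse(tab$retained, tab[[score_col]], -Inf)
  tab[order(-key, seq_len(nrow(tab))), , drop = FALSE]
}

#' Write the scored tables of a cohort
#'
#' Writes `predictions_scored.tsv` (every hetero job with all constituent
#' scores, gate status and retention flag), `homo_oligomers_scored.tsv`
#' (same for homo jobs), `retained_interactions.tsv` and
#' `retained_homooligomers.tsv` (retained subsets, composite-descending).
#'
#' @param scored result of [score_and_filter()].
#' @param out_dir output directory (created if needed).
#' @return named character vector of files written, invisibly.
#' @export
write_scored_tables <- function(scored, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    all_het = file.path(out_dir, "predictions_scored.tsv"),
    all_hom = file.path(out_dir, "homo_oligomers_scored.tsv"),
    ret_het = file.path(out_dir, "retained_interactions.tsv"),
    ret_hom = file.path(out_dir, "retained_homooligomers.tsv"))
  het <- scored$interactions
  hom <- scored$homo_oligomers
  utils::write.table(het, files[["all_het"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(hom, files[["all_hom"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(het[which(het$retained), , drop = FALSE],
                     files[["ret_het"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(hom[which(hom$retained), , drop = FALSE],
                     files[["ret_hom"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(files)
}
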