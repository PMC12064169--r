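# End-to-end orchestration: QC -> planning -> scoring -> report. Each stage
# is also callable on its own; this file only wires them together the way
# the command-line interface and the worked examples use them.

#' Score every job under a models directory
#'
#' Discovers job directories, loads their models, selects the best model of
#' each by ipTM and runs [score_and_filter()] over the cohort.
#'
#' @param models_dir directory with one subdirectory per job.
#' @param shallow_ids protein ids flagged by [flag_shallow()].
#' @param iq_cutoff,hiq_cutoff,pae_threshold,pae_stat see
#'   [score_and_filter()].
#' @param patterns file-layout patterns, see [model_file_patterns()].
#' @return list with `scored` (the [score_and_filter()] result) and
#'   `best_models` (named list of best [model_result()]s).
#' @export
score_jobs <- function(models_dir, shallow_ids = character(),
                       iq_cutoff = 50, hiq_cutoff = 50,
                       pae_threshold = 10, pae_stat = "min",
                       patterns = model_file_patterns()) {
  score_table <- discover_model_scores(models_dir, patterns)
  best_models <- list()
  for (jd in list.dirs(models_dir, recursive = FALSE)) {
    models <- load_job_models(jd, patterns)
    best <- select_best_model(models)
    best_models[[best$job_id]] <- best
  }
  scored <- score_and_filter(best_models, score_table, shallow_ids,
                             iq_cutoff, hiq_cutoff, pae_threshold, pae_stat)
  list(scored = scored, best_models = best_models)
}

#' Run the full pre/post-processing pipeline
#'
#' Sequence QC (signal-peptide trimming, MSA depth, shallow flagging), job
#' planning with memory-aware exclusion, composite scoring of predicted
#' models, and the report bundle. Stages whose inputs are absent are
#' skipped: without `msa_dir` there is no depth QC, without `models_dir`
#' the run stops after planning.
#'
#' @param fasta input FASTA of protein sequences.
#' @param out_dir output directory for all artifacts.
#' @param signalp_table optional SignalP-style summary TSV.
#' @param msa_dir optional directory of per-protein alignments
#'   (`<id>.a3m`).
#' @param models_dir optional directory of per-job model outputs.
#' @param gpu_memory_gb accelerator memory used for the OOM exclusion.
#' @param max_copies largest homo-oligomer copy count to plan.
#' @param depth_threshold shallow-MSA threshold (rows), see
#'   [flag_shallow()].
#' @param iq_cutoff,hiq_cutoff,pae_threshold,pae_stat scoring settings,
#'   see [score_and_filter()].
#' @param contact_cutoff_A,atom_mode interface analysis settings, see
#'   [interface_contacts()] and [compute_distance_matrix()].
#' @param capacity_map accelerator capacity anchors, see
#'   [default_capacity_map()].
#' @return list with `entries`, `msa_records`, `shallow_ids`, `jobs`
#'   (runnable/oom partition), and when models were scored, `scored`,
#'   `best_models` and `manifest` (path of the report manifest).
#' @export
run_pipeline <- function(fasta, out_dir,
                         signalp_table = NULL, msa_dir = NULL,
                         models_dir = NULL,
                         gpu_memory_gb = 24, max_copies = 2L,
                         depth_threshold = 100,
                         iq_cutoff = 50, hiq_cutoff = 50,
                         pae_threshold = 10, pae_stat = "min",
                         contact_cutoff_A = 8.0, atom_mode = "CB",
                         capacity_map = default_capacity_map()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  entries <- read_fasta(fasta)
  if (!is.null(signalp_table)) {
    entries <- trim_signal_peptides(entries, read_signalp_table(signalp_table))
  }
  write_fasta(entries, file.path(out_dir, "mature_proteins.fasta"),
              mature = TRUE)

  msa_records <- list()
  shallow_ids <- character()
  if (!is.null(msa_dir)) {
    qc_dir <- file.path(out_dir, "msa_depth")
    dir.create(qc_dir, showWarnings = FALSE)
    for (id in entries$id) {
      hits <- list.files(msa_dir, pattern = paste0("^", id, "\\."),
                         full.names = TRUE)
      if (!length(hits)) next
      rec <- compute_msa_depth(hits[1L], query_id = id)
      msa_records[[id]] <- rec
      plot_msa_depth(rec, file.path(qc_dir, paste0(id, "_depth.png")),
                     depth_threshold)
    }
    shallow_ids <- flag_shallow(msa_records, depth_threshold,
                                file.path(out_dir, "shallow_MSA.txt"))
  }

  jobs <- rbind(plan_hetero_pairs(entries),
                plan_homo_oligomers(entries, max_copies))
  partition <- apply_memory_limit(jobs, gpu_memory_gb, capacity_map,
                                  oom_file = file.path(out_dir, "OOM_int.txt"))
  write_job_lists(partition$runnable, out_dir)

  result <- list(entries = entries, msa_records = msa_records,
                 shallow_ids = shallow_ids, jobs = partition)
  if (!is.null(models_dir)) {
    sj <- score_jobs(models_dir, shallow_ids, iq_cutoff, hiq_cutoff,
                     pae_threshold, pae_stat)
    config <- list(gpu_memory_gb = gpu_memory_gb, max_copies = max_copies,
                   depth_threshold = depth_threshold,
                   iq_cutoff = iq_cutoff, hiq_cutoff = hiq_cutoff,
                   pae_threshold = pae_threshold, pae_stat = pae_stat,
                   contact_cutoff_A = contact_cutoff_A,
                   atom_mode = atom_mode)
    manifest <- render_report(
      sj$scored, sj$best_models, proteins = entries$id,
      out_dir = file.path(out_dir, "report"),
      shallow_ids = shallow_ids, config = config,
      input_files = c(fasta, signalp_table),
      contact_cutoff_A = contact_cutoff_A, atom_mode = atom_mode)
    result$scored <- sj$scored
    result$best_models <- sj$best_models
    result$manifest <- manifest
  }
  result
}
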