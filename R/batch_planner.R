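# Job planning for the screening phase: all-against-all hetero pairs,
# homo-oligomer series, and memory-aware exclusion of complexes too large
# for the accelerator (listed in OOM_int.txt rather than attempted).
# All sizes are in mature-sequence residues — that is what gets folded.

#' Plan all-against-all hetero-pair jobs
#'
#' One job per unordered distinct pair, so `n` proteins yield
#' `choose(n, 2)` jobs; members within a job are ordered lexicographically.
#'
#' @param entries protein entries table (mature sequences are used for
#'   sizes).
#' @return data.frame of candidate jobs with columns `job_id`, `kind`,
#'   `member_a`, `member_b`, `copies`, `total_residues`.
#' @export
plan_hetero_pairs <- function(entries) {
  entries <- validate_protein_entries(entries)
  if (nrow(entries) < 2L) {
    warning("fewer than 2 proteins: no hetero pairs to plan")
    return(empty_job_table())
  }
  ids <- sort(entries$id)
  len <- stats::setNames(nchar(entries$mature_sequence), entries$id)
  pairs <- utils::combn(ids, 2L)
  data.frame(
    job_id = apply(pairs, 2L, paste, collapse = ";"),
    kind = "hetero",
    member_a = pairs[1L, ], member_b = pairs[2L, ], copies = 1L,
    total_residues = unname(len[pairs[1L, ]] + len[pairs[2L, ]]),
    stringsAsFactors = FALSE)
}

#' Plan homo-oligomer jobs
#'
#' For each protein, one job per copy count in `2..max_copies`. The default
#' `max_copies = 2` suits the screening phase; higher stoichiometries are a
#' user choice.
#'
#' @param entries protein entries table.
#' @param max_copies largest copy count to plan (>= 2).
#' @return candidate-job data.frame, as for [plan_hetero_pairs()].
#' @export
plan_homo_oligomers <- function(entries, max_copies = 2L) {
  entries <- validate_protein_entries(entries)
  max_copies <- as.integer(max_copies)
  stopifnot(max_copies >= 2L)
  if (nrow(entries) == 0L) return(empty_job_table())
  ids <- sort(entries$id)
  len <- stats::setNames(nchar(entries$mature_sequence), entries$id)
  grid <- expand.grid(copies = 2L:max_copies, id = ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(
    job_id = paste0(grid$id, ",", grid$copies),
    kind = "homo",
    member_a = grid$id, member_b = NA_character_, copies = grid$copies,
    total_residues = unname(len[grid$id]) * grid$copies,
    stringsAsFactors = FALSE)
}

empty_job_table <- function() {
  data.frame(job_id = character(), kind = character(),
             member_a = character(), member_b = character(),
             copies = integer(), total_residues = integer(),
             stringsAsFactors = FALSE)
}

#' Default GPU-memory capacity map
#'
#' Anchor points (GPU memory in GB -> largest total residue count that fits)
#' interpolated piecewise-linearly. The exact numbers are
#' environment-dependent and user-overridable; the mechanism, not the
#' constants, is the contract.
#'
#' @return data.frame with columns `memory_gb`, `max_residues`.
#' @export
default_capacity_map <- function() {
  data.frame(memory_gb = c(8, 16, 24, 48, 80),
             max_residues = c(1800, 2700, 3600, 5500, 7200))
}

#' Residue capacity for a given GPU memory
#'
#' Piecewise-linear interpolation through the capacity map, clamped at the
#' map's ends (monotonically non-decreasing in memory).
#'
#' @param gpu_memory_gb accelerator memory in GB (> 0).
#' @param capacity_map anchor table, see [default_capacity_map()].
#' @return maximum total residue count (numeric).
#' @export
gpu_capacity <- function(gpu_memory_gb, capacity_map = default_capacity_map()) {
  if (any(gpu_memory_gb <= 0)) stop("GPU memory must be positive")
  if (is.unsorted(capacity_map$memory_gb, strictly = TRUE) ||
      is.unsorted(capacity_map$max_residues)) {
    stop("capacity map must be increasing in memory and non-decreasing in residues")
  }
  stats::approx(capacity_map$memory_gb, capacity_map$max_residues,
                xout = gpu_memory_gb, rule = 2)$y
}

#' Partition jobs into runnable and out-of-memory sets
#'
#' Jobs whose `total_residues` exceeds the capacity for the given memory are
#' excluded (not attempted) and listed, one job per line, in `OOM_int.txt`.
#' The two sets preserve input order and partition the input exactly.
#'
#' @param jobs candidate-job data.frame.
#' @param gpu_memory_gb accelerator memory in GB.
#' @param capacity_map see [default_capacity_map()].
#' @param oom_file optional path for the OOM job list (`NULL` skips
#'   writing).
#' @return list with elements `runnable` and `oom` (both job data.frames)
#'   and `capacity` (the residue limit applied).
#' @export
apply_memory_limit <- function(jobs, gpu_memory_gb,
                               capacity_map = default_capacity_map(),
                               oom_file = NULL) {
  cap <- gpu_capacity(gpu_memory_gb, capacity_map)
  over <- jobs$total_residues > cap
  out <- list(runnable = jobs[!over, , drop = FALSE],
              oom = jobs[over, , drop = FALSE],
              capacity = cap)
  if (!is.null(oom_file)) writeLines(out$oom$job_id, oom_file)
  out
}

#' Write the screening job lists
#'
#' Emits the two plain-text to-do lists consumed by the upstream predictor's
#' custom mode: `all_against_all.txt` (hetero pairs, members joined with
#' ";") and `homo_oligomers.txt` (`id,copies`). The line format equals the
#' job id; pass a different `formatter` to adapt to another tool dialect.
#'
#' @param jobs candidate-job data.frame (typically the runnable set).
#' @param out_dir output directory.
#' @param formatter function(job-row) -> line; defaults to the job id.
#' @return named character vector of the files written, invisibly.
#' @export
write_job_lists <- function(jobs, out_dir,
                            formatter = function(job) job$job_id) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(hetero = file.path(out_dir, "all_against_all.txt"),
             homo = file.path(out_dir, "homo_oligomers.txt"))
  for (kind in names(files)) {
    sub <- jobs[jobs$kind == kind, , drop = FALSE]
    lines <- if (nrow(sub)) {
      vapply(seq_len(nrow(sub)), function(i) formatter(sub[i, ]), character(1))
    } else character()
    writeLines(lines, files[[kind]])
  }
  invisible(files)
}
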