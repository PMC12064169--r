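# Shared toy cohort, generated once per test run, plus independent
# brute-force oracles used against the package implementations.

cohort_dir <- file.path(tempdir(), "ppiscorekit-test-cohort")
if (!dir.exists(cohort_dir)) {
  cohort_manifest <- generate_cohort(cohort_dir, seed = 7L)
} else {
  cohort_manifest <- jsonlite::fromJSON(
    file.path(cohort_dir, "manifest.json"), simplifyVector = TRUE)
}

# minimal in-memory model with a PAE matrix over two chains
make_pae_model <- function(pae, len_a, len_b, job_id = "A;B",
                           iptm = 0.8, iptm_ptm = 0.8) {
  model_result(job_id = job_id, model_index = 1L, iptm = iptm,
               iptm_ptm = iptm_ptm, pae = pae,
               chain_ranges = list(A = c(0L, len_a),
                                   B = c(len_a, len_a + len_b)))
}

# oracle: explicit per-cell scan for the minimum inter-chain PAE
brute_min_interchain_pae <- function(pae, len_a) {
  n <- nrow(pae)
  best <- Inf
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      chain_i <- if (i <= len_a) 1L else 2L
      chain_j <- if (j <= len_a) 1L else 2L
      if (chain_i != chain_j && pae[i, j] < best) best <- pae[i, j]
    }
  }
  best
}

# oracle: O(n^2) scan of a distance matrix for cross-chain contacts
brute_contacts <- function(dm, cutoff) {
  lab <- dm$residue_labels
  hits <- list()
  for (i in seq_len(nrow(lab))) {
    for (j in seq_len(nrow(lab))) {
      if (i < j && lab$chain[i] != lab$chain[j] &&
          dm$values[i, j] <= cutoff) {
        hits[[length(hits) + 1L]] <-
          data.frame(chain_a = lab$chain[i], resno_a = lab$resno[i],
                     chain_b = lab$chain[j], resno_b = lab$resno[j],
                     distance_A = dm$values[i, j])
      }
    }
  }
  if (!length(hits)) return(NULL)
  out <- do.call(rbind, hits)
  out[order(out$distance_A, out$chain_a, out$resno_a, out$resno_b), ,
      drop = FALSE]
}

# straight-line composite-score evaluation, duplicated here as the test
# oracle for the scoring implementation
oracle_iq_test <- function(pi, iptm_ptm, pdockq) {
  pi <- pmin(pmax(pi, -2.63), 2.63)
  ((pi + 2.63) / 5.26) * 40 + iptm_ptm * 30 + pdockq * 30
}
oracle_hiq_test <- function(pi_list, iptm_ptm) {
  m <- min(max(sum(pi_list) / length(pi_list), -2.63), 2.63)
  ((m + 2.63) / 5.26) * 60 + iptm_ptm * 40
}

# tiny FASTA writer for constructed cases
write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
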