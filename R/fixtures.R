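# Deterministic toy-cohort generator. Emits every input format the
# pipeline consumes — FASTA, signal-peptide table, A3M alignments,
# multi-chain PDB models with planted interface contacts, PAE JSONs and
# per-model score JSONs — together with a ground-truth manifest computed by
# straight-line arithmetic that is deliberately independent of the scoring
# and geometry modules, so it can serve as an oracle for them.
#
# Toy geometry: poly-alanine chains with consecutive Cbeta positions
# 7 Angstrom apart on a line, the partner chain 40 Angstrom away except at
# planted contact residues. Only inter-residue distances matter downstream;
# no rotamer realism is attempted, and the generous backbone spacing keeps
# planted contacts isolated from incidental neighbor contacts at the 8
# Angstrom screening cutoff.

#' Default toy-cohort design
#'
#' Seven proteins exercising every code path: a signal-peptide carrier,
#' two shallow-MSA proteins, one protein too large to pair on a 24 GB
#' accelerator, six scored hetero pairs (high/low composite, a PAE-gate
#' failure, a near-miss) and four scored homo-dimers, with four intended
#' retentions forming network components of sizes 3, 2 and 1.
#'
#' @return a design list understood by [generate_cohort()].
#' @export
default_cohort_design <- function() {
  list(
    proteins = data.frame(
      id = sprintf("P%02d", 1:7),
      mature_length = c(12L, 11L, 13L, 10L, 3595L, 12L, 11L),
      signal_peptide_len = c(4L, 0L, 0L, 0L, 0L, 0L, 0L),
      msa_class = c("deep", "deep", "deep", "deep", "shallow", "shallow",
                    "deep"),
      stringsAsFactors = FALSE),
    msa = list(deep_rows = 120L, shallow_rows = 5L, gap_rate = 0.1),
    hetero = data.frame(
      a = c("P01", "P02", "P04", "P01", "P03", "P06"),
      b = c("P02", "P03", "P06", "P03", "P07", "P07"),
      pi_score = c(1.0, 0.3, 0.5, -0.8, 0.9, 0.0),
      iptm_ptm = c(0.8, 0.6, 0.65, 0.45, 0.7, 0.5),
      pdockq = c(0.7, 0.55, 0.5, 0.3, 0.6, 0.45),
      iptm_best = c(0.85, 0.7, 0.72, 0.5, 0.8, 0.55),
      min_interchain_pae = c(4.0, 6.0, 5.5, 8.0, 15.0, 7.0),
      n_contacts = c(3L, 2L, 2L, 1L, 2L, 1L),
      intended_retained = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
      stringsAsFactors = FALSE),
    homo = data.frame(
      id = c("P07", "P01", "P03", "P06"),
      copies = c(2L, 2L, 2L, 2L),
      pi_score = c(0.5, -0.5, 0.2, 0.1),
      iptm_ptm = c(0.65, 0.5, 0.4, 0.45),
      iptm_best = c(0.75, 0.55, 0.5, 0.5),
      min_interchain_pae = c(4.0, 6.0, 8.0, 9.0),
      intended_retained = c(TRUE, FALSE, FALSE, FALSE),
      stringsAsFactors = FALSE),
    gpu_memory_gb = 24,
    capacity_residues = 3600,
    depth_threshold = 100,
    iq_cutoff = 50, hiq_cutoff = 50, pae_threshold = 10)
}

# straight-line composite evaluations: kept textually separate from
# scoring.R on purpose (oracle independence)
oracle_iq <- function(pi, iptm_ptm, pdockq) {
  ((pi + 2.63) / 5.26) * 40 + iptm_ptm * 30 + pdockq * 30
}
oracle_hiq <- function(pi_list, iptm_ptm) {
  ((sum(pi_list) / length(pi_list) + 2.63) / 5.26) * 60 + iptm_ptm * 40
}

#' Generate a toy input cohort on disk
#'
#' Writes a complete input bundle under `out_dir`: `proteins.fasta` (full
#' sequences, signal peptides included), `signalp.tsv`, `msas/<id>.a3m`,
#' `models/<job>/` directories with per-model score JSONs, PAE JSONs and
#' PDB structures, and `manifest.json` with the generator's own
#' expectations (shallow set, OOM partition at the stated capacity,
#' retained set with composite scores, planted contacts). The generator
#' refuses contradictory designs (an intended retention whose straight-line
#' composite or PAE gate disagrees) and re-verifies its own geometry by
#' brute-force rescan of the coordinates it wrote.
#'
#' @param out_dir output directory (created; must not already contain a
#'   cohort).
#' @param design a design list, see [default_cohort_design()].
#' @param seed integer seed; fixed seed gives a byte-identical bundle.
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
generate_cohort <- function(out_dir, design = default_cohort_design(),
                            seed = 7L) {
  validate_design(design)
  set.seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "msas"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "models"), showWarnings = FALSE)

  pro <- design$proteins
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  mature <- vapply(pro$mature_length, function(n)
    paste(sample(aa, n, replace = TRUE), collapse = ""), character(1))
  sp <- vapply(pro$signal_peptide_len, function(n)
    if (n > 0L) paste(sample(aa, n, replace = TRUE), collapse = "") else "",
    character(1))
  full <- paste0(sp, mature)
  writeLines(paste0(">", pro$id, " toy protein\n", full),
             file.path(out_dir, "proteins.fasta"))

  sig <- data.frame(
    id = pro$id,
    prediction = ifelse(pro$signal_peptide_len > 0L, "SP(Sec/SPI)", "OTHER"),
    cs_position = ifelse(pro$signal_peptide_len > 0L,
                         pro$signal_peptide_len, NA_integer_))
  utils::write.table(sig, file.path(out_dir, "signalp.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")

  # --- alignments: query + sampled rows with known gap pattern ------------
  depth_profiles <- list()
  msa_rows <- integer(nrow(pro))
  for (i in seq_len(nrow(pro))) {
    n_rows <- if (pro$msa_class[i] == "deep") design$msa$deep_rows else
      design$msa$shallow_rows
    len <- pro$mature_length[i]
    gaps <- matrix(stats::runif((n_rows - 1L) * len) < design$msa$gap_rate,
                   nrow = n_rows - 1L)
    rows <- matrix(sample(aa, (n_rows - 1L) * len, replace = TRUE),
                   nrow = n_rows - 1L)
    rows[gaps] <- "-"
    lines <- c(paste0(">", pro$id[i]), mature[i])
    for (r in seq_len(n_rows - 1L)) {
      body <- paste(rows[r, ], collapse = "")
      # one row per deep alignment carries an A3M lowercase insertion
      if (r == 1L && pro$msa_class[i] == "deep") {
        body <- paste0(substring(body, 1L, 3L), "xyz",
                       substring(body, 4L))
      }
      lines <- c(lines, paste0(">hom", r), body)
    }
    writeLines(lines, file.path(out_dir, "msas", paste0(pro$id[i], ".a3m")))
    depth_profiles[[pro$id[i]]] <- unname(1L + colSums(!gaps))
    msa_rows[i] <- n_rows
  }
  expected_shallow <- sort(pro$id[vapply(
    pro$id, function(p) stats::median(depth_profiles[[p]]), numeric(1)) <
      design$depth_threshold])

  # --- job universe and OOM partition at the stated capacity --------------
  mlen <- stats::setNames(pro$mature_length, pro$id)
  ids <- sort(pro$id)
  pairs <- utils::combn(ids, 2L)
  all_jobs <- data.frame(
    job_id = c(apply(pairs, 2L, paste, collapse = ";"),
               paste0(ids, ",2")),
    total = c(mlen[pairs[1L, ]] + mlen[pairs[2L, ]], 2L * mlen[ids]),
    stringsAsFactors = FALSE)
  expected_oom <- all_jobs$job_id[all_jobs$total > design$capacity_residues]

  # --- scored jobs: structures, PAE, score files --------------------------
  contacts <- list()
  expected <- list()
  jobs <- rbind(
    data.frame(job_id = mapply(function(a, b) paste(sort(c(a, b)),
                                                    collapse = ";"),
                               design$hetero$a, design$hetero$b),
               kind = "hetero", design$hetero, stringsAsFactors = FALSE,
               row.names = NULL),
    NULL)
  for (k in seq_len(nrow(jobs))) {
    h <- jobs[k, ]
    members <- sort(c(h$a, h$b))
    iq <- oracle_iq(h$pi_score, h$iptm_ptm, h$pdockq)
    gate_ok <- h$min_interchain_pae <= design$pae_threshold
    retain <- gate_ok && iq > design$iq_cutoff
    if (retain != h$intended_retained) {
      stop("contradictory design for ", h$job_id, ": straight-line iQ ",
           round(iq, 2), ", gate ", gate_ok, " vs intended_retained ",
           h$intended_retained)
    }
    planted <- plant_contacts(h$n_contacts)
    write_job_bundle(
      file.path(out_dir, "models", job_dir_name(h$job_id)),
      job_id = h$job_id,
      chain_lens = unname(mlen[members]),
      planted = planted,
      min_pae = h$min_interchain_pae,
      iptm_best = h$iptm_best, iptm_ptm = h$iptm_ptm,
      pi_score = h$pi_score, pdockq = h$pdockq,
      dialect_b = k %% 2L == 0L)
    contacts[[h$job_id]] <- planted
    expected[[h$job_id]] <- list(
      kind = "hetero", iq_score = if (gate_ok) iq else NA,
      gate_passed = gate_ok, retained = retain,
      unreliable_msa = any(members %in% expected_shallow))
  }
  for (k in seq_len(nrow(design$homo))) {
    h <- design$homo[k, ]
    job_id <- paste0(h$id, ",", h$copies)
    hiq <- oracle_hiq(h$pi_score, h$iptm_ptm)
    gate_ok <- h$min_interchain_pae <= design$pae_threshold
    retain <- gate_ok && hiq > design$hiq_cutoff
    if (retain != h$intended_retained) {
      stop("contradictory design for ", job_id, ": straight-line hiQ ",
           round(hiq, 2), ", gate ", gate_ok, " vs intended_retained ",
           h$intended_retained)
    }
    planted <- plant_contacts(1L)
    write_job_bundle(
      file.path(out_dir, "models", job_dir_name(job_id)),
      job_id = job_id,
      chain_lens = rep(mlen[h$id], h$copies),
      planted = planted,
      min_pae = h$min_interchain_pae,
      iptm_best = h$iptm_best, iptm_ptm = h$iptm_ptm,
      pi_score = h$pi_score, pdockq = NULL,
      dialect_b = k %% 2L == 0L)
    contacts[[job_id]] <- planted
    expected[[job_id]] <- list(
      kind = "homo", hiq_score = if (gate_ok) hiq else NA,
      gate_passed = gate_ok, retained = retain,
      unreliable_msa = h$id %in% expected_shallow)
  }

  manifest <- list(
    seed = seed,
    proteins = data.frame(pro, full_length = nchar(full),
                          msa_rows = msa_rows, stringsAsFactors = FALSE),
    depth_profiles = depth_profiles,
    depth_threshold = design$depth_threshold,
    expected_shallow = expected_shallow,
    gpu_memory_gb = design$gpu_memory_gb,
    capacity_residues = design$capacity_residues,
    n_hetero_jobs = ncol(pairs),
    expected_oom = expected_oom,
    expected_jobs = expected,
    planted_contacts = contacts,
    expected_retained = sort(names(expected)[vapply(expected, `[[`,
                                                    logical(1), "retained")]),
    cutoffs = list(iq = design$iq_cutoff, hiq = design$hiq_cutoff,
                   pae = design$pae_threshold))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

validate_design <- function(design) {
  pro <- design$proteins
  stopifnot(!anyDuplicated(pro$id), all(pro$mature_length >= 8L),
            all(pro$msa_class %in% c("deep", "shallow")))
  scored_ids <- unique(c(design$hetero$a, design$hetero$b, design$homo$id))
  missing <- setdiff(scored_ids, pro$id)
  if (length(missing)) stop("scored job references unknown protein(s): ",
                            paste(missing, collapse = ", "))
  need <- pmax(design$hetero$n_contacts) * 2L + 1L
  lens <- stats::setNames(pro$mature_length, pro$id)
  if (any(lens[design$hetero$a] < need | lens[design$hetero$b] < need)) {
    stop("a scored chain is too short for its planted contact count")
  }
  invisible(TRUE)
}

# planted contact positions: residues 2, 4, 6, ... on both chains, with
# distances stepping 4.0, 5.5, 7.0 Angstrom (all >= 4 so that 7-Angstrom
# backbone spacing keeps neighbors outside the 8-Angstrom cutoff)
plant_contacts <- function(n) {
  d <- c(4.0, 5.5, 7.0)[seq_len(n)]
  data.frame(res_a = 2L * seq_len(n), res_b = 2L * seq_len(n),
             distance = d)
}

BACKBONE_SPACING <- 7.0
CHAIN_SEPARATION <- 40.0

# Cbeta coordinates of every chain of a toy complex; chain 1 on the y = 0
# line, later chains on y = 40, planted residues of chain 2 pulled down to
# the designed distance above their chain-1 partner
toy_cb_coords <- function(chain_lens, planted) {
  lapply(seq_along(chain_lens), function(ci) {
    len <- chain_lens[ci]
    x <- (seq_len(len) - 1L) * BACKBONE_SPACING
    y <- rep(if (ci == 1L) 0 else CHAIN_SEPARATION, len)
    z <- rep((ci - 1L) * 0.0, len)
    if (ci == 2L && nrow(planted)) {
      x[planted$res_b] <- (planted$res_a - 1L) * BACKBONE_SPACING
      y[planted$res_b] <- planted$distance
    }
    cbind(x = x, y = y, z = z)
  })
}

# one job directory: two models (index 1 = designed best), each with a
# score JSON, a PAE JSON (two dialects, alternating) and a PDB structure
write_job_bundle <- function(job_dir, job_id, chain_lens, planted, min_pae,
                             iptm_best, iptm_ptm, pi_score, pdockq,
                             dialect_b = FALSE) {
  dir.create(job_dir, showWarnings = FALSE, recursive = TRUE)
  cb <- toy_cb_coords(chain_lens, planted)
  # independent brute-force audit of the geometry just planned
  audit_planted_geometry(cb, planted, chain_lens)
  pae <- toy_pae(chain_lens, min_pae, planted)
  for (m in 1:2) {
    scores <- list(job_id = job_id, model_index = m,
                   iptm = if (m == 1L) iptm_best else
                     round(iptm_best * 0.5, 3),
                   iptm_ptm = if (m == 1L) iptm_ptm else
                     round(iptm_ptm * 0.5, 3),
                   pi_score = if (m == 1L) pi_score else pi_score - 0.4)
    if (!is.null(pdockq)) {
      scores$pdockq <- if (m == 1L) pdockq else round(pdockq * 0.5, 3)
    }
    jsonlite::write_json(scores, file.path(job_dir,
                                           sprintf("scores_model_%d.json", m)),
                         auto_unbox = TRUE, digits = NA)
    payload <- list(predicted_aligned_error = pae)
    if (dialect_b) payload <- list(payload)
    jsonlite::write_json(payload,
                         file.path(job_dir, sprintf("pae_model_%d.json", m)),
                         auto_unbox = TRUE, digits = NA)
    write_toy_pdb(cb, file.path(job_dir, sprintf("model_%d.pdb", m)))
  }
  invisible(job_dir)
}

audit_planted_geometry <- function(cb, planted, chain_lens) {
  if (length(cb) < 2L) return(invisible(TRUE))
  found <- list()
  for (ci in 2L:length(cb)) {
    d2 <- outer(rowSums(cb[[1L]]^2), rowSums(cb[[ci]]^2), `+`) -
      2 * (cb[[1L]] %*% t(cb[[ci]]))
    hit <- which(sqrt(pmax(d2, 0)) <= 8.0, arr.ind = TRUE)
    found[[ci - 1L]] <- hit
  }
  hits <- do.call(rbind, found)
  ok <- nrow(hits) == nrow(planted) &&
    all(sort(hits[, 1L]) == sort(planted$res_a))
  if (!ok) {
    stop("geometry audit failed: planted contacts and brute-force rescan ",
         "disagree (", nrow(hits), " found vs ", nrow(planted), " planted)")
  }
  invisible(TRUE)
}

# PAE: low within chains (3 A), high between chains (25 A) except one cell
# carrying the designed minimum
toy_pae <- function(chain_lens, min_pae, planted) {
  n <- sum(chain_lens)
  ends <- cumsum(chain_lens)
  starts <- c(0L, ends[-length(ends)])
  chain_of <- rep(seq_along(chain_lens), chain_lens)
  inter_fill <- max(25, min_pae + 10)
  pae <- matrix(inter_fill, n, n)
  same <- outer(chain_of, chain_of, `==`)
  pae[same] <- 3
  diag(pae) <- 0
  i <- starts[1L] + if (nrow(planted)) planted$res_a[1L] else 1L
  j <- starts[2L] + if (nrow(planted)) planted$res_b[1L] else 1L
  pae[i, j] <- min_pae
  pae
}

# minimal but column-correct PDB writer: poly-alanine, N/CA/CB/C/O per
# residue placed around the Cbeta anchor
write_toy_pdb <- function(cb, path) {
  lines <- character()
  serial <- 0L
  offsets <- list(N = c(-1.2, 0.8, 1.5), CA = c(0, 0, 1.53),
                  CB = c(0, 0, 0), C = c(1.2, 0.8, 1.5),
                  O = c(1.9, 1.6, 1.5))
  elements <- c(N = "N", CA = "C", CB = "C", C = "C", O = "O")
  for (ci in seq_along(cb)) {
    chain <- LETTERS[ci]
    for (r in seq_len(nrow(cb[[ci]]))) {
      for (at in names(offsets)) {
        serial <- serial + 1L
        xyz <- cb[[ci]][r, ] + offsets[[at]]
        lines <- c(lines, sprintf(
          "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, at, "ALA", chain, r, xyz[1L], xyz[2L], xyz[3L],
          1.0, 0.0, elements[[at]]))
      }
    }
    lines <- c(lines, "TER")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
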