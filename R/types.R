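# Domain types shared across the pipeline.
#
# Protein entries are kept as a plain data.frame (one row per protein) because
# every consumer treats them as a table; MSA records and model results are
# small classed lists.

#' Construct a table of protein entries
#'
#' @param id character vector of unique protein identifiers.
#' @param sequence amino-acid sequences (one-letter codes, upper case).
#' @param signal_peptide_end optional integer vector, 1-based index of the
#'   last signal-peptide residue (`NA` when none).
#' @return a `data.frame` with columns `id`, `sequence`,
#'   `signal_peptide_end`, `mature_sequence`. `mature_sequence` equals
#'   `sequence` with positions `1..signal_peptide_end` removed.
#' @export
protein_entries <- function(id, sequence, signal_peptide_end = NA_integer_) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  n <- length(id)
  stopifnot(length(sequence) == n)
  signal_peptide_end <- rep_len(as.integer(signal_peptide_end), n)
  if (anyDuplicated(id)) {
    stop("duplicate protein id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  check_residue_alphabet(sequence, id)
  mature <- ifelse(is.na(signal_peptide_end), sequence,
                   substring(sequence, signal_peptide_end + 1L))
  out <- data.frame(id = id, sequence = sequence,
                    signal_peptide_end = signal_peptide_end,
                    mature_sequence = mature,
                    stringsAsFactors = FALSE)
  validate_protein_entries(out)
}

#' @keywords internal
validate_protein_entries <- function(entries) {
  needed <- c("id", "sequence", "signal_peptide_end", "mature_sequence")
  missing <- setdiff(needed, names(entries))
  if (length(missing)) {
    stop("protein entries table lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(!nzchar(entries$sequence))) {
    stop("empty sequence for protein: ",
         paste(entries$id[!nzchar(entries$sequence)], collapse = ", "))
  }
  trimmed <- !is.na(entries$signal_peptide_end)
  if (any(trimmed)) {
    ok <- nchar(entries$mature_sequence[trimmed]) ==
      nchar(entries$sequence[trimmed]) - entries$signal_peptide_end[trimmed]
    if (!all(ok)) {
      stop("mature_sequence length inconsistent with signal_peptide_end for: ",
           paste(entries$id[trimmed][!ok], collapse = ", "))
    }
  }
  entries
}

# Alphabet: 20 canonical residues plus X (unknown).
check_residue_alphabet <- function(sequence, id) {
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", sequence)
  if (any(bad)) {
    stop("illegal residue character in sequence(s): ",
         paste(id[bad], collapse = ", "))
  }
  invisible(TRUE)
}

#' Construct an MSA depth record
#'
#' @param protein_id query protein identifier.
#' @param n_rows number of aligned sequences (query included).
#' @param depth_profile integer vector, per-column count of non-gap residues
#'   over the query's ungapped coordinates.
#' @return an object of class `msa_record`.
#' @export
msa_record <- function(protein_id, n_rows, depth_profile) {
  n_rows <- as.integer(n_rows)
  depth_profile <- as.integer(depth_profile)
  if (length(depth_profile) < 1L) stop("empty depth profile")
  if (any(depth_profile < 1L) || any(depth_profile > n_rows)) {
    stop("depth profile must lie in [1, n_rows] for ", protein_id)
  }
  structure(list(protein_id = as.character(protein_id),
                 n_rows = n_rows,
                 depth_profile = depth_profile),
            class = "msa_record")
}

#' @export
print.msa_record <- function(x, ...) {
  cat(sprintf("MSA record for %s: %d rows, %d query columns, median depth %g\n",
              x$protein_id, x$n_rows, length(x$depth_profile),
              stats::median(x$depth_profile)))
  invisible(x)
}

#' Construct a model result for one predicted complex
#'
#' @param job_id job identifier (see [format_job_id()]).
#' @param model_index integer in 1..5.
#' @param iptm interface predicted TM-score in \[0, 1\] (used for ranking).
#' @param iptm_ptm weighted ipTM/pTM combination in \[0, 1\] (used in the
#'   composite scores).
#' @param structure_path path to the model's PDB/mmCIF file (may be `NA`).
#' @param pae square numeric matrix of predicted aligned error (Angstrom);
#'   dimension must equal the total residue count of the complex.
#' @param chain_ranges named list mapping chain id to a length-2 integer
#'   vector `c(start, end)`, the 0-based half-open residue interval of that
#'   chain within the PAE matrix.
#' @return an object of class `model_result`.
#' @export
model_result <- function(job_id, model_index, iptm, iptm_ptm,
                         structure_path = NA_character_,
                         pae = NULL, chain_ranges = NULL) {
  model_index <- as.integer(model_index)
  stopifnot(model_index >= 1L, model_index <= 5L)
  stopifnot(iptm >= 0, iptm <= 1, iptm_ptm >= 0, iptm_ptm <= 1)
  if (!is.null(pae)) {
    if (!is.matrix(pae) || nrow(pae) != ncol(pae)) {
      stop("PAE must be a square matrix; got ", nrow(pae), " x ", ncol(pae))
    }
    if (any(pae < 0)) stop("PAE values must be non-negative")
    if (is.null(chain_ranges)) stop("chain_ranges required alongside a PAE matrix")
    validate_chain_ranges(chain_ranges, nrow(pae))
  }
  structure(list(job_id = as.character(job_id), model_index = model_index,
                 iptm = as.numeric(iptm), iptm_ptm = as.numeric(iptm_ptm),
                 structure_path = structure_path,
                 pae = pae, chain_ranges = chain_ranges),
            class = "model_result")
}

# chain_ranges intervals must be disjoint and cover 0..dim (0-based half-open)
validate_chain_ranges <- function(chain_ranges, dim) {
  if (is.null(names(chain_ranges)) || any(!nzchar(names(chain_ranges)))) {
    stop("chain_ranges must be a named list")
  }
  m <- do.call(rbind, lapply(chain_ranges, as.integer))
  m <- m[order(m[, 1L]), , drop = FALSE]
  if (any(m[, 2L] <= m[, 1L])) stop("chain_ranges contain an empty interval")
  if (m[1L, 1L] != 0L || m[nrow(m), 2L] != dim ||
      (nrow(m) > 1L && any(m[-1L, 1L] != m[-nrow(m), 2L]))) {
    stop("chain_ranges must disjointly cover 0..", dim,
         " (total chain length ", sum(m[, 2L] - m[, 1L]), ")")
  }
  invisible(TRUE)
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("Model %d of job %s: ipTM %.3f, ipTM_pTM %.3f, %s chains\n",
              x$model_index, x$job_id, x$iptm, x$iptm_ptm,
              if (is.null(x$chain_ranges)) "?" else length(x$chain_ranges)))
  invisible(x)
}
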