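# Readers and writers for the external formats the pipeline touches:
# FASTA sequences, PDB/mmCIF structures, PAE JSON matrices and per-model
# score files. Everything is normalized into the types of types.R.

#' Read protein sequences from a FASTA file
#'
#' Record ids are the header up to the first whitespace; sequences are
#' upper-cased and restricted to the 20 canonical residues plus X.
#' Duplicate ids are an error. `mature_sequence` starts equal to `sequence`
#' (see [trim_signal_peptides()]).
#'
#' @param path path to a FASTA file.
#' @return a protein entries `data.frame` (see [protein_entries()]).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA ", path, ": ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  protein_entries(id = ids, sequence = as.character(set))
}

#' Write protein entries to FASTA
#'
#' @param entries protein entries table.
#' @param path output path.
#' @param mature write the mature (signal-peptide-trimmed) sequence instead
#'   of the full sequence.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(entries, path, mature = FALSE) {
  seqs <- if (mature) entries$mature_sequence else entries$sequence
  writeLines(paste0(">", entries$id, "\n", seqs), path)
  invisible(path)
}

#' Read a predicted-aligned-error matrix from JSON
#'
#' Two dialects emitted by the AlphaFold-Multimer tool family are accepted:
#' an object with key `predicted_aligned_error` holding a list of rows, and a
#' one-element list wrapping the same object. Anything else is rejected.
#'
#' @param path path to the PAE JSON file.
#' @param chain_ranges optional named list of 0-based half-open chain
#'   intervals; when given, the matrix dimension is validated against the
#'   summed chain lengths.
#' @return a square numeric matrix of PAE values (Angstrom).
#' @export
read_pae_matrix <- function(path, chain_ranges = NULL) {
  if (!file.exists(path)) stop("PAE file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  # dialect (b): list of one object wrapping dialect (a)
  if (is.data.frame(obj) && "predicted_aligned_error" %in% names(obj) &&
      nrow(obj) == 1L) {
    obj <- list(predicted_aligned_error = obj$predicted_aligned_error[[1L]])
  } else if (is.list(obj) && is.null(names(obj)) && length(obj) == 1L) {
    obj <- obj[[1L]]
  }
  if (!is.list(obj) || !"predicted_aligned_error" %in% names(obj)) {
    stop("unrecognized PAE JSON dialect in ", path,
         ": expected key 'predicted_aligned_error'")
  }
  pae <- obj$predicted_aligned_error
  if (is.list(pae)) pae <- do.call(rbind, pae)
  pae <- as.matrix(pae)
  storage.mode(pae) <- "double"
  if (nrow(pae) != ncol(pae)) {
    stop("PAE matrix in ", path, " is not square: ",
         nrow(pae), " x ", ncol(pae))
  }
  if (any(pae < 0)) stop("negative PAE values in ", path)
  if (!is.null(chain_ranges)) {
    total <- sum(vapply(chain_ranges, function(r) r[2L] - r[1L], numeric(1)))
    if (total != nrow(pae)) {
      stop("PAE dimension ", nrow(pae), " does not match total chain length ",
           total, " in ", path)
    }
  }
  pae
}

#' Read a predicted complex structure
#'
#' Parses a PDB or mmCIF file into per-chain, per-residue atom records.
#' Chains are keyed by author chain id and residues follow file order.
#'
#' @param path path to a `.pdb` or `.cif` file.
#' @return an object of class `ppi_structure`: a list with `chains` (named
#'   list of data.frames with columns `resno`, `resname`, `atom`, `x`, `y`,
#'   `z`, one row per heavy atom) and `path`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path) else bio3d::read.pdb(path),
    error = function(e) stop("cannot parse structure ", path, ": ",
                             conditionMessage(e)))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records (zero residues) in ", path)
  at$chain[is.na(at$chain) | !nzchar(at$chain)] <- "A"
  chains <- lapply(split(at, factor(at$chain, levels = unique(at$chain))),
                   function(d) {
                     data.frame(resno = d$resno, resname = d$resid,
                                atom = d$elety,
                                x = d$x, y = d$y, z = d$z,
                                stringsAsFactors = FALSE)
                   })
  structure(list(chains = chains, path = path), class = "ppi_structure")
}

#' @export
print.ppi_structure <- function(x, ...) {
  lens <- vapply(x$chains, function(d) length(unique(d$resno)), integer(1))
  cat(sprintf("Structure %s: %d chain(s) [%s]\n", x$path, length(x$chains),
              paste(sprintf("%s: %d res", names(lens), lens), collapse = ", ")))
  invisible(x)
}

#' Residue counts per chain of a parsed structure
#' @param structure a `ppi_structure`.
#' @return named integer vector of residue counts in chain order.
#' @export
chain_lengths <- function(structure) {
  vapply(structure$chains, function(d) length(unique(d$resno)), integer(1))
}

#' 0-based half-open chain intervals of a parsed structure
#' @param structure a `ppi_structure`.
#' @return named list of `c(start, end)` intervals in chain order.
#' @export
structure_chain_ranges <- function(structure) {
  lens <- chain_lengths(structure)
  ends <- cumsum(lens)
  starts <- c(0L, ends[-length(ends)])
  stats::setNames(Map(function(s, e) c(s, e), starts, ends), names(lens))
}

#' Read an assembled per-model score table
#'
#' Expects a CSV/TSV with columns `job_id`, `model_index`, `iptm`,
#' `iptm_ptm`, `pi_score` and optionally `pdockq` (homo-oligomer jobs have
#' no pDockQ; absence is recorded as `NA`, never as zero). Homo-oligomer
#' jobs may carry several rows per model, one per distinct chain-pair
#' interface pi-score.
#'
#' @param path path to the table.
#' @return data.frame with one row per (job, model, interface) record.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop("score table not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("job_id", "model_index", "iptm", "iptm_ptm", "pi_score")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("score table ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!"pdockq" %in% names(tab)) tab$pdockq <- NA_character_
  num_cols <- c("model_index", "iptm", "iptm_ptm", "pi_score", "pdockq")
  for (cl in num_cols) {
    raw <- tab[[cl]]
    empty <- is.na(raw) | !nzchar(raw)
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!empty & is.na(val))
    if (length(bad)) {
      stop("non-numeric value '", raw[bad[1L]], "' in column '", cl,
           "', row ", bad[1L], " of ", path)
    }
    tab[[cl]] <- val
  }
  tab$model_index <- as.integer(tab$model_index)
  tab
}

#' Write an assembled score table
#' @param tab score table data.frame.
#' @param path output path (TSV).
#' @return `path`, invisibly.
#' @export
write_score_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' File-layout convention for a job's model outputs
#'
#' Upstream predictors emit one score JSON, one PAE JSON and one structure
#' per model inside a per-job directory. The glob patterns here are the
#' package's convention and can be overridden wherever a discovery routine
#' accepts a `patterns` argument (`%d` is the model index).
#'
#' @return named list of sprintf patterns `scores`, `pae`, `structure`.
#' @export
model_file_patterns <- function() {
  list(scores = "scores_model_%d.json",
       pae = "pae_model_%d.json",
       structure = "model_%d.pdb")
}

#' Discover per-model score files under a models directory
#'
#' Scans each job subdirectory of `models_dir` for per-model score JSONs and
#' assembles them into one score table. Score JSONs carry `job_id`,
#' `model_index`, `iptm`, `iptm_ptm`, `pi_score` (scalar, or vector with one
#' value per distinct interface for homo-oligomers) and optionally `pdockq`.
#'
#' @param models_dir directory containing one subdirectory per job.
#' @param patterns file-layout patterns, see [model_file_patterns()].
#' @return score table data.frame as from [read_score_table()].
#' @export
discover_model_scores <- function(models_dir, patterns = model_file_patterns()) {
  if (!dir.exists(models_dir)) stop("models directory not found: ", models_dir)
  job_dirs <- list.dirs(models_dir, recursive = FALSE)
  rows <- list()
  glob <- utils::glob2rx(gsub("%d", "*", patterns$scores))
  for (jd in job_dirs) {
    for (f in sort(list.files(jd, pattern = glob, full.names = TRUE))) {
      rec <- jsonlite::fromJSON(f)
      pi <- as.numeric(rec$pi_score)
      rows[[length(rows) + 1L]] <- data.frame(
        job_id = rec$job_id,
        model_index = as.integer(rec$model_index),
        iptm = as.numeric(rec$iptm),
        iptm_ptm = as.numeric(rec$iptm_ptm),
        pi_score = pi,
        pdockq = if (is.null(rec$pdockq)) NA_real_ else as.numeric(rec$pdockq),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no per-model score files found under ", models_dir)
  do.call(rbind, rows)
}

#' Load all models of one job from its directory
#'
#' Reads the per-model score JSONs, structures and PAE matrices of one job
#' directory into [model_result()] objects. Chain intervals are derived from
#' each model's structure file.
#'
#' @param job_dir the job's directory.
#' @param patterns file-layout patterns, see [model_file_patterns()].
#' @return list of `model_result`, ordered by model index.
#' @export
load_job_models <- function(job_dir, patterns = model_file_patterns()) {
  glob <- utils::glob2rx(gsub("%d", "*", patterns$scores))
  score_files <- sort(list.files(job_dir, pattern = glob, full.names = TRUE))
  if (!length(score_files)) stop("no model score files in ", job_dir)
  models <- lapply(score_files, function(f) {
    rec <- jsonlite::fromJSON(f)
    k <- as.integer(rec$model_index)
    spath <- file.path(job_dir, sprintf(patterns$structure, k))
    ppath <- file.path(job_dir, sprintf(patterns$pae, k))
    cr <- NULL
    pae <- NULL
    if (file.exists(spath)) cr <- structure_chain_ranges(read_structure(spath))
    if (file.exists(ppath)) {
      if (is.null(cr)) stop("PAE without structure for model ", k, " in ", job_dir)
      pae <- read_pae_matrix(ppath, cr)
    }
    model_result(job_id = rec$job_id, model_index = k,
                 iptm = as.numeric(rec$iptm),
                 iptm_ptm = as.numeric(rec$iptm_ptm),
                 structure_path = if (file.exists(spath)) spath else NA_character_,
                 pae = pae, chain_ranges = cr)
  })
  models[order(vapply(models, `[[`, integer(1), "model_index"))]
}

# ---- job identifiers ------------------------------------------------------

#' Format a job identifier
#'
#' Hetero pairs are the two ids, lexicographic, joined with ";"
#' (`"A;B"`); homo-oligomers are `"id,copies"` (`"A,3"`). The same syntax is
#' used for job-list lines.
#'
#' @param members character vector of member protein ids.
#' @param copies integer copy count (homo-oligomers only).
#' @return a single job-id string.
#' @export
format_job_id <- function(members, copies = 1L) {
  if (length(members) == 1L && copies >= 2L) {
    paste0(members, ",", copies)
  } else if (length(members) == 2L && copies == 1L) {
    paste(sort(members), collapse = ";")
  } else {
    stop("a job is either a hetero pair (2 members) or a homo-oligomer ",
         "(1 member, copies >= 2)")
  }
}

#' Parse a job identifier
#' @param job_id a job-id string as produced by [format_job_id()].
#' @return list with `kind` ("hetero" or "homo"), `members` (ids) and
#'   `copies`.
#' @export
parse_job_id <- function(job_id) {
  if (grepl(";", job_id, fixed = TRUE)) {
    list(kind = "hetero", members = strsplit(job_id, ";", fixed = TRUE)[[1L]],
         copies = 1L)
  } else if (grepl(",", job_id, fixed = TRUE)) {
    parts <- strsplit(job_id, ",", fixed = TRUE)[[1L]]
    list(kind = "homo", members = parts[1L], copies = as.integer(parts[2L]))
  } else {
    stop("unrecognized job id: ", job_id)
  }
}

# job directories cannot contain ";" portably; sanitize both ways
job_dir_name <- function(job_id) gsub("[;,]", "_and_", job_id)
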