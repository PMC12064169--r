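# Sequence cleaning and MSA quality control: signal-peptide trimming from a
# SignalP-style annotation table, per-position alignment depth, and
# shallow-MSA flagging. Shallow proteins are annotated downstream, never
# dropped: exclusion would silently discard discoveries.

#' Read a SignalP-style signal-peptide summary table
#'
#' Expects a TSV with columns `id`, `prediction` and `cs_position` (1-based
#' index of the last signal-peptide residue; empty/NA for proteins without a
#' signal peptide). Lines starting with `#` are ignored. Organism class
#' (gram+/gram-/eukaryote) only affects how the external predictor was run,
#' so it is not interpreted here.
#'
#' @param path path to the summary TSV.
#' @return data.frame with columns `protein_id`, `cleavage_position`
#'   (rows without a predicted signal peptide are dropped).
#' @export
read_signalp_table <- function(path) {
  if (!file.exists(path)) stop("signal-peptide table not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(c("id", "cs_position"), names(tab))
  if (length(missing)) {
    stop("signal-peptide table lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  cs <- suppressWarnings(as.integer(tab$cs_position))
  keep <- !is.na(cs) & cs > 0L
  data.frame(protein_id = as.character(tab$id[keep]),
             cleavage_position = cs[keep], stringsAsFactors = FALSE)
}

#' Trim signal peptides from protein entries
#'
#' Annotated entries get `mature_sequence` with positions
#' `1..cleavage_position` removed and `signal_peptide_end` set; unannotated
#' entries are untouched. Downstream modules (job planning, structure
#' analysis) consume `mature_sequence` only — that is what the predictor
#' folds after translocation.
#'
#' @param entries protein entries table (see [read_fasta()]).
#' @param annotations data.frame with columns `protein_id`,
#'   `cleavage_position` (1-based index of the last signal-peptide residue).
#' @return the entries table with trimming applied. Re-applying the same
#'   annotations is a no-op.
#' @export
trim_signal_peptides <- function(entries, annotations) {
  entries <- validate_protein_entries(entries)
  if (is.null(annotations) || nrow(annotations) == 0L) return(entries)
  unknown <- setdiff(annotations$protein_id, entries$id)
  if (length(unknown)) {
    warning("signal-peptide annotation for unknown protein(s), skipped: ",
            paste(unknown, collapse = ", "))
    annotations <- annotations[!annotations$protein_id %in% unknown, ,
                               drop = FALSE]
  }
  for (k in seq_len(nrow(annotations))) {
    i <- match(annotations$protein_id[k], entries$id)
    cs <- as.integer(annotations$cleavage_position[k])
    len <- nchar(entries$sequence[i])
    if (cs >= len) {
      stop("signal-peptide cleavage at ", cs, " leaves an empty mature ",
           "sequence for ", entries$id[i], " (length ", len, ")")
    }
    entries$signal_peptide_end[i] <- cs
    entries$mature_sequence[i] <- substring(entries$sequence[i], cs + 1L)
  }
  validate_protein_entries(entries)
}

#' Compute per-position MSA depth
#'
#' Reads an A3M or aligned-FASTA alignment whose first record is the query
#' and counts, for each query column, the rows carrying a non-gap residue.
#' A3M insertion columns (lowercase) do not consume query columns and are
#' excluded; in aligned FASTA, columns where the query has a gap are
#' likewise skipped, so the profile always lives on the query's ungapped
#' coordinates.
#'
#' @param msa_file path to the alignment.
#' @param query_id optional id the first record must match (checked when
#'   given).
#' @return an [msa_record()].
#' @export
compute_msa_depth <- function(msa_file, query_id = NULL) {
  recs <- read_fasta_text(msa_file)
  if (length(recs$seq) == 0L) stop("empty alignment: ", msa_file)
  if (!is.null(query_id) && recs$id[1L] != query_id) {
    stop("first record of ", msa_file, " is '", recs$id[1L],
         "', expected query '", query_id, "'")
  }
  # drop A3M insertion states (lowercase) — they are unaligned to the query
  aligned <- gsub("[a-z]", "", recs$seq)
  widths <- nchar(aligned)
  if (length(unique(widths)) != 1L) {
    stop("rows of ", msa_file, " disagree on aligned width after removing ",
         "insertion columns")
  }
  rows <- do.call(rbind, strsplit(aligned, "", fixed = TRUE))
  query_cols <- which(rows[1L, ] != "-" & rows[1L, ] != ".")
  if (length(query_cols) < 1L) stop("query has no residues in ", msa_file)
  sub <- rows[, query_cols, drop = FALSE]
  depth <- colSums(sub != "-" & sub != ".")
  msa_record(protein_id = recs$id[1L], n_rows = nrow(rows),
             depth_profile = depth)
}

# minimal FASTA text reader that preserves A3M case (Biostrings readers are
# used for sequence FASTA; alignments need the raw characters)
read_fasta_text <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not FASTA-formatted: ", path)
  idx <- cumsum(hdr)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste0, character(1),
                 collapse = "")
  list(id = ids, seq = unname(seqs))
}

#' Flag proteins with shallow alignments
#'
#' A protein is shallow when the median of its depth profile falls below
#' `depth_threshold`. The median (not the mean) is used so ragged alignment
#' ends do not dominate. Flagged proteins are recorded one id per line in
#' `shallow_MSA.txt`; their predictions are annotated as unreliable
#' downstream but are not removed.
#'
#' @param records list of [msa_record()] objects.
#' @param depth_threshold positive number of rows below which an alignment
#'   is too shallow for reliable co-evolutionary signal (default 100).
#' @param out_file optional path to write the flagged ids
#'   (`shallow_MSA.txt`); `NULL` skips writing.
#' @return character vector of flagged protein ids (sorted, unique).
#' @export
flag_shallow <- function(records, depth_threshold = 100, out_file = NULL) {
  stopifnot(depth_threshold > 0)
  med <- vapply(records, function(r) stats::median(r$depth_profile), numeric(1))
  ids <- vapply(records, `[[`, character(1), "protein_id")
  flagged <- sort(unique(ids[med < depth_threshold]))
  if (!is.null(out_file)) writeLines(flagged, out_file)
  flagged
}

#' Plot per-position MSA depth
#'
#' Draws depth against query position with the shallow threshold as a
#' horizontal line, and writes the underlying (position, depth) pairs as a
#' TSV sidecar next to the image so the figure is never the only record.
#'
#' @param record an [msa_record()].
#' @param out_path output image path (PNG).
#' @param depth_threshold threshold line to draw (default 100).
#' @return `out_path`, invisibly. The sidecar is `out_path` with a `.tsv`
#'   extension.
#' @export
plot_msa_depth <- function(record, out_path, depth_threshold = 100) {
  depth <- record$depth_profile
  tsv <- paste0(tools::file_path_sans_ext(out_path), ".tsv")
  utils::write.table(
    data.frame(position = seq_along(depth), depth = depth),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  grDevices::png(out_path, width = 900, height = 450)
  on.exit(grDevices::dev.off())
  graphics::plot(seq_along(depth), depth, type = "h", col = "steelblue",
                 xlab = "query position", ylab = "alignment depth (rows)",
                 main = paste0("MSA depth: ", record$protein_id),
                 ylim = c(0, max(depth, depth_threshold) * 1.05))
  graphics::abline(h = depth_threshold, col = "firebrick", lty = 2)
  invisible(out_path)
}
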