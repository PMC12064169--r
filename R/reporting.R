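# Report assembly: the iQ-score heatmap over all protein pairs, the
# interaction network with homo-oligomer self-annotations, and the bundle
# of figures/tables written at the end of a run. Every number shown on a
# figure is also present in a TSV sidecar; absent (unscored or gate-failed)
# cells are NA, never zero.

#' Build the iQ-score heatmap matrix
#'
#' Symmetric matrix over all proteins with the hetero iQ-score at (a, b)
#' and (b, a); the diagonal holds each protein's best hiQ-score when one
#' exists. Pairs that were never scored, or whose best model failed the PAE
#' gate, are `NA` — gate-failed is not scored-at-zero.
#'
#' @param interactions hetero table from [score_and_filter()].
#' @param homo_oligomers homo table from [score_and_filter()] (optional).
#' @param proteins character vector of all protein ids (must cover every id
#'   appearing in the scored tables).
#' @return numeric matrix with dimnames `proteins`.
#' @export
build_heatmap_matrix <- function(interactions, homo_oligomers = NULL,
                                 proteins) {
  proteins <- as.character(proteins)
  seen <- unique(c(interactions$protein_a, interactions$protein_b,
                   if (!is.null(homo_oligomers)) homo_oligomers$protein))
  unknown <- setdiff(seen, proteins)
  if (length(unknown)) {
    stop("scored pair references protein(s) absent from the protein list: ",
         paste(unknown, collapse = ", "))
  }
  m <- matrix(NA_real_, length(proteins), length(proteins),
              dimnames = list(proteins, proteins))
  for (i in seq_len(nrow(interactions))) {
    a <- interactions$protein_a[i]
    b <- interactions$protein_b[i]
    m[a, b] <- m[b, a] <- interactions$iq_score[i]
  }
  if (!is.null(homo_oligomers) && nrow(homo_oligomers)) {
    for (p in unique(homo_oligomers$protein)) {
      sub <- homo_oligomers[homo_oligomers$protein == p, , drop = FALSE]
      if (all(is.na(sub$hiq_score))) next
      m[p, p] <- max(sub$hiq_score, na.rm = TRUE)
    }
  }
  m
}

#' Build the interaction network
#'
#' Nodes are proteins with at least one retained hetero interaction, plus
#' proteins whose only retained result is a homo-oligomer (kept as isolated
#' nodes so self-association is not lost). Edges are undirected, weighted
#' by iQ-score; each node carries its best retained homo-oligomer
#' annotation (copy number of the highest hiQ-score) and its shallow-MSA
#' flag.
#'
#' @param retained_het retained hetero rows from [score_and_filter()].
#' @param retained_homo retained homo rows (optional).
#' @param shallow_ids protein ids flagged by [flag_shallow()].
#' @return an `igraph` graph with vertex attributes `hiq_score`,
#'   `hiq_copies`, `unreliable_msa` and edge attribute `iq_score`.
#' @export
build_network <- function(retained_het, retained_homo = NULL,
                          shallow_ids = character()) {
  retained_het <- retained_het[which(retained_het$retained), , drop = FALSE]
  if (!is.null(retained_homo)) {
    retained_homo <- retained_homo[which(retained_homo$retained), ,
                                   drop = FALSE]
  }
  nodes <- sort(unique(c(retained_het$protein_a, retained_het$protein_b,
                         retained_homo$protein)))
  edges <- retained_het[, c("protein_a", "protein_b")]
  g <- igraph::graph_from_data_frame(
    cbind(edges, iq_score = round(retained_het$iq_score, 2)),
    directed = FALSE,
    vertices = if (length(nodes)) data.frame(name = nodes) else NULL)
  hiq <- rep(NA_real_, length(nodes))
  copies <- rep(NA_integer_, length(nodes))
  if (!is.null(retained_homo) && nrow(retained_homo)) {
    for (p in unique(retained_homo$protein)) {
      sub <- retained_homo[retained_homo$protein == p, , drop = FALSE]
      best <- which.max(sub$hiq_score)
      i <- match(p, nodes)
      hiq[i] <- round(sub$hiq_score[best], 2)
      copies[i] <- sub$n_copies[best]
    }
  }
  igraph::V(g)$hiq_score <- hiq
  igraph::V(g)$hiq_copies <- copies
  igraph::V(g)$unreliable_msa <- nodes %in% shallow_ids
  g
}

#' Render the iQ-score heatmap
#'
#' Heat image of the pairwise composite-score matrix with `NA` cells left
#' blank (neutral background), plus a TSV sidecar of the matrix.
#'
#' @param heatmap matrix from [build_heatmap_matrix()].
#' @param out_path output PNG path; sidecar replaces the extension with
#'   `.tsv`.
#' @return `out_path`, invisibly.
#' @export
render_heatmap <- function(heatmap, out_path) {
  tsv <- paste0(tools::file_path_sans_ext(out_path), ".tsv")
  utils::write.table(heatmap, tsv, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  n <- nrow(heatmap)
  grDevices::png(out_path, width = 650, height = 650)
  on.exit(grDevices::dev.off())
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  graphics::image(seq_len(n), seq_len(n),
                  t(heatmap[n:1, , drop = FALSE]),
                  col = pal, zlim = c(0, 100), axes = FALSE,
                  xlab = "", ylab = "", main = "Composite interaction scores")
  graphics::axis(1, at = seq_len(n), labels = colnames(heatmap), las = 2)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(heatmap)), las = 2)
  graphics::box()
  invisible(out_path)
}

#' Render the interaction network figure
#'
#' Seeded force-directed layout (deterministic across reruns), edges
#' labeled with iQ-scores, retained homo-oligomers annotated on the node
#' label as `(xN, hiQ)`, shallow-MSA proteins drawn with a distinct
#' outline. Writes a GraphML file and a TSV edge list alongside the image.
#'
#' @param network graph from [build_network()].
#' @param out_path output PNG path; `.graphml` and `_edges.tsv` siblings
#'   are written next to it.
#' @param layout_seed RNG seed for the layout (default 42).
#' @return `out_path`, invisibly.
#' @export
render_network <- function(network, out_path, layout_seed = 42L) {
  base <- tools::file_path_sans_ext(out_path)
  igraph::write_graph(network, paste0(base, ".graphml"), format = "graphml")
  el <- igraph::as_data_frame(network, what = "edges")
  utils::write.table(el, paste0(base, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  grDevices::png(out_path, width = 750, height = 750)
  on.exit(grDevices::dev.off())
  if (igraph::vcount(network) == 0L) {
    graphics::plot.new()
    graphics::title(main = "Interaction network")
    graphics::text(0.5, 0.5, "no retained interactions")
  } else {
    set.seed(layout_seed)
    lay <- igraph::layout_with_fr(network)
    v <- igraph::V(network)
    lab <- v$name
    annotated <- !is.na(v$hiq_score)
    lab[annotated] <- sprintf("%s\n(x%d, hiQ %.2f)", lab[annotated],
                              v$hiq_copies[annotated], v$hiq_score[annotated])
    igraph::plot.igraph(
      network, layout = lay,
      vertex.label = lab, vertex.size = 28,
      vertex.color = "lightsteelblue",
      vertex.frame.color = ifelse(v$unreliable_msa, "firebrick", "grey30"),
      vertex.frame.width = ifelse(v$unreliable_msa, 3, 1),
      edge.label = sprintf("%.2f", igraph::E(network)$iq_score),
      edge.width = 2)
    graphics::title(main = "Interaction network (edge: iQ, node: hiQ)")
    if (any(v$unreliable_msa)) {
      graphics::mtext("red outline: shallow MSA, prediction unreliable",
                      side = 1, col = "firebrick")
    }
  }
  invisible(out_path)
}

#' Assemble the full report bundle
#'
#' Writes, under `out_dir`: the scored tables (see
#' [write_scored_tables()]), the heatmap figure + TSV, the network figure +
#' GraphML + edge list, a per-retained-interaction distogram and contact
#' table (when the best model's structure is available), and a JSON run
#' manifest recording configuration, thresholds, package version and input
#' checksums. With an empty retained set the bundle still appears, with
#' empty tables and a clear note.
#'
#' @param scored result of [score_and_filter()].
#' @param best_models named list of best models (for structures), may be
#'   `NULL`.
#' @param proteins character vector of all protein ids.
#' @param out_dir output directory.
#' @param shallow_ids shallow-MSA protein ids.
#' @param config named list of run settings recorded in the manifest.
#' @param input_files character vector of input paths to checksum.
#' @param all_structures also render distograms for non-retained jobs.
#' @param contact_cutoff_A interface contact cutoff (default 8).
#' @param atom_mode distance mode, see [compute_distance_matrix()].
#' @return path of the manifest JSON, invisibly.
#' @export
render_report <- function(scored, best_models = NULL, proteins, out_dir,
                          shallow_ids = character(), config = list(),
                          input_files = character(),
                          all_structures = FALSE,
                          contact_cutoff_A = 8.0, atom_mode = "CB") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_scored_tables(scored, out_dir)
  het <- scored$interactions
  hom <- scored$homo_oligomers
  heat <- build_heatmap_matrix(het, hom, proteins)
  render_heatmap(heat, file.path(out_dir, "heatmap.png"))
  net <- build_network(het, hom, shallow_ids)
  render_network(net, file.path(out_dir, "network.png"))
  if (!any(het$retained) && !any(hom$retained)) {
    writeLines("no retained interactions at the configured cutoffs",
               file.path(out_dir, "NO_RETAINED_INTERACTIONS.txt"))
  }
  # distograms + contact tables for retained jobs with a structure
  fig_dir <- file.path(out_dir, "interfaces")
  wanted <- c(het$job_id[if (all_structures) TRUE else het$retained],
              hom$job_id[if (all_structures) TRUE else hom$retained])
  for (job_id in wanted) {
    model <- best_models[[job_id]]
    if (is.null(model) || is.na(model$structure_path)) next
    dir.create(fig_dir, showWarnings = FALSE)
    dm <- compute_distance_matrix(read_structure(model$structure_path),
                                  atom_mode)
    stem <- file.path(fig_dir, job_dir_name(job_id))
    render_distogram(dm, paste0(stem, "_distogram.png"))
    utils::write.table(interface_contacts(dm, contact_cutoff_A),
                       paste0(stem, "_contacts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    package = "ppiscorekit",
    version = as.character(utils::packageVersion("ppiscorekit")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    shallow_msa_proteins = as.list(shallow_ids),
    n_proteins = length(proteins),
    n_retained_interactions = sum(het$retained),
    n_retained_homo_oligomers = sum(hom$retained),
    input_checksums = as.list(tools::md5sum(
      input_files[file.exists(input_files)])))
  manifest_path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest_path)
}
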