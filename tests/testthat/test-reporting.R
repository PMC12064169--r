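# Heatmap matrix, network construction and the report bundle.

scored_fixture <- local({
  het <- data.frame(
    job_id = c("A;B", "A;C", "B;C", "C;D"),
    protein_a = c("A", "A", "B", "C"), protein_b = c("B", "C", "C", "D"),
    pi_score = c(1.0, 0.2, -1.0, 0.1), iptm = 0.8,
    iptm_ptm = c(0.8, 0.6, 0.4, 0.5), pdockq = c(0.7, 0.6, 0.2, 0.5),
    min_interchain_pae = c(4, 5, 15, 6),
    pae_gate_passed = c(TRUE, TRUE, FALSE, TRUE),
    iq_score = c(72.60, 53.53, NA, 50.76),
    retained = c(TRUE, TRUE, FALSE, TRUE),
    unreliable_msa = FALSE, reason = "", stringsAsFactors = FALSE)
  hom <- data.frame(
    job_id = c("E,2", "A,2"), protein = c("E", "A"),
    n_copies = 2L, n_interfaces = 1L, mean_interface_pi = c(0.5, -1),
    iptm = 0.7, iptm_ptm = c(0.65, 0.3), min_interchain_pae = 4,
    pae_gate_passed = TRUE, hiq_score = c(61.70, 30.60),
    retained = c(TRUE, FALSE), unreliable_msa = FALSE, reason = "",
    stringsAsFactors = FALSE)
  list(interactions = het, homo_oligomers = hom)
})

test_that("heatmap matrix is symmetric with hiQ diagonal and NA absences", {
  m <- build_heatmap_matrix(scored_fixture$interactions,
                            scored_fixture$homo_oligomers,
                            proteins = c("A", "B", "C", "D", "E"))
  expect_equal(m, t(m))
  expect_equal(m["A", "B"], 72.60)
  expect_equal(m["B", "A"], 72.60)
  # gate-failed pair carries NA, not zero
  expect_true(is.na(m["B", "C"]))
  # never-scored pair is NA too
  expect_true(is.na(m["A", "D"]))
  # diagonal: best hiQ where available
  expect_equal(m["E", "E"], 61.70)
  expect_equal(m["A", "A"], 30.60)
  expect_true(is.na(m["B", "B"]))
  expect_error(build_heatmap_matrix(scored_fixture$interactions, NULL,
                                    proteins = c("A", "B")), "unknown|absent")
})

test_that("heatmap of a single scored pair places the score off-diagonal", {
  het <- scored_fixture$interactions[1, , drop = FALSE]
  m <- build_heatmap_matrix(het, NULL, proteins = c("A", "B"))
  expect_equal(m["A", "B"], 72.60)
  expect_equal(m["B", "A"], 72.60)
  expect_true(all(is.na(diag(m))))
  # no scored pairs: all-absent matrix
  m0 <- build_heatmap_matrix(het[0, ], NULL, proteins = c("A", "B"))
  expect_true(all(is.na(m0)))
})

test_that("network has retained edges only, with self-annotations", {
  g <- build_network(scored_fixture$interactions,
                     scored_fixture$homo_oligomers, shallow_ids = "C")
  expect_setequal(igraph::V(g)$name, c("A", "B", "C", "D", "E"))
  expect_equal(igraph::ecount(g), 3L)  # B;C not retained
  # degree equals the count of retained pairs containing each protein
  deg <- igraph::degree(g)
  expect_equal(unname(deg[c("A", "B", "C", "D", "E")]), c(2, 1, 2, 1, 0))
  # every edge weight is the retained iQ-score
  expect_setequal(igraph::E(g)$iq_score, c(72.60, 53.53, 50.76))
  # homo-only protein E is an isolated node with its annotation
  vE <- igraph::V(g)[["E"]]
  expect_equal(igraph::V(g)$hiq_score[match("E", igraph::V(g)$name)], 61.70)
  expect_equal(igraph::V(g)$hiq_copies[match("E", igraph::V(g)$name)], 2L)
  # rejected homo-oligomer of A is not annotated
  expect_true(is.na(igraph::V(g)$hiq_score[match("A", igraph::V(g)$name)]))
  expect_true(igraph::V(g)$unreliable_msa[match("C", igraph::V(g)$name)])

  empty <- build_network(scored_fixture$interactions[0, ])
  expect_equal(igraph::vcount(empty), 0L)
})

test_that("cohort network recovers the designed component structure", {
  sj <- score_jobs(file.path(cohort_dir, "models"),
                   shallow_ids = cohort_manifest$expected_shallow)
  g <- build_network(sj$scored$interactions, sj$scored$homo_oligomers,
                     cohort_manifest$expected_shallow)
  comp <- igraph::components(g)
  expect_setequal(comp$csize, c(3L, 2L, 1L))
})

test_that("report bundle contains figures, sidecars and a faithful manifest", {
  out <- file.path(tempdir(), "report-test")
  unlink(out, recursive = TRUE)
  sj <- score_jobs(file.path(cohort_dir, "models"),
                   shallow_ids = cohort_manifest$expected_shallow)
  cfg <- list(iq_cutoff = 50, pae_threshold = 10)
  manifest_path <- render_report(
    sj$scored, sj$best_models,
    proteins = cohort_manifest$proteins$id, out_dir = out,
    shallow_ids = cohort_manifest$expected_shallow, config = cfg,
    input_files = file.path(cohort_dir, "proteins.fasta"))
  for (f in c("predictions_scored.tsv", "retained_interactions.tsv",
              "retained_homooligomers.tsv", "heatmap.png", "heatmap.tsv",
              "network.png", "network.graphml", "network_edges.tsv",
              "run_manifest.json")) {
    expect_true(file.exists(file.path(out, f)), info = f)
  }
  man <- jsonlite::fromJSON(manifest_path)
  expect_equal(man$config$iq_cutoff, 50)
  expect_equal(man$config$pae_threshold, 10)
  expect_equal(man$n_retained_interactions +
                 man$n_retained_homo_oligomers,
               length(cohort_manifest$expected_retained))
  # per-retained-interaction distograms and contact tables
  ret <- sj$scored$interactions
  for (job in ret$job_id[ret$retained]) {
    stem <- file.path(out, "interfaces", gsub("[;,]", "_and_", job))
    expect_true(file.exists(paste0(stem, "_distogram.png")), info = job)
    expect_true(file.exists(paste0(stem, "_contacts.tsv")), info = job)
  }
  # heatmap sidecar is the single source of truth for the figure
  side <- as.matrix(utils::read.table(file.path(out, "heatmap.tsv"),
                                      header = TRUE, row.names = 1,
                                      sep = "\t", check.names = FALSE))
  hm <- build_heatmap_matrix(sj$scored$interactions,
                             sj$scored$homo_oligomers,
                             cohort_manifest$proteins$id)
  expect_equal(side, hm, tolerance = 1e-6)
  # edge list equals the retained set with 2-dp scores
  edges <- utils::read.table(file.path(out, "network_edges.tsv"),
                             header = TRUE, sep = "\t")
  expect_setequal(edges$iq_score, round(ret$iq_score[ret$retained], 2))
})

test_that("an empty retained set still yields a bundle with a clear note", {
  out <- file.path(tempdir(), "report-empty")
  unlink(out, recursive = TRUE)
  scored <- list(interactions = scored_fixture$interactions[0, ],
                 homo_oligomers = scored_fixture$homo_oligomers[0, ])
  render_report(scored, NULL, proteins = c("A", "B"), out_dir = out)
  expect_true(file.exists(file.path(out, "NO_RETAINED_INTERACTIONS.txt")))
  ret <- utils::read.table(file.path(out, "retained_interactions.tsv"),
                           header = TRUE, sep = "\t")
  expect_equal(nrow(ret), 0L)
})

test_that("report TSV sidecars are byte-identical across reruns", {
  sj <- score_jobs(file.path(cohort_dir, "models"))
  outs <- character(2)
  for (i in 1:2) {
    out <- file.path(tempdir(), paste0("report-rerun", i))
    unlink(out, recursive = TRUE)
    render_report(sj$scored, sj$best_models,
                  proteins = cohort_manifest$proteins$id, out_dir = out)
    outs[i] <- out
  }
  for (f in c("heatmap.tsv", "network_edges.tsv",
              "predictions_scored.tsv", "retained_interactions.tsv")) {
    expect_identical(readLines(file.path(outs[1], f)),
                     readLines(file.path(outs[2], f)), info = f)
  }
})
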