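# Distance matrices and interface contacts against constructed geometry
# and the cohort generator's planted contacts.

# two chains x three residues with CA/CB at chosen positions
write_two_chain_pdb <- function(cb_a, cb_b, path = tempfile(fileext = ".pdb")) {
  fmt <- paste0("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f",
                "%6.2f%6.2f          %2s")
  lines <- character()
  s <- 0L
  for (ch in list(A = cb_a, B = cb_b)) {
    chain <- if (identical(ch, cb_a)) "A" else "B"
    for (r in seq_len(nrow(ch))) {
      for (at in c("CA", "CB")) {
        s <- s + 1L
        off <- if (at == "CA") c(0, 0, 1.5) else c(0, 0, 0)
        xyz <- ch[r, ] + off
        lines <- c(lines, sprintf(fmt, s, at, "ALA", chain, r,
                                  xyz[1], xyz[2], xyz[3], 1, 0,
                                  substr(at, 1, 1)))
      }
    }
    lines <- c(lines, "TER")
  }
  writeLines(c(lines, "END"), path)
  path
}

test_that("distances follow the 3-4-5 triangle and matrix invariants", {
  p <- write_two_chain_pdb(rbind(c(0, 0, 0)), rbind(c(3, 4, 0)))
  dm <- compute_distance_matrix(read_structure(p), atom_mode = "CB")
  expect_equal(dim(dm$values), c(2L, 2L))
  expect_equal(dm$values[1, 2], 5.0, tolerance = 1e-9)
  expect_equal(dm$values, t(dm$values))
  expect_equal(diag(dm$values), c(0, 0))
})

test_that("CB mode falls back to CA for glycine and min-heavy lower-bounds CA", {
  # glycine has no CB: write CA-only glycine next to an alanine
  fmt <- paste0("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f",
                "%6.2f%6.2f          %2s")
  p <- write_lines_tmp(c(
    sprintf(fmt, 1, "CA", "GLY", "A", 1, 0, 0, 0, 1, 0, "C"),
    sprintf(fmt, 2, "CA", "ALA", "B", 1, 6, 0, 0, 1, 0, "C"),
    sprintf(fmt, 3, "CB", "ALA", "B", 1, 5, 0, 0, 1, 0, "C"),
    "END"), ".pdb")
  st <- read_structure(p)
  cb <- compute_distance_matrix(st, "CB")
  ca <- compute_distance_matrix(st, "CA")
  mh <- compute_distance_matrix(st, "min-heavy")
  expect_equal(cb$values[1, 2], 5.0)   # GLY CA -> ALA CB
  expect_equal(ca$values[1, 2], 6.0)
  expect_true(all(mh$values <= ca$values + 1e-9))
  expect_true(all(mh$values <= cb$values + 1e-9))
})

test_that("missing representative atom without fallback is an error", {
  fmt <- paste0("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f",
                "%6.2f%6.2f          %2s")
  p <- write_lines_tmp(c(
    sprintf(fmt, 1, "N", "ALA", "A", 1, 0, 0, 0, 1, 0, "N"),
    "END"), ".pdb")
  expect_error(compute_distance_matrix(read_structure(p), "CB"), "A:1")
})

test_that("interface contacts find planted pairs, monotone in cutoff", {
  cb_a <- rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0))
  cb_b <- rbind(c(0, 4, 0), c(10, 30, 0), c(20, 30, 0))
  dm <- compute_distance_matrix(read_structure(
    write_two_chain_pdb(cb_a, cb_b)), "CB")
  hits <- interface_contacts(dm, 8)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$chain_a, "A")
  expect_equal(hits$resno_a, 1L)
  expect_equal(hits$resno_b, 1L)
  expect_equal(hits$distance_A, 4.0, tolerance = 1e-9)
  # cutoff 0 gives nothing
  expect_equal(nrow(interface_contacts(dm, 0)), 0L)
  # monotone in cutoff
  prev <- 0L
  for (cut in c(2, 4.5, 25, 50)) {
    cur <- nrow(interface_contacts(dm, cut))
    expect_gte(cur, prev)
    prev <- cur
  }
  # single chain warns and returns nothing
  one <- compute_distance_matrix(read_structure(write_lines_tmp(c(
    sprintf(paste0("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f",
                   "%6.2f%6.2f          %2s"),
            1, "CB", "ALA", "A", 1, 0, 0, 0, 1, 0, "C"), "END"), ".pdb")))
  expect_warning(empty <- interface_contacts(one, 8), "single-chain")
  expect_equal(nrow(empty), 0L)
})

test_that("cohort structures recover planted contacts against brute force", {
  jobs <- names(cohort_manifest$planted_contacts)
  for (job in jobs) {
    jd <- file.path(cohort_dir, "models", gsub("[;,]", "_and_", job))
    dm <- compute_distance_matrix(read_structure(
      file.path(jd, "model_1.pdb")), "CB")
    expect_equal(dm$values, t(dm$values), tolerance = 1e-6)
    expect_true(all(abs(diag(dm$values)) < 1e-9))
    hits <- interface_contacts(dm, 8)
    planted <- cohort_manifest$planted_contacts[[job]]
    expect_equal(nrow(hits), nrow(planted), info = job)
    expect_setequal(hits$resno_a, planted$res_a)
    expect_setequal(hits$resno_b, planted$res_b)
    # distances equal the generator's analytic values
    expect_equal(sort(hits$distance_A), sort(planted$distance),
                 tolerance = 1e-6, info = job)
    # full agreement with the O(n^2) oracle
    oracle <- brute_contacts(dm, 8)
    expect_equal(hits[, c("chain_a", "resno_a", "chain_b", "resno_b",
                          "distance_A")],
                 oracle, ignore_attr = TRUE, info = job)
  }
})

test_that("contact lists are invariant to chain labeling order", {
  cb_a <- rbind(c(0, 0, 0), c(10, 0, 0))
  cb_b <- rbind(c(0, 5, 0), c(10, 40, 0))
  d1 <- compute_distance_matrix(read_structure(
    write_two_chain_pdb(cb_a, cb_b)), "CB")
  d2 <- compute_distance_matrix(read_structure(
    write_two_chain_pdb(cb_b, cb_a)), "CB")
  h1 <- interface_contacts(d1, 8)
  h2 <- interface_contacts(d2, 8)
  # chains are reported lexicographically, so the record sets coincide up
  # to which physical chain got which label
  expect_equal(nrow(h1), nrow(h2))
  expect_equal(h1$distance_A, h2$distance_A, tolerance = 1e-9)
  expect_equal(sort(c(h1$resno_a, h1$resno_b)),
               sort(c(h2$resno_a, h2$resno_b)))
})

test_that("distogram renders with a TSV sidecar equal to the matrix", {
  jd <- list.dirs(file.path(cohort_dir, "models"), recursive = FALSE)[1L]
  dm <- compute_distance_matrix(read_structure(
    file.path(jd, "model_1.pdb")), "CB")
  img <- tempfile(fileext = ".png")
  render_distogram(dm, img)
  expect_true(file.exists(img))
  side <- as.matrix(utils::read.table(sub("\\.png$", ".tsv", img)))
  dimnames(side) <- NULL
  expect_equal(side, dm$values, tolerance = 1e-6)
})
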