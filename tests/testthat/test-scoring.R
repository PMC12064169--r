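# Composite scores, best-model selection, PAE gate and retention.

test_that("iQ-score matches hand evaluation and respects its bounds", {
  expect_equal(compute_iq_score(1.0, 0.8, 0.7),
               ((1.0 + 2.63) / 5.26) * 40 + 0.8 * 30 + 0.7 * 30,
               tolerance = 1e-9)
  expect_equal(round(compute_iq_score(1.0, 0.8, 0.7), 2), 72.60)
  expect_equal(compute_iq_score(-2.63, 0, 0), 0)
  expect_equal(compute_iq_score(2.63, 1, 1), 100)
  expect_warning(clamped <- compute_iq_score(10, 0.5, 0.5), "clamped")
  expect_equal(clamped, compute_iq_score(2.63, 0.5, 0.5))
  expect_error(compute_iq_score(0, 1.2, 0.5), "iptm_ptm")
  expect_error(compute_iq_score(0, 0.5, -0.1), "pdockq")
})

test_that("hiQ-score averages interface pi-scores and respects its bounds", {
  expect_equal(compute_hiq_score(c(-2.63, -2.63), 0), 0)
  expect_equal(compute_hiq_score(2.63, 1), 100)
  # mean invariance: n identical interface scores equal a single one
  for (x in c(-1.5, 0.05, 2.0)) {
    expect_equal(compute_hiq_score(rep(x, 4), 0.6),
                 compute_hiq_score(x, 0.6), tolerance = 1e-12)
  }
  expect_equal(compute_hiq_score(c(0.2, 0.6), 0.5),
               oracle_hiq_test(c(0.2, 0.6), 0.5), tolerance = 1e-9)
  expect_error(compute_hiq_score(numeric(), 0.5), "at least one")
})

test_that("composite scores are strictly increasing in every argument", {
  set.seed(11)
  for (k in 1:200) {
    pi <- stats::runif(1, -2.63, 2.53)
    t1 <- stats::runif(1, 0, 0.9)
    t2 <- stats::runif(1, 0, 0.9)
    eps <- 0.05
    base <- compute_iq_score(pi, t1, t2)
    expect_gt(compute_iq_score(pi + eps, t1, t2), base)
    expect_gt(compute_iq_score(pi, t1 + eps, t2), base)
    expect_gt(compute_iq_score(pi, t1, t2 + eps), base)
    hbase <- compute_hiq_score(pi, t1)
    expect_gt(compute_hiq_score(pi + eps, t1), hbase)
    expect_gt(compute_hiq_score(pi, t1 + eps), hbase)
  }
})

test_that("composite scores stay in [0, 100] over random clamped inputs", {
  set.seed(42)
  n <- 10000L
  iq <- compute_iq_score(stats::runif(n, -2.63, 2.63),
                         stats::runif(n), stats::runif(n))
  expect_true(all(iq >= 0 & iq <= 100))
  hiq <- vapply(seq_len(n), function(i)
    compute_hiq_score(stats::runif(sample(1:4, 1), -2.63, 2.63),
                      stats::runif(1)), numeric(1))
  expect_true(all(hiq >= 0 & hiq <= 100))
})

test_that("best-model selection maximizes ipTM with deterministic ties", {
  mk <- function(idx, iptm) model_result("A;B", idx, iptm, iptm)
  expect_equal(select_best_model(list(mk(1, 0.3), mk(2, 0.9),
                                      mk(3, 0.5)))$model_index, 2L)
  expect_equal(select_best_model(list(mk(1, 0.7)))$model_index, 1L)
  expect_equal(select_best_model(list(mk(1, 0.7), mk(2, 0.7)))$model_index, 1L)
  expect_equal(select_best_model(list(mk(2, 0.7), mk(1, 0.7)))$model_index, 1L)
  expect_error(select_best_model(list()), "no models")
})

test_that("PAE gate aggregates inter-chain cells only", {
  # all-zero PAE passes with minimum 0
  z <- make_pae_model(matrix(0, 4, 4), 2L, 2L)
  expect_true(pae_gate(z)$passed)
  expect_equal(pae_gate(z)$min_interchain_pae, 0)

  # inter-chain uniformly 30, intra 5: fails with min 30
  pae <- matrix(5, 6, 6)
  pae[1:3, 4:6] <- 30
  pae[4:6, 1:3] <- 30
  diag(pae) <- 0
  g <- pae_gate(make_pae_model(pae, 3L, 3L))
  expect_false(g$passed)
  expect_equal(g$min_interchain_pae, 30)

  # one inter-chain cell at 7.5 amid 20s passes at 7.5
  pae2 <- matrix(20, 5, 5)
  diag(pae2) <- 0
  pae2[2, 4] <- 7.5
  g2 <- pae_gate(make_pae_model(pae2, 2L, 3L))
  expect_true(g2$passed)
  expect_equal(g2$min_interchain_pae, 7.5)

  single <- model_result("A,2", 1, 0.5, 0.5, pae = matrix(0, 3, 3),
                         chain_ranges = list(A = c(0L, 3L)))
  expect_error(pae_gate(single), "single-chain")
})

test_that("PAE gate agrees with a brute-force per-cell scan on random matrices", {
  set.seed(23)
  for (k in 1:40) {
    la <- sample(2:6, 1)
    lb <- sample(2:6, 1)
    n <- la + lb
    # inter-chain values straddle the 10-Angstrom threshold
    pae <- matrix(stats::runif(n * n, 0, 25), n, n)
    diag(pae) <- 0
    g <- pae_gate(make_pae_model(pae, la, lb))
    oracle <- brute_min_interchain_pae(pae, la)
    expect_equal(g$min_interchain_pae, oracle)
    expect_equal(g$passed, oracle <= 10)
  }
})

test_that("alternative PAE statistics are available for sensitivity analysis", {
  pae <- matrix(5, 4, 4)
  pae[1:2, 3:4] <- c(2, 12, 14, 20)
  pae[3:4, 1:2] <- 30
  diag(pae) <- 0
  m <- make_pae_model(pae, 2L, 2L)
  inter <- c(pae[1:2, 3:4], pae[3:4, 1:2])
  expect_equal(pae_gate(m, stat = "median")$min_interchain_pae,
               stats::median(inter))
  expect_equal(pae_gate(m, stat = "mean")$min_interchain_pae, mean(inter))
})

test_that("score_and_filter applies gate, cutoff and shallow annotation", {
  pae_ok <- matrix(c(0, 3, 4, 3, 0, 25, 4, 25, 0), 3, 3)
  pae_bad <- matrix(15, 3, 3); diag(pae_bad) <- 0
  best <- list(
    "A;B" = make_pae_model(pae_ok, 1L, 2L, "A;B"),
    "A;C" = make_pae_model(pae_bad, 1L, 2L, "A;C"),
    "C,2" = make_pae_model(pae_ok, 1L, 2L, "C,2"))
  tab <- data.frame(
    job_id = c("A;B", "A;C", "C,2"), model_index = 1L,
    iptm = 0.8, iptm_ptm = c(0.8, 0.9, 0.65),
    pi_score = c(1.0, 2.0, 0.5), pdockq = c(0.7, 0.9, NA))
  res <- score_and_filter(best, tab, shallow_ids = "C")
  het <- res$interactions
  expect_equal(het$iq_score[het$job_id == "A;B"],
               oracle_iq_test(1.0, 0.8, 0.7), tolerance = 1e-9)
  expect_true(het$retained[het$job_id == "A;B"])
  # gate failure: no composite, a reason, not retained
  bad <- het[het$job_id == "A;C", ]
  expect_false(bad$retained)
  expect_true(is.na(bad$iq_score))
  expect_match(bad$reason, "PAE gate")
  # shallow protein annotated, not dropped
  expect_true(bad$unreliable_msa)
  hom <- res$homo_oligomers
  expect_equal(hom$hiq_score, oracle_hiq_test(0.5, 0.65), tolerance = 1e-9)
  expect_true(hom$retained)
  expect_true(hom$unreliable_msa)
})

test_that("pdockq is mandatory for hetero jobs", {
  pae <- matrix(0, 2, 2)
  best <- list("A;B" = make_pae_model(pae, 1L, 1L, "A;B"))
  tab <- data.frame(job_id = "A;B", model_index = 1L, iptm = 0.8,
                    iptm_ptm = 0.8, pi_score = 0.5, pdockq = NA_real_)
  expect_error(score_and_filter(best, tab), "pdockq")
})

test_that("retention is monotone in the cutoff and matches brute force", {
  set.seed(31)
  n_jobs <- 300L
  pae_ok <- matrix(c(0, 4, 4, 0), 2, 2)
  best <- list()
  tabs <- list()
  for (i in seq_len(n_jobs)) {
    id <- sprintf("L%03d;R%03d", i, i)
    gate_bad <- i %% 7L == 0L
    pae <- if (gate_bad) matrix(c(0, 18, 18, 0), 2, 2) else pae_ok
    best[[id]] <- make_pae_model(pae, 1L, 1L, id)
    tabs[[i]] <- data.frame(job_id = id, model_index = 1L, iptm = 0.8,
                            iptm_ptm = stats::runif(1),
                            pi_score = stats::runif(1, -2.63, 2.63),
                            pdockq = stats::runif(1))
  }
  tab <- do.call(rbind, tabs)
  res50 <- score_and_filter(best, tab, iq_cutoff = 50)$interactions
  # brute-force re-evaluation of formula + gate + cutoff per record
  expected <- vapply(seq_len(n_jobs), function(i) {
    r <- tab[i, ]
    gate_bad <- i %% 7L == 0L
    !gate_bad && oracle_iq_test(r$pi_score, r$iptm_ptm, r$pdockq) > 50
  }, logical(1))
  expect_equal(sort(res50$job_id[res50$retained]),
               sort(tab$job_id[expected]))
  # raising the cutoff never adds a retained interaction
  prev <- res50$job_id[res50$retained]
  for (cut in c(60, 70, 85)) {
    cur <- score_and_filter(best, tab, iq_cutoff = cut)$interactions
    cur <- cur$job_id[cur$retained]
    expect_true(all(cur %in% prev), info = paste("cutoff", cut))
    prev <- cur
  }
  # retained rows come first, sorted by composite descending
  ret <- res50[res50$retained, ]
  expect_false(is.unsorted(rev(ret$iq_score)))
})
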