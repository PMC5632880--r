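test_that("CPM normalization is exact arithmetic and honours declared library sizes", {
  m <- matrix(c(100, 0, 0, 0, 50, 0), nrow = 3,
              dimnames = list(paste0("mmu-miR-sim-", 1:3), c("a", "b")))
  se <- MitomirExperiment(m, c("mitochondrial", "total"), c("sham", "tac4w"),
                          library_size = c(1e6, 2e6))
  cpm <- cpmNormalize(se)
  expect_equal(cpm["mmu-miR-sim-1", "a"], 100)
  expect_equal(cpm[, "b"], c(`mmu-miR-sim-1` = 0, `mmu-miR-sim-2` = 25,
                             `mmu-miR-sim-3` = 0))
  # random table: column sums are 1e6 * colsum / library_size
  set.seed(10)
  m2 <- matrix(rpois(15, 30), 5, 3)
  rownames(m2) <- paste0("m", 1:5); colnames(m2) <- paste0("l", 1:3)
  ls <- c(500, 1000, 2000)
  cpm2 <- cpmNormalize(m2, ls)
  expect_equal(colSums(cpm2), 1e6 * colSums(m2) / ls)
  expect_error(cpmNormalize(m2, c(0, 1, 1)), "positive")
})

test_that("exact conditional binomial test matches enumeration and binom.test", {
  # no information: both counts zero
  expect_equal(exactPoissonTest(0, 0, 1e6, 3e6), 1)
  # frozen enumeration value: P(0) + P(10) under Binomial(10, 1/2)
  expect_equal(exactPoissonTest(10, 0, 1e6, 1e6), 2 / 2^10,
               tolerance = 1e-12)
  # equivalence with two independent oracles over a sampled grid, n <= 50
  set.seed(1)
  for (ratio in c(1, 2, 5)) {
    n1 <- 1e6; n2 <- ratio * 1e6
    prob <- n1 / (n1 + n2)
    for (rep in 1:60) {
      n <- sample(0:50, 1)
      x1 <- if (n > 0) sample(0:n, 1) else 0
      p <- exactPoissonTest(x1, n - x1, n1, n2)
      expect_equal(p, binomTwoSidedEnum(x1, n, prob), tolerance = 1e-12)
      if (n > 0)
        expect_equal(p, stats::binom.test(x1, n, prob)$p.value,
                     tolerance = 1e-12)
    }
  }
})

test_that("exact test is symmetric under swapping the two libraries", {
  set.seed(2)
  for (i in 1:200) {
    x1 <- rpois(1, 15); x2 <- rpois(1, 15)
    n1 <- sample(c(1e6, 2e6, 5e6), 1); n2 <- sample(c(1e6, 2e6, 5e6), 1)
    expect_equal(exactPoissonTest(x1, x2, n1, n2),
                 exactPoissonTest(x2, x1, n2, n1), tolerance = 1e-12)
  }
  expect_error(exactPoissonTest(-1, 0, 1, 1), "negative")
  expect_error(exactPoissonTest(1, 0, 0, 1), "positive")
})

test_that("doubled-tail alternative is a valid p-value and agrees at symmetric extremes", {
  expect_equal(exactPoissonTest(10, 0, 1e6, 1e6, method = "doubled"),
               2 / 2^10, tolerance = 1e-12)
  set.seed(3)
  p <- exactPoissonTest(rpois(50, 10), rpois(50, 10), 1e6, 1e6,
                        method = "doubled")
  expect_true(all(p >= 0 & p <= 1))
})

test_that("log2 fold change uses pseudo-CPM and is antisymmetric", {
  expect_equal(log2FoldChange(10, 10, 1e6, 1e6, 0), 0)
  expect_equal(log2FoldChange(5, 20, 1e6, 1e6, 0), 2)
  expect_equal(log2FoldChange(5, 40, 1e6, 1e6, 0.5), log2(40.5 / 5.5),
               tolerance = 1e-12)
  expect_equal(log2(40.5 / 5.5), 2.8805, tolerance = 1e-4)
  # double zero is missing, never infinite
  expect_true(is.na(log2FoldChange(0, 0, 1e6, 1e6, 0)))
  expect_true(is.finite(log2FoldChange(0, 10, 1e6, 1e6, 0.5)))
  set.seed(4)
  for (i in 1:200) {
    x1 <- rpois(1, 20); x2 <- rpois(1, 20)
    n1 <- sample(c(1e6, 3e6), 1); n2 <- sample(c(1e6, 3e6), 1)
    a <- log2FoldChange(x1, x2, n1, n2)
    b <- log2FoldChange(x2, x1, n2, n1)
    expect_equal(a, -b, tolerance = 1e-12)
  }
})

test_that("BH adjustment equals the step-up definition and keeps its invariants", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bhFdr(0.2), 0.2)
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
  expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(5)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))
    q <- bhFdr(p)
    expect_equal(q, bhStepUp(p), tolerance = 1e-12)
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))   # non-decreasing along sorted p
    expect_true(all(q >= p - 1e-12))         # q >= p elementwise
  }
})

test_that("DE calls reproduce the reference TAC profile filter counts and use strict thresholds", {
  ref <- referenceDeTable()
  w4 <- callDE(ref[ref$comparison == "sham_vs_tac4w", ])
  w8 <- callDE(ref[ref$comparison == "sham_vs_tac8w", ])
  expect_equal(sum(w4$call == "down"), 2)
  expect_equal(sum(w4$call == "up"), 11)
  expect_equal(sum(w8$call == "down"), 6)
  # one 8-week row sits above the fold threshold but fails p < 0.05
  expect_equal(w8$call[w8$mirna == "mmu-miR-28a-3p"], "ns")
  # boundary convention: log2 fc exactly 1 with fc_up = 2 stays ns
  bnd <- data.frame(mirna = "x", log2_fc = 1, p_value = 0.001)
  expect_equal(callDE(bnd)$call, "ns")
  expect_error(callDE(bnd, fc_up = 0.8), "fc_up")
  expect_error(callDE(bnd, fc_down = 1.5), "fc_down")
})

test_that("pairwise profiles test detected miRNAs only and find planted fold changes", {
  # two identical libraries: everything ns at p = 1
  m <- matrix(c(5, 0, 80, 5, 0, 80), ncol = 2,
              dimnames = list(paste0("mmu-miR-sim-", 1:3), c("a", "b")))
  se <- MitomirExperiment(m, rep("mitochondrial", 2), c("sham", "tac4w"))
  prof <- pairwiseProfile(se)[["sham_vs_tac4w"]]
  expect_false("mmu-miR-sim-2" %in% prof$mirna)  # zero in both: filtered
  expect_true(all(prof$p_value == 1))
  expect_true(all(prof$call == "ns"))
  # planted 8-fold mitochondrial changes at 2e6 depth are recovered
  hits <- vapply(1:20, function(s) {
    cfg <- SimulationConfig(mitomir_indices = 1:20, mito_log2_effect = c(3, 1),
                            contamination = 0, seed = 1000 + s)
    sim <- simulateCounts(cfg)
    de <- pairwiseProfile(sim$experiment,
                          pairs = list(c("sham", "tac4w")))[[1]]
    planted <- rownames(trueAbundance(sim$truth))[isMitomir(sim$truth)]
    sum(de$call[de$mirna %in% planted] == "up")
  }, numeric(1))
  expect_true(all(hits >= 18))
  expect_error(pairwiseProfile(se, pairs = list(c("sham", "tac8w"))),
               "exactly one library")
})

test_that("hierarchical clustering follows the 1 - Pearson / average-linkage convention", {
  # identical rows merge first at height 0
  m <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 1, 3, 0))
  cl <- hierarchicalCluster(m)
  expect_equal(min(cl$tree$height), 0)
  ord <- cl$order
  expect_equal(abs(diff(match(1:2, ord))), 1)  # a and b adjacent
  # correlated pair groups together, anti-correlated row apart
  m2 <- rbind(r1 = c(1, 2, 3), r2 = c(2, 4.1, 5.9), r3 = c(3, 2, 1))
  ord2 <- hierarchicalCluster(m2)$order
  expect_equal(abs(diff(match(1:2, ord2))), 1)
  # heights match a brute-force UPGMA recomputation on a random matrix
  set.seed(6)
  m3 <- matrix(rnorm(60), 10, 6)
  rownames(m3) <- paste0("m", 1:10)
  cl3 <- hierarchicalCluster(m3)
  expect_equal(sort(cl3$tree$height),
               sort(upgmaHeights(1 - cor(t(m3)))), tolerance = 1e-10)
  # constant rows: warning, excluded from the tree, placed last
  m4 <- rbind(m3, flat = rep(2, 6))
  expect_warning(cl4 <- hierarchicalCluster(m4), "zero-variance")
  expect_equal(cl4$order[11], 11)
  expect_equal(cl4$constant_rows, 11L)
  expect_error(hierarchicalCluster(m3[1, , drop = FALSE]), "2 rows")
})
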