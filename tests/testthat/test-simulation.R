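test_that("identical config and seed reproduce counts, Ct records and annotation bit-identically", {
  cfg <- SimulationConfig(n_mirnas = 80, library_size = 1e5,
                          mitomir_indices = 1:8, seed = 42)
  a <- simulateCounts(cfg)
  b <- simulateCounts(cfg)
  expect_identical(counts(a$experiment), counts(b$experiment))
  expect_identical(trueAbundance(a$truth), trueAbundance(b$truth))
  sel <- rownames(trueAbundance(a$truth))[1:5]
  expect_identical(simulateQpcr(cfg, a$truth, sel),
                   simulateQpcr(cfg, b$truth, sel))
  expect_identical(simulateAnnotation(cfg, a$truth, n_genes = 300,
                                      n_pathways = 5, pathway_size = 20),
                   simulateAnnotation(cfg, b$truth, n_genes = 300,
                                      n_pathways = 5, pathway_size = 20))
  # and the simulator leaves the caller's RNG untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulateCounts(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("ground-truth pools are conserved: each compartment/condition abundance column sums to 1", {
  cfg <- SimulationConfig(n_mirnas = 120, mitomir_indices = 1:10,
                          mito_log2_effect = c(3, 1),
                          total_log2_effect = c(-0.5, 0), seed = 3)
  truth <- simulateCounts(cfg)$truth
  expect_true(all(abs(colSums(trueAbundance(truth, "mitochondrial")) - 1) < 1e-12))
  expect_true(all(abs(colSums(trueAbundance(truth, "total")) - 1) < 1e-12))
})

test_that("null configuration gives identical expected CPM in both compartments", {
  cfg <- SimulationConfig(n_mirnas = 50, mitomir_indices = integer(0),
                          mito_log2_effect = c(0, 0),
                          total_log2_effect = c(0, 0),
                          contamination = 0, seed = 5)
  truth <- simulateCounts(cfg)$truth
  expect_equal(expectedCpm(truth, 0, "mitochondrial"),
               expectedCpm(truth, 0, "total"))
})

test_that("full contamination collapses the expected mitochondrial CPM onto the total CPM", {
  cfg <- SimulationConfig(n_mirnas = 60, mitomir_indices = 1:6, seed = 8)
  truth <- simulateCounts(cfg)$truth
  expect_identical(expectedCpm(truth, 1, "mitochondrial"),
                   expectedCpm(truth, 0, "total"))
})

test_that("expected planted-mitomiR CPM decreases monotonically toward the total CPM as contamination rises", {
  cfg <- SimulationConfig(n_mirnas = 100, mitomir_indices = 1:10, seed = 9)
  truth <- simulateCounts(cfg)$truth
  planted <- isMitomir(truth)
  grid <- c(0, 0.2, 0.5, 0.8, 0.99)
  cpms <- sapply(grid, function(phi)
    expectedCpm(truth, phi, "mitochondrial")[planted, "tac4w"])
  expect_true(all(diff(t(cpms)) < 0))
  expect_true(all(cpms[, length(grid)] >
                    expectedCpm(truth, 0, "total")[planted, "tac4w"]))
})

test_that("invalid simulation configurations are rejected by name", {
  expect_error(SimulationConfig(contamination = 1), "contamination")
  expect_error(SimulationConfig(contamination = -0.1), "contamination")
  expect_error(SimulationConfig(dispersion = -1), "dispersion")
  expect_error(SimulationConfig(mitomir_indices = c(1, 999)), "mitomir_indices")
  expect_error(SimulationConfig(mito_log2_effect = c(1, 2, 3)),
               "mito_log2_effect")
  expect_error(SimulationConfig(conditions = "sham"), "condition")
})

test_that("negative-binomial counts show the configured overdispersion", {
  cfg <- SimulationConfig(n_mirnas = 2000, library_size = 2e5,
                          mitomir_indices = integer(0),
                          mito_log2_effect = c(0, 0), baseline_log_sd = 0,
                          dispersion = 0.5, seed = 21)
  cnt <- counts(simulateCounts(cfg)$experiment)[, "total_sham"]
  m <- mean(cnt)
  # variance should be near m + 0.5 m^2, far above Poisson
  expect_gt(stats::var(cnt), m + 0.25 * m^2)
})

test_that("noiseless simulated qPCR reproduces planted abundance ratios exactly", {
  # miRNA 1 halves its abundance between conditions: ddCt = +1, fold = 0.5
  cfg <- SimulationConfig(n_mirnas = 2, conditions = c("sham", "tac"),
                          mitomir_indices = integer(0),
                          mito_log2_effect = 0, total_log2_effect = 0,
                          reference_log2_drift = 0, contamination = 0,
                          seed = 1)
  truth <- makeTruth(mito = cbind(sham = c(0.4, 0.6), tac = c(0.2, 0.8)),
                     total = cbind(sham = c(0.4, 0.6), tac = c(0.2, 0.8)))
  ct <- simulateQpcr(cfg, truth, "mmu-miR-sim-0001", ct_noise_sd = 0)
  fc <- qpcrFoldChanges(ct, control_condition = "sham")
  expect_equal(fc$ddct, rep(1, 2), tolerance = 1e-12)
  expect_equal(fc$fold_change, rep(0.5, 2), tolerance = 1e-12)
  # equal abundances: fold exactly 1
  truth2 <- makeTruth(mito = cbind(sham = c(0.4, 0.6), tac = c(0.4, 0.6)),
                      total = cbind(sham = c(0.4, 0.6), tac = c(0.4, 0.6)))
  fc2 <- qpcrFoldChanges(simulateQpcr(cfg, truth2, "mmu-miR-sim-0001",
                                      ct_noise_sd = 0))
  expect_equal(fc2$fold_change, rep(1, 2), tolerance = 1e-12)
})

test_that("noisy qPCR recovers the planted fold on average (Monte-Carlo vs closed form)", {
  # the delta-delta-Ct estimator is log-normally biased: with replicate noise
  # sd 0.3 and four triplicate means entering ddCt, E[fold / true fold] =
  # exp((sd_ddct * ln 2)^2 / 2). The reference-gene noise is shared by all
  # targets of one run, so the mean is taken across independent runs.
  sd_ddct <- 0.3 * 2 / sqrt(3)
  closed_form <- exp((sd_ddct * log(2))^2 / 2)
  ratios <- unlist(lapply(1:100, function(s) {
    cfg <- SimulationConfig(n_mirnas = 10, conditions = c("sham", "tac"),
                            mitomir_indices = 1:10,
                            mito_log2_effect = 2, total_log2_effect = 2,
                            contamination = 0, seed = 7000 + s)
    truth <- simulateCounts(cfg)$truth
    planted <- rownames(trueAbundance(truth))[isMitomir(truth)]
    ct <- simulateQpcr(cfg, truth, planted, ct_noise_sd = 0.3)
    fc <- suppressWarnings(qpcrFoldChanges(ct))
    tot <- fc[fc$compartment == "total", ]
    ab <- trueAbundance(truth, "total")
    tot$fold_change / (ab[tot$mirna, "tac"] / ab[tot$mirna, "sham"])
  }))
  expect_equal(mean(ratios), closed_form, tolerance = 0.05)
})

test_that("qPCR simulation rejects empty or unknown selections", {
  cfg <- SimulationConfig(n_mirnas = 10, mitomir_indices = 1:2, seed = 2)
  truth <- simulateCounts(cfg)$truth
  expect_error(simulateQpcr(cfg, truth, character(0)), "at least one")
  expect_error(simulateQpcr(cfg, truth, "mmu-miR-nope"), "not simulated")
})

test_that("annotation respects its preconditions and score structure", {
  cfg <- SimulationConfig(n_mirnas = 30, mitomir_indices = 1:5, seed = 4)
  truth <- simulateCounts(cfg)$truth
  expect_error(simulateAnnotation(cfg, truth, n_genes = 10,
                                  pathway_size = 20), "pathway_size")
  ann <- simulateAnnotation(cfg, truth, n_genes = 400, n_pathways = 6,
                            pathway_size = 25, targets_per_mirna = 10,
                            decoys_per_mirna = 10)
  expect_false(any(duplicated(ann$target_map[, c("mirna", "gene")])))
  expect_true(all(ann$target_map$score >= 0 & ann$target_map$score <= 1))
  # every miRNA has both above- and below-threshold edges
  above <- tapply(ann$target_map$score > 0.9, ann$target_map$mirna, any)
  below <- tapply(ann$target_map$score < 0.9, ann$target_map$mirna, any)
  expect_true(all(above) && all(below))
  expect_identical(ann$planted_pathway, "path01")
})
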