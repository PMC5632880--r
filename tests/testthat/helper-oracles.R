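# Independent oracles used to check the package's statistics.

# Two-sided binomial p by direct enumeration of point masses computed from
# binomial coefficients (minimum-likelihood rule).
binomTwoSidedEnum <- function(x1, n, prob) {
  if (n == 0) return(1)
  k <- 0:n
  mass <- choose(n, k) * prob^k * (1 - prob)^(n - k)
  obs <- mass[x1 + 1]
  min(1, sum(mass[mass <= obs * (1 + 1e-7)]))
}

# Textbook Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) m / j.
bhStepUp <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Hypergeometric upper tail P(X >= k) by direct enumeration.
hypergeomTailEnum <- function(k, K, M, n) {
  i <- k:min(n, K)
  if (k > min(n, K)) return(0)
  sum(choose(K, i) * choose(M - K, n - i)) / choose(M, n)
}

# Naive O(n^3) average-linkage (UPGMA) agglomeration; returns merge heights.
upgmaHeights <- function(D) {
  D <- as.matrix(D)
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    bd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          dd <- mean(D[clusters[[i]], clusters[[j]]])
          if (dd < bd) {
            bd <- dd
            best <- c(i, j)
          }
        }
      }
    }
    heights <- c(heights, bd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Hand-built ground truth for qPCR arithmetic checks.
makeTruth <- function(mito, total, planted = NULL) {
  ids <- sprintf("mmu-miR-sim-%04d", seq_len(nrow(mito)))
  dimnames(mito) <- dimnames(total) <- list(ids, colnames(mito))
  flags <- logical(nrow(mito))
  if (!is.null(planted)) flags[planted] <- TRUE
  new("MitomirTruth", mito_abundance = mito, total_abundance = total,
      is_mitomir = flags, planted_pathway = NA_character_)
}

# One full simulate -> DE -> qPCR -> classify -> enrich recovery run under
# the default study design; returns per-seed summaries.
recoveryRun <- function(seed, ct_noise_sd = 0.15) {
  cfg <- SimulationConfig(seed = seed)
  sim <- simulateCounts(cfg)
  de <- pairwiseProfile(sim$experiment,
                        pairs = list(c("sham", "tac4w")))[[1]]
  ct <- simulateQpcr(cfg, sim$truth,
                     selected = rownames(trueAbundance(sim$truth)),
                     ct_noise_sd = ct_noise_sd)
  fc <- suppressWarnings(qpcrFoldChanges(ct))
  tot <- fc[fc$compartment == "total" & fc$condition == "tac4w", ]
  calls <- classifyBatch(de, tot,
                         candidate_ids = intersect(de$mirna, tot$mirna))
  flags <- isMitomir(sim$truth)[calls$mirna]
  ann <- simulateAnnotation(cfg, sim$truth)
  hits <- calls$mirna[calls$classification == "enriched"]
  top_id <- NA_character_
  if (length(hits)) {
    tg <- collectTargets(hits, ann$target_map)
    enr <- enrichmentReport(suppressWarnings(
      hypergeomEnrich(tg$genes, ann$pathways, mirna_sets = tg$per_mirna)))
    top_id <- enr$pathway_id[1]
  }
  list(sensitivity = mean(calls$classification[flags] == "enriched"),
       fpr = mean(calls$classification[!flags] == "enriched"),
       planted_first = identical(top_id, ann$planted_pathway))
}
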