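#' Simulate compartment-fractionated pooled small-RNA libraries
#'
#' Draws one pooled sequencing library per (compartment, condition) cell,
#' emulating a design in which RNA from many animals is pooled into a single
#' library per group so that no biological replicates exist. Baseline miRNA
#' abundances are log-normal. Planted mitomiRs receive per-condition log2
#' effects in the mitochondrial pool (and, independently, in the whole-tissue
#' pool); each pool is renormalized to sum to one. The observed mitochondrial
#' library is a mixture: a fraction \eqn{1-\phi} of its reads comes from the
#' true mitochondrial pool and \eqn{\phi} from the whole-tissue pool,
#' modelling residual cytosolic contamination that RNase treatment of intact
#' mitochondria cannot fully remove. Counts are Poisson when `dispersion`
#' is 0, otherwise negative binomial with variance \eqn{m + dispersion\,m^2}.
#'
#' @param config a [SimulationConfig-class].
#' @return a list with elements `experiment` (a [MitomirExperiment-class]
#'   with one library per compartment/condition) and `truth`
#'   (a [MitomirTruth-class]).
#' @examples
#' sim <- simulateCounts(SimulationConfig(n_mirnas = 50, library_size = 1e5,
#'                                        mitomir_indices = 1:5, seed = 7))
#' sim$experiment
#' @export
simulateCounts <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  n <- config@n_mirnas
  conds <- config@conditions
  k <- length(conds)
  ids <- sprintf("mmu-miR-sim-%04d", seq_len(n))
  planted <- logical(n)
  planted[config@mitomir_indices] <- TRUE
  eff_m <- c(0, config@mito_log2_effect)
  eff_t <- c(0, config@total_log2_effect)
  phi <- config@contamination

  out <- withSeed(config@seed, {
    base <- rlnorm(n, config@baseline_log_mean, config@baseline_log_sd)
    mito <- total <- matrix(0, n, k, dimnames = list(ids, conds))
    for (j in seq_len(k)) {
      wt <- base
      wt[planted] <- wt[planted] * 2^eff_t[j]
      total[, j] <- wt / sum(wt)
      wm <- base
      wm[planted] <- wm[planted] * 2^eff_m[j]
      mito[, j] <- wm / sum(wm)
    }
    mix <- (1 - phi) * mito + phi * total
    mu <- cbind(config@library_size * mix, config@library_size * total)
    colnames(mu) <- c(paste0("mito_", conds), paste0("total_", conds))
    draw <- function(m) {
      if (config@dispersion == 0) rpois(length(m), m)
      else rnbinom(length(m), mu = m, size = 1 / config@dispersion)
    }
    cnt <- matrix(draw(mu), n, 2L * k, dimnames = dimnames(mu))
    list(counts = cnt, mito = mito, total = total)
  })

  se <- MitomirExperiment(
    counts = out$counts,
    compartment = rep(c("mitochondrial", "total"), each = k),
    condition = rep(conds, 2L))
  truth <- new("MitomirTruth",
               mito_abundance = out$mito,
               total_abundance = out$total,
               is_mitomir = planted,
               planted_pathway = NA_character_)
  list(experiment = se, truth = truth)
}

#' Expected counts-per-million under the simulation model
#'
#' Closed-form expectation of the CPM of each miRNA in each condition for a
#' given compartment, including the contamination mixture for the
#' mitochondrial fraction: \eqn{10^6 [(1-\phi) m + \phi t]} where `m` and `t`
#' are the true pool abundances.
#'
#' @param truth a [MitomirTruth-class].
#' @param contamination contamination fraction \eqn{\phi \in [0, 1]};
#'   ignored for the total compartment. \eqn{\phi = 1} is allowed here (the
#'   full-contamination limit in which the mitochondrial library is pure
#'   whole-tissue RNA).
#' @param compartment `"mitochondrial"` or `"total"`.
#' @return miRNA x condition matrix of expected CPM.
#' @export
expectedCpm <- function(truth, contamination = 0,
                        compartment = c("mitochondrial", "total")) {
  stopifnot(is(truth, "MitomirTruth"))
  compartment <- match.arg(compartment)
  .assertScalarNum(contamination, "contamination", 0, 1)
  if (compartment == "total") return(1e6 * truth@total_abundance)
  1e6 * ((1 - contamination) * truth@mito_abundance +
           contamination * truth@total_abundance)
}

#' Simulate stem-loop qPCR Ct triplicates
#'
#' For each selected miRNA, compartment and condition, three replicate Ct
#' values are drawn as \eqn{Ct = Ct_0 - \log_2(a) + \epsilon} with
#' \eqn{\epsilon \sim N(0, ct\_noise\_sd^2)}, where `a` is the miRNA's
#' relative abundance in the *observed* RNA of that compartment (the
#' contamination mixture for the mitochondrial fraction). A small-RNA
#' reference gene (U6 by default) is generated with constant abundance
#' across conditions, unless the config declares a reference drift.
#'
#' @param config the [SimulationConfig-class] used for the counts.
#' @param truth matching [MitomirTruth-class].
#' @param selected character vector of miRNA ids to assay (must be simulated
#'   miRNAs; must be non-empty).
#' @param ct_noise_sd replicate-level Gaussian Ct noise, in cycles. The
#'   default 0.15 is a typical triplicate technical SD for SYBR stem-loop
#'   assays; 0 gives noiseless records.
#' @param ct_intercept cycle offset \eqn{Ct_0} (Ct of a transcript making up
#'   the whole pool).
#' @param reference_id name of the reference gene.
#' @param reference_abundance its fixed relative abundance.
#' @return a data.frame with columns `mirna`, `compartment`, `condition`,
#'   `replicate`, `ct`, `is_reference` — the CSV dialect read back by
#'   [readCtCsv()].
#' @export
simulateQpcr <- function(config, truth, selected, ct_noise_sd = 0.15,
                         ct_intercept = 20, reference_id = "U6",
                         reference_abundance = 0.05) {
  stopifnot(is(config, "SimulationConfig"), is(truth, "MitomirTruth"))
  .assertScalarNum(ct_noise_sd, "ct_noise_sd", 0)
  ids <- rownames(truth@mito_abundance)
  if (length(selected) == 0L)
    stop("'selected' must name at least one miRNA", call. = FALSE)
  missing_ids <- setdiff(selected, ids)
  if (length(missing_ids))
    stop("selected miRNAs not simulated: ",
         paste(head(missing_ids, 5L), collapse = ", "), call. = FALSE)

  conds <- config@conditions
  phi <- config@contamination
  abund <- list(
    mitochondrial = (1 - phi) * truth@mito_abundance +
      phi * truth@total_abundance,
    total = truth@total_abundance)
  drift <- c(0, config@reference_log2_drift)

  grid <- expand.grid(mirna = c(selected, reference_id),
                      compartment = names(abund),
                      condition = conds,
                      replicate = 1:3,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$compartment, match(grid$condition, conds),
                     match(grid$mirna, c(selected, reference_id)),
                     grid$replicate), , drop = FALSE]
  rownames(grid) <- NULL
  grid$is_reference <- grid$mirna == reference_id

  j <- match(grid$condition, conds)
  a <- ifelse(grid$is_reference,
              reference_abundance * 2^drift[j],
              abund$mitochondrial[cbind(match(grid$mirna, ids), j)])
  tot_rows <- grid$compartment == "total" & !grid$is_reference
  a[tot_rows] <- abund$total[cbind(match(grid$mirna[tot_rows], ids),
                                   j[tot_rows])]
  grid$ct <- withSeed(config@seed + 1L,
                      ct_intercept - log2(a) +
                        rnorm(nrow(grid), 0, ct_noise_sd))
  grid[, c("mirna", "compartment", "condition", "replicate", "ct",
           "is_reference")]
}

#' Simulate a scored miRNA target map and pathway gene sets
#'
#' Generates toy annotation with known structure: every miRNA gets
#' `targets_per_mirna` "true" target edges whose interaction scores lie
#' strictly above `score_threshold`, plus `decoys_per_mirna` decoy edges
#' scored below it. When `planted = TRUE`, a fraction `in_pathway_frac` of
#' each planted mitomiR's true targets is drawn from one designated
#' pathway's gene set, so that pathway should dominate a downstream
#' hypergeometric enrichment of the mitomiR target union; with
#' `planted = FALSE` all targets are uniform over the gene universe and no
#' pathway is preferred.
#'
#' @param config the [SimulationConfig-class] (supplies the seed).
#' @param truth matching [MitomirTruth-class] (supplies mitomiR flags).
#' @param n_genes size of the gene universe; must be at least
#'   `pathway_size`.
#' @param n_pathways number of gene sets.
#' @param pathway_size genes per set.
#' @param targets_per_mirna true (above-threshold) edges per miRNA.
#' @param decoys_per_mirna below-threshold edges per miRNA.
#' @param in_pathway_frac fraction of a planted mitomiR's true targets drawn
#'   from the planted pathway.
#' @param score_threshold the interaction-score cutoff the map is built
#'   around (microT-style, default 0.9).
#' @param planted logical; `FALSE` yields a decoy-only (uniform) map.
#' @return list with `target_map` (data.frame `mirna`, `gene`, `score`),
#'   `pathways` (named list of gene vectors), `pathway_names` (named
#'   character, descriptions) and `planted_pathway` (id, or `NA` when
#'   `planted = FALSE`).
#' @export
simulateAnnotation <- function(config, truth, n_genes = 2000L,
                               n_pathways = 20L, pathway_size = 60L,
                               targets_per_mirna = 25L,
                               decoys_per_mirna = 25L,
                               in_pathway_frac = 0.8,
                               score_threshold = 0.9,
                               planted = TRUE) {
  stopifnot(is(config, "SimulationConfig"), is(truth, "MitomirTruth"))
  .assertScalarNum(in_pathway_frac, "in_pathway_frac", 0, 1)
  .assertScalarNum(score_threshold, "score_threshold", 0, 1,
                   strict_lower = TRUE, strict_upper = TRUE)
  if (n_genes < pathway_size)
    stop("n_genes must be at least pathway_size", call. = FALSE)
  ids <- rownames(truth@mito_abundance)
  genes <- sprintf("gene%05d", seq_len(n_genes))

  withSeed(config@seed + 2L, {
    sets <- lapply(seq_len(n_pathways),
                   function(i) sample(genes, pathway_size))
    names(sets) <- sprintf("path%02d", seq_len(n_pathways))
    planted_id <- if (planted) names(sets)[1L] else NA_character_

    edge <- function(mirna, tgt_genes, lo, hi) {
      if (!length(tgt_genes)) return(NULL)
      data.frame(mirna = mirna, gene = tgt_genes,
                 score = runif(length(tgt_genes), lo, hi))
    }
    eps <- 1e-3
    rows <- lapply(seq_along(ids), function(i) {
      if (planted && truth@is_mitomir[i]) {
        n_in <- round(in_pathway_frac * targets_per_mirna)
        tgt <- c(sample(sets[[1L]], min(n_in, pathway_size)),
                 sample(genes, targets_per_mirna - min(n_in, pathway_size)))
      } else {
        tgt <- sample(genes, targets_per_mirna)
      }
      rbind(edge(ids[i], unique(tgt), score_threshold + eps, 1 - eps),
            edge(ids[i], sample(genes, decoys_per_mirna), eps,
                 score_threshold - eps))
    })
    map <- do.call(rbind, rows)
    map <- map[!duplicated(map[, c("mirna", "gene")]), , drop = FALSE]
    rownames(map) <- NULL
    list(target_map = map,
         pathways = sets,
         pathway_names = setNames(
           sprintf("Synthetic pathway %02d", seq_len(n_pathways)),
           names(sets)),
         planted_pathway = planted_id)
  })
}
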