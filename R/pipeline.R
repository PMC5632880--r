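# End-to-end orchestration: simulate -> de -> qpcr -> classify -> enrich ->
# report, bound together by the plain-text formats in io.R. Every artifact
# is written atomically and listed in a JSON run manifest with its md5 sum,
# so a re-run under the same configuration and seed is byte-identical and
# verifiably so.

#' Default pipeline configuration
#'
#' A flat named list holding every tunable of the pipeline stages with the
#' package defaults: the simulated study design (300 miRNAs, 20 planted
#' mitomiRs, pooled libraries of 2e6 reads, mitochondrial log2 effects
#' (3, 1) at 4 and 8 weeks, flat whole-tissue effects, contamination 0.2,
#' Poisson counts), the DE thresholds (fold > 2 or < 0.5 at p < 0.05, BH
#' q-values reported alongside), qPCR settings, the classifier tolerance and
#' the enrichment score threshold. [readPipelineConfig()] merges a JSON or
#' YAML file over these defaults, rejecting unknown keys.
#'
#' @return named list of configuration values.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    n_mirnas = 300L,
    library_size = 2e6,
    conditions = c("sham", "tac4w", "tac8w"),
    n_mitomirs = 20L,
    mito_log2_effect = c(3, 1),
    total_log2_effect = c(0, 0),
    contamination = 0.2,
    dispersion = 0,
    baseline_log_mean = 0,
    baseline_log_sd = 1.5,
    ct_noise_sd = 0.15,
    n_qpcr_candidates = 15L,
    n_genes = 2000L,
    n_pathways = 20L,
    pathway_size = 60L,
    targets_per_mirna = 25L,
    decoys_per_mirna = 25L,
    in_pathway_frac = 0.8,
    min_count = 1,
    pseudo_cpm = 0.5,
    fc_up = 2,
    fc_down = 0.5,
    alpha = 0.05,
    use_q = FALSE,
    de_method = "minlike",
    score_threshold = 0.9,
    unchanged_tolerance = 0.2,
    control_condition = "sham",
    treatment_condition = "tac4w")
}

#' Load a pipeline configuration file
#'
#' Reads JSON (`.json`) or YAML (`.yml` / `.yaml`) whose keys mirror
#' [defaultPipelineConfig()]; unknown keys are rejected (typo safety) and
#' every numeric threshold is validated at load.
#'
#' @param path configuration file path.
#' @return the merged configuration list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  user <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yml = ,
    yaml = yaml::read_yaml(path),
    stop("config must be .json, .yml or .yaml, got .", ext, call. = FALSE))
  if (is.null(user)) user <- list()
  cfg <- defaultPipelineConfig()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(user)] <- user
  .validatePipelineConfig(cfg)
}

.validatePipelineConfig <- function(cfg) {
  .assertScalarNum(cfg$seed, "seed")
  .assertScalarNum(cfg$n_mirnas, "n_mirnas", 1)
  .assertScalarNum(cfg$library_size, "library_size", 1)
  .assertScalarNum(cfg$contamination, "contamination", 0, 1,
                   strict_upper = TRUE)
  .assertScalarNum(cfg$dispersion, "dispersion", 0)
  .assertScalarNum(cfg$ct_noise_sd, "ct_noise_sd", 0)
  .assertScalarNum(cfg$min_count, "min_count", 0)
  .assertScalarNum(cfg$pseudo_cpm, "pseudo_cpm", 0)
  .assertScalarNum(cfg$fc_up, "fc_up", 1, strict_lower = TRUE)
  .assertScalarNum(cfg$fc_down, "fc_down", 0, 1,
                   strict_lower = TRUE, strict_upper = TRUE)
  .assertScalarNum(cfg$alpha, "alpha", 0, 1)
  .assertScalarNum(cfg$score_threshold, "score_threshold", 0, 1)
  .assertScalarNum(cfg$unchanged_tolerance, "unchanged_tolerance", 0)
  if (!cfg$de_method %in% c("minlike", "doubled"))
    stop("de_method must be 'minlike' or 'doubled'", call. = FALSE)
  if (!cfg$control_condition %in% cfg$conditions ||
      !cfg$treatment_condition %in% cfg$conditions)
    stop("control/treatment conditions must be among 'conditions'",
         call. = FALSE)
  cfg
}

.simConfigFromPipeline <- function(cfg) {
  SimulationConfig(
    n_mirnas = cfg$n_mirnas,
    library_size = cfg$library_size,
    conditions = cfg$conditions,
    mitomir_indices = seq_len(cfg$n_mitomirs),
    mito_log2_effect = cfg$mito_log2_effect,
    total_log2_effect = cfg$total_log2_effect,
    contamination = cfg$contamination,
    dispersion = cfg$dispersion,
    baseline_log_mean = cfg$baseline_log_mean,
    baseline_log_sd = cfg$baseline_log_sd,
    seed = cfg$seed)
}

#' Run the mitomiR pipeline end to end
#'
#' Executes the requested stages in order, reading and writing the
#' plain-text artifacts of each stage under `out_dir`:
#'
#' * `simulate` — synthetic counts (`counts.tsv`, `libraries.tsv`), ground
#'   truth (`truth.json`), qPCR Ct records (`ct_records.csv`) for the top
#'   mitochondrial DE candidates plus planted mitomiRs, a scored target map
#'   (`target_map.tsv`) and pathway gene sets (`pathways.gmt`).
#' * `de` — pairwise exact-test DE tables per condition pair for both
#'   compartments (`de_<compartment>_<pair>.tsv`) and a clustered log-CPM
#'   heatmap matrix in leaf order (`heatmap_matrix.tsv`).
#' * `qpcr` — delta-delta-Ct fold changes (`qpcr_fold_changes.tsv`).
#' * `classify` — mitomiR calls joining mitochondrial DE with whole-tissue
#'   qPCR (`mitomir_calls.tsv`).
#' * `enrich` — ranked hypergeometric pathway enrichment of the union
#'   target set of the enriched miRNAs (`enrichment.tsv`).
#' * `report` — a JSON manifest (`manifest.json`) listing every artifact
#'   with md5 checksum and row count, plus the configuration and seed.
#'
#' Later stages read the files earlier stages wrote, so a subset of stages
#' can be re-run against an existing directory.
#'
#' @param config a configuration list ([defaultPipelineConfig()] shape) or
#'   the path of a JSON/YAML config file.
#' @param out_dir output directory (created if needed).
#' @param steps character vector of stages, or `"all"`.
#' @return invisibly, a list with the artifact paths and the manifest.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), out_dir,
                        steps = "all") {
  if (is.character(config) && length(config) == 1L)
    config <- readPipelineConfig(config)
  cfg <- .validatePipelineConfig(config)
  all_steps <- c("simulate", "de", "qpcr", "classify", "enrich", "report")
  if (identical(steps, "all")) steps <- all_steps
  bad <- setdiff(steps, all_steps)
  if (length(bad))
    stop("unknown step(s): ", paste(bad, collapse = ", "), call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(out_dir, f)
  artifacts <- character()
  note <- function(f) artifacts <<- unique(c(artifacts, f))

  if ("simulate" %in% steps) {
    sc <- .simConfigFromPipeline(cfg)
    sim <- simulateCounts(sc)
    writeCountTable(sim$experiment, pth("counts.tsv"), pth("libraries.tsv"))
    note("counts.tsv"); note("libraries.tsv")
    writeTruthJson(sim$truth, pth("truth.json")); note("truth.json")
    # qPCR panel: strongest mitochondrial movers by sequencing, the way a
    # validation panel would be picked, topped up with planted mitomiRs
    de_tmp <- pairwiseProfile(
      sim$experiment,
      pairs = list(c(cfg$control_condition, cfg$treatment_condition)),
      compartment = "mitochondrial", min_count = cfg$min_count,
      pseudo_cpm = cfg$pseudo_cpm, fc_up = cfg$fc_up, fc_down = cfg$fc_down,
      alpha = cfg$alpha, method = cfg$de_method)[[1L]]
    picks <- de_tmp$mirna[order(-de_tmp$log2_fc)]
    panel <- unique(c(head(picks, cfg$n_qpcr_candidates),
                      rownames(trueAbundance(sim$truth))[isMitomir(sim$truth)]))
    ct <- simulateQpcr(sc, sim$truth, selected = panel,
                       ct_noise_sd = cfg$ct_noise_sd)
    writeCtCsv(ct, pth("ct_records.csv")); note("ct_records.csv")
    ann <- simulateAnnotation(sc, sim$truth, n_genes = cfg$n_genes,
                              n_pathways = cfg$n_pathways,
                              pathway_size = cfg$pathway_size,
                              targets_per_mirna = cfg$targets_per_mirna,
                              decoys_per_mirna = cfg$decoys_per_mirna,
                              in_pathway_frac = cfg$in_pathway_frac,
                              score_threshold = cfg$score_threshold)
    writeTargetMap(ann$target_map, pth("target_map.tsv")); note("target_map.tsv")
    writeGmt(ann$pathways, pth("pathways.gmt"), ann$pathway_names)
    note("pathways.gmt")
  }

  if ("de" %in% steps) {
    se <- readCountTable(pth("counts.tsv"), pth("libraries.tsv"))
    for (comp in unique(unname(compartments(se)))) {
      prof <- pairwiseProfile(se, compartment = comp,
                              min_count = cfg$min_count,
                              pseudo_cpm = cfg$pseudo_cpm, fc_up = cfg$fc_up,
                              fc_down = cfg$fc_down, alpha = cfg$alpha,
                              use_q = cfg$use_q, method = cfg$de_method)
      for (nm in names(prof)) {
        f <- sprintf("de_%s_%s.tsv",
                     sub("mitochondrial", "mito", comp), nm)
        writeTsv(prof[[nm]], pth(f)); note(f)
      }
    }
    logcpm <- log2(cpmNormalize(se) + cfg$pseudo_cpm)
    expressed <- rowSums(counts(se)) >= cfg$min_count
    cl <- suppressWarnings(hierarchicalCluster(logcpm[expressed, , drop = FALSE]))
    hm <- logcpm[which(expressed)[cl$order], , drop = FALSE]
    writeTsv(data.frame(mirna = rownames(hm), hm, check.names = FALSE),
             pth("heatmap_matrix.tsv"))
    note("heatmap_matrix.tsv")
  }

  if ("qpcr" %in% steps) {
    ct <- readCtCsv(pth("ct_records.csv"))
    fc <- qpcrFoldChanges(ct, control_condition = cfg$control_condition)
    writeTsv(fc, pth("qpcr_fold_changes.tsv")); note("qpcr_fold_changes.tsv")
  }

  if ("classify" %in% steps) {
    de_mito <- readTsv(pth(sprintf("de_mito_%s_vs_%s.tsv",
                                   cfg$control_condition,
                                   cfg$treatment_condition)))
    fc <- readTsv(pth("qpcr_fold_changes.tsv"))
    tot <- fc[fc$compartment == "total" &
                fc$condition == cfg$treatment_condition, , drop = FALSE]
    cand <- intersect(unique(fc$mirna), de_mito$mirna)
    calls <- classifyBatch(de_mito, tot, cand, fc_up = cfg$fc_up,
                           alpha = cfg$alpha,
                           unchanged_tolerance = cfg$unchanged_tolerance)
    writeTsv(calls, pth("mitomir_calls.tsv")); note("mitomir_calls.tsv")
  }

  if ("enrich" %in% steps) {
    calls <- readTsv(pth("mitomir_calls.tsv"))
    hits <- calls$mirna[calls$classification == "enriched"]
    map <- readTargetMap(pth("target_map.tsv"))
    sets <- readGmt(pth("pathways.gmt"))
    if (length(hits)) {
      tg <- collectTargets(hits, map, cfg$score_threshold)
      enr <- enrichmentReport(
        hypergeomEnrich(tg$genes, sets, mirna_sets = tg$per_mirna))
    } else {
      enr <- hypergeomEnrich(character(0), sets)[0, , drop = FALSE]
    }
    writeTsv(enr, pth("enrichment.tsv")); note("enrichment.tsv")
  }

  manifest <- NULL
  if ("report" %in% steps) {
    present <- artifacts[file.exists(pth(artifacts))]
    if (!length(present)) {
      known <- c("counts.tsv", "libraries.tsv", "truth.json",
                 "ct_records.csv", "target_map.tsv", "pathways.gmt",
                 "heatmap_matrix.tsv", "qpcr_fold_changes.tsv",
                 "mitomir_calls.tsv", "enrichment.tsv")
      present <- c(known, grep("^de_", list.files(out_dir), value = TRUE))
      present <- unique(present[file.exists(pth(present))])
    }
    files <- lapply(sort(present), function(f) {
      n_rows <- length(readLines(pth(f), warn = FALSE)) - 1L
      list(path = f, md5 = unname(tools::md5sum(pth(f))), rows = n_rows)
    })
    manifest <- list(seed = cfg$seed, config = cfg, files = files)
    .atomicWrite(pth("manifest.json"), function(tmp)
      jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE))
  }
  invisible(list(out_dir = out_dir, artifacts = pth(artifacts),
                 manifest = manifest))
}
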