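#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats dbinom pbinom phyper p.adjust rlnorm rpois rnbinom rnorm
#'   runif cor hclust as.dist setNames
#' @importFrom utils read.delim read.csv write.table head
NULL

#' Compartment-fractionated miRNA count container
#'
#' `MitomirExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment-class] and holds one miRNA x
#' library matrix of non-negative integer read counts (assay `"counts"`)
#' together with per-library metadata: the subcellular `compartment`
#' (`"mitochondrial"` or `"total"`), the experimental `condition` (e.g. sham,
#' 4-week TAC, 8-week TAC) and the `library_size` used for counts-per-million
#' scaling. The declared library size defaults to the column sum and may only
#' be larger (a pooled library may contain reads that did not map to a known
#' miRNA).
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment-class].
#' @aliases MitomirExperiment-class
#' @exportClass MitomirExperiment
setClass("MitomirExperiment", contains = "SummarizedExperiment")

.validMitomirExperiment <- function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'counts' is required")
  } else {
    m <- SummarizedExperiment::assay(object, "counts")
    if (any(!is.finite(m)) || any(m < 0))
      msg <- c(msg, "counts must be finite and non-negative")
    else if (any(abs(m - round(m)) > 1e-8))
      msg <- c(msg, "counts must be integers")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "miRNA ids (rownames) must be present and unique")
  cd <- SummarizedExperiment::colData(object)
  need <- c("compartment", "condition", "library_size")
  absent <- setdiff(need, colnames(cd))
  if (length(absent)) {
    msg <- c(msg, paste0("colData must contain: ", paste(absent, collapse = ", ")))
  } else {
    if (!all(cd$compartment %in% c("mitochondrial", "total")))
      msg <- c(msg, "compartment must be 'mitochondrial' or 'total'")
    if (any(!is.finite(cd$library_size)) || any(cd$library_size <= 0))
      msg <- c(msg, "library_size must be positive")
    if ("counts" %in% SummarizedExperiment::assayNames(object)) {
      cs <- colSums(SummarizedExperiment::assay(object, "counts"))
      if (any(cd$library_size < cs - 1e-6))
        msg <- c(msg, "library_size may not be smaller than the column sum")
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("MitomirExperiment", .validMitomirExperiment)

#' Construct a MitomirExperiment
#'
#' @param counts non-negative integer matrix, miRNA x library; rownames are
#'   miRNA ids, colnames are library ids.
#' @param compartment character vector, one of `"mitochondrial"`, `"total"`
#'   per library.
#' @param condition character vector of condition labels per library.
#' @param library_size optional numeric vector of declared library sizes;
#'   defaults to the column sums of `counts`.
#' @return a [MitomirExperiment-class] object.
#' @examples
#' m <- matrix(rpois(12, 50), 4, 3,
#'             dimnames = list(paste0("mmu-miR-sim-", 1:4), c("a", "b", "c")))
#' se <- MitomirExperiment(m, rep("mitochondrial", 3), c("sham", "tac4w", "tac8w"))
#' librarySizes(se)
#' @export
MitomirExperiment <- function(counts, compartment, condition,
                              library_size = NULL) {
  counts <- as.matrix(counts)
  if (is.null(library_size)) library_size <- colSums(counts)
  cd <- S4Vectors::DataFrame(
    library_id = colnames(counts),
    compartment = as.character(compartment),
    condition = as.character(condition),
    library_size = as.numeric(library_size),
    row.names = colnames(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  new("MitomirExperiment", se)
}

#' Configuration of the compartment-fractionation simulator
#'
#' Describes one synthetic study: a pooled single library per
#' (compartment, condition) cell, a log-normal baseline abundance profile, a
#' set of planted mitochondria-enriched miRNAs with per-condition log2
#' effects in each compartment's RNA pool, and a contamination fraction
#' \eqn{\phi} giving the share of mitochondrial-library reads that actually
#' originate from the whole-tissue pool.
#'
#' @slot n_mirnas number of simulated miRNAs.
#' @slot library_size expected total reads per pooled library.
#' @slot conditions ordered condition labels; the first is the reference.
#' @slot mitomir_indices 1-based indices of the planted mitomiRs.
#' @slot mito_log2_effect per non-reference condition log2 effect applied to
#'   planted mitomiRs in the mitochondrial pool.
#' @slot total_log2_effect per non-reference condition log2 effect applied to
#'   planted mitomiRs in the whole-tissue pool (0 or negative emulates
#'   "decreased or unchanged in total RNA").
#' @slot contamination \eqn{\phi \in [0, 1)}.
#' @slot dispersion negative-binomial overdispersion; 0 means Poisson counts
#'   (variance m), otherwise variance \eqn{m + dispersion \cdot m^2}.
#' @slot baseline_log_mean,baseline_log_sd log-normal (meanlog/sdlog)
#'   parameters of the baseline abundance profile.
#' @slot reference_log2_drift per non-reference condition log2 drift of the
#'   qPCR reference gene (0 = the reference is truly invariant).
#' @slot seed integer master seed; every random draw derives from it.
#' @aliases SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    n_mirnas = "integer",
    library_size = "numeric",
    conditions = "character",
    mitomir_indices = "integer",
    mito_log2_effect = "numeric",
    total_log2_effect = "numeric",
    contamination = "numeric",
    dispersion = "numeric",
    baseline_log_mean = "numeric",
    baseline_log_sd = "numeric",
    reference_log2_drift = "numeric",
    seed = "integer"))

.validSimulationConfig <- function(object) {
  msg <- character()
  k <- length(object@conditions) - 1L
  if (length(object@conditions) < 2L || anyDuplicated(object@conditions))
    msg <- c(msg, "need at least two distinct condition labels")
  if (object@n_mirnas < 1L)
    msg <- c(msg, "n_mirnas must be positive")
  if (!is.finite(object@library_size) || object@library_size < 1)
    msg <- c(msg, "library_size must be a positive number")
  if (length(object@mitomir_indices) &&
      (min(object@mitomir_indices) < 1L ||
       max(object@mitomir_indices) > object@n_mirnas))
    msg <- c(msg, "mitomir_indices out of 1..n_mirnas")
  if (anyDuplicated(object@mitomir_indices))
    msg <- c(msg, "mitomir_indices must be unique")
  if (length(object@mito_log2_effect) != k)
    msg <- c(msg, "mito_log2_effect must have one entry per non-reference condition")
  if (length(object@total_log2_effect) != k)
    msg <- c(msg, "total_log2_effect must have one entry per non-reference condition")
  if (length(object@reference_log2_drift) != k)
    msg <- c(msg, "reference_log2_drift must have one entry per non-reference condition")
  if (!all(is.finite(c(object@mito_log2_effect, object@total_log2_effect,
                       object@reference_log2_drift,
                       object@baseline_log_mean, object@baseline_log_sd))))
    msg <- c(msg, "effects and baseline parameters must be finite")
  if (!is.finite(object@contamination) ||
      object@contamination < 0 || object@contamination >= 1)
    msg <- c(msg, "contamination must lie in [0, 1)")
  if (!is.finite(object@dispersion) || object@dispersion < 0)
    msg <- c(msg, "dispersion must be non-negative")
  if (object@baseline_log_sd < 0)
    msg <- c(msg, "baseline_log_sd must be non-negative")
  if (length(msg)) msg else TRUE
}
setValidity("SimulationConfig", .validSimulationConfig)

#' @rdname SimulationConfig-class
#' @param n_mirnas,library_size,conditions,mitomir_indices,mito_log2_effect,total_log2_effect,contamination,dispersion,baseline_log_mean,baseline_log_sd,reference_log2_drift,seed
#'   see the corresponding slots. Defaults reproduce the study design the
#'   simulator emulates: 300 miRNAs, 20 planted mitomiRs, pooled libraries of
#'   2e6 reads for sham / 4-week / 8-week groups, mitochondrial log2 effects
#'   (3, 1), flat whole-tissue effects, contamination 0.2, Poisson counts.
#' @export
SimulationConfig <- function(n_mirnas = 300L,
                             library_size = 2e6,
                             conditions = c("sham", "tac4w", "tac8w"),
                             mitomir_indices = seq_len(20L),
                             mito_log2_effect = c(3, 1),
                             total_log2_effect = rep(0, length(conditions) - 1L),
                             contamination = 0.2,
                             dispersion = 0,
                             baseline_log_mean = 0,
                             baseline_log_sd = 1.5,
                             reference_log2_drift = rep(0, length(conditions) - 1L),
                             seed = 1L) {
  new("SimulationConfig",
      n_mirnas = as.integer(n_mirnas),
      library_size = as.numeric(library_size),
      conditions = as.character(conditions),
      mitomir_indices = as.integer(mitomir_indices),
      mito_log2_effect = as.numeric(mito_log2_effect),
      total_log2_effect = as.numeric(total_log2_effect),
      contamination = as.numeric(contamination),
      dispersion = as.numeric(dispersion),
      baseline_log_mean = as.numeric(baseline_log_mean),
      baseline_log_sd = as.numeric(baseline_log_sd),
      reference_log2_drift = as.numeric(reference_log2_drift),
      seed = as.integer(seed))
}

#' Ground truth of a simulated study
#'
#' Records the true relative abundance of every miRNA in each compartment's
#' RNA pool (before contamination and sampling) per condition, plus the
#' planted mitomiR flags. Each pool column sums to one.
#'
#' @slot mito_abundance,total_abundance miRNA x condition matrices of
#'   relative abundances; columns sum to 1.
#' @slot is_mitomir logical flag per miRNA.
#' @slot planted_pathway id of the pathway planted by [simulateAnnotation()],
#'   or `NA` before annotation is generated.
#' @aliases MitomirTruth-class
#' @exportClass MitomirTruth
setClass("MitomirTruth",
  representation(
    mito_abundance = "matrix",
    total_abundance = "matrix",
    is_mitomir = "logical",
    planted_pathway = "character"))

setValidity("MitomirTruth", function(object) {
  msg <- character()
  for (nm in c("mito_abundance", "total_abundance")) {
    a <- slot(object, nm)
    if (any(a < 0)) msg <- c(msg, paste0(nm, " must be non-negative"))
    if (any(abs(colSums(a) - 1) > 1e-12))
      msg <- c(msg, paste0(nm, " columns must sum to 1"))
  }
  if (length(object@is_mitomir) != nrow(object@mito_abundance))
    msg <- c(msg, "is_mitomir length must equal the number of miRNAs")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@n_mirnas, "miRNAs,",
      length(object@mitomir_indices), "planted mitomiRs\n")
  cat("  conditions:", paste(object@conditions, collapse = ", "),
      "| library size:", format(object@library_size, big.mark = ","), "\n")
  cat("  contamination phi =", object@contamination,
      "| dispersion =", object@dispersion,
      "| seed =", object@seed, "\n")
})

setMethod("show", "MitomirTruth", function(object) {
  cat("MitomirTruth:", nrow(object@mito_abundance), "miRNAs,",
      sum(object@is_mitomir), "planted mitomiRs,",
      ncol(object@mito_abundance), "conditions\n")
  if (!is.na(object@planted_pathway))
    cat("  planted pathway:", object@planted_pathway, "\n")
})
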