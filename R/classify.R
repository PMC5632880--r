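#' Classify a miRNA as mitochondria-enriched
#'
#' Decision rule for compartment-fractionation studies: a miRNA is
#' *enriched* in mitochondria of the failing heart when its
#' mitochondrial-fraction fold change (TAC over sham) strictly exceeds
#' `fc_up` with supporting significance (`mito_p < alpha`, or no p-value
#' available, as for qPCR point estimates), while its whole-tissue fold
#' change is decreased or unchanged — operationalized as
#' `total_fold <= 1 + unchanged_tolerance`. A miRNA meeting the
#' mitochondrial criteria but also rising in total RNA, or failing the
#' mitochondrial criteria, is *not_enriched*; a missing required input
#' makes it *indeterminate*.
#'
#' @param mito_fold positive mitochondrial-fraction fold change(s).
#' @param mito_p p-value(s) for the mitochondrial change, or `NA` when the
#'   evidence is a qPCR estimate without a test.
#' @param total_fold positive whole-tissue fold change(s).
#' @param mirna_id optional ids carried through to the output.
#' @param fc_up mitochondrial fold-change threshold (default 2).
#' @param alpha significance threshold (default 0.05).
#' @param unchanged_tolerance how far above 1 the total fold may sit and
#'   still count as "unchanged" (default 0.2, i.e. total fold <= 1.2).
#' @return data.frame with columns `mirna`, `mito_fold`, `mito_p`,
#'   `total_fold`, `classification` (`enriched` / `not_enriched` /
#'   `indeterminate`) and a machine-readable `rationale` code.
#' @examples
#' classifyMitomir(2^2.91, 0.0013, 0.8)   # enriched
#' classifyMitomir(4, 0.01, 4)            # rises in both: not_enriched
#' @export
classifyMitomir <- function(mito_fold, mito_p = NA_real_, total_fold,
                            mirna_id = NULL, fc_up = 2, alpha = 0.05,
                            unchanged_tolerance = 0.2) {
  .assertScalarNum(fc_up, "fc_up", 1, strict_lower = TRUE)
  .assertScalarNum(alpha, "alpha", 0, 1)
  .assertScalarNum(unchanged_tolerance, "unchanged_tolerance", 0)
  m <- max(length(mito_fold), length(total_fold), length(mito_p))
  mito_fold <- rep_len(as.numeric(mito_fold), m)
  total_fold <- rep_len(as.numeric(total_fold), m)
  mito_p <- rep_len(as.numeric(mito_p), m)
  if (is.null(mirna_id)) mirna_id <- rep(NA_character_, m)
  if (any(mito_fold <= 0 | total_fold <= 0, na.rm = TRUE))
    stop("fold changes must be positive", call. = FALSE)

  flat_cap <- 1 + unchanged_tolerance
  cls <- rat <- character(m)
  for (i in seq_len(m)) {
    if (is.na(mito_fold[i]) || is.na(total_fold[i])) {
      cls[i] <- "indeterminate"
      rat[i] <- if (is.na(mito_fold[i])) "missing_mito_evidence"
                else "missing_total_evidence"
      next
    }
    mito_up <- mito_fold[i] > fc_up &&
      (is.na(mito_p[i]) || mito_p[i] < alpha)
    if (!mito_up) {
      cls[i] <- "not_enriched"
      rat[i] <- if (mito_fold[i] > fc_up) "mito_not_significant"
                else "mito_not_up"
    } else if (total_fold[i] <= flat_cap) {
      cls[i] <- "enriched"
      rat[i] <- "mito_up_total_flat_or_down"
    } else {
      cls[i] <- "not_enriched"
      rat[i] <- "total_up"
    }
  }
  data.frame(mirna = mirna_id, mito_fold = mito_fold, mito_p = mito_p,
             total_fold = total_fold, classification = cls,
             rationale = rat, row.names = NULL)
}

#' Batch mitomiR classification from sequencing and qPCR evidence
#'
#' Joins mitochondrial-fraction evidence with whole-tissue fold changes for
#' a candidate list and applies [classifyMitomir()]. Mitochondrial evidence
#' defaults to the sequencing DE table (`2^log2_fc`, with its exact-test
#' p-value); when a mitochondrial qPCR table is also supplied its fold
#' change takes precedence (qPCR being the validation instrument) and no
#' p-value is attached. Candidates absent from either evidence table come
#' back *indeterminate*. No multiple-testing adjustment is applied across
#' candidates.
#'
#' @param de_mito data.frame with `mirna`, `log2_fc`, `p_value`
#'   (mitochondrial-fraction DE, one condition pair).
#' @param qpcr_total data.frame with `mirna`, `fold_change` (whole-tissue
#'   qPCR fold changes for the same pair); extra columns such as
#'   `compartment` / `condition` should be filtered by the caller.
#' @param candidate_ids miRNA ids to classify.
#' @param qpcr_mito optional data.frame with `mirna`, `fold_change` for the
#'   mitochondrial fraction, overriding the sequencing folds.
#' @inheritParams classifyMitomir
#' @return a [classifyMitomir()] table, one row per candidate.
#' @export
classifyBatch <- function(de_mito, qpcr_total, candidate_ids,
                          qpcr_mito = NULL, fc_up = 2, alpha = 0.05,
                          unchanged_tolerance = 0.2) {
  stopifnot(is.data.frame(de_mito), is.data.frame(qpcr_total))
  if (anyDuplicated(candidate_ids))
    stop("duplicate candidate ids", call. = FALSE)
  for (nm in c("de_mito", "qpcr_total")) {
    tab <- get(nm)
    if (nrow(tab) && anyDuplicated(tab$mirna))
      stop("duplicate miRNA ids in ", nm, call. = FALSE)
  }
  i_de <- match(candidate_ids, de_mito$mirna)
  mito_fold <- 2^de_mito$log2_fc[i_de]
  mito_p <- de_mito$p_value[i_de]
  if (!is.null(qpcr_mito) && nrow(qpcr_mito)) {
    if (anyDuplicated(qpcr_mito$mirna))
      stop("duplicate miRNA ids in qpcr_mito", call. = FALSE)
    i_q <- match(candidate_ids, qpcr_mito$mirna)
    use <- !is.na(i_q)
    mito_fold[use] <- qpcr_mito$fold_change[i_q[use]]
    mito_p[use] <- NA_real_
  }
  i_t <- match(candidate_ids,
               if (nrow(qpcr_total)) qpcr_total$mirna else character())
  total_fold <- if (nrow(qpcr_total)) qpcr_total$fold_change[i_t]
                else rep(NA_real_, length(candidate_ids))
  classifyMitomir(mito_fold, mito_p, total_fold, mirna_id = candidate_ids,
                  fc_up = fc_up, alpha = alpha,
                  unchanged_tolerance = unchanged_tolerance)
}
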