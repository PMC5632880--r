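#' Collect the putative target set of a miRNA list
#'
#' Filters a scored target map at a strict score threshold (microT-style,
#' score > 0.9 by default) and returns the union of the retained target
#' genes over the input miRNAs, plus the per-miRNA sets needed to count
#' contributing miRNAs per pathway. A miRNA absent from the map contributes
#' an empty set, with a warning.
#'
#' @param mirnas non-empty character vector of miRNA ids.
#' @param target_map data.frame with columns `mirna`, `gene`,
#'   `score` in `[0, 1]`.
#' @param score_threshold retain edges with `score` strictly greater
#'   (default 0.9).
#' @return list with `genes` (character union) and `per_mirna` (named list
#'   of character vectors).
#' @export
collectTargets <- function(mirnas, target_map, score_threshold = 0.9) {
  if (!length(mirnas))
    stop("'mirnas' must be non-empty", call. = FALSE)
  stopifnot(is.data.frame(target_map),
            all(c("mirna", "gene", "score") %in% names(target_map)))
  if (any(target_map$score < 0 | target_map$score > 1, na.rm = TRUE))
    stop("target scores must lie in [0, 1]", call. = FALSE)
  absent <- setdiff(mirnas, target_map$mirna)
  if (length(absent))
    warning(length(absent), " miRNA(s) absent from the target map: ",
            paste(head(absent, 5L), collapse = ", "), call. = FALSE)
  kept <- target_map[target_map$score > score_threshold &
                       target_map$mirna %in% mirnas, , drop = FALSE]
  per <- lapply(setNames(as.list(mirnas), mirnas),
                function(m) unique(kept$gene[kept$mirna == m]))
  list(genes = unique(kept$gene), per_mirna = per)
}

#' Hypergeometric pathway enrichment of a target gene set
#'
#' For each pathway with \eqn{K} genes inside a universe of \eqn{M} genes,
#' given a target set of \eqn{n} universe genes with \eqn{k} of them in the
#' pathway, the one-sided upper-tail p-value is
#' \deqn{p = \sum_{i=k}^{\min(n, K)} \frac{\binom{K}{i}\binom{M-K}{n-i}}
#' {\binom{M}{n}},} computed with [stats::phyper()]. P-values are BH-adjusted
#' across pathways; `significant` flags q < 0.05. Target genes outside the
#' universe are dropped with a warning. The default universe is the union of
#' all pathway genes; a wider universe (e.g. all genes in the target map)
#' may be supplied.
#'
#' @param targets character vector of target genes (e.g.
#'   `collectTargets(...)$genes`).
#' @param pathways named list of gene-set character vectors (the shape
#'   returned by [readGmt()] / [simulateAnnotation()]).
#' @param universe optional background gene set; pathway genes outside a
#'   supplied universe are trimmed (with a message) so set sizes stay
#'   consistent with the background.
#' @param mirna_sets optional named list of per-miRNA target sets (from
#'   [collectTargets()]) used to count contributing miRNAs per pathway.
#' @param pathway_names optional named character vector of descriptions.
#' @return data.frame with columns `pathway_id`, `name`, `p_value`,
#'   `q_value`, `n_mirnas_hit`, `n_targets_hit`, `pathway_size`,
#'   `significant`, in input pathway order.
#' @examples
#' pw <- list(A = paste0("g", 1:5))
#' hypergeomEnrich(paste0("g", c(1:4, 10)), pw, universe = paste0("g", 1:20))
#' @export
hypergeomEnrich <- function(targets, pathways, universe = NULL,
                            mirna_sets = NULL, pathway_names = NULL) {
  stopifnot(is.list(pathways), length(pathways) > 0L,
            !is.null(names(pathways)))
  if (is.null(universe)) universe <- unique(unlist(pathways))
  universe <- unique(as.character(universe))
  if (!length(universe))
    stop("the gene universe is empty", call. = FALSE)
  pathways <- lapply(pathways, unique)
  trimmed <- vapply(pathways, function(g) sum(!g %in% universe), integer(1))
  if (any(trimmed > 0)) {
    message(sum(trimmed), " pathway gene(s) outside the universe trimmed")
    pathways <- lapply(pathways, intersect, y = universe)
  }
  targets <- unique(as.character(targets))
  outside <- setdiff(targets, universe)
  if (length(outside)) {
    warning(length(outside), " target gene(s) outside the universe dropped",
            call. = FALSE)
    targets <- intersect(targets, universe)
  }
  M <- length(universe)
  n <- length(targets)
  K <- lengths(pathways)
  k <- vapply(pathways, function(g) length(intersect(targets, g)), integer(1))
  # upper tail P(X >= k); k = 0 gives the whole support, p = 1
  p <- phyper(k - 1L, K, M - K, n, lower.tail = FALSE)
  p <- pmin(1, pmax(0, p))
  n_mir <- if (is.null(mirna_sets)) NA_integer_ else
    vapply(pathways, function(g)
      sum(vapply(mirna_sets, function(s) length(intersect(s, g)) > 0L,
                 logical(1))), integer(1))
  nm <- if (is.null(pathway_names)) names(pathways) else
    unname(pathway_names[names(pathways)])
  res <- data.frame(pathway_id = names(pathways),
                    name = nm,
                    p_value = unname(p),
                    q_value = bhFdr(unname(p)),
                    n_mirnas_hit = unname(n_mir),
                    n_targets_hit = unname(k),
                    pathway_size = unname(K),
                    row.names = NULL)
  res$significant <- res$q_value < 0.05
  res
}

#' Rank an enrichment table for reporting
#'
#' Orders pathways by ascending p-value, ties broken lexicographically by
#' pathway id, and optionally truncates to the top rows — the layout of a
#' ranked enriched-pathway listing with miRNA-hit and target-hit counts.
#'
#' @param results a [hypergeomEnrich()] table.
#' @param top_n optional number of rows to keep.
#' @return the reordered (and possibly truncated) data.frame.
#' @export
enrichmentReport <- function(results, top_n = NULL) {
  stopifnot(is.data.frame(results),
            all(c("pathway_id", "p_value") %in% names(results)))
  res <- results[order(results$p_value, results$pathway_id), , drop = FALSE]
  rownames(res) <- NULL
  if (!is.null(top_n)) res <- head(res, top_n)
  res
}
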