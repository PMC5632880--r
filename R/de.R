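#' Counts-per-million normalization
#'
#' Scales each count by \eqn{10^6 / library\_size}. When the declared
#' library size equals the column sum, each CPM column sums to exactly
#' \eqn{10^6}; declared sizes larger than the column sum (reads not mapping
#' to known miRNAs) give column sums below \eqn{10^6}.
#'
#' @param x a [MitomirExperiment-class], or a count matrix.
#' @param library_size numeric vector of library sizes; required when `x` is
#'   a bare matrix, taken from `colData` otherwise.
#' @return numeric matrix of CPM values with the dimnames of `x`.
#' @export
cpmNormalize <- function(x, library_size = NULL) {
  if (is(x, "MitomirExperiment")) {
    library_size <- librarySizes(x)
    x <- counts(x)
  }
  x <- as.matrix(x)
  if (is.null(library_size))
    stop("'library_size' is required for a bare matrix", call. = FALSE)
  if (length(library_size) != ncol(x))
    stop("one library size per column is required", call. = FALSE)
  if (any(!is.finite(library_size)) || any(library_size <= 0))
    stop("library sizes must be positive", call. = FALSE)
  sweep(x, 2L, library_size, "/") * 1e6
}

.exactP <- function(x1, n, prob, method) {
  if (n == 0L) return(1)
  if (method == "minlike") {
    # two-sided by the minimum-likelihood rule: sum all outcomes no more
    # probable than the observed one (relative tolerance as in binom.test)
    d0 <- dbinom(x1, n, prob) * (1 + 1e-7)
    d <- dbinom(0:n, n, prob)
    min(1, sum(d[d <= d0]))
  } else {
    min(1, 2 * min(pbinom(x1, n, prob),
                   1 - pbinom(x1 - 1, n, prob)))
  }
}

#' Exact test for two unreplicated count libraries
#'
#' The "exact Poisson" test for differential abundance between two pooled
#' libraries without replicates. Modelling the two counts as independent
#' Poisson draws with rates proportional to library size times relative
#' abundance, and conditioning on the total \eqn{n = x_1 + x_2}, the first
#' count is \eqn{Binomial(n, \pi)} with \eqn{\pi = N_1 / (N_1 + N_2)} under
#' the null hypothesis of equal relative abundance. The two-sided p-value
#' sums all binomial outcomes whose point mass does not exceed the observed
#' one (`method = "minlike"`, the usual exact-binomial convention) or doubles
#' the smaller tail (`method = "doubled"`). `n = 0` carries no information
#' and yields p = 1.
#'
#' @param x1,x2 observed counts (vectorized, recycled).
#' @param n1,n2 library sizes.
#' @param method `"minlike"` (default) or `"doubled"`.
#' @return vector of p-values in `[0, 1]`.
#' @examples
#' exactPoissonTest(10, 0, 1e6, 1e6)  # 2 / 2^10
#' @export
exactPoissonTest <- function(x1, x2, n1, n2,
                             method = c("minlike", "doubled")) {
  method <- match.arg(method)
  .assertCounts(x1, "x1"); .assertCounts(x2, "x2")
  if (any(!is.finite(c(n1, n2))) || any(c(n1, n2) <= 0))
    stop("library sizes must be positive", call. = FALSE)
  m <- max(length(x1), length(x2), length(n1), length(n2))
  x1 <- rep_len(x1, m); x2 <- rep_len(x2, m)
  n1 <- rep_len(n1, m); n2 <- rep_len(n2, m)
  vapply(seq_len(m), function(i)
    .exactP(x1[i], x1[i] + x2[i], n1[i] / (n1[i] + n2[i]), method),
    numeric(1))
}

#' Log2 fold change between two libraries on the CPM scale
#'
#' \eqn{\log_2((x_2 10^6/N_2 + c) / (x_1 10^6/N_1 + c))} with pseudo-CPM
#' `c`, i.e. the second library relative to the first (TAC over sham when
#' the pair is (sham, TAC)). With `pseudo_cpm = 0` a double-zero row has no
#' defined ratio and is reported `NA`, never infinite.
#'
#' @inheritParams exactPoissonTest
#' @param pseudo_cpm non-negative pseudo-count on the CPM scale added to
#'   both sides (default 0.5) so single-zero rows stay finite.
#' @return numeric vector of log2 fold changes (`NA` where undefined).
#' @export
log2FoldChange <- function(x1, x2, n1, n2, pseudo_cpm = 0.5) {
  .assertCounts(x1, "x1"); .assertCounts(x2, "x2")
  .assertScalarNum(pseudo_cpm, "pseudo_cpm", 0)
  if (any(!is.finite(c(n1, n2))) || any(c(n1, n2) <= 0))
    stop("library sizes must be positive", call. = FALSE)
  cpm1 <- x1 * 1e6 / n1
  cpm2 <- x2 * 1e6 / n2
  out <- log2((cpm2 + pseudo_cpm) / (cpm1 + pseudo_cpm))
  out[cpm1 + pseudo_cpm == 0 & cpm2 + pseudo_cpm == 0] <- NA_real_
  out[is.infinite(out)] <- NA_real_
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (q-values): for sorted \eqn{p_{(1)} \le \dots
#' \le p_{(m)}}, \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, clamped at 1
#' and mapped back to input order. Delegates to
#' [stats::p.adjust()] after validating the input.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @return q-values in input order.
#' @export
bhFdr <- function(p) {
  if (!is.numeric(p))
    stop("'p' must be numeric", call. = FALSE)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Call differential expression at fold-change and significance thresholds
#'
#' A miRNA is called `up` when its fold change strictly exceeds `fc_up`
#' (log2 scale: `log2_fc > log2(fc_up)`) and its p-value (or q-value with
#' `use_q = TRUE`) is strictly below `alpha`; `down` symmetrically with
#' `fc_down`; `ns` otherwise. Rows with an undefined fold change are `ns`.
#'
#' @param results data.frame with columns `log2_fc`, `p_value` and (if
#'   `use_q`) `q_value`.
#' @param fc_up,fc_down linear-scale fold-change thresholds,
#'   `0 < fc_down < 1 < fc_up` (defaults 2 and 0.5).
#' @param alpha significance threshold (default 0.05).
#' @param use_q use BH q-values instead of raw p-values.
#' @return `results` with a `call` column (`"up"`, `"down"`, `"ns"`).
#' @export
callDE <- function(results, fc_up = 2, fc_down = 0.5, alpha = 0.05,
                   use_q = FALSE) {
  stopifnot(is.data.frame(results),
            all(c("log2_fc", "p_value") %in% names(results)))
  .assertScalarNum(fc_up, "fc_up", 1, strict_lower = TRUE)
  .assertScalarNum(fc_down, "fc_down", 0, 1,
                   strict_lower = TRUE, strict_upper = TRUE)
  .assertScalarNum(alpha, "alpha", 0, 1)
  pv <- if (use_q) {
    if (!"q_value" %in% names(results))
      stop("'q_value' column required when use_q = TRUE", call. = FALSE)
    results$q_value
  } else results$p_value
  lfc <- results$log2_fc
  call <- rep("ns", nrow(results))
  call[!is.na(lfc) & !is.na(pv) & lfc > log2(fc_up) & pv < alpha] <- "up"
  call[!is.na(lfc) & !is.na(pv) & lfc < log2(fc_down) & pv < alpha] <- "down"
  results$call <- call
  results
}

#' Pairwise two-library differential expression profiles
#'
#' For each requested condition pair within one compartment, keeps the
#' miRNAs detected (count >= `min_count`) in at least one of the two
#' libraries, runs the exact conditional binomial test per miRNA, adjusts by
#' BH across the retained miRNAs of that pair, and calls up/down at the
#' fold-change and significance thresholds.
#'
#' @param x a [MitomirExperiment-class].
#' @param pairs list of 2-vectors of condition labels; default all ordered
#'   pairs of the conditions present, in declared order. The fold change is
#'   the second condition over the first.
#' @param compartment which compartment's libraries to compare.
#' @param min_count detection threshold in reads (default 1).
#' @param pseudo_cpm pseudo-CPM for the fold change (default 0.5).
#' @inheritParams callDE
#' @param method two-sided convention of [exactPoissonTest()].
#' @return named list (`"<cond1>_vs_<cond2>"`) of data.frames with columns
#'   `mirna`, `count_1`, `count_2`, `log2_fc`, `p_value`, `q_value`, `call`.
#' @export
pairwiseProfile <- function(x, pairs = NULL, compartment = "mitochondrial",
                            min_count = 1, pseudo_cpm = 0.5, fc_up = 2,
                            fc_down = 0.5, alpha = 0.05, use_q = FALSE,
                            method = "minlike") {
  stopifnot(is(x, "MitomirExperiment"))
  comp <- compartments(x)
  cond <- conditions(x)
  keep <- comp == compartment
  if (!any(keep))
    stop("no libraries in compartment '", compartment, "'", call. = FALSE)
  conds <- unique(cond[keep])
  if (is.null(pairs)) {
    pairs <- list()
    for (i in seq_along(conds))
      for (j in seq_along(conds))
        if (i < j) pairs[[length(pairs) + 1L]] <- c(conds[i], conds[j])
  }
  cnt <- counts(x)
  ls <- librarySizes(x)
  out <- list()
  for (pr in pairs) {
    idx <- vapply(pr, function(cc) {
      w <- which(keep & cond == cc)
      if (length(w) != 1L)
        stop("condition '", cc, "' must have exactly one library in ",
             "compartment '", compartment, "'", call. = FALSE)
      w
    }, integer(1))
    x1 <- cnt[, idx[1]]; x2 <- cnt[, idx[2]]
    n1 <- ls[idx[1]]; n2 <- ls[idx[2]]
    det <- x1 >= min_count | x2 >= min_count
    df <- data.frame(
      mirna = rownames(cnt)[det],
      count_1 = x1[det],
      count_2 = x2[det],
      log2_fc = log2FoldChange(x1[det], x2[det], n1, n2, pseudo_cpm),
      p_value = exactPoissonTest(x1[det], x2[det], n1, n2, method),
      row.names = NULL)
    df$q_value <- bhFdr(df$p_value)
    df <- callDE(df, fc_up = fc_up, fc_down = fc_down, alpha = alpha,
                 use_q = use_q)
    out[[paste0(pr[1], "_vs_", pr[2])]] <- df
  }
  out
}

#' Hierarchical clustering of expression rows for heatmap display
#'
#' Agglomerative average-linkage clustering with distance
#' \eqn{1 - Pearson correlation} across libraries, the common convention for
#' expression heatmaps. Rows with zero variance have no defined correlation;
#' they are assigned the maximal distance, excluded from the tree, and
#' appended after the clustered rows in the returned leaf order (with a
#' warning).
#'
#' @param mat numeric matrix with at least 2 rows (e.g. log CPM).
#' @return list with `order` (integer leaf order for the heatmap), `tree`
#'   (an [stats::hclust] object over the non-constant rows, or `NULL` if
#'   fewer than 2), and `constant_rows` (indices placed last).
#' @export
hierarchicalCluster <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L)
    stop("need at least 2 rows to cluster", call. = FALSE)
  sds <- apply(mat, 1L, stats::sd)
  const <- unname(which(sds == 0 | !is.finite(sds)))
  if (length(const))
    warning(length(const), " zero-variance row(s) placed last with maximal ",
            "distance", call. = FALSE)
  var_rows <- setdiff(seq_len(nrow(mat)), const)
  if (length(var_rows) < 2L)
    return(list(order = c(var_rows, const), tree = NULL,
                constant_rows = const))
  d <- as.dist(1 - cor(t(mat[var_rows, , drop = FALSE])))
  tree <- hclust(d, method = "average")
  list(order = c(var_rows[tree$order], const), tree = tree,
       constant_rows = const)
}
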