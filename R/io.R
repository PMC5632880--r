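# Readers and writers for the package's plain-text dialects: TSV with a
# mandatory header, UTF-8, "." decimal; GMT as name <TAB> description
# <TAB> genes...; Ct records as CSV. All writers are atomic
# (temp-then-rename) so a crashed run never leaves a half-written table.

.writeTable <- function(df, path, sep = "\t") {
  .atomicWrite(path, function(tmp)
    write.table(df, tmp, sep = sep, quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8"))
}

#' Write / read a generic results TSV
#'
#' @param df a data.frame.
#' @param path file path.
#' @return `writeTsv` the path invisibly; `readTsv` a data.frame.
#' @export
writeTsv <- function(df, path) .writeTable(df, path)

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write and read the miRNA count-table dialect
#'
#' The count table is a TSV whose first column `mirna` holds the miRNA ids
#' and whose remaining columns are libraries of integer counts; the side-car
#' metadata TSV has columns `library_id`, `compartment`, `condition`,
#' `library_size`. `readCountTable()` validates integrality (naming the
#' offending row and column), uniqueness of ids, non-negativity and the
#' metadata contract, and returns a [MitomirExperiment-class];
#' `writeCountTable()` writes both files atomically. A write of a read
#' round-trips byte-identically.
#'
#' @param x a [MitomirExperiment-class].
#' @param counts_file,meta_file paths of the count TSV and metadata TSV.
#' @return `readCountTable()` a [MitomirExperiment-class];
#'   `writeCountTable()` the count path, invisibly.
#' @export
writeCountTable <- function(x, counts_file, meta_file) {
  stopifnot(is(x, "MitomirExperiment"))
  cnt <- counts(x)
  df <- data.frame(mirna = rownames(cnt), cnt, check.names = FALSE)
  .writeTable(df, counts_file)
  meta <- data.frame(library_id = colnames(cnt),
                     compartment = unname(compartments(x)),
                     condition = unname(conditions(x)),
                     library_size = unname(librarySizes(x)))
  .writeTable(meta, meta_file)
  invisible(counts_file)
}

#' @rdname writeCountTable
#' @export
readCountTable <- function(counts_file, meta_file) {
  nf <- utils::count.fields(counts_file, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L)
    stop("malformed count table '", counts_file, "': line ",
         which(nf != nf[1L])[1L], " has ", nf[nf != nf[1L]][1L],
         " fields, expected ", nf[1L], call. = FALSE)
  df <- tryCatch(
    read.delim(counts_file, check.names = FALSE, stringsAsFactors = FALSE,
               colClasses = NA),
    error = function(e)
      stop("malformed count table '", counts_file, "': ",
           conditionMessage(e), call. = FALSE))
  if (ncol(df) < 2L || names(df)[1] != "mirna")
    stop("count table must start with a 'mirna' column", call. = FALSE)
  ids <- as.character(df$mirna)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicated miRNA id(s) in count table: ",
         paste(unique(head(dup, 5L)), collapse = ", "), call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  for (j in seq_len(ncol(m))) {
    col <- suppressWarnings(as.numeric(m[, j]))
    bad <- which(!is.finite(col) | col < 0 | abs(col - round(col)) > 1e-8)
    if (length(bad))
      stop("non-integer or negative count at row ", bad[1L], " (",
           ids[bad[1L]], "), column '", colnames(m)[j], "'", call. = FALSE)
  }
  storage.mode(m) <- if (max(m) <= .Machine$integer.max) "integer" else
    "numeric"
  rownames(m) <- ids
  meta <- read.delim(meta_file, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("library_id", "compartment", "condition", "library_size")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!setequal(meta$library_id, colnames(m)) ||
      anyDuplicated(meta$library_id))
    stop("metadata library ids do not match count-table columns",
         call. = FALSE)
  meta <- meta[match(colnames(m), meta$library_id), , drop = FALSE]
  MitomirExperiment(m, meta$compartment, meta$condition, meta$library_size)
}

#' Write and read qPCR Ct records as CSV
#'
#' Long format with columns `mirna`, `compartment`, `condition`,
#' `replicate`, `ct`, `is_reference`; Ct values must lie in (0, 45) cycles.
#'
#' @param ct data.frame in the dialect above.
#' @param path CSV path.
#' @return `readCtCsv()` the validated data.frame; `writeCtCsv()` the path,
#'   invisibly.
#' @export
writeCtCsv <- function(ct, path) {
  .writeTable(ct, path, sep = ",")
  invisible(path)
}

#' @rdname writeCtCsv
#' @export
readCtCsv <- function(path) {
  ct <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("mirna", "compartment", "condition", "replicate", "ct",
            "is_reference")
  miss <- setdiff(need, names(ct))
  if (length(miss))
    stop("Ct CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(ct$ct) || any(!is.finite(ct$ct)))
    stop("'ct' column must be finite numeric", call. = FALSE)
  bad <- which(ct$ct <= 0 | ct$ct >= 45)
  if (length(bad))
    stop("Ct value out of (0, 45) at row ", bad[1L], " (",
         ct$mirna[bad[1L]], ")", call. = FALSE)
  ct$is_reference <- as.logical(ct$is_reference)
  if (any(is.na(ct$is_reference)))
    stop("'is_reference' must be logical", call. = FALSE)
  ct
}

#' Write and read a scored miRNA target map (TSV)
#'
#' Columns `mirna`, `gene`, `score`; duplicate (mirna, gene) pairs and
#' out-of-range scores are rejected.
#'
#' @param map data.frame with the columns above.
#' @param path TSV path.
#' @return `readTargetMap()` the validated data.frame; `writeTargetMap()`
#'   the path, invisibly.
#' @export
writeTargetMap <- function(map, path) {
  .writeTable(map, path)
  invisible(path)
}

#' @rdname writeTargetMap
#' @export
readTargetMap <- function(path) {
  map <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna", "gene", "score")
  if (!all(need %in% names(map)))
    stop("target map must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  dup <- duplicated(map[, c("mirna", "gene")])
  if (any(dup))
    stop("duplicate target-map pair: ", map$mirna[which(dup)[1L]], " / ",
         map$gene[which(dup)[1L]], call. = FALSE)
  if (!is.numeric(map$score) || any(!is.finite(map$score)) ||
      any(map$score < 0 | map$score > 1))
    stop("scores must be numeric in [0, 1]", call. = FALSE)
  map
}

#' Write and read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated member genes
#' (a single-gene set is valid). Reading delegates to
#' [fgsea::gmtPathways()] and validates name uniqueness.
#'
#' @param sets named list of character gene vectors.
#' @param path GMT path.
#' @param descriptions optional named character vector of set descriptions
#'   (defaults to the set name).
#' @return `readGmt()` a named list of gene vectors; `writeGmt()` the path,
#'   invisibly.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else nm
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  .atomicWrite(path, function(tmp) writeLines(lines, tmp, useBytes = TRUE))
  invisible(path)
}

#' @rdname writeGmt
#' @export
readGmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set names in '", path, "'", call. = FALSE)
  if (any(lengths(sets) == 0L))
    stop("empty gene set in '", path, "'", call. = FALSE)
  sets
}

#' Serialize a simulation ground truth to JSON
#'
#' @param truth a [MitomirTruth-class].
#' @param path JSON path.
#' @return the path, invisibly.
#' @export
writeTruthJson <- function(truth, path) {
  stopifnot(is(truth, "MitomirTruth"))
  obj <- list(
    mirna = rownames(truth@mito_abundance),
    conditions = colnames(truth@mito_abundance),
    mito_abundance = unname(apply(truth@mito_abundance, 2L, as.numeric,
                                  simplify = FALSE)),
    total_abundance = unname(apply(truth@total_abundance, 2L, as.numeric,
                                   simplify = FALSE)),
    is_mitomir = unname(truth@is_mitomir),
    planted_pathway = truth@planted_pathway)
  .atomicWrite(path, function(tmp)
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA))
  invisible(path)
}
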