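#' Accessors for MitomirExperiment and MitomirTruth
#'
#' `counts()` returns the raw count matrix, `compartments()` and
#' `conditions()` the per-library metadata, `librarySizes()` the declared
#' library sizes (named by library id). `isMitomir()` and `trueAbundance()`
#' expose the simulator's ground truth.
#'
#' @param object a [MitomirExperiment-class] or [MitomirTruth-class].
#' @param ... unused.
#' @return vectors / matrices as described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("compartments", function(object, ...) standardGeneric("compartments"))

#' @rdname accessors
#' @export
setGeneric("conditions", function(object, ...) standardGeneric("conditions"))

#' @rdname accessors
#' @export
setGeneric("librarySizes", function(object, ...) standardGeneric("librarySizes"))

#' @rdname accessors
#' @export
setGeneric("isMitomir", function(object, ...) standardGeneric("isMitomir"))

#' @rdname accessors
#' @param compartment `"mitochondrial"` or `"total"` pool.
#' @export
setGeneric("trueAbundance",
           function(object, compartment = c("mitochondrial", "total"), ...)
             standardGeneric("trueAbundance"))

#' @rdname accessors
#' @importFrom BiocGenerics counts
#' @export counts
#' @exportMethods counts
NULL
setMethod(BiocGenerics::counts, "MitomirExperiment", function(object, ...)
  SummarizedExperiment::assay(object, "counts"))

#' @rdname accessors
#' @export
setMethod("compartments", "MitomirExperiment", function(object, ...)
  setNames(SummarizedExperiment::colData(object)$compartment, colnames(object)))

#' @rdname accessors
#' @export
setMethod("conditions", "MitomirExperiment", function(object, ...)
  setNames(SummarizedExperiment::colData(object)$condition, colnames(object)))

#' @rdname accessors
#' @export
setMethod("librarySizes", "MitomirExperiment", function(object, ...)
  setNames(SummarizedExperiment::colData(object)$library_size, colnames(object)))

#' @rdname accessors
#' @export
setMethod("isMitomir", "MitomirTruth", function(object, ...)
  setNames(object@is_mitomir, rownames(object@mito_abundance)))

#' @rdname accessors
#' @export
setMethod("trueAbundance", "MitomirTruth",
  function(object, compartment = c("mitochondrial", "total"), ...) {
    compartment <- match.arg(compartment)
    if (compartment == "mitochondrial") object@mito_abundance
    else object@total_abundance
  })

setMethod("show", "MitomirExperiment", function(object) {
  cat("MitomirExperiment:", nrow(object), "miRNAs x", ncol(object), "libraries\n")
  cd <- SummarizedExperiment::colData(object)
  print(table(compartment = cd$compartment, condition = cd$condition))
  invisible(NULL)
})
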