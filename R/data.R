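#' Reference differential-expression table of mitochondrial miRNAs in
#' pressure-overload heart failure
#'
#' Loads the packaged table of top differentially expressed miRNAs from
#' mitochondrial fractions of mouse hearts after transverse aortic
#' constriction (TAC), as published for the sham vs 4-week and sham vs
#' 8-week comparisons: miRBase-21 identifiers with the reported
#' log2 fold change (TAC over sham) and exact-test p-value. It is the
#' in-package reference input for the fold-change / significance filter
#' (fold > 2 or < 0.5, p < 0.05): applying [callDE()] to it yields 2
#' down-regulated miRNAs at 4 weeks and 6 at 8 weeks.
#'
#' @return data.frame with columns `comparison`, `mirna`, `log2_fc`,
#'   `p_value`.
#' @examples
#' ref <- referenceDeTable()
#' with(callDE(ref[ref$comparison == "sham_vs_tac4w", ]), table(call))
#' @export
referenceDeTable <- function() {
  path <- system.file("extdata", "tac_mito_de_top.tsv",
                      package = "mitomiRseq", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
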