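#' Reference-normalized Ct difference (delta-Ct)
#'
#' Averages the replicate Ct values of the target and of the reference gene
#' measured on the same sample and returns
#' \eqn{\Delta Ct = \overline{Ct}_{target} - \overline{Ct}_{reference}}.
#' Triplicates are expected; duplicates are accepted only with
#' `require_triplicate = FALSE`. Replicate spread beyond `max_spread` cycles
#' triggers a QC warning, never rejection.
#'
#' @param target,reference numeric vectors of replicate Ct values (cycles)
#'   for the target and the reference gene of one sample.
#' @param require_triplicate require exactly three replicates (default).
#' @param max_spread QC limit on max - min within a replicate set, cycles.
#' @return the delta-Ct in cycles.
#' @examples
#' deltaCt(c(25, 25, 25), c(20, 20, 20))  # 5
#' @export
deltaCt <- function(target, reference, require_triplicate = TRUE,
                    max_spread = 0.5) {
  .checkReps <- function(x, name) {
    if (!is.numeric(x) || any(!is.finite(x)))
      stop("'", name, "' replicate Cts must be finite numbers", call. = FALSE)
    if (any(x <= 0 | x >= 45))
      stop("'", name, "' Ct values must lie in (0, 45) cycles", call. = FALSE)
    n_ok <- if (require_triplicate) 3L else 2:3
    if (!length(x) %in% n_ok)
      stop("'", name, "' needs ", if (require_triplicate) "exactly 3" else
           "2 or 3", " replicates, got ", length(x), call. = FALSE)
    if (diff(range(x)) > max_spread)
      warning("'", name, "' replicate spread ",
              format(diff(range(x)), digits = 3),
              " cycles exceeds QC limit ", max_spread, call. = FALSE)
    x
  }
  mean(.checkReps(target, "target")) - mean(.checkReps(reference, "reference"))
}

#' Delta-delta-Ct fold change
#'
#' \eqn{\Delta\Delta Ct = \Delta Ct_{treatment} - \Delta Ct_{control}} and
#' fold change \eqn{2^{-\Delta\Delta Ct}}, assuming perfect per-cycle
#' doubling. Vectorized.
#'
#' @param dct_treatment,dct_control reference-normalized delta-Ct values.
#' @return data.frame with columns `delta_ct_treatment`, `delta_ct_control`,
#'   `ddct` and `fold_change`.
#' @examples
#' ddctFoldChange(4, 5)  # one cycle earlier: fold 2
#' @export
ddctFoldChange <- function(dct_treatment, dct_control) {
  if (any(!is.finite(dct_treatment)) || any(!is.finite(dct_control)))
    stop("delta-Ct inputs must be finite", call. = FALSE)
  ddct <- dct_treatment - dct_control
  data.frame(delta_ct_treatment = dct_treatment,
             delta_ct_control = rep_len(dct_control, length(ddct)),
             ddct = ddct,
             fold_change = 2^(-ddct))
}

#' Fold changes from a table of qPCR Ct records
#'
#' Groups a long-format Ct table (the dialect of [readCtCsv()] /
#' [simulateQpcr()]) by sample — a (compartment, condition) cell — averages
#' triplicates, normalizes each target against the reference gene of the
#' same sample, and reports \eqn{\Delta\Delta Ct} fold changes of every
#' non-control condition versus `control_condition`.
#'
#' @param ct data.frame with columns `mirna`, `condition`, `replicate`,
#'   `ct`, `is_reference` and optionally `compartment`.
#' @param control_condition the reference condition (default `"sham"`).
#' @inheritParams deltaCt
#' @return data.frame with columns `mirna`, `compartment`, `condition`,
#'   `delta_ct_treatment`, `delta_ct_control`, `ddct`, `fold_change`; one
#'   row per target x compartment x non-control condition.
#' @export
qpcrFoldChanges <- function(ct, control_condition = "sham",
                            require_triplicate = TRUE, max_spread = 0.5) {
  need <- c("mirna", "condition", "replicate", "ct", "is_reference")
  miss <- setdiff(need, names(ct))
  if (length(miss))
    stop("Ct table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"compartment" %in% names(ct)) ct$compartment <- "total"
  if (!control_condition %in% ct$condition)
    stop("control condition '", control_condition,
         "' absent from the Ct table", call. = FALSE)

  out <- list()
  for (comp in unique(ct$compartment)) {
    sub <- ct[ct$compartment == comp, , drop = FALSE]
    conds <- unique(sub$condition)
    targets <- unique(sub$mirna[!sub$is_reference])
    dct <- matrix(NA_real_, length(targets), length(conds),
                  dimnames = list(targets, conds))
    for (cc in conds) {
      cell <- sub[sub$condition == cc, , drop = FALSE]
      ref <- cell$ct[cell$is_reference]
      if (!length(ref))
        stop("no reference-gene record for sample (", comp, ", ", cc, ")",
             call. = FALSE)
      for (tg in unique(cell$mirna[!cell$is_reference]))
        dct[tg, cc] <- deltaCt(cell$ct[cell$mirna == tg & !cell$is_reference],
                               ref, require_triplicate, max_spread)
    }
    if (!control_condition %in% conds) next
    for (cc in setdiff(conds, control_condition)) {
      ok <- !is.na(dct[, cc]) & !is.na(dct[, control_condition])
      if (!any(ok)) next
      fc <- ddctFoldChange(dct[ok, cc], dct[ok, control_condition])
      out[[length(out) + 1L]] <- cbind(
        data.frame(mirna = rownames(dct)[ok], compartment = comp,
                   condition = cc, row.names = NULL),
        fc)
    }
  }
  if (!length(out))
    return(data.frame(mirna = character(), compartment = character(),
                      condition = character(),
                      delta_ct_treatment = numeric(),
                      delta_ct_control = numeric(), ddct = numeric(),
                      fold_change = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
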