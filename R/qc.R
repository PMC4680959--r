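#' Default hierarchical QC criteria
#'
#' The ordered criterion list of the hierarchical single-cell filter. Each
#' criterion names a QC metric, a comparator and a cutoff; criteria are
#' evaluated in order and a failing cell is attributed to the first
#' criterion it violates. The cutoffs are representative published
#' single-cell choices and are fully configurable; the hierarchy itself is
#' the tested structure.
#'
#' @return a data.frame with columns `criterion`, `metric`, `comparator`
#'   (`">="` or `"<="`) and `cutoff`, in evaluation order.
#' @examples
#' qcDefaultThresholds()
#' @export
qcDefaultThresholds <- function() {
    data.frame(
        criterion = c("min_total_fragments", "min_mapped_fraction",
            "min_genes_detected", "max_ercc_fraction",
            "max_top_gene_fraction"),
        metric = c("total_fragments", "mapped_fraction", "genes_detected",
            "ercc_fraction", "top_gene_fraction"),
        comparator = c(">=", ">=", ">=", "<=", "<="),
        cutoff = c(5e5, 0.5, 2000, 0.2, 0.25),
        stringsAsFactors = FALSE)
}

#' Hierarchical single-cell QC filter
#'
#' Applies an ordered list of QC criteria to per-cell metrics. A cell
#' passes only if it satisfies every criterion; a failing cell records all
#' violated criteria and is attributed to the first one in the hierarchy,
#' so per-criterion attributions partition the failures.
#'
#' @param metrics data.frame of per-cell QC metrics with a `cell` column
#'   (or rownames) and one column per metric named in `thresholds`.
#' @param thresholds ordered criterion table as in [qcDefaultThresholds()].
#' @return a list with `decisions` (data.frame: `cell`, `pass`,
#'   `first_failed` or `NA`, `failed` as a comma-separated list) and
#'   `summary` (`n_pass`, `n_fail`, named per-criterion attribution counts).
#' @examples
#' m <- data.frame(cell = "c1", total_fragments = 0, mapped_fraction = 0.9,
#'     genes_detected = 5000, ercc_fraction = 0.05, top_gene_fraction = 0.1)
#' qcFilter(m)$decisions
#' @export
qcFilter <- function(metrics, thresholds = qcDefaultThresholds()) {
    if (!"cell" %in% colnames(metrics))
        metrics$cell <- rownames(metrics)
    missing <- setdiff(thresholds$metric, colnames(metrics))
    if (length(missing))
        stop("unknown QC metric(s) in thresholds: ",
            paste(missing, collapse = ", "))
    if (!all(thresholds$comparator %in% c(">=", "<=")))
        stop("comparator must be '>=' or '<='")
    n <- nrow(metrics)
    ok <- matrix(TRUE, n, nrow(thresholds),
        dimnames = list(metrics$cell, thresholds$criterion))
    for (i in seq_len(nrow(thresholds))) {
        v <- metrics[[thresholds$metric[i]]]
        ok[, i] <- if (thresholds$comparator[i] == ">=")
            v >= thresholds$cutoff[i] else v <= thresholds$cutoff[i]
    }
    firstFail <- apply(ok, 1L, function(row)
        if (all(row)) NA_character_ else
            thresholds$criterion[which(!row)[1L]])
    decisions <- data.frame(
        cell = metrics$cell,
        pass = !rowSums(!ok),
        first_failed = firstFail,
        failed = apply(ok, 1L, function(row)
            paste(thresholds$criterion[!row], collapse = ",")),
        stringsAsFactors = FALSE)
    attribution <- table(factor(firstFail, levels = thresholds$criterion))
    list(decisions = decisions,
         summary = list(n_pass = sum(decisions$pass),
             n_fail = sum(!decisions$pass),
             attribution = c(attribution)))
}
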