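#' Train the PC1-sign cell-cycle classifier
#'
#' Calibrates a binary G1 vs S/G2-M classifier on a labeled reference:
#' expression of the cell-cycle gene panel is transformed to
#' log10(normalized counts + 1), centered on the reference gene means, and
#' the first principal axis of the reference is extracted. The axis is
#' oriented so that G1 reference samples project negative; the decision
#' rule is then simply the sign of the projection. A separation statistic
#' (between-label projection gap over the pooled within-label standard
#' deviation) measures how well the reference stages separate; training
#' warns when it is too small to support confident calls.
#'
#' @param reference normalized gene x sample reference matrix (or a
#'   `SummarizedExperiment` with a `normcounts` assay and `label` column).
#' @param labels character vector, `"G1"` or `"S/G2-M"` per reference
#'   sample (taken from `colData()` when `reference` is a
#'   `SummarizedExperiment`).
#' @param genes cell-cycle gene identifiers; at least 10 must be present
#'   in the reference.
#' @param minSeparation warn below this separation (default 2).
#' @return a [CellCycleModel-class].
#' @examples
#' ref <- generateReferenceCellCycle(SimConfig(seed = 1))
#' model <- trainCellCycle(ref)
#' model
#' @export
trainCellCycle <- function(reference, labels = NULL, genes = NULL,
                           minSeparation = 2) {
    if (methods::is(reference, "SummarizedExperiment")) {
        if (is.null(labels))
            labels <- SummarizedExperiment::colData(reference)$label
        reference <- SummarizedExperiment::assay(reference)
    }
    if (is.null(genes)) genes <- rownames(reference)
    labels <- as.character(labels)
    if (length(unique(labels)) < 2L)
        stop("both cell-cycle labels must be present in the reference")
    if (!"G1" %in% labels)
        stop("reference labels must include \"G1\"")
    genes <- intersect(genes, rownames(reference))
    if (length(genes) < 10L)
        stop("fewer than 10 cell-cycle genes overlap the reference")
    y <- logDisplay(reference[genes, , drop = FALSE])
    centers <- rowMeans(y)
    yc <- y - centers
    if (all(abs(yc) < 1e-12))
        stop("reference has no variance over the cell-cycle genes")
    pc <- prcomp(t(yc), center = FALSE, rank. = 1L)
    loadings <- pc$rotation[, 1L]
    loadings <- loadings / sqrt(sum(loadings^2))
    proj <- as.numeric(crossprod(yc, loadings))
    names(proj) <- colnames(y)
    if (mean(proj[labels == "G1"]) >= 0) {
        loadings <- -loadings
        proj <- -proj
    }
    g1 <- proj[labels == "G1"]; other <- proj[labels != "G1"]
    pooled <- sqrt((sum((g1 - mean(g1))^2) + sum((other - mean(other))^2)) /
        (length(proj) - 2L))
    sep <- if (pooled > 0) abs(mean(other) - mean(g1)) / pooled else Inf
    if (sep < minSeparation)
        warning(sprintf(
            "low label separation (%.2f): stage calls are low-confidence",
            sep))
    new("CellCycleModel", genes = genes, centers = centers,
        loadings = loadings, separation = sep, refProjections = proj,
        refLabels = labels)
}

#' Classify samples into cell-cycle stages
#'
#' Projects samples onto the trained reference axis and calls G1 for
#' negative projections, S/G2-M otherwise (the boundary at exactly zero is
#' closed on the positive side). Genes absent from the test matrix are
#' ignored as long as at least `minGenes` model genes remain.
#'
#' @param model a [CellCycleModel-class].
#' @param x normalized gene x sample matrix to classify.
#' @param minGenes minimum shared genes (default 10).
#' @return data.frame per sample: `sample`, `projection`, `stage`.
#' @examples
#' cfg <- SimConfig(seed = 1, n_cells = 4, n_canonical = 3, n_typeB = 1)
#' model <- trainCellCycle(generateReferenceCellCycle(cfg))
#' sce <- generateCohort(cfg)
#' counts <- SummarizedExperiment::assay(sce, "counts")
#' x <- normalizeCounts(counts, computeSizeFactors(counts,
#'     excludeSpikeIns = TRUE))
#' classifyCellCycle(model, x)
#' @export
classifyCellCycle <- function(model, x, minGenes = 10L) {
    shared <- intersect(model@genes, rownames(x))
    if (length(shared) < minGenes)
        stop("fewer than ", minGenes,
            " model genes are present in the test matrix")
    y <- logDisplay(x[shared, , drop = FALSE]) -
        model@centers[match(shared, model@genes)]
    proj <- as.numeric(crossprod(y,
        model@loadings[match(shared, model@genes)]))
    data.frame(sample = colnames(x), projection = proj,
        stage = ifelse(proj < 0, "G1", "S/G2-M"),
        stringsAsFactors = FALSE)
}
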