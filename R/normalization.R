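#' Median-of-ratios size factors
#'
#' Computes per-sample size factors by the median-of-ratios procedure: for
#' every gene with nonzero counts in all samples, the ratio of its count to
#' the gene's geometric mean across samples is formed, and the size factor
#' of a sample is the median of these ratios. ERCC spike-ins (gene ids
#' starting `"ERCC-"`) can be excluded, as is appropriate for single-cell
#' libraries where spike-in content is decoupled from cellular mRNA. For
#' sparse single-cell data an optional gene-mean floor restricts the median
#' to well-expressed genes.
#'
#' @param counts gene x sample matrix of raw counts (>= 2 samples).
#' @param excludeSpikeIns drop `"ERCC-"` genes before computing factors.
#' @param geneMeanFloor genes with mean raw count below this are excluded
#'   from the reference set (default 1).
#' @return named numeric vector of positive size factors, one per sample.
#' @examples
#' m <- matrix(c(10, 20, 20, 40, 30, 60), 3, 2, byrow = TRUE,
#'     dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' computeSizeFactors(m)  # 1/sqrt(2), sqrt(2)
#' @export
computeSizeFactors <- function(counts, excludeSpikeIns = FALSE,
                               geneMeanFloor = 1) {
    if (ncol(counts) < 2L)
        stop("at least 2 samples are required")
    if (excludeSpikeIns && !is.null(rownames(counts)))
        counts <- counts[!startsWith(rownames(counts), "ERCC-"), ,
            drop = FALSE]
    use <- rowSums(counts == 0) == 0L & rowMeans(counts) >= geneMeanFloor
    if (!any(use))
        stop("no gene has nonzero counts in every sample; ",
            "pseudo-reference fallback is disabled")
    lc <- log(counts[use, , drop = FALSE])
    logGeo <- rowMeans(lc)
    sf <- apply(lc, 2L, function(x) exp(median(x - logGeo)))
    if (any(!is.finite(sf) | sf <= 0))
        stop("non-positive size factor computed")
    sf
}

#' Normalize counts by size factors
#'
#' Divides each sample's counts by its size factor, yielding the normalized
#' counts all downstream thresholds of this package are expressed in.
#'
#' @param counts gene x sample matrix.
#' @param sizeFactors named factors from [computeSizeFactors()]; matched to
#'   `colnames(counts)` when named.
#' @return numeric matrix of normalized counts.
#' @export
normalizeCounts <- function(counts, sizeFactors) {
    if (!is.null(names(sizeFactors)) && !is.null(colnames(counts))) {
        if (!setequal(names(sizeFactors), colnames(counts)))
            stop("size-factor samples do not match count-matrix samples")
        sizeFactors <- sizeFactors[colnames(counts)]
    } else if (length(sizeFactors) != ncol(counts)) {
        stop("size-factor samples do not match count-matrix samples")
    }
    sweep(counts, 2L, sizeFactors, "/")
}

#' Display transform for heatmaps
#'
#' `log10(normalized counts + 1)`, the transform used for every heatmap and
#' for the cell-cycle classifier.
#'
#' @param x normalized counts.
#' @return transformed matrix.
#' @export
logDisplay <- function(x) log10(x + 1)

#' Sample-similarity matrix
#'
#' Spearman rank correlation between all pairs of samples of a normalized
#' matrix, the statistic used to compare single cells against bulk
#' references. Ties get average ranks; a constant sample yields `NA`
#' correlations, reported with a message.
#'
#' @param x normalized gene x sample matrix with >= 2 samples.
#' @param method correlation method (default `"spearman"`).
#' @return symmetric sample x sample correlation matrix, unit diagonal.
#' @export
sampleSimilarity <- function(x, method = "spearman") {
    if (ncol(x) < 2L) stop("at least 2 samples are required")
    const <- apply(x, 2L, function(v) length(unique(v)) == 1L)
    r <- suppressWarnings(cor(x, method = method))
    if (any(const))
        message("constant sample(s) with undefined correlation: ",
            paste(colnames(x)[const], collapse = ", "))
    r
}
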