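#' Two-group negative-binomial Wald test
#'
#' Per-gene differential expression between two sample groups under a
#' negative-binomial model: counts are normalized by median-of-ratios size
#' factors, a per-gene dispersion is estimated by the method of moments
#' from the pooled within-group variance (floored at 1e-8), and the Wald
#' statistic is the log2 fold change between group means divided by its
#' delta-method standard error. P-values are two-sided against a Student-t
#' reference with `nA + nB - 2` degrees of freedom (the small-sample
#' calibration appropriate for a plug-in variance); genes whose mean
#' normalized count falls below `minBaseMean` get a missing adjusted
#' p-value, mirroring independent filtering of weakly expressed genes.
#' This is a deliberately simple engine without dispersion shrinkage or
#' outlier replacement; its statistical contract (type-I error and FDR
#' control) is what downstream decisions rely on.
#'
#' @param counts gene x sample matrix of raw counts.
#' @param groupA,groupB disjoint character vectors of sample ids, each of
#'   size >= 2.
#' @param sizeFactors optional named size factors (computed on the union of
#'   the two groups when omitted).
#' @param minBaseMean below this mean normalized count `padj` is `NA`.
#' @param pseudocount added to group means before forming the fold change,
#'   so genes absent from one group remain testable.
#' @return data.frame with columns `gene`, `baseMean`, `log2FoldChange`,
#'   `lfcSE`, `stat`, `pvalue`, `padj`.
#' @examples
#' sce <- generateCohort(SimConfig(seed = 1, n_cells = 6, n_canonical = 4,
#'     n_typeB = 2))
#' cells <- colnames(sce)
#' de <- deTest(SummarizedExperiment::assay(sce, "counts"),
#'     cells[1:3], cells[4:6])
#' head(de)
#' @export
deTest <- function(counts, groupA, groupB, sizeFactors = NULL,
                   minBaseMean = 1, pseudocount = 0.5) {
    if (length(intersect(groupA, groupB)))
        stop("the two groups overlap")
    if (length(groupA) < 2L || length(groupB) < 2L)
        stop("each group needs at least 2 samples")
    samples <- c(groupA, groupB)
    if (!all(samples %in% colnames(counts)))
        stop("group sample(s) absent from the count matrix")
    counts <- counts[, samples, drop = FALSE]
    if (is.null(sizeFactors))
        sizeFactors <- computeSizeFactors(counts, excludeSpikeIns = TRUE)
    sizeFactors <- sizeFactors[samples]
    x <- normalizeCounts(counts, sizeFactors)
    nA <- length(groupA); nB <- length(groupB)
    xA <- x[, groupA, drop = FALSE]; xB <- x[, groupB, drop = FALSE]
    mA <- rowMeans(xA); mB <- rowMeans(xB)
    baseMean <- rowMeans(x)
    ## pooled within-group variance of normalized counts
    vA <- rowSums((xA - mA)^2); vB <- rowSums((xB - mB)^2)
    pooledVar <- (vA + vB) / (nA + nB - 2L)
    ## method-of-moments NB dispersion: Var(x) = mu * E[1/s] + alpha mu^2
    invS <- mean(1 / sizeFactors)
    alpha <- pmax((pooledVar - baseMean * invS) / baseMean^2, 1e-8)
    alpha[!is.finite(alpha)] <- 1e-8
    mAp <- mA + pseudocount; mBp <- mB + pseudocount
    lfc <- log2(mAp / mBp)
    varMa <- (mAp * mean(1 / sizeFactors[groupA]) + alpha * mAp^2) / nA
    varMb <- (mBp * mean(1 / sizeFactors[groupB]) + alpha * mBp^2) / nB
    lfcSE <- sqrt(varMa / mAp^2 + varMb / mBp^2) / log(2)
    stat <- lfc / lfcSE
    pvalue <- 2 * pt(-abs(stat), df = nA + nB - 2L)
    pvalue[baseMean == 0] <- NA_real_
    padj <- rep(NA_real_, length(pvalue))
    test <- baseMean >= minBaseMean & !is.na(pvalue)
    padj[test] <- bhAdjust(pvalue[test])
    data.frame(gene = rownames(counts), baseMean = baseMean,
        log2FoldChange = lfc, lfcSE = lfcSE, stat = stat,
        pvalue = pvalue, padj = padj, row.names = NULL,
        stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment: sorted p-values are scaled by
#' m/rank and made monotone from the largest down. Missing values are
#' passed through untouched and do not count towards m.
#'
#' @param pvalues numeric vector in [0, 1]; `NA` allowed.
#' @return adjusted p-values, same length and order as the input.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(pvalues) {
    if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    out <- rep(NA_real_, length(pvalues))
    ok <- !is.na(pvalues)
    p <- pvalues[ok]
    m <- length(p)
    if (m) {
        ord <- order(p)
        adj <- p[ord] * m / seq_len(m)
        adj <- rev(cummin(rev(adj)))
        adj <- pmin(adj, 1)
        out[ok][ord] <- adj
    }
    out
}

#' Threshold a DE result into up/down gene sets
#'
#' Selects differentially expressed genes by adjusted p-value and linear
#' fold change: up-regulated genes exceed `fcUp`, down-regulated genes fall
#' below `fcDown`.
#'
#' @param de data.frame from [deTest()].
#' @param fcUp,fcDown linear fold-change thresholds (default 3 and 1/3).
#' @param fdr adjusted p-value cutoff (default 0.05).
#' @return list with character vectors `up` and `down`.
#' @export
deClassify <- function(de, fcUp = 3, fcDown = 1 / 3, fdr = 0.05) {
    fc <- 2^de$log2FoldChange
    sig <- !is.na(de$padj) & de$padj < fdr
    list(up = de$gene[sig & fc > fcUp],
         down = de$gene[sig & fc < fcDown])
}

#' Variable genes by coefficient of variation
#'
#' Finds genes with heterogeneous expression across single cells: among
#' genes reaching `minMaxCount` normalized counts in at least one cell, the
#' coefficient of variation (sample standard deviation over mean) is
#' computed and genes with CV above `cvCutoff` are selected. Each selected
#' gene is attributed to the cell where it peaks, supporting per-cell
#' audits of unusually variable cells.
#'
#' @param x normalized gene x cell matrix (>= 2 cells).
#' @param minMaxCount eligibility gate on the per-gene maximum (default
#'   1000, inclusive).
#' @param cvCutoff CV selection threshold (default 4, exclusive).
#' @return data.frame per eligible gene: `gene`, `mean`, `sd`, `cv`,
#'   `max_cell`, `selected`.
#' @export
cvVariableGenes <- function(x, minMaxCount = 1000, cvCutoff = 4) {
    if (ncol(x) < 2L) stop("at least 2 cells are required")
    maxPer <- apply(x, 1L, max)
    eligible <- maxPer >= minMaxCount
    xe <- x[eligible, , drop = FALSE]
    mu <- rowMeans(xe)
    sdv <- apply(xe, 1L, sd)
    cv <- sdv / mu
    data.frame(gene = rownames(xe), mean = mu, sd = sdv, cv = cv,
        max_cell = colnames(xe)[apply(xe, 1L, which.max)],
        selected = cv > cvCutoff, row.names = NULL,
        stringsAsFactors = FALSE)
}

#' Unique-coexpression signature of a cell pair
#'
#' Among a set of candidate DE genes, the genes highly expressed in both
#' cells of a pair and below a low cutoff in every other cell. This is the
#' statistic that distinguishes a genuinely distinct cell type (many genes
#' exclusive to the pair) from ordinary cell-to-cell variability.
#'
#' @param x normalized gene x cell matrix covering the pair and the rest.
#' @param pair character vector of the two cell ids.
#' @param deGenes candidate genes (typically DE between pair and rest).
#' @param highCutoff minimum normalized counts in both pair cells.
#' @param lowCutoff (exclusive) maximum in every other cell; must be below
#'   `highCutoff`.
#' @return character vector of signature genes.
#' @export
uniqueCoexpressionSignature <- function(x, pair, deGenes,
                                        highCutoff = 100, lowCutoff = 10) {
    if (highCutoff <= lowCutoff || lowCutoff < 0)
        stop("cutoffs must satisfy highCutoff > lowCutoff >= 0")
    if (length(pair) != 2L || !all(pair %in% colnames(x)))
        stop("'pair' must name two cells present in the matrix")
    rest <- setdiff(colnames(x), pair)
    if (!length(rest)) stop("no cells left outside the pair")
    genes <- intersect(deGenes, rownames(x))
    if (!length(genes)) return(character(0))
    xp <- x[genes, pair, drop = FALSE]
    xr <- x[genes, rest, drop = FALSE]
    genes[rowSums(xp >= highCutoff) == 2L &
          rowSums(xr < lowCutoff) == length(rest)]
}

#' Exhaustive pairwise unique-coexpression scan
#'
#' For every unordered pair of cells, tests the pair against all remaining
#' cells ([deTest()]), counts the uniquely coexpressed DE genes
#' ([uniqueCoexpressionSignature()]), and ranks the pairs. A pair sharing
#' more than `flagRatio` times the signature of the runner-up is flagged as
#' a candidate distinct cell type.
#'
#' @param counts gene x cell raw count matrix with >= 3 cells.
#' @param sizeFactors optional named size factors for all cells.
#' @param fdr DE cutoff within each pair-vs-rest test.
#' @param highCutoff,lowCutoff signature cutoffs.
#' @param flagRatio top/second ratio above which the top pair is flagged.
#' @return list with `pairs` (data.frame `cell1`, `cell2`, `n_shared`,
#'   `rank`), `top_pair`, `ratio` (top over second-best count; `Inf` when
#'   the second-best is 0) and `distinct_type` flag.
#' @export
pairwiseSharingScan <- function(counts, sizeFactors = NULL, fdr = 0.05,
                                highCutoff = 100, lowCutoff = 10,
                                flagRatio = 2) {
    cells <- colnames(counts)
    n <- length(cells)
    if (n < 3L)
        stop("at least 3 cells are required (the rest group must be ",
            "non-empty)")
    if (is.null(sizeFactors))
        sizeFactors <- computeSizeFactors(counts, excludeSpikeIns = TRUE)
    x <- normalizeCounts(counts, sizeFactors)
    combos <- utils::combn(cells, 2L)
    nShared <- integer(ncol(combos))
    for (i in seq_len(ncol(combos))) {
        pair <- combos[, i]
        rest <- setdiff(cells, pair)
        de <- deTest(counts, pair, rest, sizeFactors = sizeFactors)
        deGenes <- de$gene[!is.na(de$padj) & de$padj < fdr]
        nShared[i] <- length(uniqueCoexpressionSignature(x, pair, deGenes,
            highCutoff, lowCutoff))
    }
    ord <- order(nShared, decreasing = TRUE)
    pairs <- data.frame(cell1 = combos[1L, ], cell2 = combos[2L, ],
        n_shared = nShared, stringsAsFactors = FALSE)
    pairs$rank <- rank(-nShared, ties.method = "min")
    top <- ord[1L]
    second <- nShared[ord[2L]]
    ratio <- if (second > 0) nShared[top] / second else Inf
    list(pairs = pairs,
         top_pair = c(combos[1L, top], combos[2L, top]),
         ratio = ratio,
         distinct_type = is.infinite(ratio) || ratio > flagRatio)
}
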