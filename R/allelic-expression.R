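#' Allele-specific expression call for one gene in one cell
#'
#' Sums strain-A and strain-B read counts over a gene's SNPs in one cell
#' and computes the majority-allele fraction p. Reads supporting other
#' bases (sequencing error) are excluded from the denominator but reported.
#' The strain is called when p reaches `callThreshold` with at least
#' `minReads` informative reads.
#'
#' @param alleleCounts data.frame with columns `cell`, `gene`, `pos`,
#'   `count_A`, `count_B`, `count_other`.
#' @param gene,cell the gene and cell to call.
#' @param minReads minimum informative reads for a call (default 20).
#' @param callThreshold majority fraction needed for a strain call
#'   (default 0.95).
#' @return list with `n` (informative reads), `p` (majority fraction, in
#'   [0.5, 1]), `percent` (p as a percentage, 2 decimals), `strain`
#'   (`"A"`, `"B"`, `"ambiguous"` or `"insufficient"`), `other_fraction`,
#'   and `per_snp` (per-SNP breakdown with per-SNP majority fractions).
#' @examples
#' ac <- data.frame(cell = "OSN_222", gene = "Olfr55", pos = 1,
#'     count_A = 54563, count_B = 114, count_other = 0)
#' allelicPurity(ac, "Olfr55", "OSN_222")$percent  # 99.79
#' @export
allelicPurity <- function(alleleCounts, gene, cell, minReads = 20L,
                          callThreshold = 0.95) {
    rows <- alleleCounts$gene == gene & alleleCounts$cell == cell
    if (!any(rows))
        stop("no informative SNPs for gene ", gene, " in cell ", cell)
    tab <- alleleCounts[rows, , drop = FALSE]
    nA <- sum(tab$count_A); nB <- sum(tab$count_B)
    nOther <- sum(tab$count_other)
    n <- nA + nB
    p <- if (n > 0) max(nA, nB) / n else NA_real_
    strain <- if (n < minReads) "insufficient"
        else if (p >= callThreshold) if (nA >= nB) "A" else "B"
        else "ambiguous"
    perSnp <- data.frame(pos = tab$pos, count_A = tab$count_A,
        count_B = tab$count_B, count_other = tab$count_other,
        p = ifelse(tab$count_A + tab$count_B > 0,
            pmax(tab$count_A, tab$count_B) / (tab$count_A + tab$count_B),
            NA_real_))
    list(n = n, p = p, percent = round(100 * p, 2L), strain = strain,
        other_fraction = nOther / max(n + nOther, 1L), per_snp = perSnp)
}

#' Allele calls for every cell with an abundant OR
#'
#' Runs [allelicPurity()] for each cell's abundantly expressed OR; cells
#' whose OR carries no SNP in the table are reported as
#' `"no_informative_snps"`, mirroring the receptors for which the two
#' strains cannot be distinguished.
#'
#' @param alleleCounts per-SNP allele read counts (see [allelicPurity()]).
#' @param receptorCalls data.frame from [classifyCells()]; only cells with
#'   exactly one abundant intact OR are considered.
#' @param snpTable SNP definitions with a `gene` column.
#' @param ... passed to [allelicPurity()].
#' @return data.frame per cell: `cell`, `gene`, `n`, `p`, `percent`,
#'   `strain`.
#' @export
callAlleles <- function(alleleCounts, receptorCalls, snpTable, ...) {
    mono <- receptorCalls[receptorCalls$class == "monogenic", ,
        drop = FALSE]
    res <- lapply(seq_len(nrow(mono)), function(i) {
        cell <- mono$cell[i]; gene <- mono$abundant_intact[i]
        if (!gene %in% snpTable$gene ||
            !any(alleleCounts$gene == gene & alleleCounts$cell == cell))
            return(data.frame(cell = cell, gene = gene, n = 0L,
                p = NA_real_, percent = NA_real_,
                strain = "no_informative_snps",
                stringsAsFactors = FALSE))
        ap <- allelicPurity(alleleCounts, gene, cell, ...)
        data.frame(cell = cell, gene = gene, n = ap$n, p = ap$p,
            percent = ap$percent, strain = ap$strain,
            stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}

#' Summarize strain-of-origin calls over a cohort
#'
#' Partitions the cells with an abundant OR into strain-A expressers,
#' strain-B expressers, ambiguous calls, and cells whose OR has no
#' informative SNPs.
#'
#' @param calls data.frame from [callAlleles()].
#' @return named integer vector with entries `strain_A`, `strain_B`,
#'   `ambiguous`, `insufficient`, `no_informative_snps`.
#' @export
strainSummary <- function(calls) {
    lv <- c("A", "B", "ambiguous", "insufficient", "no_informative_snps")
    out <- table(factor(calls$strain, levels = lv))
    setNames(as.integer(out),
        c("strain_A", "strain_B", "ambiguous", "insufficient",
          "no_informative_snps"))
}
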