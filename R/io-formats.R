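#' Read a gene x sample count matrix
#'
#' Reads integer counts from either a tab-delimited table (genes in rows,
#' first column = gene id, header = sample ids) or a MatrixMarket
#' coordinate file with sidecar row (`<path>.rownames`) and column
#' (`<path>.colnames`) index files, one id per line. Rows and columns are
#' returned sorted by id so reader output does not depend on file order.
#'
#' @param path file path.
#' @param format `"tsv"` or `"mtx"`.
#' @return an integer matrix with unique gene rownames and sample colnames.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeCounts(matrix(1:4, 2, dimnames = list(c("g1", "g2"),
#'     c("s1", "s2"))), f)
#' readCounts(f)
#' @export
readCounts <- function(path, format = c("tsv", "mtx")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "tsv") {
        tab <- read.table(path, header = TRUE, sep = "\t",
            check.names = FALSE, stringsAsFactors = FALSE)
        ids <- as.character(tab[[1L]])
        m <- as.matrix(tab[, -1L, drop = FALSE])
        rownames(m) <- ids
    } else {
        m <- as.matrix(Matrix::readMM(path))
        rn <- readLines(paste0(path, ".rownames"))
        cn <- readLines(paste0(path, ".colnames"))
        if (length(rn) != nrow(m) || length(cn) != ncol(m))
            stop("MTX sidecar row/column files do not match matrix shape")
        dimnames(m) <- list(rn, cn)
    }
    .validateCountMatrix(m)
    m <- m[order(rownames(m)), order(colnames(m)), drop = FALSE]
    storage.mode(m) <- "integer"
    m
}

.validateCountMatrix <- function(m) {
    if (anyDuplicated(rownames(m)))
        stop("duplicate gene ids: ",
            paste(unique(rownames(m)[duplicated(rownames(m))]),
                collapse = ", "))
    if (anyDuplicated(colnames(m)))
        stop("duplicate sample ids: ",
            paste(unique(colnames(m)[duplicated(colnames(m))]),
                collapse = ", "))
    bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf(
            "counts must be non-negative integers; offending cell [%s, %s]",
            rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
    invisible(m)
}

#' Write a count matrix
#'
#' Inverse of [readCounts()]: TSV (gene id column + one column per sample)
#' or MatrixMarket coordinate format with `.rownames`/`.colnames` sidecars.
#'
#' @param m integer matrix with gene rownames and sample colnames.
#' @param path output path.
#' @param format `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
writeCounts <- function(m, path, format = c("tsv", "mtx")) {
    format <- match.arg(format)
    .validateCountMatrix(m)
    if (format == "tsv") {
        tab <- data.frame(gene = rownames(m), m, check.names = FALSE,
            stringsAsFactors = FALSE)
        write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
        Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
        writeLines(rownames(m), paste0(path, ".rownames"))
        writeLines(colnames(m), paste0(path, ".colnames"))
    }
    invisible(path)
}

#' Read or write a pipeline table
#'
#' Generic TSV helpers for annotation, coverage, allele-count, QC and truth
#' tables: tab-delimited, header row, UTF-8, `"."` for missing values.
#' Rows are returned sorted by the first column so the result does not
#' depend on input row order.
#'
#' @param path file path.
#' @param tab a data.frame.
#' @return `readTable`: a data.frame; `writeTable`: `path`, invisibly.
#' @export
readTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- read.table(path, header = TRUE, sep = "\t", na.strings = ".",
        check.names = FALSE, stringsAsFactors = FALSE)
    tab[order(tab[[1L]]), , drop = FALSE]
}

#' @rdname readTable
#' @export
writeTable <- function(tab, path) {
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
        na = ".")
    invisible(path)
}

#' Read strain-discriminating SNPs from a minimal VCF
#'
#' Parses a VCF 4.x file in which `CHROM` carries the gene id and `POS` the
#' 1-based position in transcript coordinates; `REF` is the strain-A base
#' and `ALT` the strain-B base. Only biallelic SNP records are kept;
#' multi-allelic and indel records are skipped with a logged count.
#'
#' @param path VCF file path.
#' @return a data.frame with columns `gene`, `pos`, `base_A`, `base_B`.
#' @examples
#' vcf <- tempfile(fileext = ".vcf")
#' writeLines(c("##fileformat=VCFv4.2",
#'     "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
#'     "OlfrS0001\t101\t.\tA\tG\t.\t.\t."), vcf)
#' readSnpVcf(vcf)
#' @export
readSnpVcf <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    ref <- as.character(VariantAnnotation::ref(vcf))
    altList <- VariantAnnotation::alt(vcf)
    nAlt <- S4Vectors::elementNROWS(altList)
    alt1 <- rep(NA_character_, length(ref))
    alt1[nAlt == 1L] <- as.character(unlist(altList[nAlt == 1L]))
    keep <- nAlt == 1L & nchar(ref) == 1L & !is.na(alt1) &
        nchar(alt1) == 1L & alt1 %in% c("A", "C", "G", "T")
    skipped <- sum(!keep)
    if (skipped > 0L)
        message(skipped,
            " multi-allelic or indel record(s) skipped while reading ", path)
    if (any(keep & ref == alt1))
        stop("REF equals ALT at ",
            paste(GenomeInfoDb::seqnames(rr)[keep & ref == alt1],
                collapse = ", "))
    out <- data.frame(
        gene = as.character(GenomeInfoDb::seqnames(rr))[keep],
        pos = BiocGenerics::start(rr)[keep],
        base_A = ref[keep], base_B = alt1[keep],
        stringsAsFactors = FALSE)
    rownames(out) <- NULL
    if (anyDuplicated(out[, c("gene", "pos")]))
        stop("duplicate SNP positions within a gene")
    out[order(out$gene, out$pos), , drop = FALSE]
}

#' Write a cohort to plain-text files
#'
#' Serializes a synthetic cohort to an output directory: counts as TSV and
#' MTX, annotation, coverage, allele counts, QC metrics and truth as TSV,
#' and the configuration as JSON. This is the `simulate` entry point of the
#' companion command-line script.
#'
#' @param sce a cohort from [generateCohort()].
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
writeCohort <- function(sce, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    counts <- SummarizedExperiment::assay(sce, "counts")
    writeCounts(counts, file.path(outdir, "counts.tsv"))
    writeCounts(counts, file.path(outdir, "counts.mtx"), format = "mtx")
    writeTable(as.data.frame(SummarizedExperiment::rowData(sce)),
        file.path(outdir, "annotation.tsv"))
    cov <- SummarizedExperiment::assay(sce, "coverage")
    covLong <- which(!is.na(cov), arr.ind = TRUE)
    writeTable(data.frame(gene = rownames(cov)[covLong[, 1L]],
        cell = colnames(cov)[covLong[, 2L]],
        coverage = cov[covLong]), file.path(outdir, "coverage.tsv"))
    writeTable(alleleCounts(sce), file.path(outdir, "allele_counts.tsv"))
    writeTable(snpTable(sce), file.path(outdir, "snps.tsv"))
    writeTable(qcMetrics(sce), file.path(outdir, "qc_metrics.tsv"))
    writeTable(cohortTruth(sce), file.path(outdir, "truth.tsv"))
    cfg <- S4Vectors::metadata(sce)$config
    if (!is.null(cfg) && requireNamespace("jsonlite", quietly = TRUE)) {
        lst <- lapply(slotNames(cfg), function(s) slot(cfg, s))
        names(lst) <- slotNames(cfg)
        writeLines(jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA),
            file.path(outdir, "config.json"))
    }
    invisible(outdir)
}
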