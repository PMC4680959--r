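#' Create a simulation configuration
#'
#' Constructor for [SimConfig-class]. Defaults encode the statistical
#' structure of the single mature OSN cohort the package models: canonical
#' cells express one intact OR abundantly (mean 36,162.46 normalized
#' counts) over 11-28 background OR events (mean 15.99), roughly 4,717
#' endogenous genes are detected per cell, type-B cells carry a 55-gene
#' signature instead of an abundant OR, and the abundant OR's allele split
#' is 99.8:0.2. Free parameters (dispersion, library-size spread, coverage
#' shapes) are fixed realistic choices documented in the methods vignette.
#'
#' @param seed integer seed for the generator.
#' @param n_cells,n_canonical,n_typeB cohort composition; cells beyond
#'   `n_canonical + n_typeB` are generated as QC-failure cells.
#' @param n_intact_or,n_pseudo_or OR repertoire sizes.
#' @param high_mean_counts,high_cv abundant-OR class mean and CV.
#' @param low_mean_counts,low_cv background OR event mean and CV.
#' @param background_or_range per-cell range of background OR gene counts.
#' @param genes_detected_mean,genes_detected_sd detected-genes target.
#' @param signature_size type-B signature size.
#' @param allelic_purity active-allele read fraction, in (0.5, 1].
#' @param snps_per_or SNPs per informative OR gene.
#' @param snp_informative_fraction fraction of intact ORs carrying SNPs.
#' @param qc_fail_fractions named, ordered criterion -> fraction profile.
#' @param nb_dispersion shared negative-binomial dispersion.
#' @param library_size_lognormal c(meanlog, sdlog) of library-size factors.
#' @param n_cellcycle_genes,cc_effect cell-cycle gene count and log10
#'   program separation.
#' @param n_other_genes unstructured background genes.
#' @param n_taar TAAR gene count (simulated silent).
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- SimConfig(seed = 1, n_cells = 5, n_canonical = 4, n_typeB = 1)
#' @export
SimConfig <- function(seed = 1L,
                      n_cells = 21L,
                      n_canonical = 19L,
                      n_typeB = 2L,
                      n_intact_or = 1099L,
                      n_pseudo_or = 151L,
                      high_mean_counts = 36162.46,
                      high_cv = 0.77,
                      low_mean_counts = 15.99,
                      low_cv = 1.13,
                      background_or_range = c(11L, 28L),
                      genes_detected_mean = 4717,
                      genes_detected_sd = 802,
                      signature_size = 55L,
                      allelic_purity = 0.998,
                      snps_per_or = 15L,
                      snp_informative_fraction = 0.5,
                      qc_fail_fractions = c(
                          min_total_fragments = 10 / 58,
                          min_mapped_fraction = 9 / 58,
                          min_genes_detected = 8 / 58,
                          max_ercc_fraction = 6 / 58,
                          max_top_gene_fraction = 4 / 58),
                      nb_dispersion = 0.3,
                      library_size_lognormal = c(0, 0.3),
                      n_cellcycle_genes = 971L,
                      cc_effect = 1.2,
                      n_other_genes = 8000L,
                      n_taar = 15L) {
    new("SimConfig",
        seed = as.integer(seed), n_cells = as.integer(n_cells),
        n_canonical = as.integer(n_canonical), n_typeB = as.integer(n_typeB),
        n_intact_or = as.integer(n_intact_or),
        n_pseudo_or = as.integer(n_pseudo_or),
        high_mean_counts = high_mean_counts, high_cv = high_cv,
        low_mean_counts = low_mean_counts, low_cv = low_cv,
        background_or_range = as.integer(background_or_range),
        genes_detected_mean = genes_detected_mean,
        genes_detected_sd = genes_detected_sd,
        signature_size = as.integer(signature_size),
        allelic_purity = allelic_purity,
        snps_per_or = as.integer(snps_per_or),
        snp_informative_fraction = snp_informative_fraction,
        qc_fail_fractions = qc_fail_fractions,
        nb_dispersion = nb_dispersion,
        library_size_lognormal = library_size_lognormal,
        n_cellcycle_genes = as.integer(n_cellcycle_genes),
        cc_effect = cc_effect,
        n_other_genes = as.integer(n_other_genes),
        n_taar = as.integer(n_taar))
}

#' Named cohort presets
#'
#' `"cohort21"` is the post-QC cohort: 21 cells, 19 canonical monogenic
#' OSNs and 2 receptorless type-B cells. `"cohort58"` is the pre-QC capture:
#' the same 21 high-quality cells plus 37 cells failing the hierarchical QC
#' filter, failures distributed over the five ordered criteria.
#'
#' @param name preset name, `"cohort21"` or `"cohort58"`.
#' @param seed integer seed.
#' @param ... further arguments forwarded to [SimConfig()].
#' @return a [SimConfig-class].
#' @examples
#' cfg <- cohortPreset("cohort21", seed = 1)
#' @export
cohortPreset <- function(name = c("cohort21", "cohort58"), seed = 1L, ...) {
    name <- match.arg(name)
    switch(name,
        cohort21 = SimConfig(seed = seed, n_cells = 21L, n_canonical = 19L,
            n_typeB = 2L, ...),
        cohort58 = SimConfig(seed = seed, n_cells = 58L, n_canonical = 19L,
            n_typeB = 2L, ...))
}

## lognormal draws with a given arithmetic mean and CV
.rlnormMeanCV <- function(n, mean, cv) {
    sdlog <- sqrt(log(1 + cv^2))
    rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

.rnbMean <- function(mu, dispersion) {
    k <- numeric(length(mu))
    pos <- mu > 0
    k[pos] <- rnbinom(sum(pos), mu = mu[pos], size = 1 / dispersion)
    k
}

## gene universe shared by generateCohort and generateReferenceCellCycle
.geneUniverse <- function(config) {
    intact <- sprintf("OlfrS%04d", seq_len(config@n_intact_or))
    pseudo <- sprintf("OlfrS%04d-ps", config@n_intact_or +
        seq_len(config@n_pseudo_or))
    taar <- sprintf("TaarS%02d", seq_len(config@n_taar))
    sigNamed <- c("Trpc2", "Gucy1b2", "Sln", "Emx1", "Sncg")
    nSigExtra <- max(config@signature_size - length(sigNamed), 0L)
    sig <- c(sigNamed, sprintf("SigS%02d", seq_len(nSigExtra)))
    markers <- c("Omp", "Stoml3", "Gnb1", "Malat1", "Calm1", "Cnga2",
        "Adcy3", "Gnal")
    cc <- sprintf("CcgS%04d", seq_len(config@n_cellcycle_genes))
    other <- sprintf("GeneS%05d", seq_len(config@n_other_genes))
    ercc <- sprintf("ERCC-%05d", seq_len(92L))
    ids <- c(intact, pseudo, taar, sig, markers, cc, other, ercc)
    category <- rep(c("OR", "OR", "TAAR", "marker", "marker", "other",
        "other", "other"),
        c(length(intact), length(pseudo), length(taar), length(sig),
          length(markers), length(cc), length(other), length(ercc)))
    status <- rep("intact", length(ids))
    status[ids %in% pseudo] <- "pseudogene"
    or_class <- rep(NA_character_, length(ids))
    orIdx <- which(category == "OR")
    list(ids = ids, intact = intact, pseudo = pseudo, taar = taar,
         sig = sig, markers = markers, cc = cc, other = other, ercc = ercc,
         category = category, status = status, or_class = or_class,
         orIdx = orIdx)
}

## integer allocation of n items over fractions (largest remainder)
.allocate <- function(fractions, total, n) {
    tgt <- fractions * total
    base <- floor(tgt)
    rem <- n - sum(base)
    if (rem > 0) {
        ord <- order(tgt - base, decreasing = TRUE)
        take <- rep(ord, length.out = rem)
        for (i in take) base[i] <- base[i] + 1L
    } else if (rem < 0) {
        ord <- order(base, decreasing = TRUE)
        i <- 1L
        while (rem < 0) {
            if (base[ord[i]] > 0) { base[ord[i]] <- base[ord[i]] - 1L
                rem <- rem + 1L }
            i <- if (i == length(ord)) 1L else i + 1L
        }
    }
    as.integer(base)
}

#' Generate a synthetic single-OSN cohort
#'
#' Draws a complete synthetic cohort with the statistical structure of a
#' single mature OSN RNA-seq experiment: raw counts (negative binomial per
#' gene per cell, mean = cell-class expression profile times a lognormal
#' library-size factor), per-event transcript coverage fractions (Beta:
#' background OR events peak below 1/3 of gene length, abundant ORs near
#' full length), strain-allele read counts at the abundant OR's SNPs, QC
#' metrics with injected hierarchical failure modes, and ground-truth
#' labels for every cell.
#'
#' @param config a [SimConfig-class]; all randomness is governed by
#'   `config@seed`, so identical configurations give identical cohorts.
#' @return a [SingleCellExperiment::SingleCellExperiment] with assays
#'   `counts` (integer) and `coverage` (fraction of transcript covered, NA
#'   for genes without mapped fragments or outside the receptor families),
#'   gene annotation in `rowData()`, QC metrics and truth in `colData()`,
#'   and `metadata()` entries `config`, `alleleCounts` (per cell/gene/SNP
#'   strain-A, strain-B and other-base read counts) and `snpTable`.
#' @examples
#' sce <- generateCohort(cohortPreset("cohort21", seed = 1))
#' table(cohortTruth(sce)$true_class)
#' @seealso [cohortTruth()], [alleleCounts()], [snpTable()], [qcMetrics()]
#' @export
generateCohort <- function(config) {
    validObject(config)
    set.seed(config@seed)
    g <- .geneUniverse(config)
    nG <- length(g$ids)
    nC <- config@n_cells
    disp <- config@nb_dispersion

    ## gene annotation
    or_class <- g$or_class
    isIntact <- g$ids %in% g$intact
    or_class[isIntact] <- ifelse(runif(sum(isIntact)) < 0.1, "I", "II")
    or_class[g$ids %in% g$pseudo] <- "II"
    length_bp <- round(rlnorm(nG, log(2000), 0.5))
    length_bp[g$category == "OR"] <- round(rnorm(sum(g$category == "OR"),
        1000, 30))
    length_bp[g$ids %in% g$ercc] <- 500L
    length_bp <- pmax(length_bp, 200L)
    rowAnn <- S4Vectors::DataFrame(
        gene_id = g$ids, category = g$category, status = g$status,
        or_class = or_class, length_bp = as.integer(length_bp),
        is_spike = startsWith(g$ids, "ERCC-"),
        in_typeB_signature = g$ids %in% g$sig,
        cc_program = ifelse(g$ids %in% g$cc,
            ifelse(g$ids %in% g$cc[seq_len(ceiling(length(g$cc) / 2))],
                "G1", "S/G2-M"), NA_character_),
        row.names = g$ids)

    ## SNP table over a random half of the intact OR repertoire
    nInf <- round(config@snp_informative_fraction * length(g$intact))
    infOrs <- sort(sample(g$intact, nInf))
    snpTable <- if (nInf > 0 && config@snps_per_or > 0) {
        do.call(rbind, lapply(infOrs, function(or) {
            pos <- sort(sample.int(
                rowAnn[or, "length_bp"], config@snps_per_or))
            a <- sample(c("A", "C", "G", "T"), config@snps_per_or,
                replace = TRUE)
            b <- vapply(a, function(x)
                sample(setdiff(c("A", "C", "G", "T"), x), 1L), character(1))
            data.frame(gene = or, pos = pos, base_A = a, base_B = b,
                stringsAsFactors = FALSE)
        }))
    } else data.frame(gene = character(), pos = integer(),
        base_A = character(), base_B = character())

    if (nC == 0L) {
        sce <- SingleCellExperiment::SingleCellExperiment(
            assays = list(
                counts = matrix(0L, nG, 0, dimnames = list(g$ids, NULL)),
                coverage = matrix(NA_real_, nG, 0,
                    dimnames = list(g$ids, NULL))),
            rowData = rowAnn)
        S4Vectors::metadata(sce) <- list(config = config,
            alleleCounts = .emptyAlleleCounts(), snpTable = snpTable)
        return(sce)
    }

    ## cell classes in randomized order
    nFail <- nC - config@n_canonical - config@n_typeB
    classes <- sample(rep(c("canonical", "typeB", "qc_fail"),
        c(config@n_canonical, config@n_typeB, nFail)))
    cells <- sprintf("OSN_%03d", seq_len(nC))

    ## expression-profile building blocks (normalized-count scale)
    ccHigh <- 300 * 10^(config@cc_effect / 2)
    ccLow <- 300 * 10^(-config@cc_effect / 2)
    markerMeans <- c(Omp = 20000, Stoml3 = 50000, Gnb1 = 48000,
        Malat1 = 52000, Calm1 = 46000, Cnga2 = 4000, Adcy3 = 3000,
        Gnal = 5000)
    sigDraw <- sort(.rlnormMeanCV(length(g$sig), 600, 0.9),
        decreasing = TRUE)
    sigMeans <- setNames(numeric(length(g$sig)), g$sig)
    named <- c("Gucy1b2", "Sln", "Emx1", "Sncg", "Trpc2")
    rank <- c(1L, 2L, 3L, 7L, min(39L, length(g$sig)))
    sigMeans[named] <- sigDraw[rank]
    sigMeans[setdiff(g$sig, named)] <- sigDraw[-rank]
    otherBase <- rlnorm(length(g$other), log(80), 1.0)
    erccMeans <- rlnorm(length(g$ercc), log(300), 1.0)
    nAlwaysOn <- config@n_cellcycle_genes + length(g$markers) + 1 +
        mean(config@background_or_range)
    pOn <- (config@genes_detected_mean - nAlwaysOn) / length(g$other)
    pOnSd <- config@genes_detected_sd / length(g$other)

    g1prog <- g$cc[seq_len(ceiling(length(g$cc) / 2))]
    sprog <- setdiff(g$cc, g1prog)
    mu <- matrix(0, nG, nC, dimnames = list(g$ids, cells))
    coverage <- matrix(NA_real_, nG, nC, dimnames = list(g$ids, cells))
    trueOr <- rep(NA_character_, nC)
    trueAllele <- rep(NA_character_, nC)
    allOr <- c(g$intact, g$pseudo)
    bgRange <- config@background_or_range

    for (j in seq_len(nC)) {
        withOr <- classes[j] != "typeB"
        if (withOr) {
            trueOr[j] <- sample(g$intact, 1L)
            trueAllele[j] <- sample(c("A", "B"), 1L)
            mu[trueOr[j], j] <- .rlnormMeanCV(1L, config@high_mean_counts,
                config@high_cv)
            coverage[trueOr[j], j] <- rbeta(1L, 20, 1.5)
        }
        k <- sample(seq(bgRange[1L], bgRange[2L]), 1L)
        bg <- sample(setdiff(allOr, trueOr[j]), k)
        mu[bg, j] <- .rlnormMeanCV(k, config@low_mean_counts, config@low_cv)
        coverage[bg, j] <- rbeta(k, 1.2, 5)
        if (classes[j] == "typeB")
            mu[g$sig, j] <- sigMeans
        mu[names(markerMeans), j] <- markerMeans
        mu[g1prog, j] <- ccHigh
        mu[sprog, j] <- ccLow
        pj <- min(max(rnorm(1L, pOn, pOnSd), 0.02), 0.98)
        on <- runif(length(g$other)) < pj
        mu[g$other[on], j] <- otherBase[on]
        mu[g$ercc, j] <- erccMeans
    }

    libSize <- rlnorm(nC, config@library_size_lognormal[1L],
        config@library_size_lognormal[2L])
    counts <- matrix(0L, nG, nC, dimnames = list(g$ids, cells))
    for (j in seq_len(nC))
        counts[, j] <- as.integer(.rnbMean(mu[, j] * libSize[j], disp))
    ## a coverage fraction exists only for receptor genes with >= 1 fragment
    recv <- g$category %in% c("OR", "TAAR")
    coverage[recv, ][counts[recv, , drop = FALSE] == 0L] <- NA_real_
    ## abundant ORs are never entirely unobserved at these means, but if the
    ## NB draw gave a background OR zero counts its event does not exist
    coverage[!recv, ] <- NA_real_

    ## allele counts at the abundant OR's SNPs
    alleleCounts <- .simulateAlleleCounts(config, cells, classes, trueOr,
        trueAllele, mu, snpTable)

    ## QC metrics: derived where the counts carry them, simulated otherwise
    endog <- !rowAnn$is_spike
    genesDetected <- colSums(counts[endog, , drop = FALSE] > 0L)
    totalCounts <- colSums(counts)
    erccFraction <- colSums(counts[!endog, , drop = FALSE]) /
        pmax(totalCounts, 1)
    topGeneFraction <- apply(counts[endog, , drop = FALSE], 2L, max) /
        pmax(colSums(counts[endog, , drop = FALSE]), 1)
    totalFragments <- round(rlnorm(nC, log(4.4e6), 0.25))
    mappedFraction <- rbeta(nC, 80, 20)

    ## inject one hierarchical failure per QC-fail cell, allocated over the
    ## ordered criterion profile
    failIdx <- which(classes == "qc_fail")
    assigned <- rep(NA_character_, nC)
    if (length(failIdx)) {
        nPer <- .allocate(config@qc_fail_fractions, nC, length(failIdx))
        crit <- rep(names(config@qc_fail_fractions), nPer)
        assigned[failIdx] <- sample(crit)
        for (j in failIdx) {
            switch(assigned[j],
                min_total_fragments =
                    totalFragments[j] <- round(runif(1L, 5e4, 4.5e5)),
                min_mapped_fraction =
                    mappedFraction[j] <- runif(1L, 0.1, 0.45),
                min_genes_detected =
                    genesDetected[j] <- round(runif(1L, 200, 1800)),
                max_ercc_fraction =
                    erccFraction[j] <- runif(1L, 0.25, 0.6),
                max_top_gene_fraction =
                    topGeneFraction[j] <- runif(1L, 0.3, 0.6))
        }
    }

    colAnn <- S4Vectors::DataFrame(
        cell = cells, sample_type = "cell",
        true_class = classes, true_or = trueOr, true_allele = trueAllele,
        true_stage = "G1",
        total_fragments = totalFragments,
        mapped_fraction = mappedFraction,
        genes_detected = as.integer(genesDetected),
        ercc_fraction = erccFraction,
        top_gene_fraction = topGeneFraction,
        qc_assigned_criterion = assigned,
        row.names = cells)

    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts, coverage = coverage),
        rowData = rowAnn, colData = colAnn)
    S4Vectors::metadata(sce) <- list(config = config,
        alleleCounts = alleleCounts, snpTable = snpTable)
    sce
}

.emptyAlleleCounts <- function()
    data.frame(cell = character(), gene = character(), pos = integer(),
        count_A = integer(), count_B = integer(), count_other = integer(),
        snp_total = integer())

.simulateAlleleCounts <- function(config, cells, classes, trueOr,
                                  trueAllele, mu, snpTable) {
    out <- list()
    readsPerCount <- 1.5
    errRate <- 0.002
    for (j in seq_along(cells)) {
        or <- trueOr[j]
        if (is.na(or) || !or %in% snpTable$gene) next
        pos <- snpTable$pos[snpTable$gene == or]
        nReads <- rpois(1L, mu[or, j] * readsPerCount)
        if (nReads == 0L) next
        perSnp <- as.vector(rmultinom(1L, nReads,
            rep(1 / length(pos), length(pos))))
        other <- rbinom(length(pos), perSnp, errRate)
        inform <- perSnp - other
        pA <- if (trueAllele[j] == "A") config@allelic_purity else
            1 - config@allelic_purity
        a <- rbinom(length(pos), inform, pA)
        out[[length(out) + 1L]] <- data.frame(
            cell = cells[j], gene = or, pos = pos,
            count_A = a, count_B = inform - a, count_other = other,
            snp_total = perSnp, stringsAsFactors = FALSE)
    }
    if (length(out)) do.call(rbind, out) else .emptyAlleleCounts()
}

#' Generate a labeled cell-cycle reference
#'
#' Builds a synthetic analogue of a staged reference dataset (e.g. staged
#' ES cells): reference samples labeled G1 or S/G2-M whose expression over
#' the cell-cycle gene panel follows two reciprocal programs separated by
#' `config@cc_effect` orders of magnitude. Used to train the PC1-sign
#' classifier of [trainCellCycle()].
#'
#' @param config a [SimConfig-class] (uses `seed`, `n_cellcycle_genes`,
#'   `cc_effect`, `nb_dispersion`).
#' @param n_per_label reference samples per label (minimum 2).
#' @return a [SummarizedExperiment::SummarizedExperiment] of normalized
#'   counts (cell-cycle genes x reference samples) with a `label` column
#'   ("G1" or "S/G2-M") in `colData()`.
#' @examples
#' ref <- generateReferenceCellCycle(SimConfig(seed = 1))
#' table(SummarizedExperiment::colData(ref)$label)
#' @export
generateReferenceCellCycle <- function(config, n_per_label = 5L) {
    validObject(config)
    if (n_per_label < 2L)
        stop("at least 2 reference samples per label are required")
    if (config@n_cellcycle_genes < 1L)
        stop("the cell-cycle gene list is empty")
    set.seed(config@seed + 104729L)  # offset stream from generateCohort
    g <- .geneUniverse(config)
    nHalf <- ceiling(length(g$cc) / 2)
    g1prog <- g$cc[seq_len(nHalf)]
    ccHigh <- 300 * 10^(config@cc_effect / 2)
    ccLow <- 300 * 10^(-config@cc_effect / 2)
    labels <- rep(c("G1", "S/G2-M"), each = n_per_label)
    samples <- sprintf("Ref_%s_%d", ifelse(labels == "G1", "G1", "SG2M"),
        rep(seq_len(n_per_label), 2L))
    mu <- matrix(ccLow, length(g$cc), length(samples),
        dimnames = list(g$cc, samples))
    mu[g1prog, labels == "G1"] <- ccHigh
    mu[setdiff(g$cc, g1prog), labels != "G1"] <- ccHigh
    x <- matrix(.rnbMean(as.vector(mu), config@nb_dispersion),
        nrow(mu), ncol(mu), dimnames = dimnames(mu))
    SummarizedExperiment::SummarizedExperiment(
        assays = list(normcounts = x),
        colData = S4Vectors::DataFrame(label = labels,
            row.names = samples))
}

#' Cohort accessors
#'
#' Small accessors over a cohort [SingleCellExperiment::SingleCellExperiment]
#' produced by [generateCohort()]: ground-truth labels, per-SNP allele read
#' counts, the SNP definition table, and QC metrics.
#'
#' @param x a cohort `SingleCellExperiment`.
#' @return `cohortTruth`: data.frame of per-cell truth (class, abundant OR,
#'   allele, stage); `alleleCounts`: data.frame of per (cell, gene, SNP)
#'   strain-A/strain-B/other read counts; `snpTable`: data.frame of SNP
#'   definitions; `qcMetrics`: data.frame of per-cell QC metrics.
#' @name cohort-accessors
#' @examples
#' sce <- generateCohort(SimConfig(seed = 1, n_cells = 4, n_canonical = 3,
#'     n_typeB = 1))
#' head(cohortTruth(sce))
NULL

#' @rdname cohort-accessors
#' @export
cohortTruth <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    as.data.frame(cd[, intersect(c("cell", "true_class", "true_or",
        "true_allele", "true_stage"), colnames(cd)), drop = FALSE])
}

#' @rdname cohort-accessors
#' @export
alleleCounts <- function(x) S4Vectors::metadata(x)$alleleCounts

#' @rdname cohort-accessors
#' @export
snpTable <- function(x) S4Vectors::metadata(x)$snpTable

#' @rdname cohort-accessors
#' @export
qcMetrics <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    as.data.frame(cd[, intersect(c("cell", "total_fragments",
        "mapped_fraction", "genes_detected", "ercc_fraction",
        "top_gene_fraction"), colnames(cd)), drop = FALSE])
}
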