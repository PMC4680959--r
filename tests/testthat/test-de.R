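nbMatrix <- function(g, n, mu, dispersion = 0.1) {
    m <- matrix(rnbinom(g * n, mu = mu, size = 1 / dispersion), g, n,
        dimnames = list(sprintf("gene%04d", seq_len(g)),
            sprintf("s%02d", seq_len(n))))
    storage.mode(m) <- "integer"
    m
}

test_that("Benjamini-Hochberg matches hand computation and p.adjust", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    expect_equal(bhAdjust(0.7), 0.7)
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
    # independent oracle and permutation invariance
    set.seed(1)
    p <- c(runif(50), NA, runif(10)^3, NA)
    expect_equal(bhAdjust(p), p.adjust(p, "BH"))
    perm <- sample(length(p))
    expect_equal(bhAdjust(p[perm]), bhAdjust(p)[perm])
    expect_true(all(bhAdjust(p) >= p, na.rm = TRUE))
})

test_that("identical groups give zero fold change everywhere", {
    set.seed(4)
    half <- nbMatrix(100, 3, mu = 50)
    counts <- cbind(half, half)
    colnames(counts) <- sprintf("s%02d", 1:6)
    de <- deTest(counts, colnames(counts)[1:3], colnames(counts)[4:6])
    expect_true(all(de$log2FoldChange == 0))
    expect_error(deTest(counts, colnames(counts)[1:3],
        colnames(counts)[3:5]), "overlap")
    expect_error(deTest(counts, colnames(counts)[1], colnames(counts)[2:4]),
        "at least 2")
})

test_that("the NB Wald test is calibrated under the null", {
    set.seed(2024)
    counts <- nbMatrix(2000, 20, mu = 100, dispersion = 0.1)
    de <- deTest(counts, colnames(counts)[1:10], colnames(counts)[11:20])
    frac <- mean(de$pvalue < 0.05, na.rm = TRUE)
    expect_gte(frac, 0.03)
    expect_lte(frac, 0.07)
    # near-uniform null p-values
    ks <- suppressWarnings(ks.test(de$pvalue, "punif"))
    expect_lt(unname(ks$statistic), 0.05)
})

test_that("an 8-fold spike at mean 500 is detected with high power", {
    set.seed(99)
    g <- 2000; spiked <- 1:100
    mu <- matrix(100, g, 12)
    mu[spiked, 1:6] <- 4000   # 8-fold above the 500 baseline
    mu[spiked, 7:12] <- 500
    counts <- matrix(rnbinom(g * 12, mu = as.vector(mu), size = 10), g, 12,
        dimnames = list(sprintf("gene%04d", 1:g), sprintf("s%02d", 1:12)))
    de <- deTest(counts, colnames(counts)[1:6], colnames(counts)[7:12])
    detected <- de$gene[!is.na(de$padj) & de$padj < 0.05 &
        de$log2FoldChange > 0]
    expect_gte(sum(detected %in% sprintf("gene%04d", spiked)), 90)
    # and the thresholded classification recovers the truth set
    sets <- deClassify(de)
    expect_setequal(sets$up, sprintf("gene%04d", spiked))
})

test_that("the NB Wald test agrees with an established DE engine", {
    skip_if_not_installed("DESeq2")
    set.seed(17)
    g <- 300
    mu <- matrix(80, g, 10)
    mu[1:30, 1:5] <- 800
    counts <- matrix(rnbinom(g * 10, mu = as.vector(mu), size = 5), g, 10,
        dimnames = list(sprintf("gene%04d", 1:g), sprintf("s%02d", 1:10)))
    de <- deTest(counts, colnames(counts)[1:5], colnames(counts)[6:10])
    dds <- DESeq2::DESeqDataSetFromMatrix(counts,
        S4Vectors::DataFrame(cond = factor(rep(c("A", "B"), each = 5),
            levels = c("B", "A"))), ~cond)
    dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
    ref <- DESeq2::results(dds)
    spiked <- sprintf("gene%04d", 1:30)
    myHits <- de$gene[!is.na(de$padj) & de$padj < 0.05]
    refHits <- rownames(ref)[!is.na(ref$padj) & ref$padj < 0.05]
    # both engines recover the spiked genes with few false calls
    expect_gte(sum(spiked %in% myHits), 28)
    expect_gte(sum(spiked %in% refHits), 28)
    expect_lte(length(setdiff(myHits, spiked)), 30)
    expect_gt(cor(de$log2FoldChange, ref$log2FoldChange), 0.95)
})

test_that("fold-change/FDR thresholding classifies single genes", {
    de <- data.frame(gene = c("a", "b", "c", "d"),
        baseMean = 10, log2FoldChange = log2(c(4, 2, 1 / 4, 4)),
        lfcSE = 1, stat = 1, pvalue = 0.01,
        padj = c(0.01, 0.01, 0.01, 0.2))
    sets <- deClassify(de, fcUp = 3, fcDown = 1 / 3, fdr = 0.05)
    expect_identical(sets$up, "a")    # b misses the fold cutoff,
    expect_identical(sets$down, "c")  # d misses the FDR cutoff
})

test_that("CV-based selection applies the eligibility gate and cutoff", {
    x <- rbind(
        flat = rep(2000, 21),
        spike = c(1000, rep(0, 20)),
        low = c(999, rep(0, 20)))
    colnames(x) <- sprintf("c%02d", 1:21)
    res <- cvVariableGenes(x)
    expect_false("low" %in% res$gene)      # max 999 < 1000 is ineligible
    expect_identical(res$cv[res$gene == "flat"], 0)
    expect_false(res$selected[res$gene == "flat"])
    # hand computation: mean 47.62, sample SD 218.2, CV 4.58
    spike <- res[res$gene == "spike", ]
    expect_equal(spike$mean, 1000 / 21, tolerance = 1e-12)
    expect_equal(spike$sd, 218.2177, tolerance = 1e-4)
    expect_equal(spike$cv, 4.5826, tolerance = 1e-4)
    expect_true(spike$selected)
    expect_identical(spike$max_cell, "c01")
    # CV itself is scale-free; only eligibility changes with rescaling
    res2 <- cvVariableGenes(x * 10)
    expect_equal(res2$cv[res2$gene == "spike"], spike$cv)
})

test_that("unique-coexpression signatures are exactly enumerable", {
    x <- matrix(0, 5, 5, dimnames = list(paste0("g", 1:5),
        paste0("c", 1:5)))
    x[1:3, 1:2] <- 500            # three genes exclusive to the pair
    x[4, ] <- 500                 # high everywhere -> excluded
    x[5, c(1, 2, 4)] <- 500       # leaks into a third cell -> excluded
    sig <- uniqueCoexpressionSignature(x, c("c1", "c2"),
        rownames(x), highCutoff = 100, lowCutoff = 10)
    expect_setequal(sig, c("g1", "g2", "g3"))
    expect_identical(uniqueCoexpressionSignature(x, c("c1", "c2"),
        character(0)), character(0))
    expect_error(uniqueCoexpressionSignature(x, c("c1", "c9"),
        rownames(x)), "present in the matrix")
    expect_error(uniqueCoexpressionSignature(x, c("c1", "c2"),
        rownames(x), highCutoff = 5, lowCutoff = 10), "cutoffs")
})

test_that("the pairwise scan singles out the type-B pair", {
    sce <- getCohort21()
    counts <- SummarizedExperiment::assay(sce, "counts")
    scan <- pairwiseSharingScan(counts)
    expect_identical(nrow(scan$pairs), as.integer(choose(21, 2)))
    tr <- cohortTruth(sce)
    expect_setequal(scan$top_pair, tr$cell[tr$true_class == "typeB"])
    expect_true(scan$distinct_type)
    expect_gt(scan$ratio, 2)
    # most of the 55-gene signature is recovered as uniquely coexpressed
    expect_gte(max(scan$pairs$n_shared), 40)
    expect_error(pairwiseSharingScan(counts[, 1:2]), "at least 3 cells")
})
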