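#' @import methods
#' @importFrom stats median quantile rnorm rpois rbinom runif rbeta rlnorm
#'   rnbinom rmultinom sd var cor dnorm pnorm pt prcomp setNames complete.cases
#' @importFrom utils read.table write.table head
NULL

#' Simulation configuration for a synthetic OSN cohort
#'
#' Holds every parameter of the synthetic-cohort generator. Defaults are the
#' descriptive statistics reported for the mouse olfactory sensory neuron
#' (OSN) single-cell cohort this package models: one abundantly expressed
#' intact OR per canonical mature OSN (mean 36,162.46 normalized counts),
#' 11-28 additional OR genes per cell at background level (mean 15.99),
#' about 4,717 genes detected per cell, two receptorless "type B" cells
#' carrying a 55-gene signature, and allelic purity of the abundant OR
#' above 99.7\%.
#'
#' @slot seed integer seed controlling all randomness of the generator.
#' @slot n_cells total number of cells.
#' @slot n_canonical number of canonical cells (one abundant intact OR each).
#' @slot n_typeB number of receptorless type-B signature cells.
#' @slot n_intact_or,n_pseudo_or numbers of intact and pseudogene OR genes.
#' @slot high_mean_counts mean normalized counts of the abundant OR class.
#' @slot high_cv coefficient of variation of abundant-OR means across cells.
#' @slot low_mean_counts mean normalized counts of background OR events.
#' @slot low_cv coefficient of variation of background OR event means.
#' @slot background_or_range integer pair: per-cell range of background ORs.
#' @slot genes_detected_mean,genes_detected_sd target mean and across-cell
#'   standard deviation of the number of endogenous genes detected per cell.
#' @slot signature_size number of genes in the type-B signature.
#' @slot allelic_purity fraction of informative reads from the active allele.
#' @slot snps_per_or number of strain-discriminating SNPs per informative OR.
#' @slot snp_informative_fraction fraction of intact ORs that carry SNPs.
#' @slot qc_fail_fractions named numeric: ordered (criterion, fraction of
#'   cells) profile of injected QC failures.
#' @slot nb_dispersion negative-binomial dispersion shared across genes.
#' @slot library_size_lognormal meanlog and sdlog of per-cell library-size
#'   factors.
#' @slot n_cellcycle_genes number of cell-cycle genes simulated.
#' @slot cc_effect log10 effect size separating the two cell-cycle programs.
#' @slot n_other_genes number of unstructured background genes.
#' @slot n_taar number of TAAR genes (simulated silent, as observed in
#'   mature OSNs).
#'
#' @seealso [SimConfig()], [cohortPreset()], [generateCohort()]
#' @export
setClass("SimConfig", representation(
    seed = "integer",
    n_cells = "integer",
    n_canonical = "integer",
    n_typeB = "integer",
    n_intact_or = "integer",
    n_pseudo_or = "integer",
    high_mean_counts = "numeric",
    high_cv = "numeric",
    low_mean_counts = "numeric",
    low_cv = "numeric",
    background_or_range = "integer",
    genes_detected_mean = "numeric",
    genes_detected_sd = "numeric",
    signature_size = "integer",
    allelic_purity = "numeric",
    snps_per_or = "integer",
    snp_informative_fraction = "numeric",
    qc_fail_fractions = "numeric",
    nb_dispersion = "numeric",
    library_size_lognormal = "numeric",
    n_cellcycle_genes = "integer",
    cc_effect = "numeric",
    n_other_genes = "integer",
    n_taar = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    chkpos <- function(x, nm) {
        if (length(slot(object, x)) != 1L || !is.finite(slot(object, x)) ||
            slot(object, x) <= 0)
            msg <<- c(msg, sprintf("'%s' must be a single positive value", x))
    }
    if (object@n_cells < 0L) msg <- c(msg, "'n_cells' must be >= 0")
    if (object@n_canonical < 0L || object@n_typeB < 0L)
        msg <- c(msg, "'n_canonical' and 'n_typeB' must be >= 0")
    if (object@n_canonical + object@n_typeB > object@n_cells)
        msg <- c(msg, "'n_canonical' + 'n_typeB' must not exceed 'n_cells'")
    for (s in c("high_mean_counts", "low_mean_counts", "high_cv", "low_cv",
                "genes_detected_mean", "nb_dispersion"))
        chkpos(s, s)
    if (object@allelic_purity <= 0.5 || object@allelic_purity > 1)
        msg <- c(msg, "'allelic_purity' must lie in (0.5, 1]")
    if (length(object@background_or_range) != 2L ||
        object@background_or_range[1L] > object@background_or_range[2L])
        msg <- c(msg, "'background_or_range' must be an ordered integer pair")
    if (any(object@qc_fail_fractions < 0) || sum(object@qc_fail_fractions) > 1)
        msg <- c(msg,
            "'qc_fail_fractions' must be non-negative with sum <= 1")
    if (length(msg)) msg else TRUE
})

#' Two-component Gaussian mixture fit of OR abundance
#'
#' Result of fitting a two-component Gaussian mixture, by
#' expectation-maximization, to the log10 normalized counts of OR
#' expression events pooled across cells. The intersection of the two
#' component densities defines the abundance threshold tau that separates
#' abundantly expressed receptors from background transcription.
#'
#' @slot weights mixing weights (sum to 1), low component first.
#' @slot means,sds component means and standard deviations on the
#'   log10(normalized counts) scale, ordered so `means[1] < means[2]`.
#' @slot tau intersection threshold on the normalized-count scale (`NA`
#'   until computed with [mixtureIntersection()]).
#' @slot nEvents number of events the mixture was fitted to.
#' @slot logLik final log-likelihood.
#' @slot logLikTrace per-iteration log-likelihood (non-decreasing).
#' @slot converged whether the log-likelihood change fell below tolerance.
#' @slot separation standardized distance between components,
#'   (mu2 - mu1) / sqrt((s1^2 + s2^2) / 2).
#' @slot overlapping flag set when `separation` is below the overlap cutoff,
#'   indicating the two components are not meaningfully distinct.
#'
#' @seealso [fitMixture()], [mixtureIntersection()]
#' @export
setClass("MixtureFit", representation(
    weights = "numeric",
    means = "numeric",
    sds = "numeric",
    tau = "numeric",
    nEvents = "integer",
    logLik = "numeric",
    logLikTrace = "numeric",
    converged = "logical",
    separation = "numeric",
    overlapping = "logical"
))

setValidity("MixtureFit", function(object) {
    msg <- character()
    if (length(object@weights) != 2L || any(object@weights <= 0) ||
        any(object@weights >= 1) ||
        abs(sum(object@weights) - 1) > 1e-8)
        msg <- c(msg, "'weights' must be two values in (0,1) summing to 1")
    if (length(object@means) != 2L || object@means[1L] > object@means[2L])
        msg <- c(msg, "'means' must be ordered (low, high)")
    if (any(object@sds <= 0))
        msg <- c(msg, "'sds' must be positive")
    if (!is.na(object@tau)) {
        ltau <- log10(object@tau)
        if (ltau < object@means[1L] || ltau > object@means[2L])
            msg <- c(msg,
                "'tau' must lie between the component means (count scale)")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn MixtureFit-class compact display of the fitted components.
#' @param object a `MixtureFit`.
#' @export
setMethod("show", "MixtureFit", function(object) {
    cat("MixtureFit: 2-component Gaussian mixture on log10 normalized",
        "counts\n")
    cat(sprintf("  n events: %d   converged: %s   logLik: %.3f\n",
        object@nEvents, object@converged, object@logLik))
    cat(sprintf("  low : w=%.3f mu=%.3f sd=%.3f\n", object@weights[1L],
        object@means[1L], object@sds[1L]))
    cat(sprintf("  high: w=%.3f mu=%.3f sd=%.3f\n", object@weights[2L],
        object@means[2L], object@sds[2L]))
    cat(sprintf("  separation: %.2f%s\n", object@separation,
        if (object@overlapping) "  (components overlap)" else ""))
    if (!is.na(object@tau))
        cat(sprintf("  intersection threshold tau: %.2f normalized counts\n",
            object@tau))
    invisible(NULL)
})

#' PC1-sign cell-cycle stage classifier
#'
#' A binary G1 vs S/G2-M classifier: cell-cycle genes are log-transformed,
#' centered on a labeled reference, and projected on the reference's first
#' principal axis, oriented so that G1 reference samples project negative.
#' A sample is called G1 when its projection is negative, S/G2-M otherwise.
#'
#' @slot genes cell-cycle gene identifiers used by the model.
#' @slot centers per-gene centering values (reference means of
#'   log10(normalized counts + 1)).
#' @slot loadings unit-norm first principal axis over `genes`.
#' @slot separation between-label projection gap divided by the pooled
#'   within-label standard deviation of projections.
#' @slot refProjections named per-reference-sample projections.
#' @slot refLabels reference labels ("G1" or "S/G2-M") per sample.
#'
#' @seealso [trainCellCycle()], [classifyCellCycle()]
#' @export
setClass("CellCycleModel", representation(
    genes = "character",
    centers = "numeric",
    loadings = "numeric",
    separation = "numeric",
    refProjections = "numeric",
    refLabels = "character"
))

setValidity("CellCycleModel", function(object) {
    msg <- character()
    if (length(object@genes) != length(object@loadings) ||
        length(object@genes) != length(object@centers))
        msg <- c(msg, "'genes', 'centers' and 'loadings' lengths must match")
    if (abs(sqrt(sum(object@loadings^2)) - 1) > 1e-6)
        msg <- c(msg, "'loadings' must have unit norm")
    g1 <- object@refProjections[object@refLabels == "G1"]
    if (length(g1) && mean(g1) >= 0)
        msg <- c(msg, "G1 reference samples must project negative")
    if (length(msg)) msg else TRUE
})

#' @describeIn CellCycleModel-class compact display of the trained model.
#' @param object a `CellCycleModel`.
#' @export
setMethod("show", "CellCycleModel", function(object) {
    cat("CellCycleModel: PC1-sign G1 vs S/G2-M classifier\n")
    cat(sprintf("  %d cell-cycle genes, %d reference samples\n",
        length(object@genes), length(object@refLabels)))
    cat(sprintf("  separation statistic: %.2f\n", object@separation))
    cat("  rule: projection < 0 -> G1, >= 0 -> S/G2-M\n")
    invisible(NULL)
})
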