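#' Extract OR/TAAR expression events
#'
#' An expression event is a (cell, receptor gene) pair with at least one
#' mapped fragment. Events carry normalized counts and the fraction of the
#' gene's transcript covered by fragments, the quantity the mismapping
#' filter operates on.
#'
#' @param sce a cohort `SingleCellExperiment` with assays `counts` and
#'   `coverage` and a `category` column in `rowData()`.
#' @param sizeFactors optional precomputed size factors; by default
#'   computed on the cohort with spike-ins excluded.
#' @param categories receptor gene categories to include.
#' @return data.frame with columns `cell`, `gene`, `norm_counts`,
#'   `coverage`.
#' @export
orExpressionEvents <- function(sce, sizeFactors = NULL,
                               categories = c("OR", "TAAR")) {
    counts <- SummarizedExperiment::assay(sce, "counts")
    if (is.null(sizeFactors))
        sizeFactors <- computeSizeFactors(counts, excludeSpikeIns = TRUE)
    norm <- normalizeCounts(counts, sizeFactors)
    keep <- SummarizedExperiment::rowData(sce)$category %in% categories
    cov <- SummarizedExperiment::assay(sce, "coverage")
    idx <- which(counts > 0L & keep, arr.ind = TRUE)
    data.frame(
        cell = colnames(counts)[idx[, 2L]],
        gene = rownames(counts)[idx[, 1L]],
        norm_counts = norm[idx],
        coverage = cov[idx],
        stringsAsFactors = FALSE)
}

#' Coverage-fraction filter
#'
#' Removes expression events whose mapped fragments cover less than one
#' third of the gene's transcript length, the signature of non-specific
#' transcription or mismapped reads. The boundary is exclusive: an event at
#' exactly 1/3 is retained.
#'
#' @param events data.frame of events with a `coverage` column in [0, 1].
#' @param minCoverage retention threshold (default 1/3).
#' @return the retained events; the number removed is reported via
#'   `message()` and as attribute `"n_removed"`.
#' @export
coverageFilter <- function(events, minCoverage = 1 / 3) {
    if (nrow(events) && any(is.na(events$coverage)))
        stop("event(s) without a coverage fraction: ",
            paste(head(paste(events$cell, events$gene, sep = "/")[
                is.na(events$coverage)], 3L), collapse = ", "))
    keep <- events$coverage >= minCoverage
    message(sum(!keep), " of ", nrow(events),
        " events removed by the coverage filter")
    out <- events[keep, , drop = FALSE]
    attr(out, "n_removed") <- sum(!keep)
    out
}

.gmmLogLik <- function(x, w, mu, sd) {
    sum(log(w[1L] * dnorm(x, mu[1L], sd[1L]) +
            w[2L] * dnorm(x, mu[2L], sd[2L])))
}

#' Fit a two-component Gaussian mixture by EM
#'
#' Expectation-maximization fit of a two-component Gaussian mixture to the
#' log10 normalized counts of pooled receptor expression events, the model
#' that deconvolves background from abundant OR transcription. Components
#' are returned ordered by mean. Initialization splits the data at a
#' quantile near the median; the best of `nRestarts` jittered restarts is
#' kept. A standard-deviation floor prevents the degenerate
#' likelihood-collapse solutions and makes exact point-mass data (each
#' component a spike) recoverable.
#'
#' @param x numeric values on the log10(normalized counts) scale, at least
#'   two distinct.
#' @param maxIter maximum EM iterations.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param nRestarts number of jittered restarts.
#' @param seed optional seed for the restart jitter.
#' @param sdFloor lower bound on component standard deviations.
#' @param overlapCutoff separation statistic below which the two components
#'   are flagged as overlapping (effectively one cluster).
#' @return a [MixtureFit-class]; its `logLikTrace` is non-decreasing.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(350, 1.2, 0.4), rnorm(150, 4.5, 0.5))
#' fitMixture(x, seed = 1)
#' @export
fitMixture <- function(x, maxIter = 500L, tol = 1e-8, nRestarts = 5L,
                       seed = NULL, sdFloor = 1e-3, overlapCutoff = 2) {
    x <- x[is.finite(x)]
    if (length(unique(x)) < 2L)
        stop("at least 2 distinct values are required to fit the mixture")
    if (!is.null(seed)) set.seed(seed)
    best <- NULL
    for (r in seq_len(nRestarts)) {
        q <- if (r == 1L) 0.5 else min(max(0.5 + rnorm(1L, 0, 0.15),
            0.1), 0.9)
        split <- quantile(x, q, names = FALSE)
        lo <- x[x <= split]; hi <- x[x > split]
        if (!length(hi)) { hi <- max(x); lo <- x[x < max(x)] }
        mu <- c(mean(lo), mean(hi))
        sd2 <- pmax(c(sd(lo), sd(hi)), sdFloor, na.rm = TRUE)
        sd2[is.na(sd2)] <- sdFloor
        w <- c(length(lo), length(hi)) / length(x)
        w <- pmin(pmax(w, 1e-3), 1 - 1e-3); w <- w / sum(w)
        fit <- .emRun(x, w, mu, sd2, maxIter, tol, sdFloor)
        if (is.null(fit)) next
        if (is.null(best) || fit$logLik > best$logLik) best <- fit
    }
    if (is.null(best))
        stop("all EM restarts collapsed to a degenerate fit")
    ord <- order(best$mu)
    sep <- (best$mu[ord[2L]] - best$mu[ord[1L]]) /
        sqrt(mean(best$sd[ord]^2))
    new("MixtureFit",
        weights = best$w[ord], means = best$mu[ord], sds = best$sd[ord],
        tau = NA_real_, nEvents = length(x), logLik = best$logLik,
        logLikTrace = best$trace, converged = best$converged,
        separation = sep, overlapping = sep < overlapCutoff)
}

.emRun <- function(x, w, mu, sd2, maxIter, tol, sdFloor) {
    n <- length(x)
    trace <- numeric(0)
    ll <- -Inf
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        d1 <- w[1L] * dnorm(x, mu[1L], sd2[1L])
        d2 <- w[2L] * dnorm(x, mu[2L], sd2[2L])
        tot <- d1 + d2
        if (any(tot == 0) || any(!is.finite(tot))) return(NULL)
        newll <- sum(log(tot))
        trace <- c(trace, newll)
        if (it > 1L && abs(newll - ll) < tol) {
            ll <- newll
            converged <- TRUE
            break
        }
        ll <- newll
        g <- d1 / tot
        n1 <- sum(g); n2 <- n - n1
        if (n1 < 1e-8 || n2 < 1e-8) return(NULL)
        mu[1L] <- sum(g * x) / n1
        mu[2L] <- sum((1 - g) * x) / n2
        sd2[1L] <- max(sqrt(sum(g * (x - mu[1L])^2) / n1), sdFloor)
        sd2[2L] <- max(sqrt(sum((1 - g) * (x - mu[2L])^2) / n2), sdFloor)
        w <- c(n1, n2) / n
        w <- pmin(pmax(w, 1e-12), 1 - 1e-12)
    }
    list(w = w, mu = mu, sd = sd2, logLik = ll, trace = trace,
        converged = converged)
}

#' Intersection threshold of a two-component mixture
#'
#' Solves \eqn{w_1 N(x; \mu_1, \sigma_1) = w_2 N(x; \mu_2, \sigma_2)} for
#' the crossing point between the two component means: the abundance
#' threshold tau separating background from abundant receptor expression.
#' The equation is quadratic in x; the in-between root is selected, and the
#' equal-variance case reduces to the closed form
#' \eqn{(\mu_1 + \mu_2)/2 + \sigma^2 \log(w_1 / w_2) / (\mu_2 - \mu_1)}.
#'
#' @param fit a converged [MixtureFit-class].
#' @param scale `"counts"` (default) returns `10^x` on the normalized-count
#'   scale; `"log10"` returns the log-scale root.
#' @return the threshold tau.
#' @examples
#' fit <- new("MixtureFit", weights = c(0.5, 0.5), means = c(1, 3),
#'     sds = c(0.5, 0.5), tau = NA_real_, nEvents = 10L, logLik = 0,
#'     logLikTrace = 0, converged = TRUE, separation = 4,
#'     overlapping = FALSE)
#' mixtureIntersection(fit)  # 100
#' @export
mixtureIntersection <- function(fit, scale = c("counts", "log10")) {
    scale <- match.arg(scale)
    if (!fit@converged)
        stop("the mixture fit did not converge")
    w <- fit@weights; mu <- fit@means; s <- fit@sds
    a <- 1 / (2 * s[2L]^2) - 1 / (2 * s[1L]^2)
    b <- mu[1L] / s[1L]^2 - mu[2L] / s[2L]^2
    cc <- mu[2L]^2 / (2 * s[2L]^2) - mu[1L]^2 / (2 * s[1L]^2) +
        log(w[1L] / w[2L]) + log(s[2L] / s[1L])
    if (abs(a) < 1e-12) {
        root <- -cc / b
    } else {
        disc <- b^2 - 4 * a * cc
        if (disc < 0)
            stop("no real intersection between the component means; ",
                "set a manual threshold")
        roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
        inBetween <- roots >= mu[1L] & roots <= mu[2L]
        if (!any(inBetween))
            stop("no intersection lies between the component means; ",
                "set a manual threshold")
        root <- roots[inBetween][1L]
    }
    if (root < mu[1L] || root > mu[2L])
        stop("no intersection lies between the component means; ",
            "set a manual threshold")
    if (scale == "log10") root else 10^root
}

#' Classify cells by abundant receptor content
#'
#' Applies the one neuron-one receptor classification: a receptor gene is
#' abundant in a cell when its normalized counts are at or above the
#' intersection threshold tau. A cell is `monogenic` when exactly one
#' abundant intact OR is present (abundant pseudogenes set the
#' pseudogene-coexpression flag without breaking monogenic status, the
#' behaviour observed for a pseudogene sitting exactly at the threshold),
#' `receptorless` when nothing is abundant, and `coexpressing` otherwise.
#' The dominance ratio (top intact OR over next intact OR, pseudogenes
#' excluded) quantifies how strongly the top receptor dominates.
#'
#' @param events retained expression events (post [coverageFilter()]).
#' @param tau abundance threshold on the normalized-count scale.
#' @param annotation data.frame with `gene_id`, `category`, `status`.
#' @param cells cell ids to classify (defaults to cells present in
#'   `events`; pass the full cohort to classify event-free cells as
#'   receptorless).
#' @return data.frame per cell: `class`, `abundant_intact`,
#'   `abundant_pseudo` (comma-separated ids), `n_background`,
#'   `pseudogene_coexpression`, `dominance`.
#' @export
classifyCells <- function(events, tau, annotation,
                          cells = unique(events$cell)) {
    if (!is.numeric(tau) || tau <= 0)
        stop("'tau' must be a positive threshold")
    ann <- annotation[match(events$gene, annotation$gene_id), ]
    events$intact <- ann$category == "OR" & ann$status == "intact"
    events$pseudo <- ann$category == "OR" & ann$status == "pseudogene"
    res <- lapply(cells, function(cl) {
        ev <- events[events$cell == cl, , drop = FALSE]
        abundant <- ev$norm_counts >= tau
        ai <- ev$gene[abundant & ev$intact]
        ap <- ev$gene[abundant & ev$pseudo]
        nAbund <- sum(abundant)
        cls <- if (nAbund == 0L) "receptorless"
            else if (length(ai) == 1L) "monogenic"
            else "coexpressing"
        intactCounts <- sort(ev$norm_counts[ev$intact], decreasing = TRUE)
        dom <- if (length(intactCounts) >= 2L)
            intactCounts[1L] / intactCounts[2L] else NA_real_
        data.frame(cell = cl, class = cls,
            abundant_intact = paste(ai, collapse = ","),
            abundant_pseudo = paste(ap, collapse = ","),
            n_background = sum(!abundant),
            pseudogene_coexpression = length(ap) > 0L,
            dominance = dom, stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}

#' Run the full receptor-calling pipeline on a cohort
#'
#' Convenience wrapper: normalization (spike-ins excluded), event
#' extraction, coverage filtering, pooled mixture fit on log10 normalized
#' counts, intersection thresholding, and per-cell classification. One
#' global threshold is fitted for the whole cohort, matching the use of a
#' single pair of abundance curves for all cells.
#'
#' @param sce a cohort `SingleCellExperiment`.
#' @param seed seed for the EM restarts.
#' @param ... passed on to [fitMixture()].
#' @return list with `calls` (see [classifyCells()]), `fit` (the
#'   [MixtureFit-class] with `tau` filled in) and `tau`.
#' @examples
#' sce <- generateCohort(cohortPreset("cohort21", seed = 1))
#' res <- callReceptors(sce)
#' table(res$calls$class)
#' @export
callReceptors <- function(sce, seed = 1L, ...) {
    events <- orExpressionEvents(sce)
    retained <- suppressMessages(coverageFilter(events))
    fit <- fitMixture(log10(retained$norm_counts), seed = seed, ...)
    tau <- mixtureIntersection(fit)
    fit@tau <- tau
    validObject(fit)
    calls <- classifyCells(retained, tau,
        as.data.frame(SummarizedExperiment::rowData(sce)),
        cells = colnames(sce))
    list(calls = calls, fit = fit, tau = tau)
}
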