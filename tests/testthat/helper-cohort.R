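# Shared fixtures, generated once per test run. Cohorts are deterministic
# in their SimConfig, so caching does not change what is tested.
.fixtures <- new.env(parent = emptyenv())

getCohort21 <- function() {
    if (is.null(.fixtures$cohort21))
        .fixtures$cohort21 <- generateCohort(cohortPreset("cohort21",
            seed = 1))
    .fixtures$cohort21
}

getCohort58 <- function() {
    if (is.null(.fixtures$cohort58))
        .fixtures$cohort58 <- generateCohort(cohortPreset("cohort58",
            seed = 1))
    .fixtures$cohort58
}

getReceptorCalls21 <- function() {
    if (is.null(.fixtures$calls21))
        .fixtures$calls21 <- callReceptors(getCohort21(), seed = 1)
    .fixtures$calls21
}

# tiny deterministic count matrix for IO and normalization tests
tinyCounts <- function() {
    matrix(c(10L, 20L, 20L, 40L, 30L, 60L), 3L, 2L, byrow = TRUE,
        dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
}
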