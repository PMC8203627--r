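# shared fixture builders; everything is generated in code at test time

# random symmetric Fisher-z-like matrix with zero diagonal
toySymmetricZ <- function(n, seed = 1) {
    withr::with_seed(seed, {
        m <- matrix(rnorm(n * n, sd = 0.5), n)
        m <- (m + t(m)) / 2
        diag(m) <- 0
        m
    })
}

toyConnectivity <- function(n, seed = 1, thresholded = FALSE) {
    new("ConnectivityMatrix", values = toySymmetricZ(n, seed),
        density = 1, thresholded = thresholded, subjectId = "toy")
}

# a connectivity matrix with prescribed row profiles (already
# "thresholded" so affinity/kernel functions accept it)
rowProfileConnectivity <- function(rows) {
    new("ConnectivityMatrix", values = rows, density = 0.5,
        thresholded = TRUE, subjectId = "toy")
}

# random affinity matrix: symmetric, entries in [0, 1], unit diagonal
randomAffinity <- function(n, seed = 1) {
    withr::with_seed(seed, {
        a <- matrix(runif(n * n, 0.05, 1), n)
        a <- (a + t(a)) / 2
        diag(a) <- 1
        a
    })
}

# small embedded cohort: returns aligned set, design and truth
smallAnalysis <- function(nSubjects = 30, nParcels = 60, nModules = 4,
                          nTimepoints = 150, effectSize = 0.13,
                          density = 0.1, seed = 1) {
    atlas <- generateAtlas(nParcels, nModules)
    cohort <- suppressWarnings(generateCohort(atlas,
        nSubjects = nSubjects, nTimepoints = nTimepoints,
        effectSize = effectSize, seed = seed))
    conns <- lapply(names(subjectTimeSeries(cohort)), function(id)
        correlationConnectome(subjectTimeSeries(cohort)[[id]], id))
    aligned <- buildAlignedSet(groupAverageConnectome(conns), conns,
        density = density)
    Y <- array(NA_real_, c(nSubjects, nParcels, 3))
    for (s in seq_len(nSubjects)) Y[s, , ] <- aligned@subjects[[s]]
    list(atlas = atlas, cohort = cohort, aligned = aligned, Y = Y,
        X = designMatrix(subjectCovariates(cohort),
            c("age", "sex", "bmi")))
}

# exhaustive hypergeometric upper-tail by choose() summation
hyperTailOracle <- function(x, K, N, n) {
    if (x <= max(0, K + n - N)) return(1)
    j <- x:min(K, n)
    sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}
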