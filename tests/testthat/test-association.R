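test_that("k = 1 Hotelling reduces to the squared univariate t-test", {
    withr::with_seed(21, {
        n <- 40
        cov <- data.frame(age = runif(n, 20, 40),
            sex = rbinom(n, 1, 0.5), bmi = rlnorm(n, 3.2, 0.2))
        y <- 0.5 + 0.02 * cov$age + 0.1 * cov$bmi + rnorm(n)
    })
    X <- designMatrix(cov, c("age", "sex", "bmi"))
    sm <- hotellingGLM(matrix(y, ncol = 1), X, "bmi")
    fit <- lm(y ~ age + sex + bmi, data = cov)
    tval <- summary(fit)$coefficients["bmi", "t value"]
    pval <- summary(fit)$coefficients["bmi", "Pr(>|t|)"]
    expect_equal(sm@statistic, tval^2, tolerance = 1e-10)
    expect_equal(sm@p, pval, tolerance = 1e-10)
})

test_that("a noise-free zero coefficient yields statistic 0 and p = 1", {
    withr::with_seed(22, {
        n <- 25
        cov <- data.frame(age = runif(n, 20, 40),
            sex = rbinom(n, 1, 0.5), bmi = rlnorm(n, 3.2, 0.2))
    })
    # y depends on age only; bmi coefficient is exactly zero
    Y <- cbind(1 + 0.3 * cov$age, 2 - 0.1 * cov$age)
    X <- designMatrix(cov, c("age", "sex", "bmi"))
    sm <- hotellingGLM(Y, X, "bmi")
    expect_equal(sm@statistic, 0)
    expect_equal(sm@p, 1)
})

test_that("Hotelling p-values are uniform under the null", {
    withr::with_seed(23, {
        n <- 60; P <- 500; k <- 3
        cov <- data.frame(age = runif(n, 22, 36),
            sex = rbinom(n, 1, 0.5), bmi = rlnorm(n, 3.25, 0.19))
        Y <- array(rnorm(n * P * k), c(n, P, k))
    })
    X <- designMatrix(cov, c("age", "sex", "bmi"))
    sm <- hotellingGLM(Y, X, "bmi")
    ks <- suppressWarnings(ks.test(sm@p, "punif"))
    expect_gt(ks$p.value, 0.01)
})

test_that("design matrices reject collinearity and missing columns", {
    cov <- data.frame(age = 1:10, sex = rep(0:1, 5))
    cov$age2 <- 2 * cov$age
    expect_error(designMatrix(cov, c("age", "age2")), "collinear")
    expect_error(designMatrix(cov, c("age", "bmi")), "bmi")
})

test_that("BH adjustment matches a brute-force step-up oracle", {
    bhOracle <- function(p, q) {
        m <- length(p)
        o <- order(p)
        ps <- p[o]
        istar <- suppressWarnings(max(which(ps <= seq_len(m) * q / m)))
        reject <- logical(m)
        if (is.finite(istar)) reject[o[seq_len(istar)]] <- TRUE
        qv <- rev(cummin(rev(ps * m / seq_len(m))))
        qs <- numeric(m)
        qs[o] <- pmin(qv, 1)
        list(q = qs, reject = reject)
    }
    for (seed in 1:5) {
        p <- withr::with_seed(seed, runif(sample(3:50, 1))^2)
        got <- fdrBH(p, 0.05)
        ora <- bhOracle(p, 0.05)
        expect_equal(got$q, ora$q)
        expect_equal(got$reject, ora$reject)
    }
    expect_equal(fdrBH(c(0.01, 0.02, 0.03, 0.04), 0.05)$reject,
        rep(TRUE, 4))
    expect_equal(fdrBH(rep(1, 5), 0.05)$q, rep(1, 5))
    expect_false(any(fdrBH(rep(1, 5), 0.05)$reject))
    one <- fdrBH(0.04, 0.05)
    expect_equal(one$q, 0.04)
    expect_true(one$reject)
    expect_length(fdrBH(numeric(0))$q, 0L)
})

test_that("permutation partial correlation nails perfect association", {
    x <- withr::with_seed(24, rnorm(30))
    res <- partialCorrelationPermutation(x, x, nPerm = 999, seed = 1)
    expect_equal(res$r, 1)
    expect_lte(res$p, 0.005)
    resNeg <- partialCorrelationPermutation(x, -x, nPerm = 999, seed = 1)
    expect_equal(resNeg$r, -1)
    expect_lte(resNeg$p, 0.005)
    expect_error(partialCorrelationPermutation(x, rep(1, 30),
        nPerm = 100), "constant")
})

test_that("permutation p is invariant to common affine transforms", {
    withr::with_seed(25, {
        x <- rnorm(40)
        y <- 0.4 * x + rnorm(40)
        covars <- data.frame(a = rnorm(40))
    })
    r1 <- partialCorrelationPermutation(x, y, covars, nPerm = 199,
        seed = 7)
    r2 <- partialCorrelationPermutation(3 * x - 5, 0.5 * y + 2, covars,
        nPerm = 199, seed = 7)
    expect_equal(r1$r, r2$r, tolerance = 1e-12)
    expect_equal(r1$p, r2$p)
})

test_that("spin nulls reassign values from the input multiset", {
    atlas <- generateAtlas(50, 4)
    map <- withr::with_seed(26, rnorm(50))
    # forced identity rotation returns the map untouched
    ident <- spinNulls(map, atlas, rotations = list(diag(3)))
    expect_equal(ident[, 1], map)
    spun <- spinNulls(map, atlas, nRotations = 20, seed = 2)
    for (r in 1:20) expect_true(all(spun[, r] %in% map))
    # deterministic under the seed
    expect_identical(spun, spinNulls(map, atlas, nRotations = 20,
        seed = 2))
})

test_that("spin rotations decorrelate a random map on average", {
    atlas <- generateAtlas(100, 7)
    map <- withr::with_seed(27, rnorm(100))
    spun <- spinNulls(map, atlas, nRotations = 500, seed = 3)
    rbar <- mean(cor(map, spun))
    expect_lt(abs(rbar), 0.05)
})

test_that("spin nulls preserve spatial autocorrelation better than shuffles", {
    atlas <- generateAtlas(100, 7)
    crd <- parcelCoords(atlas)
    # smooth map: low-order spherical pattern
    map <- crd[, "z"] + 0.7 * crd[, "x"]
    # nearest-neighbour pairs on the sphere
    d <- tcrossprod(crd)
    diag(d) <- -Inf
    nb <- max.col(d)
    neighbourCor <- function(v) cor(v, v[nb])
    spun <- spinNulls(map, atlas, nRotations = 100, seed = 4)
    spinAC <- mean(apply(spun, 2, neighbourCor))
    shufAC <- withr::with_seed(5,
        mean(replicate(100, neighbourCor(sample(map)))))
    expect_gt(spinAC, shufAC)
    expect_gt(spinAC, 0.5)
})

test_that("group comparison equals a 0/1-coded Hotelling model", {
    withr::with_seed(28, {
        n <- 50
        grp <- rbinom(n, 1, 0.5)
        covars <- data.frame(age = runif(n, 20, 40))
        Y <- array(rnorm(n * 10 * 3), c(n, 10, 3))
        Y[, 1:3, 1] <- Y[, 1:3, 1] + 1.5 * grp  # planted shift
    })
    gm <- groupHotelling(Y, grp, covars)
    X <- designMatrix(cbind(data.frame(group = grp), covars),
        c("group", "age"))
    direct <- hotellingGLM(Y, X, "group")
    expect_equal(gm@statistic, direct@statistic)
    expect_equal(gm@p, direct@p)
    # the planted parcels are detected; at most stray FDR noise elsewhere
    expect_true(all(gm@significant[1:3]))
    expect_lte(sum(gm@significant[4:10]), 1)
})

test_that("identical group means in noise-free data give zero statistics", {
    n <- 24
    grp <- rep(0:1, 12)
    age <- seq_len(n)
    Y <- cbind(1 + 0.1 * age, 2 - 0.2 * age)  # no group dependence
    gm <- groupHotelling(Y, grp, data.frame(age = age))
    expect_equal(gm@statistic, 0)
})

test_that("stratified means match a naive group-by oracle", {
    atlas <- generateAtlas(3, 2)  # modules sized 2 and 1
    expect_equal(unname(stratifyMap(c(1, 3, 2), atlas, "module")),
        c(2, 2))
    atlas40 <- generateAtlas(40, 5)
    expect_equal(unname(stratifyMap(rep(7, 40), atlas40, "module")),
        rep(7, 5))
    map <- withr::with_seed(29, rnorm(40))
    byHand <- vapply(levels(moduleLabels(atlas40)), function(m)
        mean(map[moduleLabels(atlas40) == m]), numeric(1))
    expect_equal(stratifyMap(map, atlas40, "module"), byHand)
    expect_error(stratifyMap(map, atlas40, "parcel"))
})

test_that("split-half reproducibility separates planted from null parcels", {
    withr::with_seed(30, {
        n <- 80; P <- 30; k <- 3
        cov <- data.frame(age = runif(n, 22, 36),
            sex = rbinom(n, 1, 0.5), bmi = rlnorm(n, 3.25, 0.19))
        zb <- as.numeric(scale(cov$bmi))
        Y <- array(rnorm(n * P * k), c(n, P, k))
        for (j in 1:3) Y[, 1:8, j] <- Y[, 1:8, j] + 0.8 * zb
    })
    X <- designMatrix(cov, c("age", "sex", "bmi"))
    rep1 <- splitHalfReproducibility(Y, X, "bmi", nTrain = 50,
        nRep = 1, seed = 5)
    expect_identical(rep1, splitHalfReproducibility(Y, X, "bmi",
        nTrain = 50, nRep = 1, seed = 5))
    reps <- splitHalfReproducibility(Y, X, "bmi", nTrain = 50,
        nRep = 25, seed = 6)
    expect_gt(mean(reps$train[1:8]), mean(reps$train[9:P]))
    expect_gt(mean(reps$test[1:8]), mean(reps$test[9:P]))
})
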