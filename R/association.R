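#' Build a design matrix from a covariate table
#'
#' Assembles an intercept plus the named covariate columns, checking for
#' missing values and collinearity.
#'
#' @param covariates data.frame of per-subject covariates.
#' @param terms character vector of column names to include.
#' @return numeric matrix with an `(Intercept)` column first.
#' @export
designMatrix <- function(covariates, terms) {
    .stopIfNot(all(terms %in% names(covariates)),
        "missing covariate column(s): ",
        paste(setdiff(terms, names(covariates)), collapse = ", "))
    X <- cbind(`(Intercept)` = 1,
        as.matrix(covariates[, terms, drop = FALSE]))
    .stopIfNot(!anyNA(X), "design matrix must not contain NA")
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
        stop("rank-deficient design matrix; collinear columns among: ",
            paste(colnames(X), collapse = ", "), call. = FALSE)
    }
    X
}

# single-parcel Hotelling T^2 for one tested design column.
# For a rank-1 hypothesis all classical MANOVA statistics coincide;
# T^2 converts exactly to F with (k, n - p - k + 1) df.
.hotellingOne <- function(Y, X, j, qx = qr(X), XtXinv = chol2inv(qr.R(qx))) {
    n <- nrow(X)
    p <- ncol(X)
    k <- ncol(Y)
    B <- qr.coef(qx, Y)
    E <- qr.resid(qx, Y)
    S <- crossprod(E) / (n - p)
    b <- B[j, ]
    if (max(abs(S)) < 1e-24) {
        # noise-free fit: degenerate residual covariance
        T2 <- if (max(abs(b)) < 1e-12) 0 else Inf
    } else {
        T2 <- drop(crossprod(b, solve(S, b))) / XtXinv[j, j]
    }
    Fstat <- T2 * (n - p - k + 1) / (k * (n - p))
    pval <- stats::pf(Fstat, k, n - p - k + 1, lower.tail = FALSE)
    list(F = Fstat, p = pval, T2 = T2, coef = b)
}

#' Parcel-wise multivariate association (Hotelling's T-squared)
#'
#' Fits, per parcel, the multivariate linear model `Y = X B + E` where Y
#' holds the k manifold components (e.g. aligned E1-E3) and X the design
#' (intercept, age, sex, bmi, ...), and tests the single term `term = 0`
#' across the k responses with Hotelling's T-squared, converted exactly
#' to an F statistic with `(k, n - p - k + 1)` degrees of freedom. For
#' k = 1 the F statistic equals the squared univariate t statistic.
#' Parcel-wise p-values are BH-adjusted across parcels.
#'
#' @param Y numeric array `n_subjects x n_parcels x k` (or an `n x k`
#'   matrix for a single parcel).
#' @param X design matrix from [designMatrix()].
#' @param term name of the tested column of X.
#' @param parcelCovariates optional `n x n_parcels x c` array of
#'   parcel-varying confounds (e.g. regional structural indices) appended
#'   to X per parcel.
#' @param fdrQ FDR threshold for the significance flags.
#' @return a [StatMap-class] (statType "hotelling_F"); attribute
#'   `signedStatistic` carries `sqrt(F)` signed by the first-component
#'   coefficient of the tested term, usable as a t-like decoding map.
#' @export
hotellingGLM <- function(Y, X, term, parcelCovariates = NULL,
                         fdrQ = 0.05) {
    if (is.matrix(Y)) Y <- array(Y, c(nrow(Y), 1L, ncol(Y)))
    .stopIfNot(length(dim(Y)) == 3L,
        "Y must be an n x parcels x k array")
    n <- dim(Y)[1L]
    P <- dim(Y)[2L]
    k <- dim(Y)[3L]
    .stopIfNot(nrow(X) == n, "X must have one row per subject")
    j <- match(term, colnames(X))
    .stopIfNot(!is.na(j), "term '", term, "' not found in design")
    pX <- ncol(X) + if (is.null(parcelCovariates))
        0L else dim(parcelCovariates)[3L]
    .stopIfNot(k < n - pX,
        "too few subjects for ", k, " responses and ", pX, " covariates")
    qx <- NULL
    XtXinv <- NULL
    if (is.null(parcelCovariates)) {
        qx <- qr(X)
        .stopIfNot(qx$rank == ncol(X), "rank-deficient design matrix")
        XtXinv <- chol2inv(qr.R(qx))
    }
    stat <- pval <- signed <- numeric(P)
    for (ip in seq_len(P)) {
        Yp <- matrix(Y[, ip, ], n, k)
        if (is.null(parcelCovariates)) {
            h <- .hotellingOne(Yp, X, j, qx, XtXinv)
        } else {
            Xp <- cbind(X, matrix(parcelCovariates[, ip, ], n))
            h <- .hotellingOne(Yp, Xp, j)
        }
        stat[ip] <- h$F
        pval[ip] <- h$p
        signed[ip] <- sqrt(max(h$F, 0)) * sign(h$coef[1L])
    }
    adj <- fdrBH(pval, fdrQ)
    out <- new("StatMap", statistic = stat, p = pval, q = adj$q,
        significant = adj$reject, threshold = fdrQ, term = term,
        statType = "hotelling_F")
    attr(out, "signedStatistic") <- signed
    out
}

#' Multivariate group comparison
#'
#' Hotelling comparison of manifolds between two groups (e.g. healthy
#' weight vs overweight), controlling for covariates: the group indicator
#' is entered as the tested design term, so this is the same machinery as
#' [hotellingGLM()] by construction.
#'
#' @param Y as in [hotellingGLM()].
#' @param groups binary (0/1 or two-level factor) group labels.
#' @param covars optional data.frame of adjustment covariates (all
#'   columns used).
#' @param fdrQ FDR threshold.
#' @return a [StatMap-class].
#' @export
groupHotelling <- function(Y, groups, covars = NULL, fdrQ = 0.05) {
    if (is.factor(groups)) groups <- as.integer(groups) - 1L
    g <- as.numeric(groups)
    .stopIfNot(all(g %in% c(0, 1)), "groups must be binary")
    k <- if (is.matrix(Y)) ncol(Y) else dim(Y)[3L]
    .stopIfNot(min(table(g)) >= k + 2L,
        "each group must contain at least k + 2 subjects")
    df <- data.frame(group = g)
    if (!is.null(covars)) df <- cbind(df, covars)
    X <- designMatrix(df, names(df))
    hotellingGLM(Y, X, "group", fdrQ = fdrQ)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjustment (via [stats::p.adjust()]) with a rejection mask
#' at the given threshold.
#'
#' @param p numeric p-values in \code{[0, 1]}.
#' @param q FDR threshold (default 0.05).
#' @return list with `q` (adjusted q-values) and `reject` (logical mask,
#'   `q < threshold`).
#' @export
fdrBH <- function(p, q = 0.05) {
    .stopIfNot(all(is.na(p) | (p >= 0 & p <= 1)),
        "p-values must lie in [0, 1]")
    qv <- stats::p.adjust(p, method = "BH")
    list(q = qv, reject = !is.na(qv) & qv < q)
}

#' Partial correlation with a subject-permutation null
#'
#' Correlates the residuals of `x` and `y` after regressing out `covars`
#' (plus an intercept), and assesses two-tailed significance by permuting
#' the residualised response (Freedman-Lane style), which preserves the
#' covariate structure. The add-one rule keeps p-values strictly
#' positive: `p = (1 + #{|r_null| >= |r_obs|}) / (nPerm + 1)`.
#'
#' @param x,y numeric subject vectors.
#' @param covars optional data.frame/matrix of nuisance covariates.
#' @param nPerm number of permutations (>= 100; default 5000).
#' @param seed integer seed.
#' @return list with `r`, `p`, and the permutation null vector `rNull`.
#' @export
partialCorrelationPermutation <- function(x, y, covars = NULL,
                                          nPerm = 5000L, seed = 1L) {
    .stopIfNot(length(x) == length(y), "x and y must have equal length")
    .stopIfNot(nPerm >= 100L, "nPerm must be >= 100")
    n <- length(x)
    X <- if (is.null(covars)) matrix(1, n, 1L)
        else cbind(1, as.matrix(covars))
    qx <- qr(X)
    rx <- qr.resid(qx, x)
    ry <- qr.resid(qx, y)
    tolx <- 1e-10 * (1 + max(abs(x)))
    toly <- 1e-10 * (1 + max(abs(y)))
    .stopIfNot(stats::sd(rx) > tolx && stats::sd(ry) > toly,
        "constant residuals: partial correlation undefined")
    robs <- stats::cor(rx, ry)
    .withSeed(seed, {
        perm <- replicate(nPerm, sample.int(n))
        rnull <- as.numeric(stats::cor(rx, matrix(ry[perm], n)))
        p <- (1 + sum(abs(rnull) >= abs(robs))) / (nPerm + 1)
        list(r = robs, p = p, rNull = rnull)
    })
}

#' Spherical-rotation (spin) null maps
#'
#' Generates spatial null maps that preserve the spatial autocorrelation
#' of the input better than free shuffling: each null applies a uniformly
#' random 3D rotation to the parcel centroids and reassigns every parcel
#' the value of the nearest rotated centroid (duplicates allowed).
#'
#' @param map numeric parcel vector.
#' @param atlas a [ParcelAtlas-class] with unit-sphere centroids.
#' @param nRotations number of null maps (default 100).
#' @param seed integer seed.
#' @param rotations optional list of fixed 3 x 3 rotation matrices to use
#'   instead of random draws (e.g. `list(diag(3))` for the identity).
#' @return numeric matrix `n_parcels x nRotations` of rotated maps.
#' @export
spinNulls <- function(map, atlas, nRotations = 100L, seed = 1L,
                      rotations = NULL) {
    coords <- parcelCoords(atlas)
    n <- nrow(coords)
    .stopIfNot(n >= 2L, "at least 2 parcels required")
    .stopIfNot(length(map) == n, "map must have one value per parcel")
    if (!is.null(rotations)) nRotations <- length(rotations)
    .withSeed(seed, {
        out <- matrix(NA_real_, n, nRotations)
        for (r in seq_len(nRotations)) {
            R <- if (is.null(rotations)) .randomRotation3()
                else rotations[[r]]
            sim <- coords %*% R %*% t(coords)  # sim[i, j] = c_i . (R c_j)
            out[, r] <- map[max.col(sim, ties.method = "first")]
        }
        out
    })
}

#' Stratify a statistic map by atlas labels
#'
#' Arithmetic mean of the per-parcel statistic within each module or
#' hierarchy category (the values a spider plot would display).
#'
#' @param stat a [StatMap-class] or numeric parcel vector.
#' @param atlas a [ParcelAtlas-class].
#' @param by `"module"` or `"hierarchy"`.
#' @return named numeric vector of category means.
#' @export
stratifyMap <- function(stat, atlas, by = c("module", "hierarchy")) {
    by <- match.arg(by)
    v <- if (is(stat, "StatMap")) stat@statistic else as.numeric(stat)
    .stopIfNot(length(v) == nParcels(atlas),
        "statistic must have one value per parcel")
    labs <- if (by == "module") moduleLabels(atlas)
        else hierarchyLabels(atlas)
    out <- tapply(v, labs, mean)
    stats::setNames(as.numeric(out), names(out))
}

#' Split-half reproducibility of parcel-wise detections
#'
#' Repeatedly splits the cohort into a train half of `nTrain` subjects
#' and its complement, refits the Hotelling model on each half, and
#' reports the per-parcel frequency of FDR-significant detections.
#'
#' @param Y subject x parcel x k response array.
#' @param X design matrix.
#' @param term tested term.
#' @param nTrain train-split size (< number of subjects).
#' @param nRep number of random splits (default 100).
#' @param fdrQ FDR threshold per fit.
#' @param seed integer seed.
#' @return list with `train` and `test` per-parcel detection frequencies.
#' @export
splitHalfReproducibility <- function(Y, X, term, nTrain, nRep = 100L,
                                     fdrQ = 0.05, seed = 1L) {
    n <- dim(Y)[1L]
    k <- dim(Y)[3L]
    .stopIfNot(nTrain < n, "nTrain must be smaller than the cohort")
    .stopIfNot(n - nTrain > ncol(X) + k,
        "complement too small for the model")
    P <- dim(Y)[2L]
    hitsTrain <- hitsTest <- numeric(P)
    .withSeed(seed, {
        for (r in seq_len(nRep)) {
            idx <- sample.int(n, nTrain)
            sTrain <- hotellingGLM(Y[idx, , , drop = FALSE],
                X[idx, , drop = FALSE], term, fdrQ = fdrQ)
            sTest <- hotellingGLM(Y[-idx, , , drop = FALSE],
                X[-idx, , drop = FALSE], term, fdrQ = fdrQ)
            hitsTrain <- hitsTrain + sTrain@significant
            hitsTest <- hitsTest + sTest@significant
        }
        list(train = hitsTrain / nRep, test = hitsTest / nRep)
    })
}
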