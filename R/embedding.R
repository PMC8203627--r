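#' Normalized-angle affinity between connectivity profiles
#'
#' Affinity between parcels i and j is `1 - acos(cos_sim(row_i, row_j))/pi`
#' where `cos_sim` is the cosine similarity of their (thresholded)
#' connectivity rows. Parallel profiles map to 1, orthogonal to 0.5,
#' anti-parallel to 0. The diagonal is 1.
#'
#' @param C a thresholded [ConnectivityMatrix-class] with no all-zero row.
#' @return numeric parcel x parcel affinity matrix in \code{[0, 1]}.
#' @export
normalizedAngleAffinity <- function(C) {
    .stopIfNot(is(C, "ConnectivityMatrix"),
        "C must be a ConnectivityMatrix")
    .stopIfNot(isThresholded(C),
        "affinity expects a density-thresholded connectome")
    v <- connValues(C)
    norms <- sqrt(rowSums(v^2))
    if (any(norms == 0)) {
        stop("all-zero connectivity row for parcel(s): ",
            paste(which(norms == 0), collapse = ", "), call. = FALSE)
    }
    u <- v / norms
    cosim <- .clip(tcrossprod(u), -1, 1)
    A <- 1 - acos(cosim) / pi
    A <- (A + t(A)) / 2
    diag(A) <- 1
    A
}

#' Diffusion map embedding of an affinity matrix
#'
#' Implements the alpha-normalised diffusion map: with degree matrix D of
#' the affinity A, form `W = D^-alpha A D^-alpha`, take the Markov
#' operator `P = Dw^-1 W`, and eigendecompose via the symmetric conjugate
#' `S = Dw^-1/2 W Dw^-1/2` for numerical stability. The trivial constant
#' eigenvector (eigenvalue 1) is discarded. With `t = 0` the multiscale
#' convention scales eigenvector i by `lambda_i / (1 - lambda_i)`;
#' otherwise by `lambda_i^t`. Eigenvector signs are pinned by making each
#' column's largest-magnitude entry positive, so the embedding is fully
#' deterministic. Per-component variance explained is
#' `lambda_i / sum(lambda_j)` over all nontrivial nonnegative eigenvalues.
#'
#' @param A symmetric nonnegative affinity matrix (e.g. from
#'   [normalizedAngleAffinity()]).
#' @param alpha density-normalisation exponent in \code{[0, 1]}
#'   (0.5 by default: approximate Laplace-Beltrami normalisation).
#' @param t diffusion time; `t = 0` selects the multiscale scaling.
#' @param nComponents number of nontrivial components to return.
#' @return a [ManifoldEmbedding-class].
#' @export
diffusionMapEmbed <- function(A, alpha = 0.5, t = 0, nComponents = 3L) {
    .stopIfNot(is.matrix(A) && nrow(A) == ncol(A),
        "A must be a square matrix")
    n <- nrow(A)
    .stopIfNot(nComponents < n,
        "nComponents must be smaller than the parcel count")
    .stopIfNot(max(abs(A - t(A))) < 1e-8, "A must be symmetric")
    .stopIfNot(min(A) >= 0, "A must be nonnegative")

    d <- rowSums(A)
    .stopIfNot(all(d > 0), "A must have positive row sums")
    W <- A / outer(d^alpha, d^alpha)
    dw <- rowSums(W)
    isq <- 1 / sqrt(dw)
    S <- W * outer(isq, isq)
    S <- (S + t(S)) / 2
    eig <- eigen(S, symmetric = TRUE)
    lambda <- eig$values
    if (lambda[2] > 1 - 1e-8) {
        stop("disconnected affinity graph: multiple unit eigenvalues",
            call. = FALSE)
    }
    # right eigenvectors of P = Dw^-1 W; first one is constant (trivial)
    U <- eig$vectors * isq
    lam <- lambda[-1L]
    U <- U[, -1L, drop = FALSE]
    nonneg <- lam[lam > 0]
    vexp <- ifelse(lam > 0, lam / sum(nonneg), 0)

    idx <- seq_len(nComponents)
    lamK <- lam[idx]
    scaleK <- if (t == 0) lamK / (1 - lamK) else lamK^t
    V <- sweep(U[, idx, drop = FALSE], 2L, scaleK, `*`)
    for (j in seq_len(ncol(V))) {
        i <- which.max(abs(V[, j]))
        if (V[i, j] < 0) V[, j] <- -V[, j]
    }
    colnames(V) <- sprintf("E%d", idx)
    new("ManifoldEmbedding",
        vectors = V,
        eigenvalues = lamK,
        varianceExplained = vexp[idx],
        alpha = alpha,
        t = t)
}

#' Orthogonal Procrustes alignment
#'
#' Finds the orthogonal matrix R (reflections allowed, no scaling, no
#' centering) minimising `||source %*% R - target||_F` via the SVD of
#' `t(source) %*% target`.
#'
#' @param source,target numeric matrices of equal dimension (parcels x k).
#' @return list with `aligned` (= `source %*% R`) and `rotation` R.
#' @export
procrustesAlign <- function(source, target) {
    .stopIfNot(all(dim(source) == dim(target)),
        "source and target must have equal shape")
    M <- crossprod(source, target)
    sv <- svd(M)
    if (min(sv$d) < 1e-12 * max(sv$d, 1e-300)) {
        warning("rank-deficient cross-covariance in Procrustes alignment")
    }
    R <- sv$u %*% t(sv$v)
    list(aligned = source %*% R, rotation = R)
}

#' Template manifold with Procrustes-aligned subjects
#'
#' Estimates the template manifold from the group-average connectome
#' (density thresholding, normalized-angle affinity, diffusion map), embeds
#' every subject connectome with identical parameters and aligns each to
#' the template by orthogonal Procrustes. More components than reported
#' are computed internally (`nComputed`, default 10) so the alignment and
#' variance fractions rest on a richer spectrum; the leading
#' `nComponents` are returned.
#'
#' @param groupC unthresholded group [ConnectivityMatrix-class].
#' @param subjectCs list of unthresholded subject connectomes.
#' @param density connection density for thresholding (default 0.10).
#' @param alpha,t diffusion-map parameters (defaults 0.5 and 0).
#' @param nComponents components reported (default 3: E1-E3).
#' @param nComputed components computed internally (default 10).
#' @return an [AlignedManifoldSet-class].
#' @export
buildAlignedSet <- function(groupC, subjectCs, density = 0.10,
                            alpha = 0.5, t = 0, nComponents = 3L,
                            nComputed = 10L) {
    nComputed <- max(nComputed, nComponents)
    embedOne <- function(cm) {
        A <- normalizedAngleAffinity(thresholdByDensity(cm, density))
        diffusionMapEmbed(A, alpha = alpha, t = t,
            nComponents = min(nComputed, nrow(A) - 1L))
    }
    template <- embedOne(groupC)
    Tfull <- embeddingVectors(template)
    keep <- seq_len(nComponents)
    templateK <- new("ManifoldEmbedding",
        vectors = Tfull[, keep, drop = FALSE],
        eigenvalues = embeddingEigenvalues(template)[keep],
        varianceExplained = varianceExplained(template)[keep],
        alpha = alpha, t = t)

    # subjects are aligned in the full computed space; the reported
    # components are the leading columns of the aligned matrices
    subjects <- vector("list", length(subjectCs))
    rotations <- vector("list", length(subjectCs))
    for (s in seq_along(subjectCs)) {
        emb <- embedOne(subjectCs[[s]])
        pa <- procrustesAlign(embeddingVectors(emb), Tfull)
        subjects[[s]] <- pa$aligned[, keep, drop = FALSE]
        rotations[[s]] <- pa$rotation
    }
    ids <- names(subjectCs)
    if (is.null(ids)) ids <- sprintf("sub%04d", seq_along(subjectCs))
    names(subjects) <- ids
    names(rotations) <- ids
    new("AlignedManifoldSet",
        template = templateK,
        subjects = subjects,
        rotations = rotations)
}
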