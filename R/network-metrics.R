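#' Manifold eccentricity
#'
#' Per-parcel Euclidean distance between a subject's (aligned) manifold
#' coordinates and the template manifold centre, conventionally the
#' column mean of the template eigenvectors. Larger values index greater
#' differentiation of a region within the manifold.
#'
#' @param embedding numeric parcel x k matrix of manifold coordinates.
#' @param center numeric k-vector; use
#'   `colMeans(embeddingVectors(template))`.
#' @return numeric nonnegative vector, one value per parcel.
#' @export
manifoldEccentricity <- function(embedding, center) {
    if (is(embedding, "ManifoldEmbedding"))
        embedding <- embeddingVectors(embedding)
    .stopIfNot(ncol(embedding) == length(center),
        "center length must equal the embedding dimension")
    sqrt(rowSums(sweep(embedding, 2L, center)^2))
}

# symmetrize a (possibly row-thresholded) matrix and zero negatives,
# the nonnegative-weight convention assumed by modular graph measures
.prepGraphMatrix <- function(W) {
    if (is(W, "ConnectivityMatrix")) W <- connValues(W)
    W <- pmax(W, t(W))
    W[W < 0] <- 0
    diag(W) <- 0
    W
}

.partitionLabels <- function(partition, n) {
    if (is.factor(partition)) partition <- as.character(partition)
    .stopIfNot(length(partition) == n,
        "partition must label every parcel")
    .stopIfNot(!anyNA(partition), "partition labels must not be NA")
    partition
}

#' Within-module degree z-score
#'
#' For each parcel, the summed edge weight to parcels of its own module,
#' z-scored against the parcels of that module (population SD). Modules
#' with zero weight variance (including singletons, which trigger a
#' warning) yield z = 0.
#'
#' @param W symmetric weighted matrix or [ConnectivityMatrix-class]
#'   (symmetrised, negatives zeroed internally).
#' @param partition per-parcel module labels (factor or character).
#' @return numeric z-score per parcel.
#' @export
withinModuleDegree <- function(W, partition) {
    W <- .prepGraphMatrix(W)
    n <- nrow(W)
    labs <- .partitionLabels(partition, n)
    z <- numeric(n)
    for (m in unique(labs)) {
        idx <- which(labs == m)
        if (length(idx) == 1L) {
            warning("singleton module '", m, "': z set to 0")
            next
        }
        kappa <- rowSums(W[idx, idx, drop = FALSE])
        mu <- mean(kappa)
        sdm <- sqrt(mean((kappa - mu)^2))  # population SD
        z[idx] <- if (sdm > 0) (kappa - mu) / sdm else 0
    }
    z
}

#' Participation coefficient
#'
#' `PC_p = 1 - sum_m (kappa_pm / kappa_p)^2` where `kappa_pm` is parcel
#' p's summed edge weight into module m and `kappa_p` its total strength.
#' 0 means all edges stay within one module; values approach 1 as edges
#' spread evenly across modules. Isolated parcels (zero strength) get
#' PC = 0 with a warning.
#'
#' @inheritParams withinModuleDegree
#' @return numeric in \code{[0, 1]} per parcel.
#' @export
participationCoefficient <- function(W, partition) {
    W <- .prepGraphMatrix(W)
    n <- nrow(W)
    labs <- .partitionLabels(partition, n)
    mods <- unique(labs)
    kappaM <- vapply(mods, function(m)
        rowSums(W[, labs == m, drop = FALSE]), numeric(n))
    if (n == 1L) kappaM <- matrix(kappaM, nrow = 1L)
    kappa <- rowSums(kappaM)
    pc <- numeric(n)
    iso <- kappa == 0
    if (any(iso)) warning(sum(iso), " isolated parcel(s): PC set to 0")
    ok <- !iso
    pc[ok] <- 1 - rowSums((kappaM[ok, , drop = FALSE] / kappa[ok])^2)
    pc
}

#' Louvain community detection with seeded restarts
#'
#' Runs greedy Louvain modularity optimisation `nRestarts` times under a
#' fixed random seed and keeps the partition with the highest modularity.
#' Negative weights are zeroed and the matrix symmetrised first.
#'
#' @param W symmetric weighted matrix or [ConnectivityMatrix-class].
#' @param resolution Louvain resolution parameter (default 1).
#' @param nRestarts number of restarts (default 100).
#' @param seed integer seed making the result deterministic.
#' @return integer vector of module ids (1-based), one per parcel.
#' @export
louvainPartition <- function(W, resolution = 1, nRestarts = 100L,
                             seed = 1L) {
    W <- .prepGraphMatrix(W)
    .stopIfNot(sum(W) > 0, "empty graph: no positive edge weight")
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
        weighted = TRUE, diag = FALSE)
    .withSeed(seed, {
        best <- NULL
        bestQ <- -Inf
        for (r in seq_len(nRestarts)) {
            cl <- igraph::cluster_louvain(g, resolution = resolution)
            q <- igraph::modularity(g, igraph::membership(cl),
                weights = igraph::E(g)$weight)
            if (q > bestQ) {
                bestQ <- q
                best <- as.integer(igraph::membership(cl))
            }
        }
        structure(best, modularity = bestQ)
    })
}

#' Betweenness, eigenvector and degree centrality
#'
#' Degree centrality is the node strength (summed edge weight);
#' eigenvector centrality is the nonnegative unit-norm principal
#' eigenvector of the weight matrix; betweenness counts weighted shortest
#' paths (edge length = 1/weight) through each node, normalised by
#' `(n-1)(n-2)/2`. Disconnected graphs are handled per component with a
#' warning.
#'
#' @param W symmetric nonnegative matrix or [ConnectivityMatrix-class].
#' @return data.frame with columns `betweenness`, `eigenvector`, `degree`.
#' @export
graphCentralities <- function(W) {
    W <- .prepGraphMatrix(W)
    n <- nrow(W)
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
        weighted = TRUE, diag = FALSE)
    if (igraph::components(g)$no > 1L)
        warning("disconnected graph: betweenness computed per component")
    btw <- igraph::betweenness(g, weights = 1 / igraph::E(g)$weight,
        normalized = TRUE)
    ev <- igraph::eigen_centrality(g,
        weights = igraph::E(g)$weight)$vector
    ev <- abs(ev)
    ev <- ev / sqrt(sum(ev^2))
    data.frame(
        betweenness = as.numeric(btw),
        eigenvector = as.numeric(ev),
        degree = rowSums(W))
}
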