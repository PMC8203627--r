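#' Associate a statistic map with donor-level gene expression
#'
#' For every gene, correlates its parcel expression profile with the
#' input map within each donor, aggregates donor correlations by the
#' Fisher-z mean (back-transformed to r), and derives a parametric
#' p-value from a two-sided one-sample t-test on the donor z-values
#' (a random-intercept-free approximation to a donor mixed-effect model).
#' Constant genes are skipped per donor with a warning; genes constant in
#' every donor get NA.
#'
#' @param tMap numeric parcel vector (e.g. the signed Hotelling map).
#' @param panel a [GeneExpressionPanel-class] on the same parcels.
#' @return data.frame (gene, statistic, p, nDonorsUsed) with one row per
#'   gene, plus attribute `donorZ` (gene x donor matrix of z values).
#' @export
geneMapAssociation <- function(tMap, panel) {
    nd <- length(donorIds(panel))
    np <- ncol(donorExpression(panel, 1L))
    .stopIfNot(length(tMap) == np,
        "tMap must match the panel's parcel dimension")
    genes <- geneIds(panel)
    Z <- matrix(NA_real_, length(genes), nd,
        dimnames = list(genes, donorIds(panel)))
    nskip <- 0L
    for (d in seq_len(nd)) {
        m <- donorExpression(panel, d)
        sds <- apply(m, 1L, stats::sd)
        ok <- sds > 0
        nskip <- nskip + sum(!ok)
        r <- suppressWarnings(
            as.numeric(stats::cor(t(m[ok, , drop = FALSE]), tMap)))
        Z[ok, d] <- .fisherZ(r)
    }
    if (nskip > 0)
        warning(nskip, " constant gene/donor profile(s) skipped")
    used <- rowSums(!is.na(Z))
    zbar <- rowMeans(Z, na.rm = TRUE)
    zsd <- apply(Z, 1L, stats::sd, na.rm = TRUE)
    tstat <- ifelse(used >= 2 & zsd > 0,
        zbar / (zsd / sqrt(used)), NA_real_)
    p <- 2 * stats::pt(-abs(tstat), df = used - 1)
    # exact donor agreement: zero variance across donors
    degen <- used >= 2 & !is.na(zsd) & zsd == 0
    p[degen] <- ifelse(abs(zbar[degen]) > 0, 0, 1)
    p[used == 0] <- NA_real_
    out <- data.frame(
        gene = genes,
        statistic = ifelse(used > 0, tanh(zbar), NA_real_),
        p = p,
        nDonorsUsed = used,
        stringsAsFactors = FALSE)
    attr(out, "donorZ") <- Z
    out
}

#' Spin-null significance filter for gene associations
#'
#' Re-computes the gene-map association against spherically rotated
#' copies of the input map, forming a per-gene null of Fisher-z mean
#' correlations. The per-gene spin p-value uses the add-one rule
#' (`(1 + #{|null| >= |obs|}) / (nRotations + 1)`, so the minimal
#' attainable p is `1/(nRotations + 1)`); BH-FDR is applied across the
#' tested genes and survivors are returned.
#'
#' @param assoc result of [geneMapAssociation()] on `tMap`.
#' @param tMap the observed parcel map.
#' @param atlas a [ParcelAtlas-class] (spin geometry).
#' @param panel the [GeneExpressionPanel-class].
#' @param nRotations number of rotations (default 100).
#' @param seed integer seed.
#' @param q FDR threshold (default 0.05).
#' @param genes genes to test; by default those whose parametric
#'   association p passes BH-FDR at `q`.
#' @return character vector of surviving gene ids; attribute `spinP`
#'   carries the per-gene spin p-values.
#' @export
spinSignificanceFilter <- function(assoc, tMap, atlas, panel,
                                   nRotations = 100L, seed = 1L,
                                   q = 0.05, genes = NULL) {
    if (nRotations < 10L)
        warning("fewer than 10 rotations: spin p resolution is unstable")
    if (is.null(genes)) {
        keep <- fdrBH(assoc$p, q)$reject
        genes <- assoc$gene[keep]
    }
    if (!length(genes)) {
        out <- character()
        attr(out, "spinP") <- numeric()
        return(out)
    }
    gi <- match(genes, geneIds(panel))
    .stopIfNot(!anyNA(gi), "unknown gene id(s) in 'genes'")
    obs <- assoc$statistic[match(genes, assoc$gene)]
    obsZ <- .fisherZ(obs)

    spins <- spinNulls(tMap, atlas, nRotations = nRotations, seed = seed)
    nd <- length(donorIds(panel))
    nullZ <- matrix(0, length(genes), nRotations)
    used <- matrix(0L, length(genes), nRotations)
    for (d in seq_len(nd)) {
        m <- donorExpression(panel, d)[gi, , drop = FALSE]
        sds <- apply(m, 1L, stats::sd)
        ok <- sds > 0
        r <- suppressWarnings(
            stats::cor(t(m[ok, , drop = FALSE]), spins))
        # rotated maps can be constant if one value floods the sphere
        r[is.na(r)] <- 0
        nullZ[ok, ] <- nullZ[ok, ] + .fisherZ(r)
        used[ok, ] <- used[ok, ] + 1L
    }
    nullZ <- nullZ / pmax(used, 1L)
    pspin <- (1 + rowSums(abs(nullZ) >= abs(obsZ))) / (nRotations + 1)
    survivors <- genes[fdrBH(pspin, q)$reject]
    attr(survivors, "spinP") <- stats::setNames(pspin, genes)
    survivors
}

#' Donor-consistency filter
#'
#' Keeps genes whose parcel expression profiles agree across donors:
#' all pairwise donor-donor profile correlations are Fisher-z
#' transformed and tested one-sided for a positive mean (one-sample t
#' across the `choose(nDonors, 2)` pairs; with exactly one pair, a
#' normal test on the single z-value with variance `1/(nParcels - 3)` is
#' used). BH-FDR across the tested genes.
#'
#' @param panel a [GeneExpressionPanel-class] with >= 2 donors.
#' @param genes gene ids to test.
#' @param q FDR threshold (default 0.05).
#' @return character vector of consistent genes; attribute `consistencyP`
#'   carries the per-gene p-values, `meanPairwiseR` the mean pairwise
#'   donor correlations.
#' @export
donorConsistencyFilter <- function(panel, genes, q = 0.05) {
    nd <- length(donorIds(panel))
    .stopIfNot(nd >= 2L,
        "donor consistency undefined with a single donor")
    if (!length(genes)) {
        out <- character()
        attr(out, "consistencyP") <- numeric()
        return(out)
    }
    gi <- match(genes, geneIds(panel))
    .stopIfNot(!anyNA(gi), "unknown gene id(s) in 'genes'")
    np <- ncol(donorExpression(panel, 1L))
    pairs <- utils::combn(nd, 2L)
    zmat <- matrix(NA_real_, length(genes), ncol(pairs))
    for (ip in seq_len(ncol(pairs))) {
        a <- donorExpression(panel, pairs[1L, ip])[gi, , drop = FALSE]
        b <- donorExpression(panel, pairs[2L, ip])[gi, , drop = FALSE]
        r <- vapply(seq_along(gi), function(g)
            suppressWarnings(stats::cor(a[g, ], b[g, ])), numeric(1))
        zmat[, ip] <- .fisherZ(r)
    }
    zbar <- rowMeans(zmat, na.rm = TRUE)
    if (ncol(pairs) == 1L) {
        p <- stats::pnorm(zbar * sqrt(np - 3), lower.tail = FALSE)
    } else {
        zsd <- apply(zmat, 1L, stats::sd, na.rm = TRUE)
        tstat <- zbar / (zsd / sqrt(ncol(pairs)))
        p <- stats::pt(tstat, df = ncol(pairs) - 1, lower.tail = FALSE)
        p[!is.na(zsd) & zsd == 0] <- ifelse(
            zbar[!is.na(zsd) & zsd == 0] > 0, 0, 1)
    }
    p[is.na(p)] <- 1
    survivors <- genes[fdrBH(p, q)$reject]
    attr(survivors, "consistencyP") <- stats::setNames(p, genes)
    attr(survivors, "meanPairwiseR") <- stats::setNames(tanh(zbar), genes)
    survivors
}

#' Hypergeometric (Fisher one-sided) gene-set enrichment
#'
#' For each set, tests over-representation of the gene list with the
#' one-sided hypergeometric tail `P(X >= overlap)`, reports the 2x2-table
#' odds ratio and a normal-approximation z-score alongside, and
#' BH-adjusts p-values across sets.
#'
#' @param geneList character vector of selected genes (subset of
#'   `universe`).
#' @param geneSets named list of character vectors (intersected with the
#'   universe).
#' @param universe character vector of the gene universe.
#' @return data.frame with columns set_id, overlap, set_size, list_size,
#'   universe, odds_ratio, z, p, q.
#' @export
fisherEnrichment <- function(geneList, geneSets, universe) {
    .stopIfNot(length(universe) > 0, "empty gene universe")
    universe <- unique(universe)
    geneList <- unique(geneList)
    .stopIfNot(all(geneList %in% universe),
        "geneList must be a subset of the universe")
    N <- length(universe)
    nl <- length(geneList)
    rows <- lapply(names(geneSets), function(sid) {
        set <- intersect(geneSets[[sid]], universe)
        K <- length(set)
        x <- length(intersect(set, geneList))
        p <- if (K == 0 || nl == 0) 1
            else stats::phyper(x - 1, K, N - K, nl, lower.tail = FALSE)
        mu <- nl * K / N
        v <- nl * (K / N) * ((N - K) / N) * ((N - nl) / (N - 1))
        zsc <- if (v > 0) (x - mu) / sqrt(v) else 0
        a <- x; b <- nl - x; cc <- K - x; dd <- N - K - b
        orr <- if (b * cc == 0) {
            if (a * dd == 0) NA_real_ else Inf
        } else (a * dd) / (b * cc)
        data.frame(set_id = sid, overlap = x, set_size = K,
            list_size = nl, universe = N, odds_ratio = orr,
            z = zsc, p = p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$q <- stats::p.adjust(out$p, method = "BH")
    out
}

#' Cell-type specificity enrichment across nested thresholds
#'
#' Runs [fisherEnrichment()] for every (cell type, pSI threshold) gene
#' set of a [CellTypeSpecificity-class] profile and BH-adjusts p-values
#' across all cells jointly, mirroring the hexagon layout (threshold =
#' ring) of cell-type specificity analyses.
#'
#' @param geneList character vector of selected genes.
#' @param specificity a [CellTypeSpecificity-class].
#' @param universe gene universe (default: the specificity profile's
#'   genes).
#' @return data.frame with cell_type and threshold columns plus the
#'   [fisherEnrichment()] fields, q recomputed across all cells.
#' @export
cseaEnrichment <- function(geneList, specificity,
                           universe = NULL) {
    .stopIfNot(is(specificity, "CellTypeSpecificity"),
        "specificity must be a CellTypeSpecificity")
    if (is.null(universe)) universe <- specificity@geneIds
    sets <- membershipSets(specificity)
    # nestedness is guaranteed by thresholding one index, but verify
    for (ct in names(sets)) {
        ss <- sets[[ct]]
        for (i in seq_len(length(ss) - 1L)) {
            .stopIfNot(all(ss[[i + 1L]] %in% ss[[i]]),
                "membership sets must be nested (stricter within looser)")
        }
    }
    tabs <- lapply(names(sets), function(ct) {
        tab <- fisherEnrichment(intersect(geneList, universe),
            sets[[ct]], universe)
        data.frame(cell_type = ct,
            threshold = as.numeric(tab$set_id),
            tab[, setdiff(names(tab), c("set_id", "q"))],
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, tabs)
    out$q <- stats::p.adjust(out$p, method = "BH")
    rownames(out) <- NULL
    out
}
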