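#' @rdname ParcelAtlas-class
setMethod("nParcels", "ParcelAtlas", function(x) length(x@parcelId))

#' @rdname ParcelAtlas-class
setMethod("parcelCoords", "ParcelAtlas", function(x) x@coords)

#' @rdname ParcelAtlas-class
setMethod("moduleLabels", "ParcelAtlas", function(x) x@module)

#' @rdname ParcelAtlas-class
setMethod("hierarchyLabels", "ParcelAtlas", function(x) x@hierarchy)

#' @rdname ConnectivityMatrix-class
setMethod("nParcels", "ConnectivityMatrix", function(x) nrow(x@values))

#' @rdname ConnectivityMatrix-class
setMethod("connValues", "ConnectivityMatrix", function(x) x@values)

#' @rdname ConnectivityMatrix-class
setMethod("connDensity", "ConnectivityMatrix", function(x) x@density)

#' @rdname ConnectivityMatrix-class
setMethod("isThresholded", "ConnectivityMatrix", function(x) x@thresholded)

#' @rdname ManifoldEmbedding-class
setMethod("embeddingVectors", "ManifoldEmbedding", function(x) x@vectors)

#' @rdname ManifoldEmbedding-class
setMethod("embeddingEigenvalues", "ManifoldEmbedding",
    function(x) x@eigenvalues)

#' @rdname ManifoldEmbedding-class
setMethod("varianceExplained", "ManifoldEmbedding",
    function(x) x@varianceExplained)

#' @rdname SyntheticCohort-class
setMethod("nParcels", "SyntheticCohort", function(x) nParcels(x@atlas))

#' @rdname SyntheticCohort-class
setMethod("subjectCovariates", "SyntheticCohort", function(x) x@covariates)

#' @rdname SyntheticCohort-class
setMethod("subjectTimeSeries", "SyntheticCohort", function(x) x@timeSeries)

#' @rdname SyntheticCohort-class
setMethod("cohortTruth", "SyntheticCohort", function(x) x@truth)

#' @rdname StatMap-class
setMethod("statTable", "StatMap", function(x) {
    data.frame(
        parcel_id = seq_along(x@statistic) - 1L,
        statistic = x@statistic,
        p = x@p,
        q = x@q,
        significant = x@significant
    )
})

#' @rdname GeneExpressionPanel-class
setMethod("donorIds", "GeneExpressionPanel", function(x) x@donorIds)

#' @rdname GeneExpressionPanel-class
setMethod("geneIds", "GeneExpressionPanel", function(x) x@geneIds)

#' @rdname GeneExpressionPanel-class
setMethod("donorExpression", "GeneExpressionPanel", function(x, donor) {
    if (is.numeric(donor)) donor <- x@donorIds[donor]
    m <- x@expression[[donor]]
    if (is.null(m)) stop("unknown donor: ", donor)
    m
})

#' @rdname CellTypeSpecificity-class
setMethod("membershipSets", "CellTypeSpecificity", function(x) {
    out <- lapply(colnames(x@psi), function(ct) {
        sets <- lapply(x@thresholds, function(th)
            x@geneIds[x@psi[, ct] < th])
        names(sets) <- as.character(x@thresholds)
        sets
    })
    names(out) <- colnames(x@psi)
    out
})

setMethod("show", "ParcelAtlas", function(object) {
    cat("ParcelAtlas with", nParcels(object), "parcels,",
        nlevels(object@module), "modules,",
        nlevels(object@hierarchy), "hierarchy levels\n")
})

setMethod("show", "SyntheticCohort", function(object) {
    ns <- length(object@timeSeries)
    nt <- if (ns) ncol(object@timeSeries[[1]]) else 0L
    cat("SyntheticCohort:", ns, "subjects x", nParcels(object),
        "parcels x", nt, "timepoints\n")
    cat("  planted effect size:",
        if (is.null(object@truth$effectSize)) "none"
        else object@truth$effectSize, "\n")
})

setMethod("show", "ConnectivityMatrix", function(object) {
    cat("ConnectivityMatrix", nrow(object@values), "x", ncol(object@values),
        if (object@thresholded)
            sprintf("(thresholded, density %.2f)", object@density)
        else "(unthresholded)", "\n")
})

setMethod("show", "ManifoldEmbedding", function(object) {
    cat("ManifoldEmbedding:", nrow(object@vectors), "parcels x",
        ncol(object@vectors), "components; variance explained",
        sprintf("%.1f%%", 100 * sum(object@varianceExplained)), "\n")
})

setMethod("show", "AlignedManifoldSet", function(object) {
    cat("AlignedManifoldSet:", length(object@subjects),
        "subjects aligned to a", nrow(object@template@vectors), "x",
        ncol(object@template@vectors), "template\n")
})

setMethod("show", "StatMap", function(object) {
    cat("StatMap (", object@statType, ", term '", object@term, "'): ",
        length(object@statistic), " parcels, ",
        sum(object@significant, na.rm = TRUE), " significant at q < ",
        object@threshold, "\n", sep = "")
})

setMethod("show", "GeneExpressionPanel", function(object) {
    cat("GeneExpressionPanel:", length(object@donorIds), "donors x",
        length(object@geneIds), "genes x",
        if (length(object@expression)) ncol(object@expression[[1]]) else 0L,
        "parcels\n")
})

setMethod("show", "CellTypeSpecificity", function(object) {
    cat("CellTypeSpecificity:", nrow(object@psi), "genes x",
        ncol(object@psi), "cell types; thresholds",
        paste(object@thresholds, collapse = ", "), "\n")
})
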