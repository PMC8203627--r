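#' @rdname ParcelAtlas-class
#' @param object,x a package object.
#' @export
setGeneric("nParcels", function(x) standardGeneric("nParcels"))

#' @rdname ParcelAtlas-class
#' @export
setGeneric("parcelCoords", function(x) standardGeneric("parcelCoords"))

#' @rdname ParcelAtlas-class
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))

#' @rdname ParcelAtlas-class
#' @export
setGeneric("hierarchyLabels", function(x) standardGeneric("hierarchyLabels"))

#' @rdname ConnectivityMatrix-class
#' @export
setGeneric("connValues", function(x) standardGeneric("connValues"))

#' @rdname ConnectivityMatrix-class
#' @export
setGeneric("connDensity", function(x) standardGeneric("connDensity"))

#' @rdname ConnectivityMatrix-class
#' @export
setGeneric("isThresholded", function(x) standardGeneric("isThresholded"))

#' @rdname ManifoldEmbedding-class
#' @export
setGeneric("embeddingVectors", function(x) standardGeneric("embeddingVectors"))

#' @rdname ManifoldEmbedding-class
#' @export
setGeneric("embeddingEigenvalues",
    function(x) standardGeneric("embeddingEigenvalues"))

#' @rdname ManifoldEmbedding-class
#' @export
setGeneric("varianceExplained",
    function(x) standardGeneric("varianceExplained"))

#' @rdname StatMap-class
#' @export
setGeneric("statTable", function(x) standardGeneric("statTable"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("subjectCovariates",
    function(x) standardGeneric("subjectCovariates"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("subjectTimeSeries",
    function(x) standardGeneric("subjectTimeSeries"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

#' @rdname GeneExpressionPanel-class
#' @export
setGeneric("donorIds", function(x) standardGeneric("donorIds"))

#' @rdname GeneExpressionPanel-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GeneExpressionPanel-class
#' @param donor donor identifier or index.
#' @export
setGeneric("donorExpression",
    function(x, donor) standardGeneric("donorExpression"))

#' @rdname CellTypeSpecificity-class
#' @export
setGeneric("membershipSets", function(x) standardGeneric("membershipSets"))
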