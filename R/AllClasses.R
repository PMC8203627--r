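#' @import methods
NULL

#' Parcel atlas on a sphere
#'
#' A minimal cortical parcellation: one unit-sphere centroid per parcel,
#' a module (intrinsic-community) label and a four-level hierarchy label.
#' Parcel identifiers are zero-based integers, matching the on-disk TSV
#' convention used throughout the package.
#'
#' @slot parcelId integer vector of zero-based parcel identifiers.
#' @slot coords numeric matrix (parcels x 3) of unit-norm spherical centroids.
#' @slot module factor of module labels, one per parcel.
#' @slot hierarchy factor of hierarchy labels (four levels), one per parcel.
#'
#' @seealso [generateAtlas()]
#' @export
setClass("ParcelAtlas",
    representation(
        parcelId = "integer",
        coords = "matrix",
        module = "factor",
        hierarchy = "factor"
    )
)

setValidity("ParcelAtlas", function(object) {
    n <- length(object@parcelId)
    msg <- character()
    if (ncol(object@coords) != 3L || nrow(object@coords) != n)
        msg <- c(msg, "coords must be an n x 3 matrix matching parcelId")
    if (length(object@module) != n || length(object@hierarchy) != n)
        msg <- c(msg, "module and hierarchy labels must cover every parcel")
    if (n > 0) {
        norms <- sqrt(rowSums(object@coords^2))
        if (any(abs(norms - 1) > 1e-8))
            msg <- c(msg, "centroids must have unit norm")
        if (anyNA(object@module) || anyNA(object@hierarchy))
            msg <- c(msg, "labels must not contain NA")
        if (n < nlevels(object@module))
            msg <- c(msg, "parcel count must be >= number of modules")
    }
    if (length(msg)) msg else TRUE
})

#' Synthetic cohort of parcellated time series
#'
#' Per-subject parcel x timepoint signal matrices plus a covariate table
#' (age in years, sex as a 0/1 indicator, BMI in kg/m^2, optional confounds)
#' and a `truth` record of the planted generative parameters.
#'
#' @slot timeSeries named list of parcel x timepoint matrices, one per subject.
#' @slot covariates data.frame with one row per subject (subject_id, age,
#'   sex, bmi, ...).
#' @slot truth list recording planted parameters (affected parcels, effect
#'   size, noise SD, coupling model).
#' @slot atlas the [ParcelAtlas-class] the series were generated on.
#'
#' @seealso [generateCohort()]
#' @export
setClass("SyntheticCohort",
    representation(
        timeSeries = "list",
        covariates = "data.frame",
        truth = "list",
        atlas = "ParcelAtlas"
    )
)

setValidity("SyntheticCohort", function(object) {
    msg <- character()
    ns <- length(object@timeSeries)
    if (nrow(object@covariates) != ns)
        msg <- c(msg, "covariates must have one row per subject")
    if (!all(c("subject_id", "age", "sex", "bmi") %in% names(object@covariates)))
        msg <- c(msg, "covariates must contain subject_id, age, sex, bmi")
    else if (any(object@covariates$bmi <= 0))
        msg <- c(msg, "bmi must be positive")
    np <- length(object@atlas@parcelId)
    if (ns > 0) {
        dims <- vapply(object@timeSeries, nrow, integer(1))
        if (any(dims != np))
            msg <- c(msg, "every time series must have one row per atlas parcel")
    }
    if (!is.null(object@truth$affectedParcels) &&
        length(object@truth$affectedParcels) &&
        !all(object@truth$affectedParcels %in% seq_len(np)))
        msg <- c(msg, "truth$affectedParcels must index atlas parcels")
    if (length(msg)) msg else TRUE
})

#' Functional connectivity matrix
#'
#' Symmetric parcel x parcel matrix of Fisher z-transformed correlations,
#' optionally row-thresholded to a connection density. After row-wise
#' thresholding the matrix may be asymmetric; `thresholded` flags this.
#'
#' @slot values numeric parcel x parcel matrix (Fisher z), zero diagonal.
#' @slot density retained edge fraction in (0, 1]; 1 when unthresholded.
#' @slot thresholded logical flag.
#' @slot subjectId identifier ("" for group matrices).
#' @export
setClass("ConnectivityMatrix",
    representation(
        values = "matrix",
        density = "numeric",
        thresholded = "logical",
        subjectId = "character"
    ),
    prototype(density = 1, thresholded = FALSE, subjectId = "")
)

setValidity("ConnectivityMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
    else {
        if (any(abs(diag(v)) > 1e-12)) msg <- c(msg, "diagonal must be zero")
        if (!object@thresholded && nrow(v) > 0 &&
            max(abs(v - t(v))) > 1e-8)
            msg <- c(msg, "unthresholded matrix must be symmetric")
    }
    if (object@density <= 0 || object@density > 1)
        msg <- c(msg, "density must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Low-dimensional connectome manifold
#'
#' Eigenvector embedding of a connectome affinity matrix: columns are the
#' gradient components E1..Ek, ordered by nonincreasing eigenvalue. The
#' `varianceExplained` fractions are taken over all nontrivial nonnegative
#' eigenvalues of the computed spectrum.
#'
#' @slot vectors numeric parcel x k matrix of (scaled) eigenvectors.
#' @slot eigenvalues nonincreasing eigenvalues of the diffusion operator,
#'   trivial unit eigenvalue removed.
#' @slot varianceExplained per-component fraction of the nontrivial spectrum.
#' @slot alpha density-normalisation exponent used.
#' @slot t diffusion-time parameter used (t = 0 triggers multiscale scaling).
#' @export
setClass("ManifoldEmbedding",
    representation(
        vectors = "matrix",
        eigenvalues = "numeric",
        varianceExplained = "numeric",
        alpha = "numeric",
        t = "numeric"
    )
)

setValidity("ManifoldEmbedding", function(object) {
    msg <- character()
    k <- ncol(object@vectors)
    if (length(object@eigenvalues) != k)
        msg <- c(msg, "one eigenvalue per component required")
    if (k > 1 && any(diff(object@eigenvalues) > 1e-10))
        msg <- c(msg, "eigenvalues must be nonincreasing")
    if (length(object@varianceExplained) != k)
        msg <- c(msg, "one varianceExplained entry per component required")
    if (sum(object@varianceExplained) > 1 + 1e-8)
        msg <- c(msg, "varianceExplained must sum to <= 1")
    if (length(msg)) msg else TRUE
})

#' Template-aligned set of individual manifolds
#'
#' The group template embedding, per-subject embeddings after Procrustes
#' rotation into the template frame, and the orthogonal rotations used.
#'
#' @slot template a [ManifoldEmbedding-class] from the group connectome.
#' @slot subjects named list of parcel x k aligned subject matrices.
#' @slot rotations named list of k x k orthogonal matrices.
#' @export
setClass("AlignedManifoldSet",
    representation(
        template = "ManifoldEmbedding",
        subjects = "list",
        rotations = "list"
    )
)

setValidity("AlignedManifoldSet", function(object) {
    msg <- character()
    k <- ncol(object@template@vectors)
    for (R in object@rotations) {
        if (max(abs(crossprod(R) - diag(ncol(R)))) > 1e-8) {
            msg <- c(msg, "every rotation must be orthogonal to 1e-8")
            break
        }
    }
    bad <- vapply(object@subjects, function(m) ncol(m) != k, logical(1))
    if (any(bad))
        msg <- c(msg, "subject matrices must share the template's columns")
    if (length(object@subjects) != length(object@rotations))
        msg <- c(msg, "one rotation per subject required")
    if (length(msg)) msg else TRUE
})

#' Parcel-wise statistical map
#'
#' Per-parcel statistic with raw p-values, Benjamini-Hochberg q-values and
#' a significance flag at the configured FDR threshold.
#'
#' @slot statistic per-parcel statistic (Hotelling F or correlation r).
#' @slot p raw p-values in \code{[0, 1]}.
#' @slot q BH-adjusted q-values.
#' @slot significant logical flags, `q < threshold`.
#' @slot threshold the FDR threshold used (default 0.05).
#' @slot term name of the tested model term.
#' @slot statType label of the statistic ("hotelling_F", "correlation", ...).
#' @export
setClass("StatMap",
    representation(
        statistic = "numeric",
        p = "numeric",
        q = "numeric",
        significant = "logical",
        threshold = "numeric",
        term = "character",
        statType = "character"
    ),
    prototype(threshold = 0.05, term = "", statType = "")
)

setValidity("StatMap", function(object) {
    msg <- character()
    n <- length(object@statistic)
    if (length(object@p) != n || length(object@q) != n ||
        length(object@significant) != n)
        msg <- c(msg, "statistic, p, q, significant must share length")
    pp <- object@p[!is.na(object@p)]
    qq <- object@q[!is.na(object@q)]
    if (length(pp) && (min(pp) < 0 || max(pp) > 1))
        msg <- c(msg, "p-values must lie in [0, 1]")
    if (length(qq) && (min(qq) < 0 || max(qq) > 1))
        msg <- c(msg, "q-values must lie in [0, 1]")
    ok <- !is.na(object@q)
    if (any(object@significant[ok] != (object@q[ok] < object@threshold)))
        msg <- c(msg, "significance flags must equal q < threshold")
    if (length(msg)) msg else TRUE
})

#' Donor-level gene expression panel
#'
#' Gene x parcel expression matrices, one per donor, on a shared gene and
#' parcel universe. Used for transcriptomic spatial decoding.
#'
#' @slot expression named list (by donor) of gene x parcel matrices.
#' @slot geneIds character gene identifiers (row order of every matrix).
#' @slot donorIds character donor identifiers.
#' @export
setClass("GeneExpressionPanel",
    representation(
        expression = "list",
        geneIds = "character",
        donorIds = "character"
    )
)

setValidity("GeneExpressionPanel", function(object) {
    msg <- character()
    if (length(object@expression) != length(object@donorIds))
        msg <- c(msg, "one expression matrix per donor required")
    ng <- length(object@geneIds)
    dims <- vapply(object@expression, dim, integer(2))
    if (length(object@expression)) {
        if (any(dims[1, ] != ng))
            msg <- c(msg, "every donor matrix must have one row per gene")
        if (length(unique(dims[2, ])) > 1)
            msg <- c(msg, "parcel dimension must agree across donors")
    }
    if (length(msg)) msg else TRUE
})

#' Cell-type specificity profile
#'
#' Per-gene specificity index (pSI-style) values for each cell type. Gene
#' sets are defined by thresholding the index at nested stringencies; by
#' construction the set at a stricter threshold is contained in the looser
#' one.
#'
#' @slot psi numeric gene x cell-type matrix of specificity index values.
#' @slot thresholds decreasing numeric thresholds (default 0.05, 0.01,
#'   0.001, 0.0001).
#' @slot geneIds gene identifiers (rows of `psi`).
#' @export
setClass("CellTypeSpecificity",
    representation(
        psi = "matrix",
        thresholds = "numeric",
        geneIds = "character"
    ),
    prototype(thresholds = c(0.05, 0.01, 0.001, 0.0001))
)

setValidity("CellTypeSpecificity", function(object) {
    msg <- character()
    if (nrow(object@psi) != length(object@geneIds))
        msg <- c(msg, "one psi row per gene required")
    if (any(diff(object@thresholds) >= 0))
        msg <- c(msg, "thresholds must be strictly decreasing")
    if (any(object@psi < 0 | object@psi > 1))
        msg <- c(msg, "psi values must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})
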