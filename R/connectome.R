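#' Fisher-z correlation connectome from parcel time series
#'
#' Computes the Pearson correlation between every pair of parcel time
#' series and applies the Fisher r-to-z transform, clipping correlations
#' at |r| = 1 - 1e-7 so that identical series remain finite. The diagonal
#' is set to zero.
#'
#' @param ts parcel x timepoint numeric matrix (>= 3 timepoints), or a
#'   [SyntheticCohort-class] subject entry.
#' @param subjectId identifier stored with the result.
#' @return an unthresholded [ConnectivityMatrix-class].
#' @export
correlationConnectome <- function(ts, subjectId = "") {
    .stopIfNot(is.matrix(ts) && is.numeric(ts),
        "ts must be a numeric matrix")
    .stopIfNot(!anyNA(ts), "ts must not contain NA")
    .stopIfNot(ncol(ts) >= 3L, "at least 3 timepoints required")
    sds <- apply(ts, 1L, stats::sd)
    if (any(sds == 0)) {
        bad <- which(sds == 0)
        stop("zero-variance parcel(s): ",
            paste(if (!is.null(rownames(ts))) rownames(ts)[bad] else bad,
                collapse = ", "), call. = FALSE)
    }
    r <- stats::cor(t(ts))
    z <- .fisherZ(r)
    z <- (z + t(z)) / 2  # enforce exact symmetry against rounding
    diag(z) <- 0
    new("ConnectivityMatrix", values = z, density = 1,
        thresholded = FALSE, subjectId = subjectId)
}

#' Group-average connectome
#'
#' Entrywise arithmetic mean of unthresholded connectomes of matching
#' shape.
#'
#' @param connectomes list of [ConnectivityMatrix-class] objects.
#' @return an unthresholded [ConnectivityMatrix-class] (subjectId "group").
#' @export
groupAverageConnectome <- function(connectomes) {
    .stopIfNot(length(connectomes) >= 1L,
        "at least one connectome required")
    dims <- vapply(connectomes, function(cm) nrow(connValues(cm)),
        integer(1))
    .stopIfNot(length(unique(dims)) == 1L, "connectome shapes must match")
    .stopIfNot(!any(vapply(connectomes, isThresholded, logical(1))),
        "group averaging expects unthresholded connectomes")
    acc <- Reduce(`+`, lapply(connectomes, connValues))
    avg <- acc / length(connectomes)
    avg <- (avg + t(avg)) / 2
    diag(avg) <- 0
    new("ConnectivityMatrix", values = avg, density = 1,
        thresholded = FALSE, subjectId = "group")
}

#' Row-wise density thresholding
#'
#' Each row keeps its `ceiling(density * (n - 1))` largest off-diagonal
#' entries (by signed value, so strong negative weights are dropped at
#' typical densities); all others are set to zero. Values tied with the
#' cutoff are all retained, so the rule is deterministic and idempotent.
#' The result may be asymmetric and is flagged as thresholded.
#'
#' @param C a [ConnectivityMatrix-class].
#' @param density retained fraction in (0, 1].
#' @return a thresholded [ConnectivityMatrix-class].
#' @export
thresholdByDensity <- function(C, density = 0.10) {
    .stopIfNot(is(C, "ConnectivityMatrix"),
        "C must be a ConnectivityMatrix")
    .stopIfNot(density > 0 && density <= 1,
        "density must lie in (0, 1]")
    v <- connValues(C)
    n <- nrow(v)
    k <- ceiling(density * (n - 1L))
    out <- v
    for (i in seq_len(n)) {
        row <- v[i, ]
        off <- row[-i]
        # in an already-thresholded matrix exact zeros mean "removed";
        # ranking only surviving entries keeps the rule idempotent
        cand <- if (isThresholded(C)) off[off != 0] else off
        thr <- if (length(cand) < k) -Inf
            else sort(cand, decreasing = TRUE)[k]
        out[i, row < thr] <- 0
    }
    diag(out) <- 0
    new("ConnectivityMatrix", values = out, density = density,
        thresholded = TRUE, subjectId = C@subjectId)
}
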