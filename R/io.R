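# TSV/JSON readers and writers; every artifact the pipeline emits is a
# delimited text file or a JSON sidecar so runs diff cleanly.

#' Write / read a parcel atlas as TSV
#'
#' Columns: parcel_id (0-based), module, hierarchy, x, y, z.
#'
#' @param atlas a [ParcelAtlas-class].
#' @param path output TSV path.
#' @return `writeAtlas` returns `path` invisibly; `readAtlas` returns a
#'   [ParcelAtlas-class].
#' @export
writeAtlas <- function(atlas, path) {
    df <- data.frame(
        parcel_id = atlas@parcelId,
        module = as.character(moduleLabels(atlas)),
        hierarchy = as.character(hierarchyLabels(atlas)),
        x = parcelCoords(atlas)[, 1L],
        y = parcelCoords(atlas)[, 2L],
        z = parcelCoords(atlas)[, 3L])
    utils::write.table(df, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}

#' @rdname writeAtlas
#' @export
readAtlas <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    coords <- as.matrix(df[, c("x", "y", "z")])
    coords <- coords / sqrt(rowSums(coords^2))
    new("ParcelAtlas",
        parcelId = as.integer(df$parcel_id),
        coords = coords,
        module = factor(df$module, levels = unique(df$module)),
        hierarchy = factor(df$hierarchy, levels = unique(df$hierarchy)))
}

#' Write a connectivity matrix with a JSON sidecar
#'
#' The matrix goes to `<path>` as TSV; density, thresholded flag and
#' subject id go to `<path>.json`.
#'
#' @param C a [ConnectivityMatrix-class].
#' @param path output TSV path.
#' @export
writeConnectome <- function(C, path) {
    utils::write.table(connValues(C), path, sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(list(
        density = connDensity(C),
        thresholded = isThresholded(C),
        subject_id = C@subjectId),
        paste0(path, ".json"), auto_unbox = TRUE)
    invisible(path)
}

#' Read a delimited parcel x timepoint matrix
#'
#' @param path TSV path (no header, one row per parcel).
#' @return numeric matrix.
#' @export
readTimeSeries <- function(path) {
    as.matrix(utils::read.table(path, sep = "\t"))
}

#' Write a manifold embedding as TSV plus JSON sidecar
#'
#' TSV columns: parcel_id, E1..Ek; the sidecar records eigenvalues,
#' variance explained, alpha and t.
#'
#' @param emb a [ManifoldEmbedding-class].
#' @param path output TSV path.
#' @export
writeEmbedding <- function(emb, path) {
    V <- embeddingVectors(emb)
    df <- data.frame(parcel_id = seq_len(nrow(V)) - 1L, V)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    jsonlite::write_json(list(
        eigenvalues = embeddingEigenvalues(emb),
        variance_explained = varianceExplained(emb),
        alpha = emb@alpha, t = emb@t),
        paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Write a StatMap as TSV
#'
#' Columns: parcel_id, statistic, p, q, significant.
#'
#' @param sm a [StatMap-class].
#' @param path output TSV path.
#' @export
writeStatMap <- function(sm, path) {
    utils::write.table(statTable(sm), path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' One TSV per subject under `timeseries/`, covariates.tsv, atlas.tsv
#' and truth.json.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(file.path(dir, "timeseries"), recursive = TRUE,
        showWarnings = FALSE)
    ts <- subjectTimeSeries(cohort)
    for (id in names(ts)) {
        utils::write.table(ts[[id]],
            file.path(dir, "timeseries", paste0(id, ".tsv")),
            sep = "\t", quote = FALSE, row.names = FALSE,
            col.names = FALSE)
    }
    utils::write.table(subjectCovariates(cohort),
        file.path(dir, "covariates.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    writeAtlas(cohort@atlas, file.path(dir, "atlas.tsv"))
    truth <- cohortTruth(cohort)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
        auto_unbox = TRUE, digits = NA)
    invisible(dir)
}

#' Read a cohort directory written by [writeCohort()]
#'
#' @param dir directory path.
#' @return a [SyntheticCohort-class] (truth restored from truth.json if
#'   present, otherwise empty).
#' @export
readCohort <- function(dir) {
    cov <- utils::read.delim(file.path(dir, "covariates.tsv"),
        stringsAsFactors = FALSE)
    atlas <- readAtlas(file.path(dir, "atlas.tsv"))
    ts <- lapply(cov$subject_id, function(id)
        readTimeSeries(file.path(dir, "timeseries", paste0(id, ".tsv"))))
    names(ts) <- cov$subject_id
    truthPath <- file.path(dir, "truth.json")
    truth <- if (file.exists(truthPath))
        jsonlite::read_json(truthPath, simplifyVector = TRUE) else list()
    new("SyntheticCohort", timeSeries = ts, covariates = cov,
        truth = truth, atlas = atlas)
}

#' Read gene sets in GMT format
#'
#' Each line: set id, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    out <- lapply(lines, function(l) {
        f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
        f[-(1:2)]
    })
    names(out) <- vapply(lines, function(l)
        strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1))
    out
}
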