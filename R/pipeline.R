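#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with defaults set to
#' the study's standard operating point: connection density 0.10,
#' diffusion-map parameters alpha = 0.5 and t = 0, three reported
#' components, 5000 permutations, 100 spin rotations and an FDR threshold
#' of 0.05. The full configuration is serialised verbatim into every run
#' record.
#'
#' @param paths input directory (written by [writeCohort()]) or
#'   `"synthetic"` to generate a cohort in-process.
#' @param outDir output directory for run artifacts (NULL: nothing
#'   written).
#' @param density,alpha,t,nComponents manifold parameters.
#' @param nPerm,nSpins,fdrQ inference parameters.
#' @param seed master integer seed for every stochastic stage.
#' @param covariates design covariates for the main model (tested term
#'   last is not required; `term` names it).
#' @param term tested design term.
#' @param moduleSource module definition for modular metrics:
#'   `"atlas_communities"`, `"louvain"` or `"hierarchy"`.
#' @param groupComparison run the healthy-weight vs overweight contrast.
#' @param graphMeasures correlate per-subject modular/centrality measures
#'   with eccentricity and BMI (slower).
#' @param nParcels,nModules,nSubjects,nTimepoints,effectSize,noiseSd
#'   synthetic-cohort parameters (used when `paths == "synthetic"`).
#' @param decodePanel optional [GeneExpressionPanel-class] for
#'   transcriptomic decoding.
#' @param geneSets optional named list of gene sets for enrichment.
#' @param specificity optional [CellTypeSpecificity-class].
#' @return a validated `PipelineConfig` list.
#' @export
pipelineConfig <- function(paths = "synthetic", outDir = NULL,
                           density = 0.10, alpha = 0.5, t = 0,
                           nComponents = 3L, nPerm = 5000L,
                           nSpins = 100L, fdrQ = 0.05, seed = 1L,
                           covariates = c("age", "sex", "bmi"),
                           term = "bmi",
                           moduleSource = "atlas_communities",
                           groupComparison = FALSE,
                           graphMeasures = FALSE,
                           nParcels = 200L, nModules = 7L,
                           nSubjects = 100L, nTimepoints = 400L,
                           effectSize = 0.13, noiseSd = 1.0,
                           decodePanel = NULL, geneSets = NULL,
                           specificity = NULL) {
    .stopIfNot(density > 0 && density <= 1, "density must be in (0, 1]")
    .stopIfNot(fdrQ > 0 && fdrQ < 1, "fdrQ must be in (0, 1)")
    .stopIfNot(term %in% covariates,
        "the tested term must be among the covariates")
    .stopIfNot(moduleSource %in%
        c("atlas_communities", "louvain", "hierarchy"),
        "unknown moduleSource")
    cfg <- list(paths = paths, outDir = outDir, density = density,
        alpha = alpha, t = t, nComponents = as.integer(nComponents),
        nPerm = as.integer(nPerm), nSpins = as.integer(nSpins),
        fdrQ = fdrQ, seed = as.integer(seed), covariates = covariates,
        term = term, moduleSource = moduleSource,
        groupComparison = groupComparison,
        graphMeasures = graphMeasures,
        nParcels = as.integer(nParcels), nModules = as.integer(nModules),
        nSubjects = as.integer(nSubjects),
        nTimepoints = as.integer(nTimepoints),
        effectSize = effectSize, noiseSd = noiseSd,
        decodePanel = decodePanel, geneSets = geneSets,
        specificity = specificity)
    class(cfg) <- "PipelineConfig"
    cfg
}

.configSnapshot <- function(config) {
    snap <- config[!vapply(config, is.object, logical(1))]
    snap$decodePanel <- !is.null(config$decodePanel)
    snap$specificity <- !is.null(config$specificity)
    snap$geneSets <- if (is.null(config$geneSets)) character()
        else names(config$geneSets)
    class(snap) <- NULL
    snap
}

.log <- function(...) message("[pipeline] ", ...)

#' Run the full connectome-manifold analysis
#'
#' Executes the stages in dependency order: cohort (synthetic or loaded),
#' subject and group connectomes, template manifold with aligned subject
#' embeddings, manifold eccentricity, the parcel-wise Hotelling
#' association of E1..Ek with the tested term, the eccentricity
#' permutation test within the significant-parcel mask, modular and
#' stratified summaries, the optional group comparison and the optional
#' transcriptomic decoding chain. When `outDir` is set, every artifact is
#' written as TSV/JSON under `outDir/run-<id>` together with a RunRecord
#' (config snapshot, package version, seed, per-file MD5 digests,
#' captured warnings).
#'
#' @param config a [pipelineConfig()] object.
#' @return invisible list with the in-memory results (`atlas`, `cohort`,
#'   `aligned`, `eccentricity`, `statMap`, `eccTest`, `stratified`,
#'   `modular`, `groupMap`, `decoding`, `runRecord`, `outDir`).
#' @export
runPipeline <- function(config) {
    .stopIfNot(inherits(config, "PipelineConfig"),
        "config must come from pipelineConfig()")
    warningsSeen <- character()
    wHandler <- function(w) {
        warningsSeen <<- c(warningsSeen, conditionMessage(w))
        invokeRestart("muffleWarning")
    }
    res <- withCallingHandlers(
        .runPipelineStages(config), warning = wHandler)
    res$runRecord$warnings <- warningsSeen

    if (!is.null(config$outDir)) {
        runDir <- res$outDir
        files <- list.files(runDir, recursive = TRUE, full.names = TRUE)
        dig <- tools::md5sum(files)
        names(dig) <- substring(names(dig), nchar(runDir) + 2L)
        res$runRecord$digests <- as.list(dig)
        jsonlite::write_json(res$runRecord,
            file.path(runDir, "run_record.json"),
            auto_unbox = TRUE, digits = NA, null = "null")
    }
    invisible(res)
}

.runPipelineStages <- function(config) {
    seed <- config$seed
    .log("stage data (seed ", seed, ")")
    if (identical(config$paths, "synthetic")) {
        atlas <- generateAtlas(config$nParcels, config$nModules)
        cohort <- generateCohort(atlas,
            nSubjects = config$nSubjects,
            nTimepoints = config$nTimepoints,
            effectSize = config$effectSize,
            noiseSd = config$noiseSd,
            seed = seed)
    } else {
        cohort <- readCohort(config$paths)
        atlas <- cohort@atlas
    }
    cov <- subjectCovariates(cohort)
    n <- nrow(cov)

    .log("stage connectome (", n, " subjects)")
    conns <- lapply(names(subjectTimeSeries(cohort)), function(id)
        correlationConnectome(subjectTimeSeries(cohort)[[id]], id))
    names(conns) <- names(subjectTimeSeries(cohort))
    groupC <- groupAverageConnectome(conns)

    .log("stage embedding (density ", config$density, ", alpha ",
        config$alpha, ", t ", config$t, ")")
    aligned <- buildAlignedSet(groupC, conns,
        density = config$density, alpha = config$alpha, t = config$t,
        nComponents = config$nComponents)
    center <- colMeans(embeddingVectors(aligned@template))
    ecc <- vapply(aligned@subjects, manifoldEccentricity,
        numeric(nParcels(atlas)), center = center)

    .log("stage association (term '", config$term, "')")
    k <- config$nComponents
    Y <- array(NA_real_, c(n, nParcels(atlas), k))
    for (s in seq_len(n)) Y[s, , ] <- aligned@subjects[[s]]
    X <- designMatrix(cov, config$covariates)
    statMap <- hotellingGLM(Y, X, config$term, fdrQ = config$fdrQ)
    mask <- which(statMap@significant)

    eccTest <- NULL
    if (length(mask)) {
        eccMean <- colMeans(ecc[mask, , drop = FALSE])
        nuis <- setdiff(config$covariates, config$term)
        eccTest <- partialCorrelationPermutation(
            cov[[config$term]], eccMean,
            covars = if (length(nuis)) cov[, nuis, drop = FALSE],
            nPerm = config$nPerm, seed = .deriveSeed(seed, 11L))
    }

    .log("stage stratification")
    stratified <- list(
        module = stratifyMap(statMap, atlas, "module"),
        hierarchy = stratifyMap(statMap, atlas, "hierarchy"))

    modular <- NULL
    if (config$graphMeasures && length(mask)) {
        .log("stage modular metrics (", config$moduleSource, ")")
        groupThr <- thresholdByDensity(groupC, config$density)
        partition <- switch(config$moduleSource,
            atlas_communities = as.character(moduleLabels(atlas)),
            hierarchy = as.character(hierarchyLabels(atlas)),
            louvain = as.character(louvainPartition(groupThr,
                seed = .deriveSeed(seed, 21L))))
        wmd <- pc <- matrix(NA_real_, nParcels(atlas), n)
        for (s in seq_len(n)) {
            Ws <- thresholdByDensity(conns[[s]], config$density)
            wmd[, s] <- withinModuleDegree(Ws, partition)
            pc[, s] <- participationCoefficient(Ws, partition)
        }
        eccMean <- colMeans(ecc[mask, , drop = FALSE])
        nuis <- setdiff(config$covariates, config$term)
        covarsDf <- if (length(nuis)) cov[, nuis, drop = FALSE]
        testOne <- function(m, off) partialCorrelationPermutation(
            eccMean, colMeans(m[mask, , drop = FALSE]),
            covars = covarsDf, nPerm = config$nPerm,
            seed = .deriveSeed(seed, off))
        tests <- list(
            within_module_degree = testOne(wmd, 31L),
            participation_coefficient = testOne(pc, 32L))
        praw <- vapply(tests, `[[`, numeric(1), "p")
        adj <- fdrBH(praw, config$fdrQ)
        modular <- list(partition = partition, tests = tests,
            q = adj$q, centralities = graphCentralities(
                thresholdByDensity(groupC, config$density)))
    }

    groupMap <- NULL
    if (config$groupComparison) {
        .log("stage group comparison")
        keep <- cov$bmi >= 18.5
        grp <- as.integer(cov$bmi[keep] >= 25)
        nuis <- setdiff(config$covariates, config$term)
        groupMap <- groupHotelling(Y[keep, , , drop = FALSE], grp,
            covars = if (length(nuis))
                cov[keep, nuis, drop = FALSE],
            fdrQ = config$fdrQ)
    }

    decoding <- NULL
    if (!is.null(config$decodePanel)) {
        .log("stage decoding (", config$nSpins, " spins)")
        tmap <- attr(statMap, "signedStatistic")
        assoc <- geneMapAssociation(tmap, config$decodePanel)
        spun <- spinSignificanceFilter(assoc, tmap, atlas,
            config$decodePanel, nRotations = config$nSpins,
            seed = .deriveSeed(seed, 41L), q = config$fdrQ)
        consistent <- donorConsistencyFilter(config$decodePanel,
            spun, q = config$fdrQ)
        enrichment <- if (!is.null(config$geneSets))
            fisherEnrichment(consistent, config$geneSets,
                geneIds(config$decodePanel))
        csea <- if (!is.null(config$specificity))
            cseaEnrichment(consistent, config$specificity)
        decoding <- list(assoc = assoc, spinSurvivors = spun,
            consistentGenes = consistent, enrichment = enrichment,
            csea = csea)
    }

    runRecord <- list(
        config = .configSnapshot(config),
        package_version = as.character(utils::packageVersion(
            "connectomeManifold")),
        seed = seed,
        n_subjects = n,
        n_parcels = nParcels(atlas),
        n_significant = length(mask))

    outDir <- NULL
    if (!is.null(config$outDir)) {
        runId <- substr(tools::md5sum(
            jsonTmp <- local({
                f <- tempfile(fileext = ".json")
                jsonlite::write_json(.configSnapshot(config), f,
                    auto_unbox = TRUE, digits = NA)
                f
            }))[[1L]], 1L, 12L)
        unlink(jsonTmp)
        runRecord$run_id <- runId
        outDir <- file.path(config$outDir, paste0("run-", runId))
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        writeAtlas(atlas, file.path(outDir, "atlas.tsv"))
        writeEmbedding(aligned@template,
            file.path(outDir, "template_manifold.tsv"))
        utils::write.table(
            data.frame(parcel_id = seq_len(nParcels(atlas)) - 1L, ecc),
            file.path(outDir, "eccentricity.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
        writeStatMap(statMap, file.path(outDir, "statmap_main.tsv"))
        utils::write.table(
            data.frame(parcel_id = mask - 1L),
            file.path(outDir, "significant_mask.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
        for (by in names(stratified)) {
            utils::write.table(
                data.frame(category = names(stratified[[by]]),
                    mean_statistic = as.numeric(stratified[[by]])),
                file.path(outDir, sprintf("stratified_%s.tsv", by)),
                sep = "\t", quote = FALSE, row.names = FALSE)
        }
        if (!is.null(groupMap))
            writeStatMap(groupMap, file.path(outDir, "statmap_group.tsv"))
    }

    list(atlas = atlas, cohort = cohort, aligned = aligned,
        eccentricity = ecc, statMap = statMap, eccTest = eccTest,
        stratified = stratified, modular = modular, groupMap = groupMap,
        decoding = decoding, runRecord = runRecord, outDir = outDir)
}

#' Density and parcel-scale sensitivity sweep
#'
#' Re-estimates the template manifold and the parcel-wise association at
#' each connection density, reporting cross-density spatial correlations
#' of the principal gradient (E1) and of the statistic maps; optionally
#' regenerates the cohort at different atlas scales (parcel counts) and
#' reports the per-scale significant-parcel fraction.
#'
#' @param config a [pipelineConfig()] object.
#' @param densities densities to sweep (default 0.05, 0.10, 0.15, 0.20).
#' @param scales optional parcel counts to re-simulate at (synthetic
#'   cohorts only).
#' @return list with `byDensity` (per-density statMaps and template E1),
#'   `e1Correlation` and `statCorrelation` (cross-density correlation
#'   matrices), and `byScale`.
#' @export
sensitivitySuite <- function(config, densities = c(0.05, 0.10, 0.15, 0.20),
                             scales = NULL) {
    .stopIfNot(all(densities > 0 & densities <= 1),
        "densities must lie in (0, 1]")
    .stopIfNot(identical(config$paths, "synthetic") || is.null(scales),
        "scale sweeps require a synthetic cohort")
    atlas <- generateAtlas(config$nParcels, config$nModules)
    cohort <- if (identical(config$paths, "synthetic"))
        generateCohort(atlas, nSubjects = config$nSubjects,
            nTimepoints = config$nTimepoints,
            effectSize = config$effectSize, noiseSd = config$noiseSd,
            seed = config$seed)
    else readCohort(config$paths)
    atlas <- cohort@atlas
    cov <- subjectCovariates(cohort)
    conns <- lapply(names(subjectTimeSeries(cohort)), function(id)
        correlationConnectome(subjectTimeSeries(cohort)[[id]], id))
    groupC <- groupAverageConnectome(conns)
    X <- designMatrix(cov, config$covariates)
    n <- nrow(cov)

    byDensity <- lapply(densities, function(d) {
        aligned <- buildAlignedSet(groupC, conns, density = d,
            alpha = config$alpha, t = config$t,
            nComponents = config$nComponents)
        Y <- array(NA_real_, c(n, nParcels(atlas), config$nComponents))
        for (s in seq_len(n)) Y[s, , ] <- aligned@subjects[[s]]
        sm <- hotellingGLM(Y, X, config$term, fdrQ = config$fdrQ)
        list(density = d,
            e1 = embeddingVectors(aligned@template)[, 1L],
            statMap = sm)
    })
    names(byDensity) <- sprintf("density_%g", densities)
    e1 <- vapply(byDensity, `[[`, numeric(nParcels(atlas)), "e1")
    st <- vapply(byDensity, function(b) b$statMap@statistic,
        numeric(nParcels(atlas)))

    byScale <- NULL
    if (!is.null(scales)) {
        byScale <- lapply(scales, function(np) {
            cfg <- config
            cfg$nParcels <- as.integer(np)
            a2 <- generateAtlas(np, config$nModules)
            c2 <- generateCohort(a2, nSubjects = config$nSubjects,
                nTimepoints = config$nTimepoints,
                effectSize = config$effectSize,
                noiseSd = config$noiseSd, seed = config$seed)
            cc <- lapply(subjectTimeSeries(c2), correlationConnectome)
            g2 <- groupAverageConnectome(cc)
            al <- buildAlignedSet(g2, cc, density = config$density,
                alpha = config$alpha, t = config$t,
                nComponents = config$nComponents)
            Y2 <- array(NA_real_,
                c(length(cc), np, config$nComponents))
            for (s in seq_along(cc)) Y2[s, , ] <- al@subjects[[s]]
            sm <- hotellingGLM(Y2, designMatrix(subjectCovariates(c2),
                config$covariates), config$term, fdrQ = config$fdrQ)
            list(nParcels = np,
                significantFraction = mean(sm@significant))
        })
        names(byScale) <- sprintf("scale_%d", as.integer(scales))
    }
    list(byDensity = byDensity,
        e1Correlation = stats::cor(e1),
        statCorrelation = stats::cor(st),
        byScale = byScale)
}
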