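#' Generate a spherical parcel atlas
#'
#' Places parcel centroids on a deterministic quasi-uniform Fibonacci
#' lattice over the unit sphere, partitions them into spatially contiguous
#' modules (consecutive latitude bands, sizes balanced to within one
#' parcel), and assigns each module one of four cortical-hierarchy levels.
#' The construction is fully deterministic; `seed` is accepted for
#' interface symmetry with the other generators but does not influence the
#' result.
#'
#' @param nParcels number of parcels (>= nModules).
#' @param nModules number of modules (>= 2), emulating intrinsic
#'   functional communities.
#' @param seed integer seed (unused; the lattice is deterministic).
#' @return a [ParcelAtlas-class].
#' @examples
#' atlas <- generateAtlas(40, 4)
#' table(moduleLabels(atlas))
#' @export
generateAtlas <- function(nParcels, nModules = 7L, seed = 0L) {
    nParcels <- as.integer(nParcels)
    nModules <- as.integer(nModules)
    .stopIfNot(nModules >= 2L, "nModules must be >= 2")
    .stopIfNot(nParcels >= nModules,
        "nModules must not exceed nParcels")

    # Fibonacci lattice, ordered from north to south pole
    i <- seq_len(nParcels) - 1L
    z <- 1 - 2 * (i + 0.5) / nParcels
    golden <- pi * (3 - sqrt(5))
    phi <- i * golden
    r <- sqrt(pmax(0, 1 - z^2))
    coords <- cbind(x = r * cos(phi), y = r * sin(phi), z = z)
    coords <- coords / sqrt(rowSums(coords^2))

    # balanced contiguous latitude bands: sizes differ by at most one
    base <- nParcels %/% nModules
    sizes <- rep(base, nModules)
    extra <- nParcels - base * nModules
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    module <- factor(rep(sprintf("M%d", seq_len(nModules)), times = sizes),
        levels = sprintf("M%d", seq_len(nModules)))

    hierNames <- c("idiotypic", "unimodal", "heteromodal", "paralimbic")
    hierOfModule <- hierNames[((seq_len(nModules) - 1L) %% 4L) + 1L]
    hierarchy <- factor(hierOfModule[as.integer(module)], levels = hierNames)

    new("ParcelAtlas",
        parcelId = i,
        coords = coords,
        module = module,
        hierarchy = hierarchy)
}

#' Generate a synthetic cohort with a planted BMI-coupling effect
#'
#' Simulates modular parcel time series. Every module tracks a global
#' latent factor with weight `baseCoupling`; the modules in
#' `affectedModules` additionally share a private factor whose weight
#' decreases with standardised BMI:
#' \deqn{w_s = \mathrm{affectedCoupling} - \mathrm{effectSize} \cdot z(BMI_s)}
#' so that higher BMI yields stronger segregation of the affected modules.
#' Parcel signals are their module latent plus white noise of SD `noiseSd`.
#' The planted effect therefore lives in between-module connectivity,
#' which is exactly what the manifold pipeline measures.
#'
#' Covariates: BMI is log-normal calibrated to mean 26.3 and SD 5.16
#' kg/m^2; age is uniform on 22-36 years; sex is a 0/1 indicator with
#' P(1) = 0.55.
#'
#' @param atlas a [ParcelAtlas-class].
#' @param nSubjects number of subjects.
#' @param nTimepoints timepoints per subject.
#' @param effectSize coupling slope per BMI standard deviation; 0 plants
#'   no effect.
#' @param affectedModules character vector of module labels carrying the
#'   planted effect (default: the first two modules).
#' @param noiseSd parcel-level white-noise SD (signal latents have unit SD).
#' @param baseCoupling squared loading of every module on the global
#'   factor.
#' @param affectedCoupling baseline squared loading of affected modules on
#'   their shared private factor.
#' @param bmiMean,bmiSd target moments of the BMI distribution (kg/m^2).
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return a [SyntheticCohort-class]; `cohortTruth()` records the planted
#'   parameters including per-subject coupling weights.
#' @export
generateCohort <- function(atlas, nSubjects = 325L, nTimepoints = 1200L,
                           effectSize = 0.13,
                           affectedModules = levels(moduleLabels(atlas))[1:2],
                           noiseSd = 1.0,
                           baseCoupling = 0.3,
                           affectedCoupling = 0.3,
                           bmiMean = 26.30, bmiSd = 5.16,
                           seed = 1L) {
    .stopIfNot(is(atlas, "ParcelAtlas"), "atlas must be a ParcelAtlas")
    .stopIfNot(all(affectedModules %in% levels(moduleLabels(atlas))),
        "unknown module label in affectedModules")
    .stopIfNot(baseCoupling >= 0 && baseCoupling < 1,
        "baseCoupling must lie in [0, 1)")
    nSubjects <- as.integer(nSubjects)
    nTimepoints <- as.integer(nTimepoints)
    np <- nParcels(atlas)
    mod <- moduleLabels(atlas)
    modIdx <- as.integer(mod)
    nMod <- nlevels(mod)
    affected <- levels(mod) %in% affectedModules
    affectedParcels <- which(mod %in% affectedModules)

    .withSeed(seed, {
        # covariates
        sigma2 <- log(1 + (bmiSd / bmiMean)^2)
        mu <- log(bmiMean) - sigma2 / 2
        bmi <- stats::rlnorm(nSubjects, meanlog = mu, sdlog = sqrt(sigma2))
        age <- stats::runif(nSubjects, 22, 36)
        sex <- stats::rbinom(nSubjects, 1L, 0.55)
        zbmi <- if (nSubjects > 1) as.numeric(scale(bmi)) else 0

        w <- affectedCoupling - effectSize * zbmi
        wmax <- 1 - baseCoupling - 1e-6
        if (any(w < 0)) {
            warning("planted coupling weight clipped at 0 for ",
                sum(w < 0), " subject(s)")
        }
        w <- .clip(w, 0, wmax)

        ts <- vector("list", nSubjects)
        for (s in seq_len(nSubjects)) {
            globalF <- stats::rnorm(nTimepoints)
            privateF <- stats::rnorm(nTimepoints)
            idio <- matrix(stats::rnorm(nMod * nTimepoints), nMod)
            loadG <- sqrt(baseCoupling)
            loadP <- ifelse(affected, sqrt(w[s]), 0)
            loadE <- sqrt(pmax(0, 1 - baseCoupling - loadP^2))
            latents <- loadG * matrix(globalF, nMod, nTimepoints,
                    byrow = TRUE) +
                loadP * matrix(privateF, nMod, nTimepoints, byrow = TRUE) +
                loadE * idio
            noise <- if (noiseSd > 0)
                matrix(stats::rnorm(np * nTimepoints, sd = noiseSd), np)
            else 0
            ts[[s]] <- latents[modIdx, , drop = FALSE] + noise
            rownames(ts[[s]]) <- sprintf("p%03d", seq_len(np) - 1L)
        }
        ids <- sprintf("sub%04d", seq_len(nSubjects))
        names(ts) <- ids

        new("SyntheticCohort",
            timeSeries = ts,
            covariates = data.frame(
                subject_id = ids, age = age, sex = sex, bmi = bmi,
                stringsAsFactors = FALSE),
            truth = list(
                effectSize = effectSize,
                affectedModules = affectedModules,
                affectedParcels = affectedParcels,
                noiseSd = noiseSd,
                baseCoupling = baseCoupling,
                affectedCoupling = affectedCoupling,
                couplingWeights = w,
                zBmi = zbmi,
                seed = as.integer(seed)),
            atlas = atlas)
    })
}

#' Generate per-subject structural maps
#'
#' Emulates parcel-level cortical thickness, folding and a myelin proxy:
#' each map is a smooth latitude-dependent mean pattern plus subject noise,
#' with an optional linear BMI effect planted in `targetParcels`.
#'
#' @param atlas a [ParcelAtlas-class].
#' @param cohort a [SyntheticCohort-class] supplying subjects and BMI.
#' @param effectSizeStruct slope (map units per BMI SD) of the planted
#'   structural effect; negative values emulate BMI-related thinning.
#' @param targetParcels parcel indices carrying the effect (default: the
#'   cohort's affected parcels).
#' @param subjectSd subject-level noise SD in map units.
#' @param seed integer seed.
#' @return list with `maps` (named list of subject x parcel matrices for
#'   thickness, folding, myelin) and `truth`.
#' @export
generateStructuralMaps <- function(atlas, cohort, effectSizeStruct = 0,
                                   targetParcels =
                                       cohortTruth(cohort)$affectedParcels,
                                   subjectSd = 0.1, seed = 2L) {
    np <- nParcels(atlas)
    ns <- nrow(subjectCovariates(cohort))
    zc <- parcelCoords(atlas)[, "z"]
    zbmi <- cohortTruth(cohort)$zBmi
    base <- list(
        thickness = 2.5 + 0.3 * zc,
        folding = 0.30 + 0.05 * zc,
        myelin = 1.5 - 0.2 * zc)
    eff <- numeric(np)
    eff[targetParcels] <- effectSizeStruct

    .withSeed(seed, {
        maps <- lapply(base, function(mu) {
            m <- matrix(mu, ns, np, byrow = TRUE) +
                outer(zbmi, eff) +
                matrix(stats::rnorm(ns * np, sd = subjectSd), ns)
            dimnames(m) <- list(subjectCovariates(cohort)$subject_id,
                sprintf("p%03d", seq_len(np) - 1L))
            m
        })
        list(maps = maps,
             truth = list(effectSizeStruct = effectSizeStruct,
                          targetParcels = targetParcels,
                          subjectSd = subjectSd, seed = as.integer(seed)))
    })
}

#' Generate a donor-level gene expression panel
#'
#' Signal genes share a canonical parcel profile correlated with
#' `targetMap` at approximately `signalCorr` in every donor (donor noise
#' `donorNoiseSd` perturbs it slightly); noise genes are independent
#' Gaussian per donor, so they show no donor-to-donor consistency.
#'
#' @param atlas a [ParcelAtlas-class] fixing the parcel dimension.
#' @param nDonors number of donors (>= 2).
#' @param nGenes total genes.
#' @param nSignalGenes number of planted signal genes (<= nGenes).
#' @param targetMap numeric parcel vector the signal genes track; must be
#'   non-constant.
#' @param signalCorr target correlation in (0, 1).
#' @param donorNoiseSd donor-level profile noise SD (0 gives exact
#'   correlation `signalCorr`).
#' @param seed integer seed.
#' @return list with `panel` (a [GeneExpressionPanel-class]) and
#'   `signalGenes` (character ids of the planted genes).
#' @export
generateExpressionPanel <- function(atlas, nDonors = 4L, nGenes = 200L,
                                    nSignalGenes = 20L, targetMap,
                                    signalCorr = 0.9,
                                    donorNoiseSd = 0.1, seed = 3L) {
    np <- nParcels(atlas)
    .stopIfNot(length(targetMap) == np,
        "targetMap must have one value per parcel")
    .stopIfNot(stats::sd(targetMap) > 0, "targetMap must not be constant")
    .stopIfNot(nSignalGenes <= nGenes,
        "nSignalGenes must not exceed nGenes")
    .stopIfNot(nDonors >= 2L, "nDonors must be >= 2")
    .stopIfNot(signalCorr > 0 && signalCorr < 1,
        "signalCorr must lie in (0, 1)")

    genes <- sprintf("g%04d", seq_len(nGenes))
    zt <- as.numeric(scale(targetMap))

    .withSeed(seed, {
        signalIdx <- sort(sample.int(nGenes, nSignalGenes))
        # gene-specific component, orthogonalised against the target so
        # the in-sample correlation is exactly signalCorr at zero donor
        # noise
        canon <- matrix(NA_real_, nSignalGenes, np)
        for (g in seq_len(nSignalGenes)) {
            u <- stats::rnorm(np)
            u <- u - zt * sum(u * zt) / sum(zt * zt)
            u <- as.numeric(scale(u))
            canon[g, ] <- signalCorr * zt + sqrt(1 - signalCorr^2) * u
        }
        expr <- lapply(seq_len(nDonors), function(d) {
            m <- matrix(stats::rnorm(nGenes * np), nGenes, np)
            if (nSignalGenes > 0) {
                m[signalIdx, ] <- canon +
                    matrix(stats::rnorm(nSignalGenes * np,
                        sd = donorNoiseSd), nSignalGenes)
            }
            dimnames(m) <- list(genes, sprintf("p%03d", seq_len(np) - 1L))
            m
        })
        donors <- sprintf("donor%02d", seq_len(nDonors))
        names(expr) <- donors
        list(
            panel = new("GeneExpressionPanel",
                expression = expr, geneIds = genes, donorIds = donors),
            signalGenes = genes[signalIdx])
    })
}

#' Generate a cell-type specificity profile
#'
#' Draws a specificity index (pSI-style, small = specific) per gene and
#' cell type. Planted signal genes receive very small indices for
#' `enrichedType` (log-uniform below the loosest threshold), making them
#' preferential members of that type's gene sets; all other entries are
#' uniform on (0, 1). Membership sets thresholded at the nested
#' stringencies are nested by construction.
#'
#' @param nGenes gene universe size.
#' @param cellTypes character vector of cell-type labels.
#' @param enrichedType the cell type the signal genes are planted into.
#' @param signalGenes character ids (subset of the universe).
#' @param geneIds optional gene ids (default `g0001`...).
#' @param thresholds decreasing pSI thresholds.
#' @param seed integer seed.
#' @return a [CellTypeSpecificity-class].
#' @export
generateCellTypeSpecificity <- function(nGenes, cellTypes, enrichedType,
                                        signalGenes = character(),
                                        geneIds = sprintf("g%04d",
                                            seq_len(nGenes)),
                                        thresholds = c(0.05, 0.01,
                                            0.001, 0.0001),
                                        seed = 4L) {
    .stopIfNot(enrichedType %in% cellTypes,
        "enrichedType must be one of cellTypes")
    .stopIfNot(all(signalGenes %in% geneIds),
        "signalGenes must be a subset of the gene universe")
    .withSeed(seed, {
        psi <- matrix(stats::runif(nGenes * length(cellTypes)),
            nGenes, length(cellTypes),
            dimnames = list(geneIds, cellTypes))
        if (length(signalGenes)) {
            lo <- log10(1e-5)
            hi <- log10(max(thresholds) * 0.9)
            psi[signalGenes, enrichedType] <-
                10^stats::runif(length(signalGenes), lo, hi)
        }
        new("CellTypeSpecificity",
            psi = psi, thresholds = thresholds, geneIds = geneIds)
    })
}
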