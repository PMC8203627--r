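test_that("atlas centroids are unit vectors with balanced contiguous modules", {
    atlas <- generateAtlas(8, 2)
    expect_equal(nParcels(atlas), 8L)
    expect_equal(sqrt(rowSums(parcelCoords(atlas)^2)), rep(1, 8))
    expect_equal(as.integer(table(moduleLabels(atlas))), c(4L, 4L))

    big <- generateAtlas(200, 7)
    sizes <- as.integer(table(moduleLabels(big)))
    expect_lte(diff(range(sizes)), 1L)
    # modules are latitude bands: z-coordinates within a module form a
    # contiguous run of the sorted z values
    z <- parcelCoords(big)[, "z"]
    for (m in levels(moduleLabels(big))) {
        idx <- which(moduleLabels(big) == m)
        rks <- rank(-z)[idx]
        expect_equal(sort(rks), seq(min(rks), max(rks)))
    }
    # one hierarchy level per module
    tab <- table(moduleLabels(big), hierarchyLabels(big))
    expect_true(all(rowSums(tab > 0) == 1))
})

test_that("atlas construction is deterministic and validates arguments", {
    expect_identical(generateAtlas(40, 5, seed = 1),
        generateAtlas(40, 5, seed = 1))
    expect_error(generateAtlas(3, 4), "exceed")
    expect_error(generateAtlas(10, 1), ">= 2")
})

test_that("cohort generation is seed-deterministic and records truth", {
    atlas <- generateAtlas(20, 4)
    a <- generateCohort(atlas, nSubjects = 5, nTimepoints = 50, seed = 9)
    b <- generateCohort(atlas, nSubjects = 5, nTimepoints = 50, seed = 9)
    expect_identical(subjectTimeSeries(a), subjectTimeSeries(b))
    expect_identical(subjectCovariates(a), subjectCovariates(b))
    tr <- cohortTruth(a)
    expect_setequal(tr$affectedParcels,
        which(moduleLabels(atlas) %in% tr$affectedModules))
})

test_that("null cohorts have constant coupling; planted effects are directional", {
    atlas <- generateAtlas(40, 4)
    null <- generateCohort(atlas, nSubjects = 8, nTimepoints = 100,
        effectSize = 0, seed = 3)
    expect_equal(diff(range(cohortTruth(null)$couplingWeights)), 0)

    # with a planted effect, higher BMI means weaker between-affected
    # coupling: negative correlation across subjects
    coh <- suppressWarnings(generateCohort(atlas, nSubjects = 100,
        nTimepoints = 120, effectSize = 0.13, seed = 5))
    tr <- cohortTruth(coh)
    mod <- moduleLabels(atlas)
    i1 <- which(mod == tr$affectedModules[1])
    i2 <- which(mod == tr$affectedModules[2])
    fc <- vapply(subjectTimeSeries(coh), function(ts) {
        r <- cor(t(ts))
        mean(atanh(r[i1, i2]))
    }, numeric(1))
    expect_lt(cor(tr$zBmi, fc), 0)
})

test_that("noise-free cohorts give perfectly correlated within-module parcels", {
    atlas <- generateAtlas(10, 2)
    coh <- generateCohort(atlas, nSubjects = 2, nTimepoints = 60,
        effectSize = 0, noiseSd = 0, seed = 1)
    ts <- subjectTimeSeries(coh)[[1]]
    idx <- which(moduleLabels(atlas) == "M1")
    r <- cor(t(ts[idx, ]))
    expect_equal(r[upper.tri(r)], rep(1, sum(upper.tri(r))))
})

test_that("BMI marginals match the calibrated log-normal", {
    atlas <- generateAtlas(6, 2)
    coh <- generateCohort(atlas, nSubjects = 4000, nTimepoints = 5,
        effectSize = 0, seed = 2)
    bmi <- subjectCovariates(coh)$bmi
    expect_equal(mean(bmi), 26.30, tolerance = 0.02)
    expect_equal(sd(bmi), 5.16, tolerance = 0.06)
    expect_gt(min(bmi), 0)
    # right-skewed, as BMI distributions are
    expect_gt(mean((bmi - mean(bmi))^3) / sd(bmi)^3, 0)
})

test_that("coupling weights clip at zero with a warning", {
    atlas <- generateAtlas(10, 2)
    expect_warning(
        coh <- generateCohort(atlas, nSubjects = 40, nTimepoints = 20,
            effectSize = 0.5, seed = 1),
        "clipped")
    expect_gte(min(cohortTruth(coh)$couplingWeights), 0)
})

test_that("structural maps are deterministic with planted BMI slopes", {
    atlas <- generateAtlas(30, 3)
    coh <- generateCohort(atlas, nSubjects = 80, nTimepoints = 20,
        effectSize = 0, seed = 4)
    s1 <- generateStructuralMaps(atlas, coh, effectSizeStruct = -0.3,
        seed = 7)
    s2 <- generateStructuralMaps(atlas, coh, effectSizeStruct = -0.3,
        seed = 7)
    expect_identical(s1$maps, s2$maps)

    # planted negative slope is recoverable in the target parcels
    zb <- cohortTruth(coh)$zBmi
    tgt <- s1$truth$targetParcels
    rTarget <- apply(s1$maps$thickness[, tgt], 2, cor, y = zb)
    expect_true(all(rTarget < 0))
    # and absent elsewhere
    null <- generateStructuralMaps(atlas, coh, effectSizeStruct = 0,
        seed = 8)
    rNull <- apply(null$maps$thickness, 2, cor, y = zb)
    expect_lt(mean(abs(rNull)), 0.15)
})

test_that("expression panels plant donor-consistent signal genes", {
    atlas <- generateAtlas(80, 4)
    withr::with_seed(10, tmap <- rnorm(80))
    gen <- generateExpressionPanel(atlas, nDonors = 3, nGenes = 60,
        nSignalGenes = 6, targetMap = tmap, signalCorr = 0.9,
        donorNoiseSd = 0, seed = 11)
    panel <- gen$panel
    expect_length(gen$signalGenes, 6L)
    for (d in donorIds(panel)) {
        rsig <- apply(donorExpression(panel, d)[gen$signalGenes, ], 1,
            cor, y = tmap)
        expect_equal(unname(rsig), rep(0.9, 6), tolerance = 1e-10)
    }
    # noise genes: no donor-to-donor consistency
    noise <- setdiff(geneIds(panel), gen$signalGenes)
    r12 <- vapply(noise, function(g)
        cor(donorExpression(panel, 1)[g, ],
            donorExpression(panel, 2)[g, ]), numeric(1))
    expect_lt(abs(mean(r12)), 0.05)
})

test_that("expression panel rejects degenerate inputs", {
    atlas <- generateAtlas(10, 2)
    expect_error(generateExpressionPanel(atlas, targetMap = rep(1, 10)),
        "constant")
    expect_error(generateExpressionPanel(atlas, nDonors = 1,
        targetMap = seq_len(10)), "nDonors")
    expect_error(generateExpressionPanel(atlas, nGenes = 5,
        nSignalGenes = 6, targetMap = seq_len(10)), "nSignalGenes")
})

test_that("cell-type specificity sets are nested and enriched by design", {
    genes <- sprintf("g%04d", 1:200)
    sig <- genes[1:20]
    cts <- c("cortex", "striatum", "cerebellum")
    spec <- generateCellTypeSpecificity(200, cts, "striatum",
        signalGenes = sig, seed = 5)
    sets <- membershipSets(spec)
    for (ct in cts) {
        ss <- sets[[ct]]
        for (i in 1:3) expect_true(all(ss[[i + 1]] %in% ss[[i]]))
    }
    # planted enrichment at the loosest threshold is hypergeometrically
    # significant by construction
    loose <- sets[["striatum"]][["0.05"]]
    x <- length(intersect(loose, sig))
    p <- hyperTailOracle(x, length(loose), 200, length(sig))
    expect_lt(p, 0.05)
    expect_error(generateCellTypeSpecificity(200, cts, "thalamus"),
        "enrichedType")
})
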