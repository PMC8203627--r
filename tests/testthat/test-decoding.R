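makePanel <- function(expr, genes = rownames(expr[[1]])) {
    new("GeneExpressionPanel", expression = expr,
        geneIds = genes, donorIds = names(expr))
}

test_that("gene-map association matches a per-donor correlation oracle", {
    withr::with_seed(31, {
        np <- 12
        tmap <- rnorm(np)
        expr <- lapply(1:3, function(d) {
            m <- matrix(rnorm(5 * np), 5, np,
                dimnames = list(paste0("g", 1:5), NULL))
            m
        })
        names(expr) <- paste0("d", 1:3)
    })
    panel <- makePanel(expr)
    res <- geneMapAssociation(tmap, panel)
    # naive loop: per-donor correlation, Fisher z, mean, back-transform
    for (g in 1:5) {
        zs <- vapply(1:3, function(d) atanh(cor(expr[[d]][g, ], tmap)),
            numeric(1))
        expect_equal(res$statistic[g], tanh(mean(zs)), tolerance = 1e-12)
        tt <- t.test(zs)
        expect_equal(res$p[g], tt$p.value, tolerance = 1e-12)
    }
})

test_that("perfect and orthogonal gene profiles hit the limits", {
    withr::with_seed(32, {
        np <- 30
        tmap <- rnorm(np)
        orth <- residuals(lm(rnorm(np) ~ tmap))
    })
    expr <- lapply(1:2, function(d)
        rbind(perfect = tmap, orthogonal = orth))
    names(expr) <- c("d1", "d2")
    res <- geneMapAssociation(tmap, makePanel(expr))
    expect_equal(res$statistic[1], tanh(atanh(1 - 1e-7)))
    expect_equal(res$p[1], 0)
    expect_lt(abs(res$statistic[2]), 1e-10)
})

test_that("constant gene profiles are skipped per donor with a warning", {
    withr::with_seed(33, {
        np <- 10
        tmap <- rnorm(np)
        good <- rnorm(np)
    })
    expr <- list(
        d1 = rbind(g1 = good, g2 = rep(1, np)),
        d2 = rbind(g1 = good + 0.1, g2 = good))
    expect_warning(res <- geneMapAssociation(tmap, makePanel(expr)),
        "constant")
    expect_equal(res$nDonorsUsed, c(2L, 1L))
})

test_that("association is invariant to affine rescaling of donor expression", {
    withr::with_seed(34, {
        np <- 20
        tmap <- rnorm(np)
        expr <- list(d1 = matrix(rnorm(4 * np), 4, np,
                dimnames = list(paste0("g", 1:4), NULL)),
            d2 = matrix(rnorm(4 * np), 4, np,
                dimnames = list(paste0("g", 1:4), NULL)))
    })
    r1 <- geneMapAssociation(tmap, makePanel(expr))
    expr2 <- expr
    expr2$d1 <- 3 * expr2$d1 + 10
    r2 <- geneMapAssociation(tmap, makePanel(expr2))
    expect_equal(r1$statistic, r2$statistic, tolerance = 1e-10)
    expect_equal(r1$p, r2$p, tolerance = 1e-10)
})

test_that("spin filtering keeps planted genes and bounds the minimal p", {
    atlas <- generateAtlas(80, 4)
    tmap <- withr::with_seed(35, rnorm(80))
    gen <- generateExpressionPanel(atlas, nDonors = 3, nGenes = 50,
        nSignalGenes = 5, targetMap = tmap, signalCorr = 0.9, seed = 36)
    assoc <- geneMapAssociation(tmap, gen$panel)
    kept <- spinSignificanceFilter(assoc, tmap, atlas, gen$panel,
        nRotations = 50, seed = 37)
    expect_true(all(gen$signalGenes %in% kept))
    spinP <- attr(kept, "spinP")
    expect_gte(min(spinP), 1 / 51)
    expect_equal(unname(spinP[gen$signalGenes]), rep(1 / 51, 5))
})

test_that("spin filtering on pure noise selects almost nothing", {
    atlas <- generateAtlas(60, 4)
    hits <- 0L
    for (seed in 1:8) {
        tmap <- withr::with_seed(100 + seed, rnorm(60))
        gen <- generateExpressionPanel(atlas, nDonors = 3, nGenes = 40,
            nSignalGenes = 0, targetMap = tmap, seed = 200 + seed)
        assoc <- geneMapAssociation(tmap, gen$panel)
        kept <- spinSignificanceFilter(assoc, tmap, atlas, gen$panel,
            nRotations = 50, seed = 300 + seed)
        hits <- hits + length(kept)
    }
    # empirical selection rate across seeds stays near the FDR level
    expect_lte(hits / (8 * 40), 2 * 0.05)
})

test_that("donor consistency keeps shared profiles and drops noise", {
    withr::with_seed(38, {
        np <- 40
        nNoise <- 30
        shared <- rnorm(np)
        expr <- lapply(1:4, function(d) rbind(
            consistent = shared + rnorm(np, sd = 0.05),
            matrix(rnorm(nNoise * np), nNoise, np,
                dimnames = list(paste0("n", seq_len(nNoise)), NULL))))
        names(expr) <- paste0("d", 1:4)
    })
    panel <- makePanel(expr)
    kept <- donorConsistencyFilter(panel,
        c("consistent", paste0("n", 1:30)))
    expect_true("consistent" %in% kept)
    # independent donor noise is filtered out up to FDR-level leakage
    expect_lte(sum(kept != "consistent"), 2)
    r <- attr(kept, "meanPairwiseR")
    expect_gt(r["consistent"], 0.9)
    expect_lt(mean(abs(r[paste0("n", 1:30)])), 0.2)
    single <- makePanel(expr["d1"])
    expect_error(donorConsistencyFilter(single, "n1"), "single donor")
})

test_that("hypergeometric enrichment matches exhaustive summation", {
    genes <- paste0("g", 1:100)
    lst <- genes[1:10]
    sets <- list(full = genes[1:10], none = genes[90:95])
    tab <- fisherEnrichment(lst, sets, genes)
    expect_equal(tab$p[tab$set_id == "full"], 1 / choose(100, 10))
    expect_equal(tab$p[tab$set_id == "none"], 1)
    # brute-force check over a grid of small tables
    for (N in c(15, 30)) {
        uni <- paste0("u", seq_len(N))
        for (n in c(3, 7)) for (K in c(2, 5, 9)) {
            for (x in 0:min(n, K)) {
                if (K - x > N - n) next
                set <- c(uni[seq_len(x)],
                    uni[n + seq_len(K - x)])
                tab <- fisherEnrichment(uni[seq_len(n)],
                    list(s = set), uni)
                expect_equal(tab$p, hyperTailOracle(x, K, N, n),
                    tolerance = 1e-12)
                expect_equal(tab$overlap, x)
            }
        }
    }
})

test_that("cell-type enrichment recovers the planted population", {
    genes <- sprintf("g%04d", 1:150)
    sig <- genes[1:15]
    spec <- generateCellTypeSpecificity(150,
        c("cortex", "striatum", "cerebellum"), "cerebellum",
        signalGenes = sig, seed = 39)
    tab <- cseaEnrichment(sig, spec)
    loose <- tab[tab$threshold == 0.05, ]
    expect_equal(loose$cell_type[which.min(loose$q)], "cerebellum")
    # empty gene list: all p = 1
    empty <- cseaEnrichment(character(), spec)
    expect_true(all(empty$p == 1))
    # q-values respect the p ordering
    expect_true(all(diff(tab$q[order(tab$p)]) >= -1e-12))
})
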