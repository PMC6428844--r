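test_that("a two-domain scaffold places beads at the expected distance", {
    b <- genomicBinning("c", 1000L, 2L)
    m <- contactMap(b, 1, 2, 4)
    low <- buildLowresModel(m)
    # degenerate single-IF matrix: exponent falls back to 1, delta = 1/4
    expect_equal(S4Vectors::metadata(low)$alpha, 1.0)
    d <- sqrt(sum((coords(low)[1, ] - coords(low)[2, ])^2))
    expect_equal(d, 0.25, tolerance = 1e-3)

    expect_error(buildLowresModel(contactMap(b)), "empty")
})

test_that("the scaffold recovers the arrangement of true domain centers", {
    p <- simulationParams(noise = "none", depth = 1, seed = 3)
    g <- generateStructure(p)
    m <- simulateContacts(g$structure, p)
    agg <- aggregateDomainMatrix(m, g$domains)
    low <- buildLowresModel(agg)
    expect_gte(structureSimilarity(low, trueCenters(g$structure,
                                                    g$domains)), 0.9)
    low2 <- buildLowresModel(agg)
    expect_identical(coords(low), coords(low2))   # seeded determinism
})

test_that("domain models are rebuilt at the consensus exponent", {
    p <- simulationParams(nDomains = 3L, binsPerDomain = 20L,
                          noise = "none", depth = 1, seed = 9)
    g <- generateStructure(p)
    m <- simulateContacts(g$structure, p)
    dm <- buildDomainModels(m, g$domains,
                            config = optimizerConfig(maxIter = 800L))
    expect_length(dm$models, 3L)
    expect_equal(dm$consensusAlpha, median(dm$alphas))
    # models live on global bins, one per domain bin
    expect_equal(unlist(lapply(dm$models, modeledBins)),
                 seq_len(60L), ignore_attr = TRUE)
})

test_that("a single-bin domain and a contact-free domain degrade gracefully", {
    b <- genomicBinning("c", 1000L, 7L)
    # domain 2 is one bin; domain 3 has no intra-domain contacts
    ds <- domainSet(b, c(1L, 4L, 5L), c(3L, 4L, 7L))
    m <- contactMap(b, c(1, 1, 2, 1), c(2, 3, 3, 6), c(4, 2, 3, 1))
    dm <- suppressWarnings(buildDomainModels(m, ds))
    expect_equal(nrow(coords(dm$models[[2]])), 1L)
    # straight segment with unit spacing for the contact-free domain
    X3 <- coords(dm$models[[3]])
    expect_equal(.pairDistOracle(X3, 1:2, 2:3), c(1, 1))
})

test_that("center-distance estimation enumerates the triangle bound", {
    b <- genomicBinning("c", 1000L, 2L)
    one <- structure3D(b, matrix(0, 1, 3), 1L)
    inter <- data.frame(i = 1L, j = 1L, ifreq = 1)
    expect_equal(estimateCenterDistance(one, one, inter, 1), 1)

    two <- structure3D(b, rbind(c(-0.5, 0, 0), c(0.5, 0, 0)))
    inter2 <- data.frame(i = c(1L, 2L), j = c(1L, 2L), ifreq = c(1, 4))
    expect_equal(estimateCenterDistance(two, two, inter2, 1), 1.25)

    # adding a contact can only lower (or keep) the estimate
    inter3 <- rbind(inter2, data.frame(i = 1L, j = 2L, ifreq = 100))
    expect_lte(estimateCenterDistance(two, two, inter3, 1), 1.25)

    expect_true(is.na(estimateCenterDistance(two, two,
                                             inter2[0, ], 1)))
})

test_that("the center-distance estimate upper-bounds the true distance", {
    p <- simulationParams(depth = 1, noise = "none", seed = 13)
    g <- generateStructure(p)
    m <- simulateContacts(g$structure, p)
    models <- trueDomainModels(g$structure, g$domains)
    centers <- coords(trueCenters(g$structure, g$domains))
    est <- estimateScalingRatio(models,
                                trueCenters(g$structure, g$domains),
                                m, g$domains, p$alphaTrue,
                                balance = "none")
    for (r in seq_len(nrow(est@pairs))) {
        x <- est@pairs$x[r]; y <- est@pairs$y[r]
        dTrue <- sqrt(sum((centers[x, ] - centers[y, ])^2))
        expect_gte(est@pairs$dxy[r], dTrue - 1e-9)
    }
})

test_that("known shrink factors are recovered by the median ratio", {
    p <- simulationParams(depth = 1, noise = "none", seed = 7)
    g <- generateStructure(p)
    m <- simulateContacts(g$structure, p)
    models <- trueDomainModels(g$structure, g$domains)
    ctr <- trueCenters(g$structure, g$domains)
    for (r in c(1.5, 3.0)) {
        low <- structure3D(binning(ctr), coords(ctr) / r)
        est <- estimateScalingRatio(models, low, m, g$domains,
                                    p$alphaTrue, balance = "none")
        expect_lt(abs(est@medianRatio - r) / r, 0.15)
        expect_lte(nrow(est@pairs), length(g$domains) - 1L)
    }
})

test_that("uniform rescaling scales every pairwise distance exactly", {
    b <- genomicBinning("c", 1000L, 2L)
    s <- structure3D(b, rbind(c(0, 0, 0), c(1, 0, 0)))
    expect_identical(coords(scaleStructure(s, 1)), coords(s))
    s2 <- scaleStructure(s, 2.5)
    expect_equal(sqrt(sum((coords(s2)[1, ] - coords(s2)[2, ])^2)), 2.5)
    expect_equal(coords(scaleStructure(scaleStructure(s, 2), 0.5)),
                 coords(s))
    expect_error(scaleStructure(s, -1), "positive")
})

test_that("assembly puts each domain centroid on its scaffold bead", {
    p <- simulationParams(nDomains = 4L, binsPerDomain = 10L,
                          noise = "none", depth = 1, seed = 2)
    g <- generateStructure(p)
    models <- trueDomainModels(g$structure, g$domains)
    low <- trueCenters(g$structure, g$domains)
    asm <- assembleStructure(low, models, g$domains)
    expect_equal(length(asm), 40L)
    for (k in 1:4) {
        idx <- IRanges::start(domainRanges(g$domains))[k]:
            IRanges::end(domainRanges(g$domains))[k]
        rows <- match(idx, modeledBins(asm))
        expect_equal(colMeans(coords(asm)[rows, ]), coords(low)[k, ],
                     tolerance = 1e-9, ignore_attr = TRUE)
        # intra-domain distances preserved exactly (translation only)
        expect_equal(as.numeric(dist(coords(asm)[rows, ])),
                     as.numeric(dist(coords(models[[k]]))),
                     tolerance = 1e-12)
    }
    expect_error(assembleStructure(low, models[1:3], g$domains),
                 "does not match")
})

test_that("two single-bead domains assemble to the scaffold itself", {
    b <- genomicBinning("c", 1000L, 2L)
    ds <- domainSet(b, c(1L, 2L), c(1L, 2L))
    models <- list(structure3D(b, matrix(1, 1, 3), 1L),
                   structure3D(b, matrix(-1, 1, 3), 2L))
    low <- structure3D(genomicBinning("c", 2000L, 2L),
                       rbind(c(0, 0, 0), c(3, 0, 0)))
    asm <- assembleStructure(low, models, ds)
    expect_equal(coords(asm), coords(low))
})

test_that("refinement never lowers the objective and is deterministic", {
    run <- defaultPipelineRun()
    obj <- run$res$report$objectives
    expect_gte(obj$refinedTotal, obj$assembledTotal)
    expect_gte(obj$refinedInter, obj$assembledInter)

    # refining an already refined model changes essentially nothing
    again <- refineStructure(run$res$structure, run$map,
                             run$res$report$consensusAlpha)
    md <- S4Vectors::metadata(again)
    expect_gte(md$objective, md$initialObjective - 1e-9)
    expect_equal(md$scaleApplied, 1)
})

test_that("the full pipeline runs on a single-domain chromosome", {
    p <- simulationParams(nDomains = 1L, binsPerDomain = 25L, seed = 4)
    g <- generateStructure(p)
    m <- simulateContacts(g$structure, p)
    res <- runHierarchical(m, domains = g$domains)
    expect_s4_class(res$structure, "Structure3D")
    expect_equal(length(res$structure), 25L)
    expect_gte(structureSimilarity(res$structure, g$structure), 0.8)
})
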