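test_that("distance correlation is perfect for an exact model", {
    p <- simulationParams(nDomains = 2L, binsPerDomain = 15L, depth = 1,
                          noise = "none", seed = 6)
    g <- generateStructure(p)
    m <- simulateContacts(g$structure, p)
    expect_equal(distanceSpearman(g$structure, m, p$alphaTrue), 1.0)
})

test_that("distance correlation matches a rank oracle and handles cutoffs", {
    p <- simulationParams(nDomains = 2L, binsPerDomain = 15L, seed = 16)
    g <- generateStructure(p)
    m <- simulateContacts(g$structure, p)
    set.seed(17)
    # permuted and jittered: jitter breaks the exact distance ties of
    # the fixed-step walk, which rank correlation is sensitive to
    perm <- structure3D(binning(g$structure),
                        coords(g$structure)[sample(30), ] +
                            rnorm(90, sd = 1e-3))
    got <- distanceSpearman(perm, m, 1)
    cc <- contacts(m)
    off <- cc$i != cc$j
    d <- .pairDistOracle(coords(perm), cc$i[off], cc$j[off])
    expect_equal(got, spearmanOracle(d, cc$ifreq[off]^(-1)),
                 tolerance = 1e-12)
    expect_lt(abs(got), 0.3)

    expect_warning(res <- distanceSpearman(perm, m, 1,
                                           ifCutoff = max(cc$ifreq) + 1),
                   "undefined")
    expect_true(is.na(res))
})

test_that("zooming out averages fine-bin coordinates per coarse bin", {
    b <- genomicBinning("c", 5000L, 4L)
    s <- structure3D(b, rbind(c(0, 0, 0), c(2, 0, 0), c(5, 5, 5)),
                     bins = c(1L, 2L, 3L))
    z <- zoomOut(s, 10000L)
    expect_equal(coords(z), rbind(c(1, 0, 0), c(5, 5, 5)))
    expect_equal(modeledBins(z), c(1L, 2L))

    expect_identical(coords(zoomOut(s, 5000L)), coords(s))
    expect_error(zoomOut(s, 7500L), "multiple")

    # absent fine bins leave absent coarse bins
    s2 <- structure3D(b, matrix(1, 1, 3), bins = 4L)
    expect_equal(modeledBins(zoomOut(s2, 10000L)), 2L)
})

test_that("structure similarity is blind to pose, scale and chirality", {
    pc <- pointCloudRestraints(10, seed = 19)
    b <- genomicBinning("c", 1000L, 10L)
    a <- structure3D(b, pc$points)
    expect_equal(structureSimilarity(a, a), 1.0)
    set.seed(20)
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    moved <- structure3D(b, sweep(pc$points %*% Q, 2, c(1, 2, 3), "+") * 2)
    expect_equal(structureSimilarity(a, moved), 1.0)
    mirror <- structure3D(b, pc$points %*% diag(c(-1, 1, 1)))
    expect_equal(structureSimilarity(a, mirror), 1.0)

    expect_error(structureSimilarity(a, structure3D(b, pc$points[1:9, ],
                                                    bins = 1:9)),
                 "bead counts")
})

test_that("zoom-out of a structure against itself is perfectly consistent", {
    p <- simulationParams(nDomains = 3L, binsPerDomain = 16L, seed = 23)
    g <- generateStructure(p)
    z1 <- zoomOut(g$structure, 20000L)
    z2 <- zoomOut(g$structure, 20000L)
    expect_equal(structureSimilarity(z1, z2), 1.0)
})

test_that("probe distances are centroid-to-centroid", {
    b <- genomicBinning("c", 5000L, 6L)
    X <- rbind(c(0, 0, 0), c(3, 4, 0), c(1, 0, 0), c(3, 0, 0),
               c(0, 2, 0), c(0, 4, 0))
    s <- structure3D(b, X)
    expect_equal(probeDistance(s, c(0, 5000), c(0, 5000)), 0)
    expect_equal(probeDistance(s, c(0, 5000), c(5000, 10000)), 5)
    # multi-bead locus uses the centroid (bins 3-4 -> (2,0,0))
    expect_equal(probeDistance(s, c(0, 5000), c(10000, 20000)), 2)
    expect_error(probeDistance(s, c(0, 5000), c(50000, 60000)),
                 "overlaps no")
})

test_that("compartment PC1 separates interleaved groups exactly", {
    n <- 20L
    # aperiodic two-group assignment (a periodic one is invisible to
    # the observed/expected transform, which conditions on offset)
    set.seed(41)
    grp <- sample(c(0L, 1L), n, replace = TRUE)
    M <- outer(grp, grp, function(a, b2) ifelse(a == b2, 8, 1)) /
        (1 + abs(outer(seq_len(n), seq_len(n), "-")))
    ut <- which(upper.tri(M), arr.ind = TRUE)
    m <- contactMap(genomicBinning("c", 1000L, n), ut[, 1], ut[, 2],
                    M[ut])
    v <- compartmentPC1(m)
    expect_gte(v[1], 0)                    # sign convention
    expect_true(all(sign(v[grp == grp[1]]) == sign(v[1])))
    expect_true(all(sign(v[grp != grp[1]]) == -sign(v[1])))

    # power-iteration oracle on the same O/E correlation matrix
    A <- interactionMatrix(m)
    off <- abs(outer(seq_len(n), seq_len(n), "-"))
    E <- matrix(vapply(0:(n - 1), function(k) mean(A[off == k]),
                       numeric(1))[off + 1], n, n)
    OE <- A / E
    diag(OE) <- NA
    C <- stats::cor(OE, use = "pairwise.complete.obs")
    w <- rep(1, n)
    for (it in 1:500) { w <- C %*% w; w <- w / sqrt(sum(w^2)) }
    w <- as.vector(w) * sign(w[1])
    expect_equal(abs(v), abs(w), tolerance = 1e-6)
})

test_that("a uniform map has no compartment signal", {
    n <- 10L
    ut <- which(upper.tri(diag(n)), arr.ind = TRUE)
    m <- contactMap(genomicBinning("c", 1000L, n), ut[, 1], ut[, 2],
                    rep(3, nrow(ut)))
    expect_error(compartmentPC1(m), "degenerate")
})
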