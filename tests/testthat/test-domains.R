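test_that("insulation profile matches the brute-force definition", {
    m <- twoBlockMap(20L)
    w <- 5L
    out <- insulationBoundaries(m, window = w, deltaThreshold = 0.1)
    # brute-force oracle on the dense matrix
    A <- interactionMatrix(m)
    n <- nrow(A)
    raw <- rep(NA_real_, n)
    for (b in (w + 1L):(n - w + 1L))
        raw[b] <- mean(A[(b - w):(b - 1L), b:(b + w - 1L)])
    expected <- log2(raw / mean(raw, na.rm = TRUE))
    expect_equal(out$score, expected)
    expect_equal(out$boundaries, 21L)
})

test_that("uniform maps yield no boundaries and weak dips are suppressed", {
    n <- 30L
    M <- matrix(1, n, n)
    ut <- which(upper.tri(M), arr.ind = TRUE)
    flat <- contactMap(genomicBinning("c", 1000L, n), ut[, 1], ut[, 2],
                       M[ut])
    expect_length(insulationBoundaries(flat, 5L)$boundaries, 0L)

    weak <- twoBlockMap(15L, within = 1.2, between = 1.0)
    expect_length(
        insulationBoundaries(weak, 5L, deltaThreshold = 2)$boundaries,
        0L)

    expect_error(insulationBoundaries(flat, window = 15L), "too large")
})

test_that("boundaries delimit domains and long domains are split", {
    b40 <- genomicBinning("c", 1000L, 40L)
    ds <- domainsFromBoundaries(21L, b40)
    expect_equal(IRanges::start(domainRanges(ds)), c(1L, 21L))
    expect_equal(IRanges::end(domainRanges(ds)), c(20L, 40L))

    b100 <- genomicBinning("c", 1000L, 100L)
    ds2 <- domainsFromBoundaries(integer(), b100, maxDomainBins = 60L)
    expect_equal(IRanges::start(domainRanges(ds2)), c(1L, 51L))

    b30 <- genomicBinning("c", 1000L, 30L)
    ds3 <- domainsFromBoundaries(c(11L, 21L), b30)
    expect_equal(length(ds3), 3L)
})

test_that("nested domain calls keep only the outermost interval", {
    b <- genomicBinning("c", 1000L, 100L)
    ds <- resolveNested(IRanges::IRanges(c(1L, 21L), c(100L, 40L)), b)
    expect_equal(length(ds), 1L)
    expect_equal(IRanges::width(domainRanges(ds)), 100L)

    b40 <- genomicBinning("c", 1000L, 40L)
    ds2 <- resolveNested(IRanges::IRanges(c(1L, 21L), c(10L, 30L)), b40)
    expect_equal(IRanges::start(domainRanges(ds2)), c(1L, 11L, 21L, 31L))

    expect_error(
        resolveNested(IRanges::IRanges(c(1L, 6L), c(10L, 20L)), b40),
        "overlapping")
})

test_that("nested resolution always yields a disjoint cover of outermost intervals", {
    set.seed(31)
    for (rep in 1:20) {
        n <- sample(30:80, 1)
        b <- genomicBinning("c", 1000L, n)
        k <- sample(1:6, 1)
        s <- sort(sample(seq_len(n - 2L), k))
        e <- pmin(n, s + sample(1:15, k, replace = TRUE))
        raw <- IRanges::IRanges(s, e)
        # keep the attempt only if overlaps are pure nestings
        outer_of <- function(r) {
            keep <- rep(TRUE, length(r))
            for (a in seq_along(r)) for (b2 in seq_along(r)) {
                if (a == b2) next
                if (IRanges::start(r)[a] >= IRanges::start(r)[b2] &&
                    IRanges::end(r)[a] <= IRanges::end(r)[b2] &&
                    IRanges::width(r)[a] < IRanges::width(r)[b2])
                    keep[a] <- FALSE
            }
            r[keep]
        }
        kept <- outer_of(unique(raw))
        ok <- length(kept) < 2L ||
            all(IRanges::start(kept)[-1L] >
                IRanges::end(kept)[-length(kept)])
        if (!ok) next
        ds <- resolveNested(raw, b)
        r <- domainRanges(ds)
        expect_equal(sum(IRanges::width(r)), n)            # full cover
        expect_true(all(IRanges::start(r)[-1L] ==
                        IRanges::end(r)[-length(r)] + 1L)) # disjoint
        expect_true(all(IRanges::start(kept) %in% IRanges::start(r)))
    }
})

test_that("domain aggregation sums inter-domain IF and conserves mass", {
    b <- genomicBinning("c", 1000L, 4L)
    m <- contactMap(b, c(1, 2), c(3, 4), c(1, 2))
    ds <- domainSet(b, c(1L, 3L), c(2L, 4L))
    agg <- aggregateDomainMatrix(m, ds)
    expect_equal(contacts(agg),
                 data.frame(i = 1L, j = 2L, ifreq = 3))

    # conservation on a random map
    m2 <- randomFullMap(12, 5)
    b2 <- binning(m2)
    ds2 <- domainSet(b2, c(1L, 5L, 9L), c(4L, 8L, 12L))
    agg2 <- aggregateDomainMatrix(m2, ds2)
    d <- domainOfBin(ds2)
    inter <- d[contacts(m2)$i] != d[contacts(m2)$j]
    expect_equal(sum(contacts(agg2)$ifreq),
                 sum(contacts(m2)$ifreq[inter]))

    # single domain: empty one-bead map
    ds1 <- domainSet(b2, 1L, 12L)
    expect_equal(length(aggregateDomainMatrix(m2, ds1)), 0L)
})
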