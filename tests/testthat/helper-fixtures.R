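# fixtures built in code; all randomness is locally seeded

# random symmetric full-support contact map (positive everywhere off
# the diagonal)
randomFullMap <- function(n, seed, lo = 0.5, hi = 2) {
    set.seed(seed)
    M <- matrix(stats::runif(n * n, lo, hi), n)
    M <- (M + t(M)) / 2
    ut <- which(upper.tri(M), arr.ind = TRUE)
    contactMap(genomicBinning("chrT", 1000L, n), ut[, 1L], ut[, 2L],
               M[ut])
}

# complete noise-free restraints from a random 3D point cloud
pointCloudRestraints <- function(n, seed) {
    set.seed(seed)
    P <- matrix(stats::rnorm(n * 3), n, 3)
    D <- as.matrix(dist(P))
    ut <- which(upper.tri(D), arr.ind = TRUE)
    list(points = P,
         restraints = data.frame(i = ut[, 1L], j = ut[, 2L],
                                 delta = D[ut], weight = 1,
                                 adjacency = FALSE))
}

# two-block contact matrix with uniform within-block and cross-block IF
twoBlockMap <- function(blockBins = 20L, within = 5, between = 0.5) {
    n <- 2L * blockBins
    M <- matrix(between, n, n)
    M[seq_len(blockBins), seq_len(blockBins)] <- within
    M[(blockBins + 1L):n, (blockBins + 1L):n] <- within
    ut <- which(upper.tri(M), arr.ind = TRUE)
    contactMap(genomicBinning("chrT", 1000L, n), ut[, 1L], ut[, 2L],
               M[ut])
}

# paired Euclidean distances between indexed rows of a coordinate matrix
.pairDistOracle <- function(X, i, j) {
    vapply(seq_along(i), function(k) sqrt(sum((X[i[k], ] - X[j[k], ])^2)),
           numeric(1))
}

# independent Spearman oracle: Pearson correlation of ranks
spearmanOracle <- function(x, y) {
    rx <- rank(x); ry <- rank(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
        sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# true domain-center structure of a simulated ground truth
trueCenters <- function(truth, domains) {
    dr <- domainRanges(domains)
    centers <- t(vapply(seq_along(dr), function(k) {
        idx <- IRanges::start(dr)[k]:IRanges::end(dr)[k]
        colMeans(coords(truth)[idx, , drop = FALSE])
    }, numeric(3)))
    structure3D(genomicBinning(chromName(truth),
                               binResolution(truth) * 30L,
                               length(dr)), centers)
}

# per-domain ground-truth substructures (global bins)
trueDomainModels <- function(truth, domains) {
    dr <- domainRanges(domains)
    lapply(seq_along(dr), function(k) {
        idx <- IRanges::start(dr)[k]:IRanges::end(dr)[k]
        structure3D(binning(truth), coords(truth)[idx, , drop = FALSE],
                    idx)
    })
}
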