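#' Simulation parameters
#'
#' Settings of the synthetic ground-truth generator. The defaults are
#' the study conditions used throughout the package's validation: a
#' 10-domain chromosome of 30 bins per domain at 5 kb, unit conversion
#' exponent, sequencing depth 100 (expected counts at unit distance)
#' and Poisson sampling noise.
#'
#' @param nDomains Number of domains; default 10.
#' @param binsPerDomain Bins per domain (scalar or one per domain);
#'   default 30.
#' @param domainRadius Radius of each domain globule (model units);
#'   default 1.
#' @param backboneStep Distance between consecutive domain centers;
#'   default 3 (centers three globule radii apart keeps domains
#'   internally dense relative to their surroundings, as TADs are).
#' @param alphaTrue True conversion exponent in `[0.1, 3]`; default 1.
#' @param depth IF scale: expected count for a pair at unit distance;
#'   default 100.
#' @param noise `"poisson"` (default) or `"none"` (store expectations).
#' @param cutoffQuantile Pairs farther than this distance quantile are
#'   not observed (Hi-C sparsity); default 0.95, use 1 for all pairs.
#' @param resolution Bin width in bp; default 5000.
#' @param chrom Chromosome label; default `"chrS"`.
#' @param seed RNG seed; default 7.
#' @return A validated list of class `"SimulationParams"`.
#' @export
simulationParams <- function(nDomains = 10L, binsPerDomain = 30L,
                             domainRadius = 1.0, backboneStep = 3.0,
                             alphaTrue = 1.0, depth = 100,
                             noise = c("poisson", "none"),
                             cutoffQuantile = 0.95, resolution = 5000L,
                             chrom = "chrS", seed = 7L) {
    noise <- match.arg(noise)
    stopifnot(nDomains >= 1, all(binsPerDomain >= 1), domainRadius > 0,
              backboneStep > 0, alphaTrue >= 0.1, alphaTrue <= 3,
              depth > 0, cutoffQuantile > 0, cutoffQuantile <= 1)
    bpd <- rep_len(as.integer(binsPerDomain), nDomains)
    structure(list(nDomains = as.integer(nDomains), binsPerDomain = bpd,
                   domainRadius = domainRadius,
                   backboneStep = backboneStep, alphaTrue = alphaTrue,
                   depth = depth, noise = noise,
                   cutoffQuantile = cutoffQuantile,
                   resolution = as.integer(resolution), chrom = chrom,
                   seed = as.integer(seed)),
              class = "SimulationParams")
}

#' Generate a hierarchical ground-truth structure
#'
#' Domain centers follow a seeded self-avoiding random walk with step
#' `backboneStep` (steps landing within `backboneStep / 2` of any
#' previous center are rejected, up to 1000 retries). Within each
#' domain, beads follow a random walk with step
#' `domainRadius / sqrt(binsPerDomain)` reflected inside a sphere of
#' radius `domainRadius` about the center — a compact globule, so
#' intra-domain distances are systematically smaller than inter-domain
#' ones, the structural signature of TADs.
#'
#' @param params A [simulationParams()].
#' @return `list(structure = Structure3D, domains = DomainSet)`.
#' @export
generateStructure <- function(params = simulationParams()) {
    stopifnot(inherits(params, "SimulationParams"))
    nb <- sum(params$binsPerDomain)
    bng <- genomicBinning(params$chrom, params$resolution, nb)
    res <- .withSeed(params$seed, {
        centers <- matrix(0, params$nDomains, 3)
        for (k in seq_len(params$nDomains)[-1L]) {
            placed <- FALSE
            for (try in seq_len(1000L)) {
                u <- stats::rnorm(3)
                u <- u / sqrt(sum(u^2))
                cand <- centers[k - 1L, ] + params$backboneStep * u
                d2 <- colSums((t(centers[seq_len(k - 1L), ,
                                         drop = FALSE]) - cand)^2)
                if (min(d2) >= (params$backboneStep / 2)^2) {
                    centers[k, ] <- cand; placed <- TRUE; break
                }
            }
            if (!placed)
                stop("self-avoiding walk failed after 1000 retries; ",
                     "increase 'backboneStep'")
        }
        X <- matrix(0, nb, 3)
        row <- 1L
        for (k in seq_len(params$nDomains)) {
            m <- params$binsPerDomain[k]
            step <- params$domainRadius / sqrt(m)
            p <- centers[k, ]
            for (b in seq_len(m)) {
                if (b > 1L) {
                    u <- stats::rnorm(3)
                    u <- u / sqrt(sum(u^2))
                    p <- p + step * u
                    v <- p - centers[k, ]
                    nv <- sqrt(sum(v^2))
                    if (nv > params$domainRadius)   # reflect at the wall
                        p <- centers[k, ] +
                            v * (2 * params$domainRadius - nv) / nv
                }
                X[row, ] <- p
                row <- row + 1L
            }
        }
        X
    })
    ends <- cumsum(params$binsPerDomain)
    starts <- c(1L, head(ends, -1L) + 1L)
    list(structure = structure3D(bng, res),
         domains = domainSet(bng, starts, ends))
}

#' Simulate a contact map from a ground-truth structure
#'
#' Inverts the distance-conversion law: a pair at distance `d` has
#' expected `IF = depth * d^(-1 / alphaTrue)`, so in the noise-free
#' case `expectedDistance(IF / depth, alphaTrue)` returns `d` exactly.
#' Only pairs closer than the `cutoffQuantile` distance quantile are
#' observed (mimicking Hi-C sparsity); with `noise = "poisson"` each
#' stored IF is a seeded Poisson draw with the expected value as mean,
#' and zero draws are dropped. Coincident bead pairs are skipped with a
#' warning.
#'
#' @param truth A [Structure3D-class] ground truth.
#' @param params A [simulationParams()].
#' @return A [ContactMap-class] over the truth's binning.
#' @export
simulateContacts <- function(truth, params = simulationParams()) {
    stopifnot(inherits(params, "SimulationParams"))
    n <- length(truth)
    d <- as.vector(dist(coords(truth)))
    ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    # dist() enumerates pairs (j, i), j < i, by j then i; align orders
    ii <- ut[order(ut[, 1L], ut[, 2L]), , drop = FALSE]
    if (any(d == 0)) {
        warning(sum(d == 0), " coincident bead pairs skipped")
        ii <- ii[d > 0, , drop = FALSE]
        d <- d[d > 0]
    }
    keep <- d <= stats::quantile(d, params$cutoffQuantile)
    ii <- ii[keep, , drop = FALSE]
    d <- d[keep]
    mu <- params$depth * d^(-1 / params$alphaTrue)
    ifreq <- if (params$noise == "poisson")
        .withSeed(params$seed + 1L, stats::rpois(length(mu), mu))
    else mu
    bins <- modeledBins(truth)
    contactMap(binning(truth), bins[ii[, 1L]], bins[ii[, 2L]], ifreq)
}
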