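#' Spearman correlation of model vs expected distances
#'
#' Over the observed contacts (optionally only those with
#' `IF >= ifCutoff`; lower-frequency, less reliable contacts are
#' removed), computes the Spearman rank correlation between the model's
#' realized Euclidean distances and the expected distances
#' `IF^(-alpha)`. Positive values mean the model orders pairs like the
#' contact data does. Contacts touching unmodeled bins are ignored.
#'
#' @param s A [Structure3D-class].
#' @param map A [ContactMap-class].
#' @param alpha Conversion exponent.
#' @param ifCutoff Contacts with `IF < ifCutoff` are excluded;
#'   default 0.
#' @return The correlation, or `NA_real_` (with a warning) when fewer
#'   than 3 contacts survive.
#' @export
distanceSpearman <- function(s, map, alpha, ifCutoff = 0) {
    off <- map@i != map@j & map@ifreq >= ifCutoff
    bi <- match(map@i[off], modeledBins(s))
    bj <- match(map@j[off], modeledBins(s))
    ok <- !is.na(bi) & !is.na(bj)
    if (sum(ok) < 3L) {
        warning("fewer than 3 contacts survive the cutoff; ",
                "correlation undefined")
        return(NA_real_)
    }
    d <- .pairDist(coords(s), bi[ok], bj[ok])
    delta <- expectedDistance(map@ifreq[off][ok], alpha)
    stats::cor(d, delta, method = "spearman")
}

#' Coarsen a structure by averaging bead coordinates
#'
#' Each coarse bin's coordinate is the mean of the coordinates of its
#' present fine bins ("zooming out", e.g. a 5 kb model to 1 Mb); coarse
#' bins with no present fine bins are absent from the result.
#'
#' @param s A [Structure3D-class].
#' @param targetResolution Target bin width in bp; must be a multiple
#'   of the source resolution.
#' @return A coarser [Structure3D-class].
#' @export
zoomOut <- function(s, targetResolution) {
    res <- binResolution(s)
    if (targetResolution %% res != 0)
        stop("target resolution must be a multiple of ", res)
    fac <- targetResolution %/% res
    coarse <- (modeledBins(s) - 1L) %/% fac + 1L
    X <- rowsum(coords(s), coarse)
    cnt <- as.vector(table(coarse)[rownames(X)])
    b <- genomicBinning(chromName(s), targetResolution,
                       as.integer(ceiling(nBins(s) / fac)))
    structure3D(b, X / cnt, as.integer(rownames(X)))
}

#' Topological similarity of two structures
#'
#' Spearman correlation between the all-pairs distance vectors of two
#' structures with matched beads. Invariant to rigid motion, mirror
#' reflection (chirality-blind) and uniform scaling of either input.
#'
#' @param a,b [Structure3D-class] objects with equal bead counts.
#' @return The correlation, or `NA_real_` (with a warning) for fewer
#'   than 3 beads.
#' @export
structureSimilarity <- function(a, b) {
    if (length(a) != length(b))
        stop("structures have different bead counts (", length(a),
             " vs ", length(b), ")")
    if (length(a) < 3L) {
        warning("fewer than 3 beads; similarity undefined")
        return(NA_real_)
    }
    stats::cor(as.vector(dist(coords(a))), as.vector(dist(coords(b))),
               method = "spearman")
}

#' Spatial distance between two loci in a model
#'
#' Euclidean distance between the centroids of the beads overlapping
#' each genomic interval — the model analogue of a FISH probe-pair
#' measurement.
#'
#' @param s A [Structure3D-class].
#' @param locusA,locusB Numeric `c(start, end)` in bp (0-based
#'   half-open) on the structure's chromosome.
#' @return The distance (model units).
#' @export
probeDistance <- function(s, locusA, locusB) {
    centroid <- function(locus, label) {
        res <- binResolution(s)
        first <- as.integer(locus[1L] %/% res + 1)
        last <- as.integer(ceiling(locus[2L] / res))
        rows <- which(modeledBins(s) >= first & modeledBins(s) <= last)
        if (length(rows) == 0L)
            stop("locus ", label, " [", locus[1L], ", ", locus[2L],
                 ") overlaps no modeled bead")
        colMeans(coords(s)[rows, , drop = FALSE])
    }
    sqrt(sum((centroid(locusA, "A") - centroid(locusB, "B"))^2))
}

#' First principal component of the contact correlation matrix
#'
#' The classical A/B-compartment signal: each IF is divided by the mean
#' IF at its diagonal offset (observed/expected), the Pearson
#' correlation matrix of the result is formed over retained bins, and
#' its first eigenvector is returned per bin. The sign of each entry
#' assigns the compartment; the global sign is arbitrary and fixed by
#' making the first retained bin non-negative.
#'
#' @param map A balanced [ContactMap-class] with >= 4 retained bins.
#' @return Per-bin numeric vector (NA for bins with no contacts).
#' @export
compartmentPC1 <- function(map) {
    retained <- .retainedBins(map)
    if (length(retained) < 4L) stop("need >= 4 retained bins")
    A <- interactionMatrix(map)[retained, retained, drop = FALSE]
    n <- nrow(A)
    off <- abs(outer(seq_len(n), seq_len(n), "-"))
    expByOff <- vapply(0:(n - 1L), function(k) mean(A[off == k]),
                       numeric(1))
    E <- matrix(expByOff[off + 1L], n, n)
    OE <- ifelse(E > 0, A / E, 0)
    diag(OE) <- NA                          # self-contacts carry no signal
    C <- suppressWarnings(stats::cor(OE, use = "pairwise.complete.obs"))
    C[!is.finite(C)] <- 0
    if (all(abs(C[upper.tri(C)]) < 1e-12))
        stop("degenerate correlation matrix")
    eg <- eigen(C, symmetric = TRUE)
    v <- eg$vectors[, 1L]
    if (v[1L] < 0) v <- -v
    out <- rep(NA_real_, nBins(map))
    out[retained] <- v
    out
}
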