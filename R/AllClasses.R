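#' @import methods
#' @importFrom S4Vectors metadata metadata<-
#' @importFrom IRanges IRanges start end width
#' @importFrom stats median quantile cor dist rpois runif setNames sd
#' @importFrom utils head tail
NULL

#' Genomic binning of a chromosome
#'
#' A fixed-width binning of one chromosome: bin `i` (1-based) covers the
#' 0-based half-open genomic interval `[(i-1)*resolution, i*resolution)`.
#' Every contact map, domain set and 3D structure carries one of these so
#' that bead order, bin index and genomic coordinate stay in bijection.
#'
#' @slot chrom Chromosome label, e.g. `"chr21"`.
#' @slot resolution Bin width in bp (> 0).
#' @slot nBins Number of bins (>= 1).
#' @export
setClass("GenomicBinning",
    representation(chrom = "character", resolution = "integer",
                   nBins = "integer"))

setValidity("GenomicBinning", function(object) {
    msg <- NULL
    if (length(object@chrom) != 1L || is.na(object@chrom))
        msg <- c(msg, "'chrom' must be a single non-NA string")
    if (length(object@resolution) != 1L || is.na(object@resolution) ||
        object@resolution <= 0L)
        msg <- c(msg, "'resolution' must be a single positive integer")
    if (length(object@nBins) != 1L || is.na(object@nBins) ||
        object@nBins < 1L)
        msg <- c(msg, "'nBins' must be a single integer >= 1")
    if (is.null(msg)) TRUE else msg
})

#' Construct a GenomicBinning
#'
#' @param chrom Chromosome label.
#' @param resolution Bin width in bp.
#' @param nBins Number of bins.
#' @return A [GenomicBinning-class] object.
#' @examples
#' genomicBinning("chr21", 5000, 40)
#' @export
genomicBinning <- function(chrom, resolution, nBins) {
    new("GenomicBinning", chrom = as.character(chrom),
        resolution = as.integer(resolution), nBins = as.integer(nBins))
}

#' Sparse symmetric Hi-C contact map
#'
#' Stores the upper triangle (i <= j, 1-based bin indices) of a symmetric
#' matrix of interaction frequencies (IFs). Zero entries are absent; all
#' stored IFs are finite and > 0. Symmetry is a representation property:
#' querying (i, j) or (j, i) yields the same value.
#'
#' @slot binning A [GenomicBinning-class].
#' @slot i,j Integer bin indices with `i <= j`.
#' @slot ifreq Interaction frequencies, finite and positive.
#' @export
setClass("ContactMap", contains = "Annotated",
    representation(binning = "GenomicBinning", i = "integer",
                   j = "integer", ifreq = "numeric"))

setValidity("ContactMap", function(object) {
    msg <- NULL
    n <- object@binning@nBins
    if (length(object@i) != length(object@j) ||
        length(object@i) != length(object@ifreq))
        msg <- c(msg, "'i', 'j' and 'ifreq' must have equal length")
    if (length(object@i)) {
        if (any(object@i < 1L) || any(object@j > n) || any(object@i > object@j))
            msg <- c(msg, "need 1 <= i <= j <= nBins for every entry")
        if (any(!is.finite(object@ifreq)) || any(object@ifreq <= 0))
            msg <- c(msg, "all IFs must be finite and > 0")
        if (anyDuplicated(object@i + as.numeric(n) * (object@j - 1L)))
            msg <- c(msg, "duplicate (i, j) entries")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a ContactMap
#'
#' Entries are canonicalised: (i, j) pairs are mirrored into the upper
#' triangle, duplicates arising from an entry and its mirror are merged
#' (conflicting IF values raise an error), and non-finite or non-positive
#' IFs are dropped. Negative IFs are an error.
#'
#' @param binning A [GenomicBinning-class].
#' @param i,j 1-based bin indices.
#' @param ifreq Interaction frequencies.
#' @return A [ContactMap-class].
#' @examples
#' b <- genomicBinning("chr21", 5000, 4)
#' contactMap(b, c(1, 2), c(2, 3), c(3.0, 1.5))
#' @export
contactMap <- function(binning, i = integer(), j = integer(),
                       ifreq = numeric()) {
    i <- as.integer(i); j <- as.integer(j); ifreq <- as.numeric(ifreq)
    if (any(ifreq < 0, na.rm = TRUE))
        stop("negative interaction frequencies are invalid")
    keep <- is.finite(ifreq) & ifreq > 0
    i <- i[keep]; j <- j[keep]; ifreq <- ifreq[keep]
    swap <- i > j
    if (any(swap)) {
        tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
    }
    key <- paste(i, j)
    if (anyDuplicated(key)) {
        first <- match(key, key)
        conflict <- abs(ifreq - ifreq[first]) >
            1e-9 * pmax(abs(ifreq), abs(ifreq[first]))
        if (any(conflict))
            stop("conflicting IF values for mirrored entry (",
                 i[which(conflict)[1L]], ", ", j[which(conflict)[1L]], ")")
        keep <- !duplicated(key)
        i <- i[keep]; j <- j[keep]; ifreq <- ifreq[keep]
    }
    o <- order(i, j)
    new("ContactMap", binning = binning, i = i[o], j = j[o],
        ifreq = ifreq[o])
}

#' Ordered 3D bead coordinates over a genomic binning
#'
#' One bead per modeled bin; `bins` records which bins are present
#' (filtered bins are simply absent), `coords` holds their (x, y, z) in
#' genomic order. Units are arbitrary, as Hi-C constrains shape only up
#' to scale.
#'
#' @slot binning A [GenomicBinning-class].
#' @slot bins Sorted 1-based indices of modeled bins.
#' @slot coords Numeric matrix with one row per modeled bin, columns x, y, z.
#' @export
setClass("Structure3D", contains = "Annotated",
    representation(binning = "GenomicBinning", bins = "integer",
                   coords = "matrix"))

setValidity("Structure3D", function(object) {
    msg <- NULL
    if (ncol(object@coords) != 3L)
        msg <- c(msg, "'coords' must have 3 columns")
    if (nrow(object@coords) != length(object@bins))
        msg <- c(msg, "one coordinate row per modeled bin required")
    if (length(object@bins)) {
        if (is.unsorted(object@bins, strictly = TRUE))
            msg <- c(msg, "'bins' must be strictly increasing")
        if (object@bins[1L] < 1L ||
            object@bins[length(object@bins)] > object@binning@nBins)
            msg <- c(msg, "'bins' out of binning range")
        if (any(!is.finite(object@coords)))
            msg <- c(msg, "all coordinates must be finite")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a Structure3D
#'
#' @param binning A [GenomicBinning-class].
#' @param coords Numeric matrix (n x 3) of bead coordinates.
#' @param bins Modeled bin indices; defaults to `1:nrow(coords)`.
#' @return A [Structure3D-class].
#' @export
structure3D <- function(binning, coords, bins = seq_len(nrow(coords))) {
    coords <- as.matrix(coords)
    storage.mode(coords) <- "double"
    dimnames(coords) <- NULL
    new("Structure3D", binning = binning, bins = as.integer(bins),
        coords = coords)
}

#' Non-overlapping domain partition of a binning
#'
#' Ordered topologically-associating-domain (TAD) intervals, stored as
#' 1-based inclusive [IRanges::IRanges] in bin units. A valid DomainSet
#' is sorted, disjoint, and jointly covers all bins, so that every bin
#' belongs to exactly one domain.
#'
#' @slot binning A [GenomicBinning-class].
#' @slot ranges An [IRanges::IRanges] of domain extents in bin units.
#' @export
setClass("DomainSet",
    representation(binning = "GenomicBinning", ranges = "IRanges"))

setValidity("DomainSet", function(object) {
    msg <- NULL
    r <- object@ranges
    n <- object@binning@nBins
    if (length(r) == 0L) {
        msg <- c(msg, "at least one domain required")
    } else {
        s <- IRanges::start(r); e <- IRanges::end(r)
        if (any(e < s)) msg <- c(msg, "empty domain")
        if (is.unsorted(s, strictly = TRUE))
            msg <- c(msg, "domains must be sorted")
        if (s[1L] != 1L || e[length(r)] != n ||
            (length(r) > 1L && any(s[-1L] != e[-length(r)] + 1L)))
            msg <- c(msg, "domains must tile [1, nBins] without gap or overlap")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a DomainSet
#'
#' @param binning A [GenomicBinning-class].
#' @param starts,ends 1-based inclusive domain bounds in bin units, or
#'   pass an `IRanges` as `starts`.
#' @return A [DomainSet-class].
#' @examples
#' b <- genomicBinning("chr21", 5000, 40)
#' domainSet(b, c(1, 21), c(20, 40))
#' @export
domainSet <- function(binning, starts, ends = NULL) {
    r <- if (is(starts, "IRanges")) starts
         else IRanges::IRanges(start = as.integer(starts),
                               end = as.integer(ends))
    new("DomainSet", binning = binning, ranges = r)
}

#' Result of matrix balancing
#'
#' @slot map The balanced [ContactMap-class].
#' @slot biases Per-bin multiplicative biases (NA for bins excluded from
#'   balancing); balanced IF(i,j) = raw IF(i,j) * biases[i] * biases[j].
#' @slot converged Whether the tolerance was reached within `maxIter`.
#' @slot iterations Iterations used.
#' @export
setClass("BalanceResult",
    representation(map = "ContactMap", biases = "numeric",
                   converged = "logical", iterations = "integer"))

#' Scaling-ratio estimate between model resolutions
#'
#' For each pair of genomically adjacent domains with at least one
#' inter-domain contact: the estimated center-to-center distance in
#' high-resolution units, the distance of the corresponding beads in the
#' low-resolution scaffold, and their ratio. `medianRatio` is the scale
#' applied to the scaffold before assembly.
#'
#' @slot pairs data.frame with columns x, y, dxy, dLow, ratio.
#' @slot medianRatio Median of the ratios.
#' @export
setClass("ScalingEstimate",
    representation(pairs = "data.frame", medianRatio = "numeric"))

setValidity("ScalingEstimate", function(object) {
    p <- object@pairs
    if (!all(c("x", "y", "dxy", "dLow", "ratio") %in% names(p)))
        return("'pairs' must have columns x, y, dxy, dLow, ratio")
    if (nrow(p) && any(p$ratio <= 0)) return("ratios must be > 0")
    TRUE
})
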