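#' @describeIn GenomicBinning-class number of bins
#' @param x,object An object of the documented class.
#' @export
setMethod("length", "GenomicBinning", function(x) as.integer(x@nBins))

#' Accessor generics
#'
#' `binning()`, `chromName()`, `binResolution()`, `nBins()` expose the
#' binning of any binned object; `contacts()` returns a contact map's
#' entries as a data.frame; `coords()` and `modeledBins()` expose a
#' structure's coordinates; `domainRanges()` the domain intervals;
#' `balancedMap()` and `biasVector()` the parts of a balancing result.
#'
#' @param x Object to access.
#' @return The corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("binning", function(x) standardGeneric("binning"))
#' @rdname accessors
#' @export
setMethod("binning", "ContactMap", function(x) x@binning)
#' @rdname accessors
#' @export
setMethod("binning", "Structure3D", function(x) x@binning)
#' @rdname accessors
#' @export
setMethod("binning", "DomainSet", function(x) x@binning)

#' @rdname accessors
#' @export
chromName <- function(x) {
    if (is(x, "GenomicBinning")) x@chrom else binning(x)@chrom
}

#' @rdname accessors
#' @export
binResolution <- function(x) {
    if (is(x, "GenomicBinning")) x@resolution else binning(x)@resolution
}

#' @rdname accessors
#' @export
nBins <- function(x) {
    if (is(x, "GenomicBinning")) x@nBins else binning(x)@nBins
}

#' @rdname accessors
#' @export
setGeneric("contacts", function(x) standardGeneric("contacts"))
#' @rdname accessors
#' @export
setMethod("contacts", "ContactMap", function(x)
    data.frame(i = x@i, j = x@j, ifreq = x@ifreq))

#' @describeIn ContactMap-class number of stored entries
#' @export
setMethod("length", "ContactMap", function(x) length(x@ifreq))

#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setMethod("coords", "Structure3D", function(x) x@coords)

#' @rdname accessors
#' @export
modeledBins <- function(x) x@bins

#' @describeIn Structure3D-class number of beads
#' @export
setMethod("length", "Structure3D", function(x) nrow(x@coords))

#' @rdname accessors
#' @export
domainRanges <- function(x) x@ranges

#' @describeIn DomainSet-class number of domains
#' @export
setMethod("length", "DomainSet", function(x) length(x@ranges))

#' @rdname accessors
#' @export
balancedMap <- function(x) x@map

#' @rdname accessors
#' @export
biasVector <- function(x) x@biases

#' Map each bin to its domain index
#'
#' @param domains A [DomainSet-class].
#' @return Integer vector of length `nBins` giving the domain of each bin.
#' @export
domainOfBin <- function(domains) {
    r <- domainRanges(domains)
    rep.int(seq_along(r), IRanges::width(r))
}

#' Dense symmetric matrix of a contact map
#'
#' @param map A [ContactMap-class].
#' @param sparse If `TRUE`, return a `Matrix::dsCMatrix` instead.
#' @return A symmetric `nBins x nBins` matrix of IFs (zeros where absent).
#' @export
interactionMatrix <- function(map, sparse = FALSE) {
    n <- nBins(map)
    if (sparse)
        return(Matrix::sparseMatrix(i = map@i, j = map@j, x = map@ifreq,
                                    dims = c(n, n), symmetric = TRUE))
    m <- matrix(0, n, n)
    m[cbind(map@i, map@j)] <- map@ifreq
    m[cbind(map@j, map@i)] <- map@ifreq
    m
}

setMethod("show", "GenomicBinning", function(object) {
    cat("GenomicBinning:", object@chrom, "| resolution", object@resolution,
        "bp |", object@nBins, "bins\n")
})

setMethod("show", "ContactMap", function(object) {
    cat("ContactMap over ", object@binning@chrom, " (",
        object@binning@nBins, " bins @ ", object@binning@resolution,
        " bp): ", length(object@ifreq), " entries\n", sep = "")
})

setMethod("show", "Structure3D", function(object) {
    cat("Structure3D:", nrow(object@coords), "beads over",
        object@binning@nBins, "bins of", object@binning@chrom, "\n")
})

setMethod("show", "DomainSet", function(object) {
    w <- IRanges::width(object@ranges)
    cat("DomainSet:", length(object@ranges), "domains over",
        object@binning@nBins, "bins (widths", min(w), "-", max(w), ")\n")
})

setMethod("show", "BalanceResult", function(object) {
    cat("BalanceResult:", if (object@converged) "converged" else
        "NOT converged", "in", object@iterations, "iterations;",
        sum(is.na(object@biases)), "bins excluded\n")
})

setMethod("show", "ScalingEstimate", function(object) {
    cat("ScalingEstimate:", nrow(object@pairs),
        "adjacent-domain ratios; median", format(object@medianRatio), "\n")
})
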