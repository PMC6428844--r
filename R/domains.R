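#' Call domain boundaries from an insulation score
#'
#' For each candidate boundary (the junction before bin `b`) the score is
#' the mean IF of the `window x window` square of contacts crossing it,
#' i.e. bins `[b-window, b-1] x [b, b+window-1]`; junctions whose square
#' is truncated by a chromosome end are undefined (NA). Scores are
#' log2-normalised by the chromosome-wide mean score; boundaries are
#' local minima whose prominence (the smaller of the rises to the nearest
#' higher flanking local maxima) is at least `deltaThreshold`. A flat
#' minimum is reported at its leftmost bin.
#'
#' This is an insulation-profile caller in the TAD-calling tradition; it
#' stands in when no externally called domain BED is supplied.
#'
#' @param map A (balanced) [ContactMap-class].
#' @param window Window size in bins (>= 2); default 10.
#' @param deltaThreshold Minimum prominence of a boundary; default 0.1.
#' @return `list(boundaries = integer bin indices (first bin of the
#'   downstream domain), score = per-bin numeric vector with NA where
#'   undefined)`.
#' @export
insulationBoundaries <- function(map, window = 10L, deltaThreshold = 0.1) {
    n <- nBins(map)
    window <- as.integer(window)
    if (window < 2L) stop("'window' must be >= 2")
    if (window >= n / 2) stop("'window' too large for ", n, " bins")
    A <- interactionMatrix(map)
    score <- rep(NA_real_, n)
    for (b in seq.int(window + 1L, n - window + 1L))
        score[b] <- mean(A[(b - window):(b - 1L), b:(b + window - 1L)])
    mu <- mean(score, na.rm = TRUE)
    if (!is.finite(mu) || mu <= 0)
        return(list(boundaries = integer(), score = score))
    s <- log2(score / mu)
    s[is.infinite(s)] <- NA
    ok <- which(!is.na(s))
    v <- s[ok]
    if (length(v) < 3L)
        return(list(boundaries = integer(), score = s))
    # rise from v[k] to the nearest flanking local maximum on one side;
    # `idx` enumerates positions outward from the minimum
    rise <- function(k, idx) {
        if (length(idx) == 0L) return(0)
        for (t in idx) {
            prv <- if (t - 1L >= 1L) v[t - 1L] else -Inf
            nxt <- if (t + 1L <= length(v)) v[t + 1L] else -Inf
            if (v[t] >= prv && v[t] >= nxt)     # local maximum (or edge)
                return(v[t] - v[k])
        }
        max(v[idx]) - v[k]
    }
    boundaries <- integer()
    for (k in seq_along(v)) {
        if (k == 1L || k == length(v)) next     # edges are not minima
        if (v[k - 1L] <= v[k]) next             # not leftmost of a dip
        k2 <- k
        while (k2 < length(v) && v[k2 + 1L] == v[k]) k2 <- k2 + 1L
        if (k2 == length(v) || v[k2 + 1L] <= v[k]) next
        lrise <- rise(k, seq.int(k - 1L, 1L))
        rrise <- rise(k, seq.int(k2 + 1L, length(v)))
        if (min(lrise, rrise) >= deltaThreshold)
            boundaries <- c(boundaries, ok[k])
    }
    list(boundaries = boundaries, score = s)
}

#' Domains from a boundary list
#'
#' Consecutive boundaries (plus the chromosome ends) delimit domains;
#' any domain longer than `maxDomainBins` is split into equal pieces of
#' at most that many bins.
#'
#' @param boundaries Sorted bin indices; each is the first bin of the
#'   domain it opens.
#' @param binning A [GenomicBinning-class].
#' @param maxDomainBins Cap on domain length in bins; default 600.
#' @return A [DomainSet-class].
#' @export
domainsFromBoundaries <- function(boundaries, binning,
                                  maxDomainBins = 600L) {
    n <- binning@nBins
    boundaries <- as.integer(boundaries)
    stopifnot(!is.unsorted(boundaries), all(boundaries > 1L),
              all(boundaries <= n))
    cuts <- unique(c(1L, boundaries, n + 1L))
    starts <- integer(); ends <- integer()
    for (k in seq_len(length(cuts) - 1L)) {
        s <- cuts[k]; e <- cuts[k + 1L] - 1L
        len <- e - s + 1L
        if (len > maxDomainBins) {
            pieces <- ceiling(len / maxDomainBins)
            edges <- s + as.integer(round(seq(0, len, length.out =
                                              pieces + 1L)))
            starts <- c(starts, edges[-length(edges)])
            ends <- c(ends, edges[-1L] - 1L)
        } else {
            starts <- c(starts, s); ends <- c(ends, e)
        }
    }
    domainSet(binning, starts, ends)
}

#' Resolve nested domain calls into a flat partition
#'
#' When a called domain contains smaller domains inside it, only the
#' containing domain is kept (the inner ones are already represented by
#' it). Exact duplicates are collapsed; intervals that partially overlap
#' without nesting are an error. Gaps between the kept intervals and at
#' the chromosome ends become domains of their own, so the result always
#' partitions all bins.
#'
#' @param intervals An [IRanges::IRanges] of raw domain intervals in bin
#'   units (1-based inclusive), e.g. from [readDomainsBed()].
#' @param binning A [GenomicBinning-class].
#' @return A [DomainSet-class].
#' @export
resolveNested <- function(intervals, binning) {
    n <- binning@nBins
    r <- unique(intervals)
    if (length(r)) {
        ov <- IRanges::findOverlaps(r, r, type = "within")
        inner <- unique(S4Vectors::queryHits(ov)[
            S4Vectors::queryHits(ov) != S4Vectors::subjectHits(ov)])
        r <- r[setdiff(seq_along(r), inner)]
        r <- r[order(IRanges::start(r), IRanges::end(r))]
        if (length(r) > 1L) {
            s <- IRanges::start(r); e <- IRanges::end(r)
            bad <- which(s[-1L] <= e[-length(r)])
            if (length(bad))
                stop("partially overlapping non-nested domains [",
                     s[bad[1L]], ", ", e[bad[1L]], "] and [",
                     s[bad[1L] + 1L], ", ", e[bad[1L] + 1L], "]")
        }
    }
    # fill gaps
    s <- IRanges::start(r); e <- IRanges::end(r)
    starts <- integer(); ends <- integer()
    pos <- 1L
    for (k in seq_along(r)) {
        if (s[k] > pos) { starts <- c(starts, pos)
                          ends <- c(ends, s[k] - 1L) }
        starts <- c(starts, s[k]); ends <- c(ends, e[k])
        pos <- e[k] + 1L
    }
    if (pos <= n) { starts <- c(starts, pos); ends <- c(ends, n) }
    domainSet(binning, starts, ends)
}

#' Aggregate a contact map to domain level
#'
#' The IF between two distinct domains is the sum of all raw IFs between
#' their bins; the domain-level diagonal is omitted. The result is a
#' [ContactMap-class] with one "bin" (bead) per domain; total
#' inter-domain IF mass is conserved.
#'
#' @param map A [ContactMap-class].
#' @param domains A [DomainSet-class] over the same binning.
#' @return A domain-level [ContactMap-class] (its binning has one bin
#'   per domain; the bp resolution is nominal).
#' @export
aggregateDomainMatrix <- function(map, domains) {
    d <- domainOfBin(domains)
    di <- d[map@i]; dj <- d[map@j]
    keep <- di != dj
    nd <- length(domains)
    b <- genomicBinning(chromName(map), binResolution(map), nd)
    if (!any(keep)) return(contactMap(b))
    lo <- pmin(di[keep], dj[keep])
    hi <- pmax(di[keep], dj[keep])
    agg <- rowsum(map@ifreq[keep], paste(lo, hi))
    ij <- do.call(rbind, strsplit(rownames(agg), " ", fixed = TRUE))
    contactMap(b, as.integer(ij[, 1L]), as.integer(ij[, 2L]), agg[, 1L])
}
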