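#' Read a Hi-C contact map from text
#'
#' Supports the two plain-text layouts commonly used for intra-chromosomal
#' dumps: `"sparse3col"` rows of `start1 start2 IF` (whitespace separated,
#' positions are genomic starts in bp and must be divisible by
#' `resolution`), and `"dense"`, a square whitespace-separated symmetric
#' matrix. Mirrored duplicate entries are merged (an error if their IFs
#' conflict); zero and NaN entries are dropped.
#'
#' @param path File to read.
#' @param resolution Bin width in bp.
#' @param format `"sparse3col"` or `"dense"`.
#' @param chrom Chromosome label to attach (metadata only).
#' @param nBins Optional explicit bin count; default is
#'   `1 + max(observed bin index)` for sparse input, the matrix dimension
#'   for dense input.
#' @return A [ContactMap-class].
#' @export
readContactMap <- function(path, resolution,
                           format = c("sparse3col", "dense"),
                           chrom = "chr?", nBins = NULL) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("no such file: ", path)
    if (format == "dense") {
        m <- as.matrix(data.table::fread(path, header = FALSE))
        if (nrow(m) != ncol(m)) stop("dense matrix must be square")
        if (any(!is.na(m) & is.finite(m) &
                abs(m - t(m)) > 1e-9 * pmax(abs(m), abs(t(m)), 1e-300)))
            stop("dense matrix is not symmetric")
        if (any(m < 0, na.rm = TRUE))
            stop("negative interaction frequency in dense matrix")
        n <- if (is.null(nBins)) nrow(m) else as.integer(nBins)
        ut <- which(upper.tri(m, diag = TRUE) & is.finite(m) & m > 0,
                    arr.ind = TRUE)
        b <- genomicBinning(chrom, resolution, n)
        return(contactMap(b, ut[, 1L], ut[, 2L], m[ut]))
    }
    if (file.size(path) == 0L) {
        n <- if (is.null(nBins)) 1L else as.integer(nBins)
        return(contactMap(genomicBinning(chrom, resolution, n)))
    }
    dt <- tryCatch(
        data.table::fread(path, header = FALSE, fill = TRUE,
                          colClasses = "numeric"),
        error = function(e) stop("parse error reading ", path, ": ",
                                 conditionMessage(e)))
    if (ncol(dt) != 3L || anyNA(dt[[1L]]) || anyNA(dt[[2L]])) {
        bad <- which(!stats::complete.cases(dt[, 1:2]) |
                     rowSums(!is.na(dt)) != 3L)[1L]
        stop("malformed row at line ", if (is.na(bad)) "?" else bad,
             " of ", path, " (expected 'start1 start2 IF')")
    }
    s1 <- dt[[1L]]; s2 <- dt[[2L]]; ifreq <- dt[[3L]]
    if (any(s1 %% resolution != 0) || any(s2 %% resolution != 0)) {
        bad <- which(s1 %% resolution != 0 | s2 %% resolution != 0)[1L]
        stop("line ", bad, ": genomic start not divisible by resolution ",
             resolution)
    }
    if (any(ifreq < 0, na.rm = TRUE))
        stop("line ", which(ifreq < 0)[1L],
             ": negative interaction frequency")
    i <- s1 %/% resolution + 1L
    j <- s2 %/% resolution + 1L
    n <- if (is.null(nBins)) max(i, j) else as.integer(nBins)
    contactMap(genomicBinning(chrom, resolution, n), i, j, ifreq)
}

#' Write a contact map as sparse three-column text
#'
#' Rows are `start1 start2 IF` with genomic starts in bp; full precision,
#' so `readContactMap(writeContactMap(m))` reproduces `m` exactly.
#'
#' @param map A [ContactMap-class].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeContactMap <- function(map, path) {
    res <- binResolution(map)
    lines <- sprintf("%.0f %.0f %s", (map@i - 1) * as.numeric(res),
                     (map@j - 1) * as.numeric(res), .fmtNum(map@ifreq))
    writeLines(lines, path)
    invisible(path)
}

#' Read raw domain intervals from a BED file
#'
#' BED intervals (0-based half-open, bp) on the binning's chromosome are
#' converted to bin intervals with `startBin = floor(start/res)` and
#' `endBin = ceiling(end/res)` (returned as 1-based inclusive IRanges).
#' Rows for other chromosomes are skipped with a warning; intervals
#' beyond the chromosome extent are clipped with a warning. The result
#' may be nested or overlapping — pass it through [resolveNested()].
#'
#' @param path BED file.
#' @param binning A [GenomicBinning-class].
#' @return An [IRanges::IRanges] of raw domain intervals in bin units.
#' @export
readDomainsBed <- function(path, binning) {
    gr <- rtracklayer::import(path, format = "BED")
    keep <- as.character(GenomicRanges::seqnames(gr)) == binning@chrom
    if (any(!keep))
        warning(sum(!keep), " BED rows on other chromosomes skipped")
    gr <- gr[keep]
    if (length(gr) == 0L)
        return(IRanges::IRanges())
    # back to 0-based half-open bp
    s <- GenomicRanges::start(gr) - 1L
    e <- GenomicRanges::end(gr)
    if (any(e <= s)) stop("BED interval with end <= start")
    res <- binning@resolution
    sb <- s %/% res + 1L             # 1-based inclusive
    eb <- as.integer(ceiling(e / res))
    if (any(eb > binning@nBins)) {
        warning("BED intervals beyond chromosome extent clipped")
        eb <- pmin(eb, binning@nBins)
    }
    IRanges::IRanges(start = sb, end = eb)
}

#' Write domain intervals as BED
#'
#' @param domains A [DomainSet-class].
#' @param path Output BED file.
#' @return Invisibly, `path`.
#' @export
writeDomainsBed <- function(domains, path) {
    b <- binning(domains)
    r <- domainRanges(domains)
    res <- as.numeric(b@resolution)
    lines <- sprintf("%s\t%.0f\t%.0f", b@chrom,
                     (IRanges::start(r) - 1) * res, IRanges::end(r) * res)
    writeLines(lines, path)
    invisible(path)
}

#' Write a 3D structure to TSV and/or PDB
#'
#' The TSV (columns bead, chrom, binStart, x, y, z; `#`-comment header
#' recording the binning) is lossless: [readStructure()] reproduces the
#' structure exactly. The PDB rendering writes one CA ATOM per bead on
#' chain A (residue number = 1-based bead order, serial wrapping at
#' 99999) with coordinates uniformly rescaled so the maximum absolute
#' coordinate is 999.0, to fit the fixed columns.
#'
#' @param structure A [Structure3D-class].
#' @param prefix Output path prefix; `<prefix>.tsv` / `<prefix>.pdb`.
#' @param format Any subset of `c("tsv", "pdb")`.
#' @return Invisibly, the written paths.
#' @export
writeStructure <- function(structure, prefix, format = c("tsv", "pdb")) {
    format <- match.arg(format, several.ok = TRUE)
    b <- binning(structure)
    X <- coords(structure)
    paths <- character()
    if ("tsv" %in% format) {
        path <- paste0(prefix, ".tsv")
        hdr <- c(sprintf("# chrom=%s resolution=%d nBins=%d",
                         b@chrom, b@resolution, b@nBins),
                 "bead\tchrom\tbinStart\tx\ty\tz")
        body <- sprintf("%d\t%s\t%.0f\t%s\t%s\t%s",
                        seq_len(nrow(X)), b@chrom,
                        (structure@bins - 1) * as.numeric(b@resolution),
                        .fmtNum(X[, 1]), .fmtNum(X[, 2]), .fmtNum(X[, 3]))
        writeLines(c(hdr, body), path)
        paths <- c(paths, path)
    }
    if ("pdb" %in% format) {
        if (nrow(X) > 1e6)
            stop("more than 1e6 beads; PDB fixed columns cannot hold ",
                 "this many — write TSV instead")
        path <- paste0(prefix, ".pdb")
        mx <- max(abs(X))
        Xs <- if (mx > 0) X * (999.0 / mx) else X
        serial <- (seq_len(nrow(X)) - 1L) %% 99999L + 1L
        resseq <- (seq_len(nrow(X)) - 1L) %% 9999L + 1L
        lines <- sprintf(
            "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            serial, resseq, Xs[, 1], Xs[, 2], Xs[, 3])
        writeLines(c(lines, "END"), path)
        paths <- c(paths, path)
    }
    invisible(paths)
}

#' Read a 3D structure from TSV
#'
#' Reads the lossless TSV written by [writeStructure()]; bins absent
#' from the file are absent from the structure.
#'
#' @param path TSV file.
#' @return A [Structure3D-class].
#' @export
readStructure <- function(path) {
    lines <- readLines(path)
    hdr <- lines[startsWith(lines, "#")][1L]
    if (is.na(hdr)) stop("missing binning header in ", path)
    m <- regmatches(hdr, regexec(
        "chrom=(\\S+) resolution=(\\d+) nBins=(\\d+)", hdr))[[1L]]
    if (length(m) != 4L) stop("malformed binning header in ", path)
    b <- genomicBinning(m[2L], as.integer(m[3L]), as.integer(m[4L]))
    body <- lines[!startsWith(lines, "#")]
    body <- body[-1L]                      # column header
    if (length(body) == 0L)
        return(structure3D(b, matrix(numeric(), 0, 3), integer()))
    f <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(f) != 6L))
        stop("malformed row ", which(lengths(f) != 6L)[1L], " in ", path)
    f <- do.call(rbind, f)
    xyz <- suppressWarnings(matrix(as.numeric(f[, 4:6]), ncol = 3))
    starts <- suppressWarnings(as.numeric(f[, 3L]))
    if (anyNA(xyz) || anyNA(starts))
        stop("non-numeric coordinate in ", path)
    bins <- as.integer(starts %/% b@resolution + 1)
    structure3D(b, xyz, bins)
}
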