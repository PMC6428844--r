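#' Convert an interaction frequency to an expected distance
#'
#' The expected spatial distance between two bins is `IF^(-alpha)`,
#' i.e. `1 / IF^alpha`: the more frequently two loci interact, the
#' closer they are expected to be, with the conversion exponent `alpha`
#' controlling how steeply distance falls with contact frequency.
#'
#' @param ifreq Interaction frequency (> 0); vectorised.
#' @param alpha Conversion exponent.
#' @return Expected distance(s).
#' @examples
#' expectedDistance(4, 0.5)  # 0.5
#' @export
expectedDistance <- function(ifreq, alpha) {
    if (any(ifreq <= 0)) stop("interaction frequency must be > 0")
    ifreq^(-alpha)
}

#' Grid search for the conversion exponent
#'
#' For each alpha on the grid (default 0.1 to 3.0 in steps of 0.1) a
#' model is reconstructed from the map's expected distances and scored
#' by the Spearman correlation between realized model distances and the
#' expected distances over the observed contacts. The best-scoring alpha
#' is returned; ties go to the smaller alpha.
#'
#' Because the rank target is the same for every alpha (all expected
#' distances are monotone transforms of each other), the score differs
#' across the grid only through how well the expected distances at that
#' alpha can actually be realized in 3D — at the data-generating alpha a
#' perfect embedding exists, away from it the geometry is frustrated.
#' Discrimination therefore requires comparable convergence quality at
#' every grid point: each candidate model is initialized from a
#' classical-MDS (spectral) embedding of the expected-distance matrix
#' (shortest-path completed where contacts are missing) and polished by
#' gradient ascent with a reduced iteration budget
#' (`config$maxIter / gridIterDiv`). The search is fully deterministic,
#' so the score table is reproducible.
#'
#' @param map A non-empty [ContactMap-class] (typically balanced).
#' @param config An [optimizerConfig()].
#' @param grid Candidate alphas.
#' @param gridIterDiv Iteration-budget divisor during the search;
#'   default 5.
#' @return `list(alpha = best alpha, table = data.frame(alpha, score))`.
#' @export
searchAlpha <- function(map, config = optimizerConfig(),
                        grid = seq(0.1, 3.0, by = 0.1),
                        gridIterDiv = 5) {
    if (length(map) == 0L) stop("empty contact map")
    if (max(map@ifreq) - min(map@ifreq) <=
        1e-12 * max(abs(map@ifreq)))
        stop("degenerate matrix: all interaction frequencies equal")
    cfgGrid <- config
    cfgGrid$maxIter <- max(1L, as.integer(ceiling(config$maxIter /
                                                  gridIterDiv)))
    score <- vapply(grid, function(a) {
        rs <- buildRestraints(map, a, cfgGrid,
                              bins = .retainedBins(map))
        nb <- length(attr(rs, "bins"))
        fit <- optimizeStructure(rs, nBeads = nb, config = cfgGrid,
                                 init = .mdsInit(rs, nb))
        obs <- !rs$adjacency
        d <- .pairDist(coords(fit$structure), rs$i[obs], rs$j[obs])
        stats::cor(d, rs$delta[obs], method = "spearman")
    }, numeric(1))
    best <- which.max(score)
    list(alpha = grid[best],
         table = data.frame(alpha = grid, score = score))
}

#' Consensus conversion exponent across domains
#'
#' The median of the per-domain exponents (mean of the central pair for
#' an even count), used as the single exponent at which all domain
#' models are rebuilt so their distance units agree.
#'
#' @param alphas Numeric vector of per-domain exponents.
#' @return The median.
#' @examples
#' consensusAlpha(c(0.7, 0.9, 1.3))  # 0.9
#' @export
consensusAlpha <- function(alphas) {
    alphas <- alphas[!is.na(alphas)]
    if (length(alphas) == 0L) stop("no conversion exponents supplied")
    stats::median(alphas)
}
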