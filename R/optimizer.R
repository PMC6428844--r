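#' Optimizer configuration
#'
#' Hyper-parameters of the Lorentzian distance-geometry engine. The
#' objective is non-convex, so the adaptive-step gradient ascent below
#' is a local optimizer; the seed fixes the random initialization and
#' makes every run reproducible.
#'
#' @param maxIter Maximum iterations (proposals); default 2000.
#' @param tol Relative-improvement stopping threshold; default 1e-6.
#' @param gammaFrac Lorentzian half-width as a fraction of the median
#'   expected distance; default 0.3.
#' @param adjacencyWeight Weight of chain-connectivity restraints added
#'   between consecutive beads that share no contact; default 0.5.
#' @param seed RNG seed for the initialization; default 13.
#' @param initRadiusScale Initial coordinates are drawn uniformly in a
#'   sphere of radius `initRadiusScale * median(delta) * nBeads^(1/3)`.
#' @param stepInit Initial step length; `NA` (default) means
#'   `0.01 * median(delta)`.
#' @param stepUp,stepDown Step multipliers on an accepted / rejected
#'   proposal; defaults 1.1 and 0.5 (must satisfy
#'   `stepUp > 1 > stepDown > 0`).
#' @param annealStages Number of graduated non-convexity stages: the
#'   Lorentzian width starts at `annealStart * gamma` and is tightened
#'   geometrically to `gamma` over this many ascent stages, each seeded
#'   from the previous stage's result. 1 disables annealing. Default 4.
#' @param annealStart Starting width multiplier for annealing;
#'   default 10.
#' @return A validated list of class `"OptimizerConfig"`.
#' @export
optimizerConfig <- function(maxIter = 2000L, tol = 1e-6, gammaFrac = 0.3,
                            adjacencyWeight = 0.5, seed = 13L,
                            initRadiusScale = 1.0, stepInit = NA_real_,
                            stepUp = 1.1, stepDown = 0.5,
                            annealStages = 4L, annealStart = 10) {
    stopifnot(maxIter >= 1, gammaFrac > 0, tol >= 0,
              stepUp > 1, stepDown > 0, stepDown < 1,
              adjacencyWeight >= 0, initRadiusScale > 0,
              annealStages >= 1, annealStart >= 1)
    structure(list(maxIter = as.integer(maxIter), tol = tol,
                   gammaFrac = gammaFrac,
                   adjacencyWeight = adjacencyWeight,
                   seed = as.integer(seed),
                   initRadiusScale = initRadiusScale,
                   stepInit = stepInit, stepUp = stepUp,
                   stepDown = stepDown,
                   annealStages = as.integer(annealStages),
                   annealStart = annealStart),
              class = "OptimizerConfig")
}

#' Build distance restraints from a contact map
#'
#' One restraint per off-diagonal contact: expected distance
#' `delta = IF^(-alpha)` and weight `IF / max(IF)`, so high-frequency
#' (reliable) contacts dominate the objective. For consecutive beads
#' that share no contact, a chain-adjacency restraint is added with
#' `delta` equal to the median expected distance of observed
#' consecutive-bead contacts (median over all contacts, with a warning,
#' if there are none) and weight `config$adjacencyWeight`.
#'
#' Restraints are expressed in bead space: bead `k` is the k-th modeled
#' (retained) bin; the mapping is carried in the `"bins"` and
#' `"binning"` attributes.
#'
#' @param map A non-empty [ContactMap-class].
#' @param alpha Conversion exponent.
#' @param config An [optimizerConfig()].
#' @param bins Bead universe: the global bin indices to model. Defaults
#'   to every bin of the map's binning (one bead per bin); pass the
#'   retained-bin set after [filterSparseBins()] to exclude filtered
#'   bins. Contacts outside the universe are dropped, and adjacency
#'   restraints span every consecutive bead pair of the universe.
#' @return A data.frame with columns `i`, `j`, `delta`, `weight`,
#'   `adjacency`, plus attributes `bins` and `binning`.
#' @export
buildRestraints <- function(map, alpha, config = optimizerConfig(),
                            bins = NULL) {
    off <- map@i != map@j
    if (!any(off)) stop("no off-diagonal contacts to restrain")
    if (is.null(bins)) bins <- seq_len(nBins(map))
    bi <- match(map@i[off], bins)
    bj <- match(map@j[off], bins)
    keep <- !is.na(bi) & !is.na(bj)
    bi <- bi[keep]; bj <- bj[keep]
    if (length(bi) == 0L) stop("no contacts within the bead universe")
    delta <- expectedDistance(map@ifreq[off][keep], alpha)
    weight <- map@ifreq[off][keep] / max(map@ifreq[off][keep])
    consec <- abs(bi - bj) == 1L
    have <- logical(length(bins) - 1L)
    have[pmin(bi, bj)[consec]] <- TRUE
    adjDelta <- if (any(consec)) stats::median(delta[consec]) else {
        warning("no consecutive-bead contacts; using median expected ",
                "distance of all contacts for chain adjacency")
        stats::median(delta)
    }
    miss <- which(!have)
    rs <- data.frame(
        i = c(bi, miss), j = c(bj, miss + 1L),
        delta = c(delta, rep(adjDelta, length(miss))),
        weight = c(weight, rep(config$adjacencyWeight, length(miss))),
        adjacency = c(rep(FALSE, length(bi)), rep(TRUE, length(miss))))
    attr(rs, "bins") <- bins
    attr(rs, "binning") <- binning(map)
    rs
}

#' Lorentzian restraint-satisfaction objective
#'
#' `F = sum_r w_r * gamma^2 / (gamma^2 + (||x_i - x_j|| - delta_r)^2)`.
#' Each restraint contributes at most its weight (attained exactly when
#' realized and expected distance agree), and an unsatisfiable restraint
#' has bounded influence — the Cauchy-kernel property that lets noisy
#' contacts coexist with reliable ones.
#'
#' @param coords A [Structure3D-class] or an `n x 3` matrix.
#' @param restraints A restraint data.frame from [buildRestraints()].
#' @param gamma Lorentzian half-width (> 0).
#' @return The scalar objective, in `(0, sum(weights)]`.
#' @export
restraintObjective <- function(coords, restraints, gamma) {
    stopifnot(gamma > 0)
    X <- if (is(coords, "Structure3D")) coords(coords) else coords
    d <- .pairDist(X, restraints$i, restraints$j)
    err <- d - restraints$delta
    sum(restraints$weight * gamma^2 / (gamma^2 + err^2))
}

#' Analytic gradient of the Lorentzian objective
#'
#' Partial derivatives of [restraintObjective()] with respect to every
#' bead coordinate. For a pair at exactly coincident positions the
#' direction term is undefined and is set to zero (a subgradient
#' choice).
#'
#' @inheritParams restraintObjective
#' @return An `n x 3` matrix of gradients (for ascent).
#' @export
restraintGradient <- function(coords, restraints, gamma) {
    stopifnot(gamma > 0)
    X <- if (is(coords, "Structure3D")) coords(coords) else coords
    n <- nrow(X)
    ri <- restraints$i; rj <- restraints$j
    U <- X[ri, , drop = FALSE] - X[rj, , drop = FALSE]
    d <- sqrt(rowSums(U^2))
    err <- d - restraints$delta
    g2 <- gamma^2
    dFdd <- -2 * restraints$weight * g2 * err / (g2 + err^2)^2
    coef <- ifelse(d > 0, dFdd / d, 0)
    P <- U * coef
    idx <- c(ri, rj)
    V <- rbind(P, -P)
    G <- matrix(0, n, 3)
    acc <- rowsum(V, idx)
    G[as.integer(rownames(acc)), ] <- acc
    G
}

# monotone adaptive-step ascent at a fixed gamma: propose a move of at
# most `step` (gradient scaled so the fastest bead travels `step`);
# accept improvements (step *= stepUp), reject otherwise (step *=
# stepDown); stop at the proposal budget, when `patience` consecutive
# proposals fail to improve by tol relative, or when step underflows
.ascend <- function(X, restraints, gamma, step, maxIter, tol, stepUp,
                    stepDown, scale, patience = 30L) {
    fval <- restraintObjective(X, restraints, gamma)
    if (!is.finite(fval)) stop("objective is not finite at initialization")
    trace <- fval
    stall <- 0L
    it <- 0L
    converged <- FALSE
    while (it < maxIter) {
        it <- it + 1L
        G <- restraintGradient(X, restraints, gamma)
        gmax <- max(sqrt(rowSums(G^2)))
        if (gmax == 0) { converged <- TRUE; break }
        Xn <- X + (step / gmax) * G
        Fn <- restraintObjective(Xn, restraints, gamma)
        if (is.na(Fn))
            stop("objective became NaN at iteration ", it,
                 " (step ", format(step), ")")
        if (Fn > fval) {
            stall <- if ((Fn - fval) / abs(fval) < tol) stall + 1L else 0L
            X <- Xn
            fval <- Fn
            trace <- c(trace, fval)
            step <- step * stepUp
        } else {
            stall <- stall + 1L
            step <- step * stepDown
        }
        if (stall >= patience || step < 1e-14 * scale) {
            converged <- TRUE
            break
        }
    }
    list(X = X, objective = fval, trace = trace, iterations = it,
         converged = converged)
}

#' Gradient ascent on the Lorentzian objective
#'
#' Adaptive-step gradient ascent with graduated non-convexity: the
#' Lorentzian width is annealed from `annealStart * gamma` down to
#' `gamma` over `annealStages` geometric stages, each stage running a
#' monotone ascent (improving proposals accepted, step length adapted
#' up/down) initialized at the previous stage's result. The wide kernel
#' smooths away local optima early on; the final stage scores at the
#' target width. If an explicit `init` is supplied and annealing ends
#' below its objective at the target width, a direct single-stage
#' ascent from `init` is used instead, so the result never falls below
#' the supplied starting point.
#'
#' The default initialization is uniform in a sphere of radius
#' `initRadiusScale * median(delta) * nBeads^(1/3)`, drawn under
#' `config$seed`, so identical inputs give bit-identical results.
#'
#' @param restraints A restraint data.frame from [buildRestraints()]
#'   (or any data.frame with columns `i`, `j`, `delta`, `weight`).
#' @param nBeads Number of beads; defaults to the restraints' bead count.
#' @param config An [optimizerConfig()].
#' @param init Optional initial coordinates ([Structure3D-class] or
#'   matrix).
#' @return `list(structure, objective, trace, converged, gamma)`.
#' @export
optimizeStructure <- function(restraints, nBeads = NULL,
                              config = optimizerConfig(), init = NULL) {
    if (nrow(restraints) == 0L) stop("no restraints")
    bins <- attr(restraints, "bins")
    if (is.null(nBeads))
        nBeads <- if (!is.null(bins)) length(bins) else
            max(restraints$i, restraints$j)
    stopifnot(max(restraints$i, restraints$j) <= nBeads)
    bng <- attr(restraints, "binning")
    if (is.null(bng)) bng <- genomicBinning("beads", 1L, nBeads)
    if (is.null(bins)) bins <- seq_len(nBeads)
    medDelta <- stats::median(restraints$delta)
    gamma <- config$gammaFrac * medDelta
    X <- if (is.null(init)) {
        R <- config$initRadiusScale * medDelta * nBeads^(1 / 3)
        .withSeed(config$seed, {
            u <- matrix(stats::rnorm(nBeads * 3), nBeads, 3)
            u <- u / sqrt(rowSums(u^2))
            u * (R * stats::runif(nBeads)^(1 / 3))
        })
    } else if (is(init, "Structure3D")) coords(init) else as.matrix(init)
    stopifnot(nrow(X) == nBeads)
    step0 <- if (is.na(config$stepInit)) 0.01 * medDelta else
        config$stepInit
    nStage <- config$annealStages
    gammas <- if (nStage == 1L) gamma else
        gamma * config$annealStart^(seq(1, 0, length.out = nStage))
    budget <- rep(config$maxIter %/% nStage, nStage)
    budget[nStage] <- config$maxIter - sum(budget[-nStage])
    Xcur <- X
    res <- NULL
    for (stg in seq_len(nStage)) {
        res <- .ascend(Xcur, restraints, gammas[stg], step0, budget[stg],
                       config$tol, config$stepUp, config$stepDown,
                       scale = medDelta)
        Xcur <- res$X
    }
    if (!is.null(init)) {
        f0 <- restraintObjective(X, restraints, gamma)
        if (res$objective < f0 || nStage > 1L) {
            direct <- NULL
            if (res$objective < f0)
                direct <- .ascend(X, restraints, gamma, step0,
                                  config$maxIter, config$tol,
                                  config$stepUp, config$stepDown,
                                  scale = medDelta)
            if (!is.null(direct) && direct$objective > res$objective)
                res <- direct
        }
    }
    list(structure = structure3D(bng, res$X, bins),
         objective = res$objective, trace = res$trace,
         converged = res$converged, gamma = gamma)
}
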