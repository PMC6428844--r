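# Steps 2-7 of the hierarchical pipeline: low-resolution scaffold,
# per-domain models, scaling-ratio estimation, substitution, refinement.

# optimize from both the seeded random-sphere init and the
# deterministic classical-MDS init, keep the better objective
.bestFit <- function(rs, config) {
    nb <- length(attr(rs, "bins"))
    fitR <- optimizeStructure(rs, config = config)
    fitM <- optimizeStructure(rs, config = config,
                              init = .mdsInit(rs, nb))
    if (fitM$objective > fitR$objective) fitM else fitR
}

# extract the intra-domain sub-map of one domain as a local ContactMap
# (bin 1 = first bin of the domain)
.domainSubmap <- function(map, startBin, endBin) {
    keep <- map@i >= startBin & map@i <= endBin &
            map@j >= startBin & map@j <= endBin
    b <- genomicBinning(chromName(map), binResolution(map),
                        endBin - startBin + 1L)
    contactMap(b, map@i[keep] - startBin + 1L,
               map@j[keep] - startBin + 1L, map@ifreq[keep])
}

#' Low-resolution whole-chromosome scaffold
#'
#' ICE-balances the domain-level matrix, grid-searches the conversion
#' exponent, and optimizes one bead per domain at the chosen exponent
#' with the full iteration budget. If the matrix is degenerate for the
#' grid search (all IFs equal, so every exponent fits equally), the
#' exponent defaults to 1.
#'
#' @param domainMap Domain-level [ContactMap-class] from
#'   [aggregateDomainMatrix()]; needs >= 2 domains and >= 1 entry.
#' @param config An [optimizerConfig()].
#' @param tol,maxIter Balancing controls (see [iceBalance()]).
#' @return A [Structure3D-class] (bins = domain indices) with
#'   `metadata()` fields `alpha`, `alphaTable`, `objective`.
#' @export
buildLowresModel <- function(domainMap, config = optimizerConfig(),
                             tol = 1e-6, maxIter = 1000L) {
    if (length(domainMap) == 0L)
        stop("empty domain-level map: no inter-domain contacts")
    if (nBins(domainMap) < 2L) stop("need >= 2 domains")
    bal <- iceBalance(domainMap, tol = tol, maxIter = maxIter)
    sa <- tryCatch(searchAlpha(balancedMap(bal), config),
                   error = function(e) {
                       if (grepl("degenerate", conditionMessage(e)))
                           list(alpha = 1.0, table = NULL)
                       else stop(e)
                   })
    rs <- buildRestraints(balancedMap(bal), sa$alpha, config)
    fit <- .bestFit(rs, config)
    s <- fit$structure
    metadata(s) <- list(alpha = sa$alpha, alphaTable = sa$table,
                        objective = fit$objective)
    s
}

#' High-resolution models of each domain
#'
#' For every domain: extract its intra-domain sub-matrix, drop sparse
#' bins, KR-balance, and grid-search a per-domain conversion exponent
#' with a reduced iteration budget. The consensus exponent is the
#' median over domains, and every domain model is then rebuilt at the
#' consensus with the full budget, so all domain models share distance
#' units. Degenerate cases are handled gracefully: a single-bin domain
#' becomes one bead at the origin, and a domain with no usable contacts
#' becomes a straight segment with unit spacing (with a warning).
#'
#' @param map High-resolution [ContactMap-class].
#' @param domains A [DomainSet-class].
#' @param config An [optimizerConfig()] (domain `k` uses `seed + k`).
#' @param minNonzeroFrac Sparse-bin filter fraction within each domain.
#' @param tol,maxIter KR balancing controls.
#' @return `list(models = list of Structure3D (global bins), alphas =
#'   per-domain exponents (NA where inapplicable), consensusAlpha,
#'   alphaTables, removedBins = global indices of filtered bins)`.
#' @export
buildDomainModels <- function(map, domains, config = optimizerConfig(),
                              minNonzeroFrac = 0.02, tol = 1e-6,
                              maxIter = 1000L) {
    r <- domainRanges(domains)
    nd <- length(r)
    fullBinning <- binning(map)
    alphas <- rep(NA_real_, nd)
    tables <- vector("list", nd)
    balmaps <- vector("list", nd)   # balanced sub-maps, reused at rebuild
    removed <- integer()
    for (k in seq_len(nd)) {
        s <- IRanges::start(r)[k]; e <- IRanges::end(r)[k]
        if (e == s) next                       # single-bin domain
        sub <- .domainSubmap(map, s, e)
        if (length(sub) == 0L || all(sub@i == sub@j)) next
        flt <- tryCatch(filterSparseBins(sub, minNonzeroFrac),
                        error = function(err) NULL)
        if (is.null(flt) || length(flt$map) == 0L ||
            all(flt$map@i == flt$map@j)) next
        removed <- c(removed, flt$removed + s - 1L)
        bal <- krBalance(flt$map, tol = tol, maxIter = maxIter)
        balmaps[[k]] <- balancedMap(bal)
        cfg <- config; cfg$seed <- config$seed + k
        sa <- tryCatch(searchAlpha(balmaps[[k]], cfg),
                       error = function(err) NULL)
        if (!is.null(sa)) { alphas[k] <- sa$alpha; tables[[k]] <- sa$table }
    }
    consensus <- if (all(is.na(alphas))) {
        warning("no domain admitted an exponent grid search; ",
                "using conversion exponent 1")
        1.0
    } else consensusAlpha(alphas)
    models <- vector("list", nd)
    for (k in seq_len(nd)) {
        s <- IRanges::start(r)[k]; e <- IRanges::end(r)[k]
        width <- e - s + 1L
        if (is.null(balmaps[[k]])) {
            if (width > 1L)
                warning("domain ", k, " has no usable intra-domain ",
                        "contacts; modeled as a straight segment")
            X <- cbind(seq_len(width) - 1, 0, 0)
            models[[k]] <- structure3D(fullBinning, X, s:e)
            next
        }
        cfg <- config; cfg$seed <- config$seed + k
        rs <- buildRestraints(balmaps[[k]], consensus, cfg,
                              bins = .retainedBins(balmaps[[k]]))
        fit <- .bestFit(rs, cfg)
        loc <- fit$structure
        models[[k]] <- structure3D(fullBinning, coords(loc),
                                   modeledBins(loc) + s - 1L)
        metadata(models[[k]]) <- list(objective = fit$objective)
    }
    list(models = models, alphas = alphas, consensusAlpha = consensus,
         alphaTables = tables, removedBins = sort(removed))
}

#' Estimated center-to-center distance of two adjacent domain models
#'
#' Uses the triangle-inequality estimator
#' `d_xy = min over all inter-domain contacts (i, j) of
#' (d_ij + d_xi + d_yj)`, where `d_ij = IF_ij^(-alpha)` is the expected
#' distance of the contact, and `d_xi`, `d_yj` are the distances from
#' each domain's centroid (coordinate mean) to the contacting bead in
#' its own model. The true center distance never exceeds any candidate
#' sum, and with enough contacts the minimum approximates it tightly.
#'
#' @param modelX,modelY [Structure3D-class] models of the two domains.
#' @param inter data.frame with columns `i`, `j`, `ifreq`: inter-domain
#'   contacts, `i` indexing beads (rows) of `modelX`, `j` of `modelY`.
#' @param alpha Conversion exponent.
#' @return The estimate, or `NA_real_` when `inter` is empty (no
#'   estimate possible).
#' @export
estimateCenterDistance <- function(modelX, modelY, inter, alpha) {
    if (is.null(inter) || nrow(inter) == 0L) return(NA_real_)
    Xx <- coords(modelX); Xy <- coords(modelY)
    cx <- colMeans(Xx); cy <- colMeans(Xy)
    dxi <- sqrt(colSums((t(Xx[inter$i, , drop = FALSE]) - cx)^2))
    dyj <- sqrt(colSums((t(Xy[inter$j, , drop = FALSE]) - cy)^2))
    dij <- expectedDistance(inter$ifreq, alpha)
    min(dij + dxi + dyj)
}

#' Scaling ratio between high- and low-resolution models
#'
#' For each pair of genomically adjacent domains with at least one
#' inter-domain contact, the estimated center distance
#' ([estimateCenterDistance()]) is divided by the distance of the
#' corresponding beads in the low-resolution scaffold; with `n` domains
#' this yields up to `n - 1` ratios, and their median is the factor by
#' which the scaffold is rescaled before assembly. By default the
#' inter-domain IFs entering `d_ij` are taken from a KR-balanced
#' sub-matrix spanning the two domains, matching the units in which the
#' domain models were built; `balance = "none"` uses raw IFs (for
#' ground-truth models in raw units).
#'
#' @param domainModels List of per-domain [Structure3D-class] models
#'   (global bins), as from [buildDomainModels()].
#' @param lowRes Low-resolution [Structure3D-class] (bins = domain
#'   indices).
#' @param map High-resolution [ContactMap-class].
#' @param domains A [DomainSet-class].
#' @param alpha Consensus conversion exponent.
#' @param balance `"kr"` (default) or `"none"`.
#' @param tol,maxIter KR controls when `balance = "kr"`.
#' @return A [ScalingEstimate-class].
#' @export
estimateScalingRatio <- function(domainModels, lowRes, map, domains,
                                 alpha, balance = c("kr", "none"),
                                 tol = 1e-6, maxIter = 1000L) {
    balance <- match.arg(balance)
    r <- domainRanges(domains)
    nd <- length(r)
    if (nd < 2L) stop("need >= 2 domains to estimate a scale")
    lowBins <- modeledBins(lowRes)
    rows <- list()
    for (k in seq_len(nd - 1L)) {
        lx <- match(k, lowBins); ly <- match(k + 1L, lowBins)
        if (is.na(lx) || is.na(ly)) next
        sx <- IRanges::start(r)[k]; ex <- IRanges::end(r)[k]
        sy <- IRanges::start(r)[k + 1L]; ey <- IRanges::end(r)[k + 1L]
        pair <- .domainSubmap(map, sx, ey)
        if (balance == "kr" && length(pair) > 0L) {
            pair <- tryCatch(
                balancedMap(krBalance(pair, tol = tol,
                                      maxIter = maxIter)),
                warning = function(w) suppressWarnings(
                    balancedMap(krBalance(pair, tol = tol,
                                          maxIter = maxIter))),
                error = function(e) pair)
        }
        gi <- pair@i + sx - 1L; gj <- pair@j + sx - 1L
        sel <- gi <= ex & gj >= sy
        bi <- match(gi[sel], modeledBins(domainModels[[k]]))
        bj <- match(gj[sel], modeledBins(domainModels[[k + 1L]]))
        ok <- !is.na(bi) & !is.na(bj)
        inter <- data.frame(i = bi[ok], j = bj[ok],
                            ifreq = pair@ifreq[sel][ok])
        dxy <- estimateCenterDistance(domainModels[[k]],
                                      domainModels[[k + 1L]], inter,
                                      alpha)
        if (is.na(dxy)) next
        dLow <- sqrt(sum((coords(lowRes)[lx, ] -
                          coords(lowRes)[ly, ])^2))
        if (dLow <= 0) next
        rows[[length(rows) + 1L]] <-
            data.frame(x = k, y = k + 1L, dxy = dxy, dLow = dLow,
                       ratio = dxy / dLow)
    }
    if (length(rows) == 0L)
        stop("cannot estimate scale: no adjacent domain pair has ",
             "inter-domain contacts")
    pairs <- do.call(rbind, rows)
    new("ScalingEstimate", pairs = pairs,
        medianRatio = stats::median(pairs$ratio))
}

#' Uniformly rescale a structure
#'
#' @param s A [Structure3D-class].
#' @param ratio Positive scale factor; pairwise distances scale exactly
#'   by `ratio`.
#' @return The rescaled [Structure3D-class].
#' @export
scaleStructure <- function(s, ratio) {
    if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0)
        stop("'ratio' must be a single positive number")
    structure3D(binning(s), coords(s) * ratio, modeledBins(s))
}

#' Substitute domain models into the scaled scaffold
#'
#' Each domain model is translated so its centroid lands exactly on the
#' corresponding scaffold bead; orientation is unchanged (identity
#' rotation) unless `rotate = TRUE`, which applies a seeded random
#' rotation per domain (for robustness experiments). Beads are
#' concatenated in genomic order. Intra-domain pairwise distances are
#' preserved exactly (translation/rotation only).
#'
#' @param lowResScaled Scaled low-resolution [Structure3D-class]; must
#'   model one bead per domain.
#' @param domainModels List of per-domain [Structure3D-class] models.
#' @param domains A [DomainSet-class].
#' @param rotate Apply seeded random rotations to domain models.
#' @param seed Seed for the rotations.
#' @return The assembled [Structure3D-class] over the full binning.
#' @export
assembleStructure <- function(lowResScaled, domainModels, domains,
                              rotate = FALSE, seed = 13L) {
    nd <- length(domains)
    if (length(domainModels) != nd)
        stop("number of domain models (", length(domainModels),
             ") does not match number of domains (", nd, ")")
    lowBins <- modeledBins(lowResScaled)
    if (!all(seq_len(nd) %in% lowBins))
        stop("low-resolution model is missing beads for some domains")
    rots <- if (rotate) .withSeed(seed, lapply(seq_len(nd), function(k) {
        M <- matrix(stats::rnorm(9), 3, 3)
        q <- qr(M)
        Q <- qr.Q(q)
        if (det(Q) < 0) Q[, 1] <- -Q[, 1]
        Q
    })) else NULL
    allBins <- integer(); allX <- NULL
    for (k in seq_len(nd)) {
        m <- domainModels[[k]]
        X <- coords(m)
        if (!is.null(rots)) X <- X %*% rots[[k]]
        target <- coords(lowResScaled)[match(k, lowBins), ]
        X <- sweep(X, 2, colMeans(X) - target)
        allBins <- c(allBins, modeledBins(m))
        allX <- rbind(allX, X)
    }
    structure3D(binning(domainModels[[1L]]), allX, allBins)
}

#' Objective restricted to intra- or inter-domain restraints
#'
#' Builds the full restraint set of `map` at `alpha` over the
#' structure's beads and evaluates the Lorentzian objective on all
#' restraints or on the inter-/intra-domain subset. Used to verify that
#' refinement improves the satisfaction of inter-domain contacts.
#'
#' @param s A [Structure3D-class].
#' @param map A [ContactMap-class].
#' @param alpha Conversion exponent.
#' @param domains A [DomainSet-class].
#' @param config An [optimizerConfig()].
#' @param which `"all"`, `"inter"` or `"intra"`.
#' @return The objective value on the selected restraints.
#' @export
domainRestraintObjective <- function(s, map, alpha, domains,
                                     config = optimizerConfig(),
                                     which = c("all", "inter", "intra")) {
    which <- match.arg(which)
    rs <- buildRestraints(map, alpha, config, bins = modeledBins(s))
    gamma <- config$gammaFrac * stats::median(rs$delta)
    if (which != "all") {
        d <- domainOfBin(domains)
        gb <- attr(rs, "bins")
        inter <- d[gb[rs$i]] != d[gb[rs$j]]
        rs <- rs[if (which == "inter") inter else !inter, , drop = FALSE]
    }
    restraintObjective(coords(s), rs, gamma)
}

#' Refine an assembled model against all contacts
#'
#' Re-optimizes the whole structure, initialized at `initial`, using
#' every contact (intra- and inter-domain) at the consensus exponent.
#' Because the assembled model inherits its scale from the balanced
#' per-domain matrices while whole-map restraints are in raw-IF units,
#' refinement first line-searches a global scale factor for the initial
#' model (the candidate set always includes 1, and ties keep 1) and
#' then runs gradient ascent; the returned model's objective is
#' therefore never below the initial model's. Intra-domain contacts,
#' already well satisfied, are mostly preserved; the ascent mainly
#' satisfies additional inter-domain contacts.
#'
#' @param initial Assembled [Structure3D-class].
#' @param map High-resolution [ContactMap-class].
#' @param alpha Consensus conversion exponent.
#' @param config An [optimizerConfig()].
#' @return The refined [Structure3D-class]; `metadata()` carries
#'   `objective`, `initialObjective`, `scaleApplied`, `trace`.
#' @export
refineStructure <- function(initial, map, alpha,
                            config = optimizerConfig()) {
    rs <- buildRestraints(map, alpha, config, bins = modeledBins(initial))
    gamma <- config$gammaFrac * stats::median(rs$delta)
    X0 <- coords(initial)
    f0 <- restraintObjective(X0, rs, gamma)
    d0 <- stats::median(.pairDist(X0, rs$i, rs$j))
    s0 <- if (d0 > 0) stats::median(rs$delta) / d0 else 1
    cand <- unique(c(1, s0 * 2^seq(-2, 2, by = 0.25)))
    fs <- vapply(cand, function(s)
        restraintObjective(X0 * s, rs, gamma), numeric(1))
    best <- cand[which.max(fs)]
    if (max(fs) <= f0) best <- 1
    fit <- optimizeStructure(rs, config = config, init = X0 * best)
    out <- structure3D(binning(initial), coords(fit$structure),
                       modeledBins(initial))
    metadata(out) <- list(objective = fit$objective,
                          initialObjective = f0, scaleApplied = best,
                          trace = fit$trace)
    out
}

#' Run the full hierarchical reconstruction
#'
#' Executes the seven pipeline steps in order: (1) obtain a domain
#' partition (supplied, or called from the insulation profile of the
#' ICE-balanced map), (2) aggregate to a domain-level matrix, ICE-balance
#' and build the low-resolution scaffold, (3-4) KR-balance each domain's
#' sub-matrix and build per-domain models with a consensus conversion
#' exponent, (5) estimate the scaling ratio and rescale the scaffold,
#' (6) substitute domain models at their scaffold positions, and
#' (7) refine the assembled model against all contacts.
#'
#' @param map High-resolution [ContactMap-class].
#' @param domains Domain source: a [DomainSet-class], an `IRanges` of
#'   raw (possibly nested) intervals, a BED file path, or `NULL` to call
#'   domains from the insulation profile.
#' @param config An [optimizerConfig()].
#' @param window,deltaThreshold,maxDomainBins Insulation-caller controls
#'   (used when `domains` is `NULL`).
#' @param minNonzeroFrac Per-domain sparse-bin filter fraction.
#' @param rotateDomains Randomly rotate domain models at substitution.
#' @return `list(structure = refined Structure3D, report = list(domains,
#'   alphas, consensusAlpha, lowresAlpha, scaling, objectives,
#'   removedBins))`.
#' @export
runHierarchical <- function(map, domains = NULL,
                            config = optimizerConfig(), window = 10L,
                            deltaThreshold = 0.1, maxDomainBins = 600L,
                            minNonzeroFrac = 0.02,
                            rotateDomains = FALSE) {
    bng <- binning(map)
    if (is.null(domains)) {
        flt <- filterSparseBins(map, minNonzeroFrac)
        bal <- iceBalance(flt$map)
        ib <- insulationBoundaries(balancedMap(bal), window,
                                   deltaThreshold)
        domains <- domainsFromBoundaries(ib$boundaries, bng,
                                         maxDomainBins)
    } else if (is.character(domains)) {
        domains <- resolveNested(readDomainsBed(domains, bng), bng)
    } else if (is(domains, "IRanges")) {
        domains <- resolveNested(domains, bng)
    }
    stopifnot(is(domains, "DomainSet"))
    dm <- buildDomainModels(map, domains, config,
                            minNonzeroFrac = minNonzeroFrac)
    if (length(domains) == 1L) {
        # degenerate: single domain, no scaffold or scaling needed
        refined <- refineStructure(dm$models[[1L]], map,
                                   dm$consensusAlpha, config)
        report <- list(domains = domains, alphas = dm$alphas,
                       consensusAlpha = dm$consensusAlpha,
                       lowresAlpha = NA_real_, scaling = NULL,
                       objectives = metadata(refined)["objective"],
                       removedBins = dm$removedBins)
        return(list(structure = refined, report = report))
    }
    domainMap <- aggregateDomainMatrix(map, domains)
    lowRes <- buildLowresModel(domainMap, config)
    scaling <- estimateScalingRatio(dm$models, lowRes, map, domains,
                                    dm$consensusAlpha, balance = "kr")
    scaffold <- scaleStructure(lowRes, scaling@medianRatio)
    assembled <- assembleStructure(scaffold, dm$models, domains,
                                   rotate = rotateDomains,
                                   seed = config$seed + 1000L)
    refined <- refineStructure(assembled, map, dm$consensusAlpha, config)
    objectives <- list(
        assembledTotal = domainRestraintObjective(
            assembled, map, dm$consensusAlpha, domains, config, "all"),
        assembledInter = domainRestraintObjective(
            assembled, map, dm$consensusAlpha, domains, config, "inter"),
        refinedTotal = domainRestraintObjective(
            refined, map, dm$consensusAlpha, domains, config, "all"),
        refinedInter = domainRestraintObjective(
            refined, map, dm$consensusAlpha, domains, config, "inter"))
    report <- list(domains = domains, alphas = dm$alphas,
                   consensusAlpha = dm$consensusAlpha,
                   lowresAlpha = metadata(lowRes)$alpha,
                   lowresModel = lowRes, assembled = assembled,
                   scaling = scaling, objectives = objectives,
                   removedBins = dm$removedBins)
    list(structure = refined, report = report)
}
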