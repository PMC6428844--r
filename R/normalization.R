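#' Drop bins too sparse to balance
#'
#' Matrix balancing diverges on empty or nearly-empty rows, so bins with
#' fewer off-diagonal contact partners than `minNonzeroFrac * nBins` (or
#' with no entries at all) are excluded: every entry touching them is
#' removed, indices are preserved, and the removed set is returned so
#' downstream stages can mark those bins missing.
#'
#' @param map A [ContactMap-class].
#' @param minNonzeroFrac Fraction in `[0, 1]`; default 0.02.
#' @return `list(map = filtered ContactMap, removed = integer bin indices)`.
#' @export
filterSparseBins <- function(map, minNonzeroFrac = 0.02) {
    stopifnot(minNonzeroFrac >= 0, minNonzeroFrac <= 1)
    n <- nBins(map)
    off <- map@i != map@j
    offCount <- tabulate(map@i[off], n) + tabulate(map@j[off], n)
    total <- tabulate(map@i, n) + tabulate(map@j, n)
    removed <- which(offCount < minNonzeroFrac * n | total == 0L)
    if (length(removed) == n)
        stop("matrix too sparse: all bins removed")
    keep <- !(map@i %in% removed) & !(map@j %in% removed)
    list(map = contactMap(binning(map), map@i[keep], map@j[keep],
                          map@ifreq[keep]),
         removed = removed)
}

# bins participating in balancing: those with at least one entry
.retainedBins <- function(map) sort(unique(c(map@i, map@j)))

# Knight-Ruiz inner-outer Newton/CG iteration on a dense symmetric
# irreducible matrix; returns list(x, converged, iterations) with
# diag(x) A diag(x) having unit row sums (L2 residual <= tol).
.krCore <- function(A, tol, maxIter) {
    n <- nrow(A)
    e <- rep(1, n)
    x <- e
    delta <- 0.1; Delta <- 3
    g <- 0.9; etamax <- 0.1; eta <- etamax
    stopTol <- tol * 0.5
    rt <- tol^2
    v <- x * (A %*% x)[, 1L]
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rho_km2 <- rho_km1
    rout <- rho_km1; rold <- rout
    iter <- 0L
    while (rout > rt && iter < maxIter) {
        iter <- iter + 1L
        k <- 0L; y <- e
        innertol <- max(eta^2 * rout, rt)
        Z <- p <- NULL
        while (rho_km1 > innertol && k < 50L * n) {
            k <- k + 1L
            if (k == 1L) {
                Z <- rk / v; p <- Z
                rho_km1 <- sum(rk * Z)
            } else {
                beta <- rho_km1 / rho_km2
                p <- Z + beta * p
            }
            w <- x * (A %*% (x * p))[, 1L] + v * p
            alpha <- rho_km1 / sum(p * w)
            ap <- alpha * p
            ynew <- y + ap
            if (min(ynew) <= delta) {
                ind <- ap < 0
                gamma <- min((delta - y[ind]) / ap[ind])
                y <- y + gamma * ap
                break
            }
            if (max(ynew) >= Delta) {
                ind <- ynew > Delta
                gamma <- min((Delta - y[ind]) / ap[ind])
                y <- y + gamma * ap
                break
            }
            y <- ynew
            rk <- rk - alpha * w
            rho_km2 <- rho_km1
            Z <- rk / v
            rho_km1 <- sum(rk * Z)
        }
        x <- x * y
        v <- x * (A %*% x)[, 1L]
        rk <- 1 - v
        rho_km1 <- sum(rk * rk)
        rout <- rho_km1
        rat <- rout / rold; rold <- rout
        etaO <- eta
        eta <- g * rat
        if (g * etaO^2 > 0.1) eta <- max(eta, g * etaO^2)
        eta <- max(min(eta, etamax), stopTol / sqrt(rout))
    }
    list(x = x, converged = rout <= rt, iterations = iter)
}

.applyBiases <- function(map, biases) {
    contactMap(binning(map), map@i, map@j,
               map@ifreq * biases[map@i] * biases[map@j])
}

#' Knight-Ruiz matrix balancing
#'
#' Finds the symmetric diagonal scaling `diag(b) A diag(b)` with unit
#' row sums on the retained bins, via the Knight-Ruiz inner-outer
#' Newton iteration. Used for the per-domain high-resolution matrices.
#' A reducible matrix (disconnected contact graph) is balanced one
#' connected component at a time, with a warning.
#'
#' @param map A filtered, symmetric non-negative [ContactMap-class]
#'   (see [filterSparseBins()]).
#' @param tol Convergence tolerance on row sums (relative); default 1e-6.
#' @param maxIter Maximum outer iterations; default 1000.
#' @return A [BalanceResult-class]; `converged = FALSE` flags hitting
#'   `maxIter`.
#' @export
krBalance <- function(map, tol = 1e-6, maxIter = 1000L) {
    if (length(map) == 0L) stop("empty contact map")
    retained <- .retainedBins(map)
    comps <- .components(map@i, map@j, retained)
    if (length(comps) > 1L)
        warning("contact matrix is reducible; balancing ",
                length(comps), " components separately")
    biases <- rep(NA_real_, nBins(map))
    converged <- TRUE
    iterations <- 0L
    A <- interactionMatrix(map)
    for (comp in comps) {
        res <- .krCore(A[comp, comp, drop = FALSE], tol, maxIter)
        biases[comp] <- res$x
        converged <- converged && res$converged
        iterations <- max(iterations, res$iterations)
    }
    bal <- .applyBiases(map, ifelse(is.na(biases), 0, biases))
    new("BalanceResult", map = bal, biases = biases,
        converged = converged, iterations = as.integer(iterations))
}

#' ICE matrix balancing (iterative correction)
#'
#' Alternates dividing each IF by the row biases `b_i = rowSum_i /
#' mean(rowSums)` until the largest relative deviation of the retained
#' row sums from their mean is below `tol`. The balanced matrix is
#' rescaled so its mean off-diagonal IF equals that of the input,
#' keeping the magnitude scale interpretable. Used for the domain-level
#' low-resolution matrix.
#'
#' @inheritParams krBalance
#' @return A [BalanceResult-class].
#' @export
iceBalance <- function(map, tol = 1e-6, maxIter = 1000L) {
    if (length(map) == 0L) stop("empty contact map")
    retained <- .retainedBins(map)
    A <- interactionMatrix(map)[retained, retained, drop = FALSE]
    rs <- rowSums(A)
    if (any(rs == 0))
        stop("retained bin with empty row; filter sparse bins first")
    biases <- rep(1, length(retained))
    converged <- FALSE
    iter <- 0L
    while (iter < maxIter) {
        rs <- rowSums(A)
        if (max(abs(rs / mean(rs) - 1)) <= tol) { converged <- TRUE; break }
        iter <- iter + 1L
        b <- rs / mean(rs)
        A <- A / outer(b, b)
        biases <- biases / b
    }
    # preserve the input's mean off-diagonal IF
    off <- map@i != map@j
    if (any(off)) {
        li <- match(map@i[off], retained); lj <- match(map@j[off], retained)
        sc <- mean(map@ifreq[off]) / mean(A[cbind(li, lj)])
        biases <- biases * sqrt(sc)
    }
    full <- rep(NA_real_, nBins(map))
    full[retained] <- biases
    bal <- .applyBiases(map, ifelse(is.na(full), 0, full))
    new("BalanceResult", map = bal, biases = full,
        converged = converged, iterations = iter)
}
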