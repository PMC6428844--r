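# internal helpers

# run code under a temporary RNG state (restores caller's RNG)
.withSeed <- function(seed, code) {
    withr::with_seed(as.integer(seed %% 2147483647L), code)
}

# full-precision text rendering of doubles (round-trips exactly)
.fmtNum <- function(x) sprintf("%.17g", x)

# connected components of a symmetric sparsity pattern restricted to
# `nodes`; returns a list of integer vectors (node indices)
.components <- function(i, j, nodes) {
    idx <- match(nodes, nodes)
    adj <- vector("list", length(nodes))
    ii <- match(i, nodes); jj <- match(j, nodes)
    keep <- !is.na(ii) & !is.na(jj)
    ii <- ii[keep]; jj <- jj[keep]
    for (k in seq_along(ii)) {
        adj[[ii[k]]] <- c(adj[[ii[k]]], jj[k])
        adj[[jj[k]]] <- c(adj[[jj[k]]], ii[k])
    }
    seen <- logical(length(nodes))
    comps <- list()
    for (s in seq_along(nodes)) {
        if (seen[s]) next
        stack <- s; seen[s] <- TRUE; comp <- integer()
        while (length(stack)) {
            v <- stack[length(stack)]; stack <- stack[-length(stack)]
            comp <- c(comp, v)
            for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE
                stack <- c(stack, w) }
        }
        comps[[length(comps) + 1L]] <- sort(nodes[comp])
    }
    comps
}

# classical-MDS (spectral) embedding of a restraint set's expected
# distances; missing pairs are completed by graph shortest paths
# (Floyd-Warshall on the restraint graph). Deterministic.
.mdsInit <- function(restraints, nBeads) {
    D <- matrix(Inf, nBeads, nBeads)
    diag(D) <- 0
    idx <- cbind(restraints$i, restraints$j)
    D[idx] <- restraints$delta
    D[idx[, 2:1, drop = FALSE]] <- restraints$delta
    if (any(is.infinite(D)))
        for (k in seq_len(nBeads))
            D <- pmin(D, outer(D[, k], D[k, ], "+"))
    mx <- max(D[is.finite(D)])
    D[is.infinite(D)] <- 1.5 * mx      # disconnected components
    if (nBeads == 1L) return(matrix(0, 1, 3))
    X <- suppressWarnings(stats::cmdscale(D, k = min(3L, nBeads - 1L)))
    if (ncol(X) < 3L)
        X <- cbind(X, matrix(0, nBeads, 3L - ncol(X)))
    X
}

# Euclidean distances between rows of a and rows of b (paired)
.rowDist <- function(a, b) sqrt(rowSums((a - b)^2))

# distances for contact pairs (i, j) of a structure whose beads are rows
# of `X` indexed by position
.pairDist <- function(X, i, j) {
    sqrt((X[i, 1] - X[j, 1])^2 + (X[i, 2] - X[j, 2])^2 +
         (X[i, 3] - X[j, 3])^2)
}
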