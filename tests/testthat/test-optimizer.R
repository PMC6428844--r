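test_that("restraints carry power-law distances and IF-normalized weights", {
    b <- genomicBinning("c", 1000L, 3L)
    m <- contactMap(b, c(1, 2), c(2, 3), c(4, 1))
    rs <- buildRestraints(m, 0.5)
    obs <- rs[!rs$adjacency, ]
    expect_equal(obs$delta, c(0.5, 1.0))
    expect_equal(obs$weight, c(1.0, 0.25))
    expect_equal(nrow(rs), 2L)              # no adjacency gaps to fill

    # contact only between beads 1 and 3: both consecutive pairs get
    # adjacency restraints
    m2 <- contactMap(b, 1, 3, 2)
    expect_warning(rs2 <- buildRestraints(m2, 1), "adjacency")
    expect_equal(sum(rs2$adjacency), 2L)
    expect_equal(rs2$weight[rs2$adjacency], rep(0.5, 2))

    expect_error(buildRestraints(contactMap(b, 1, 1, 5), 1),
                 "off-diagonal")
})

test_that("the Lorentzian objective attains its bound exactly at satisfaction", {
    # unit regular tetrahedron, all expected distances 1
    X <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(6) / 3))
    ut <- which(upper.tri(diag(4)), arr.ind = TRUE)
    rs <- data.frame(i = ut[, 1], j = ut[, 2], delta = 1, weight = 1,
                     adjacency = FALSE)
    expect_equal(restraintObjective(X, rs, gamma = 0.3), 6,
                 tolerance = 1e-12)

    # one restraint missed by exactly gamma scores half its weight
    rs1 <- data.frame(i = 1, j = 2, delta = 1, weight = 2,
                      adjacency = FALSE)
    X1 <- rbind(c(0, 0, 0), c(1.3, 0, 0))
    expect_equal(restraintObjective(X1, rs1, gamma = 0.3), 1)
})

test_that("the analytic gradient matches central finite differences", {
    set.seed(42)
    for (rep in 1:5) {
        n <- 10L
        X <- matrix(rnorm(n * 3), n, 3)
        ut <- which(upper.tri(diag(n)), arr.ind = TRUE)
        sel <- sample(nrow(ut), 25)
        rs <- data.frame(i = ut[sel, 1], j = ut[sel, 2],
                         delta = runif(25, 0.5, 2),
                         weight = runif(25), adjacency = FALSE)
        G <- restraintGradient(X, rs, 0.4)
        h <- 1e-6
        FD <- matrix(0, n, 3)
        for (b in seq_len(n)) for (c in 1:3) {
            Xp <- X; Xp[b, c] <- Xp[b, c] + h
            Xm <- X; Xm[b, c] <- Xm[b, c] - h
            FD[b, c] <- (restraintObjective(Xp, rs, 0.4) -
                         restraintObjective(Xm, rs, 0.4)) / (2 * h)
        }
        expect_lt(max(abs(G - FD)) / max(abs(G)), 1e-5)
    }
})

test_that("gradient vanishes at an optimum and pulls distant beads together", {
    X <- rbind(c(0, 0, 0), c(1, 0, 0))
    rs <- data.frame(i = 1, j = 2, delta = 1, weight = 1,
                     adjacency = FALSE)
    expect_equal(restraintGradient(X, rs, 0.3),
                 matrix(0, 2, 3))
    Xfar <- rbind(c(0, 0, 0), c(2, 0, 0))
    G <- restraintGradient(Xfar, rs, 0.3)
    expect_gt(G[1, 1], 0)                   # bead 1 pulled toward +x
    expect_lt(G[2, 1], 0)

    # coincident beads: direction zeroed
    Xco <- rbind(c(0, 0, 0), c(0, 0, 0))
    expect_equal(restraintGradient(Xco, rs, 0.3), matrix(0, 2, 3))
})

test_that("objective is invariant under rigid motion", {
    pc <- pointCloudRestraints(8, seed = 14)
    set.seed(15)
    M <- matrix(rnorm(9), 3, 3)
    Q <- qr.Q(qr(M))
    f0 <- restraintObjective(pc$points, pc$restraints, 0.5)
    f1 <- restraintObjective(
        sweep(pc$points %*% Q, 2, c(3, -1, 2), "+"), pc$restraints, 0.5)
    expect_equal(f1, f0, tolerance = 1e-9)
})

test_that("small consistent instances are embedded essentially exactly", {
    # collinear triple
    rs <- data.frame(i = c(1, 2, 1), j = c(2, 3, 3),
                     delta = c(1, 1, 2), weight = 1, adjacency = FALSE)
    fit <- optimizeStructure(rs, nBeads = 3)
    d <- .pairDistOracle(coords(fit$structure), rs$i, rs$j)
    expect_true(all(abs(d - rs$delta) < 1e-2))
    expect_gte(fit$objective, 2.99)

    # regular tetrahedron
    ut <- which(upper.tri(diag(4)), arr.ind = TRUE)
    rs4 <- data.frame(i = ut[, 1], j = ut[, 2], delta = 1, weight = 1,
                      adjacency = FALSE)
    fit4 <- optimizeStructure(rs4, nBeads = 4)
    d4 <- .pairDistOracle(coords(fit4$structure), rs4$i, rs4$j)
    expect_true(all(abs(d4 - 1) < 1e-2))
})

test_that("optimization is deterministic and its trace non-decreasing", {
    pc <- pointCloudRestraints(12, seed = 21)
    fit1 <- optimizeStructure(pc$restraints, nBeads = 12,
                              config = optimizerConfig(maxIter = 400L))
    fit2 <- optimizeStructure(pc$restraints, nBeads = 12,
                              config = optimizerConfig(maxIter = 400L))
    expect_identical(fit1$trace, fit2$trace)
    expect_identical(coords(fit1$structure), coords(fit2$structure))
    expect_true(all(diff(fit1$trace) >= 0))
})

test_that("complete noise-free restraints are recovered to high accuracy", {
    pc <- pointCloudRestraints(15, seed = 33)
    fit <- optimizeStructure(pc$restraints, nBeads = 15)
    d <- .pairDistOracle(coords(fit$structure), pc$restraints$i,
                         pc$restraints$j)
    expect_gte(spearmanOracle(d, pc$restraints$delta), 0.99)
})
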