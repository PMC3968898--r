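test_that("replication fidelity is the fidelity power of sequence length", {
    u <- defaultUnits(1)
    expect_equal(replicationFidelity(diploidKaryotype(defaultUnits(23)),
        replicationKernel(0)), 1)
    expect_equal(replicationFidelity(100, replicationKernel(0.01)),
        0.99^100)
    expect_equal(replicationFidelity(karyotype(5L, u),
        replicationKernel(1)), 0)
    # monotone in E and in c_m
    E <- seq(0, 0.5, by = 0.05)
    fid <- vapply(E, function(e) replicationFidelity(46,
        replicationKernel(e)), numeric(1))
    expect_true(all(diff(fid) <= 0))
    fidC <- vapply(c(1, 10, 46, 100), function(cc)
        replicationFidelity(cc, replicationKernel(0.02)), numeric(1))
    expect_true(all(diff(fidC) <= 0))
})

test_that("copy event distribution is a probability vector", {
    expect_equal(unname(copyEventDistribution(replicationKernel(0))),
        c(1, 0, 0))
    expect_equal(unname(copyEventDistribution(replicationKernel(0.1, 0.5))),
        c(0.9, 0.05, 0.05))
    for (E in c(0, 0.3, 1)) for (g in c(0, 0.4, 1))
        expect_equal(sum(copyEventDistribution(replicationKernel(E, g))), 1)
})

test_that("single transitions match hand-enumerated per-copy assignments", {
    u <- defaultUnits(1)
    k <- replicationKernel(0.1, 0.5)
    expect_equal(karyotypeTransitionProbability(karyotype(2L, u),
        karyotype(3L, u), k), 2 * 0.05 * 0.9)
    expect_equal(karyotypeTransitionProbability(karyotype(1L, u),
        karyotype(0L, u), k), 0.05)
    # no error, different child: impossible
    expect_equal(karyotypeTransitionProbability(karyotype(2L, u),
        karyotype(3L, u), replicationKernel(0)), 0)
})

test_that("transition kernel matches the brute-force outcome enumeration", {
    # n_units <= 2, copies <= 3: exhaustive per-copy assignment oracle
    for (parentCopies in list(c(1L), c(3L), c(2L, 1L), c(3L, 3L),
            c(0L, 2L))) {
        nu <- length(parentCopies)
        units <- defaultUnits(nu)
        E <- 0.13; g <- 0.35
        kern <- replicationKernel(E, g)
        maxChild <- 2L * max(parentCopies, 1L)
        childGrid <- as.matrix(expand.grid(
            replicate(nu, 0:maxChild, simplify = FALSE)))
        for (i in seq_len(nrow(childGrid))) {
            child <- as.integer(childGrid[i, ])
            expect_equal(
                karyotypeTransitionProbability(
                    karyotype(parentCopies, units),
                    karyotype(child, units), kern),
                bruteTransitionProb(parentCopies, child, E, g),
                tolerance = 1e-12)
        }
    }
})

test_that("transition matrix is sub-stochastic with exact escape mass", {
    sp <- enumerateKaryotypeSpace(defaultUnits(2), 4)
    Q <- buildTransitionMatrix(sp, replicationKernel(0.1, 0.5))
    expect_true(all(Q >= 0 & Q <= 1))
    cs <- colSums(Q)
    expect_true(all(cs <= 1 + 1e-12))
    expect_equal(unname(1 - cs), unname(attr(Q, "escapeMass")),
        tolerance = 1e-12)
    # columns whose children cannot escape are exactly stochastic
    noEscape <- apply(states(sp), 1, function(v) all(2 * v <= 4))
    expect_equal(unname(cs[noEscape]), rep(1, sum(noEscape)),
        tolerance = 1e-12)
    # E = 0 gives the identity
    Q0 <- buildTransitionMatrix(sp, replicationKernel(0))
    expect_equal(unclass(Q0), diag(nrow(states(sp))), ignore_attr = TRUE)
})

test_that("no-error path probability equals Q_mm exactly for 1-copy units", {
    # with one copy per unit there is no cancelling path, so the diagonal
    # transition equals the error-free fidelity A-bar^c exactly
    sp <- enumerateKaryotypeSpace(defaultUnits(2), 3)
    kern <- replicationKernel(0.07, 0.6)
    Q <- buildTransitionMatrix(sp, kern)
    ones <- stateIndex(sp, c(1L, 1L))
    expect_equal(Q[ones, ones], replicationFidelity(2, kern),
        tolerance = 1e-15)
    # with multiple copies cancellations can only increase the diagonal
    dip <- stateIndex(sp, c(2L, 2L))
    expect_gte(Q[dip, dip], replicationFidelity(4, kern))
})
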