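test_that("value matrix combines growth, fidelity and death", {
    # 2-state toy: W[1,1] = 4 * 0.5 = 2, W[2,1] = 4 * 0.4 = 1.6
    Q <- matrix(c(0.5, 0.4, 0, 1), 2, 2)
    f <- new("FitnessAssignment", A = c(4, 1), D = c(0, 0))
    W <- buildValueMatrix(f, Q)
    expect_equal(W[1, 1], 2)
    expect_equal(W[2, 1], 1.6)
    # E = 0, D = 0: W = diag(A)
    f2 <- new("FitnessAssignment", A = c(4, 1), D = c(0, 0))
    expect_equal(buildValueMatrix(f2, diag(2)), diag(c(4, 1)))
    # diagonal = A_k Q_kk - D_k
    f3 <- new("FitnessAssignment", A = c(4, 1), D = c(0.3, 0.7))
    W3 <- buildValueMatrix(f3, Q)
    expect_equal(diag(W3), c(4 * 0.5 - 0.3, 1 * 1 - 0.7))
    expect_error(buildValueMatrix(f3, diag(3)), "conformable")
})

test_that("stationary distribution is the Perron eigenvector", {
    # single peak, no error: delta mass on the master
    sp <- enumerateKaryotypeSpace(defaultUnits(2), 3)
    master <- karyotype(c(2L, 2L), defaultUnits(2))
    f <- singlePeakLandscape(sp, master, 5, 1, lethalOnNullisomy = FALSE)
    W0 <- buildValueMatrix(f, unclass(buildTransitionMatrix(sp,
        replicationKernel(0))))
    x0 <- frequencies(stationaryDistribution(W0))
    expect_equal(x0[stateIndex(sp, master)], 1)
    # agrees with an independent power-iteration oracle on a mutated system
    W <- buildValueMatrix(f, unclass(buildTransitionMatrix(sp,
        replicationKernel(0.08, 0.5))))
    expect_equal(frequencies(stationaryDistribution(W)),
        powerIterationStationary(W), tolerance = 1e-8)
})

test_that("integrator conserves the simplex and finds the fixed point", {
    set.seed(202)
    inst <- randomSmallInstance()
    n <- nrow(states(inst$space))
    x0 <- populationState(rep(1 / n, n))
    sol <- integrateReplicatorMutator(inst$W, x0, tEnd = 400, nOut = 20)
    expect_true(all(abs(rowSums(sol$trajectory) - 1) <= 1e-8))
    expect_lt(sol$residual, 1e-6)
    # starting at the stationary point stays there
    xs <- stationaryDistribution(inst$W)
    sol2 <- integrateReplicatorMutator(inst$W, xs, tEnd = 10, nOut = 5)
    expect_equal(frequencies(sol2$final), frequencies(xs),
        tolerance = 1e-7)
    # competitive exclusion: E = 0, D = 0 drives the master to fixation
    sp <- inst$space
    f <- singlePeakLandscape(sp, inst$master, 5, 1,
        lethalOnNullisomy = FALSE)
    W0 <- buildValueMatrix(f, unclass(buildTransitionMatrix(sp,
        replicationKernel(0))))
    sol3 <- integrateReplicatorMutator(W0, x0, tEnd = 50, nOut = 5)
    expect_equal(frequencies(sol3$final)[stateIndex(sp, inst$master)], 1,
        tolerance = 1e-5)
})

test_that("eigen and ODE stationary states agree on random instances", {
    set.seed(7)
    for (r in 1:12) {
        inst <- randomSmallInstance()
        n <- nrow(states(inst$space))
        xs <- frequencies(stationaryDistribution(inst$W))
        xt <- frequencies(integrateReplicatorMutator(inst$W,
            populationState(rep(1 / n, n)), tEnd = 1000, nOut = 4)$final)
        expect_lt(0.5 * sum(abs(xs - xt)), 1e-6)
    }
})

test_that("no-back-mutation two-class system recovers the closed form", {
    for (sigma in c(2, 5, 10, 100)) for (Q in c(0.3, 0.5, 0.8, 0.95)) {
        if (sigma * Q <= 1) next
        W <- matrix(c(sigma * Q, sigma * (1 - Q), 0, 1), 2, 2)
        xm <- frequencies(stationaryDistribution(W))[1]
        expect_equal(xm, (sigma * Q - 1) / (sigma - 1), tolerance = 1e-9)
    }
})

test_that("threshold scan reports collapse and analytic bound", {
    u <- defaultUnits(1)
    master <- karyotype(10L, u)
    grid <- seq(0.02, 0.2, by = 0.01)
    scan <- thresholdScan(NULL, master, grid, AMaster = exp(1),
        AMutant = 1, method = "error-class")
    expect_equal(analyticThreshold(scan), 0.1)
    expect_lt(abs(detectedThreshold(scan) - 0.1) / 0.1, 0.25)
    # master frequency starts near 1 and is non-increasing
    expect_gt(frequencies(scan)[1], 0.6)
    expect_true(all(diff(frequencies(scan)) <= 1e-9))
    # exact route: at E = 0 a single-peak master dominates fully
    sp <- enumerateKaryotypeSpace(u, 20)
    scanExact <- thresholdScan(sp, master, c(1e-9, 0.05, 0.1),
        AMaster = exp(1), AMutant = 1, lethalOnNullisomy = FALSE)
    expect_gt(frequencies(scanExact)[1], 0.999)
    # no crossing on a too-short grid is reported as absent, not invented
    scanNone <- thresholdScan(NULL, master, c(0.001, 0.002),
        AMaster = exp(1), AMutant = 1, method = "error-class")
    expect_true(is.na(detectedThreshold(scanNone)))
})

test_that("detected threshold approaches ln(sigma)/c as c grows", {
    u <- defaultUnits(1)
    relGap <- vapply(c(10L, 20L, 46L), function(cM) {
        analytic <- 1 / cM     # sigma = e
        grid <- seq(0.3, 1.8, length.out = 60) * analytic
        scan <- thresholdScan(NULL, karyotype(cM, u), grid,
            AMaster = exp(1), AMutant = 1, method = "error-class")
        abs(detectedThreshold(scan) - analytic) / analytic
    }, numeric(1))
    expect_true(all(relGap < 0.25))
    expect_lte(relGap[3], relGap[1] + 0.02)  # converging with c_m
})
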