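test_that("one Wright-Fisher generation resamples and mutates", {
    u <- defaultUnits(5)
    pop <- cellPopulationSample(matrix(2L, 20, 5), u, generation = 0L)
    # E = 0, flat fitness: offspring are exact copies of parents
    nxt <- wrightFisherGeneration(pop, replicationKernel(0), cnFitness())
    expect_true(all(copyMatrix(nxt) == 2L))
    expect_identical(ncol(nxt), 20L)
    # extinction error when every cell is inviable
    deadM <- matrix(2L, 4, 5); deadM[, 1] <- 0L   # nullisomic unit in every cell
    dead <- cellPopulationSample(deadM, u)
    expect_error(wrightFisherGeneration(dead, replicationKernel(0),
        cnFitness()), "extinct")
})

test_that("per-copy alteration frequency matches the kernel rate", {
    # 1e4 divisions of single-copy units: L1 change per copy is Bernoulli(E)
    set.seed(99)
    E <- 0.05
    parents <- matrix(1L, 1000, 10)
    kids <- aneuqs:::.mutateProfiles(parents, replicationKernel(E))
    phat <- mean(kids != 1L)
    se <- sqrt(E * (1 - E) / length(parents))
    expect_lt(abs(phat - E), 3 * se)
})

test_that("simulation is reproducible and responds to the error rate", {
    f <- diploidKaryotype(defaultUnits(6))
    k <- replicationKernel(0.03)
    a <- simulatePopulation(f, k, N = 60, generations = 6, seed = 42)
    b <- simulatePopulation(f, k, N = 60, generations = 6, seed = 42)
    expect_identical(copyMatrix(a), copyMatrix(b))
    expect_identical(ncol(a), 60L)
    # E = 0 keeps every cell at the founder
    a0 <- simulatePopulation(f, replicationKernel(0), N = 30,
        generations = 5, seed = 1)
    expect_true(all(copyMatrix(a0) == 2L))
    # mean L1 distance to founder increases with E (paired seeds)
    meanL1 <- function(E, seed) {
        s <- simulatePopulation(f, replicationKernel(E), N = 80,
            generations = 8, seed = seed)
        tail(S4Vectors::metadata(s)$summary$mean_l1_to_founder, 1)
    }
    dLow <- vapply(1:6, function(s) meanL1(0.01, s), numeric(1))
    dHigh <- vapply(1:6, function(s) meanL1(0.08, s), numeric(1))
    expect_true(all(dHigh > dLow))
})

test_that("strong selection fixes the master karyotype", {
    u <- defaultUnits(3)
    master <- diploidKaryotype(u)
    # start from a mixed population, no mutation, sharp peak
    set.seed(5)
    start <- matrix(sample(1:3, 25 * 3, replace = TRUE), 25, 3)
    start[1, ] <- 2L
    pop <- cellPopulationSample(start, u, generation = 0L)
    fit <- cnFitness(master = master, AMaster = 20, AMutant = 1)
    fixed <- 0
    for (rep in 1:20) {
        p <- pop
        for (g in 1:15)
            p <- wrightFisherGeneration(p, replicationKernel(0), fit)
        if (all(copyMatrix(p) == 2L)) fixed <- fixed + 1
    }
    expect_gte(fixed / 20, 0.95)
})

test_that("two-site generator emulates a single metastatic clone", {
    ds <- generateTwoSiteDataset(N = 120, nCells = 40, generations = 6,
        seed = 11)
    expect_s4_class(ds$primary, "CellPopulationSample")
    expect_identical(ncol(ds$primary), 40L)
    expect_identical(siteLabel(ds$metastasis), "metastasis")
    # truth metadata records the generating parameters
    expect_equal(ds$truth$EPrimary, 0.02)
    expect_equal(ds$truth$EMetastatic, 0.1)
    expect_equal(ds$truth$seed, 11)
    expect_identical(length(ds$truth$metastasisFounder), 23L)
    # byte-identical reproduction from the same seed
    ds2 <- generateTwoSiteDataset(N = 120, nCells = 40, generations = 6,
        seed = 11)
    expect_identical(copyMatrix(ds$primary), copyMatrix(ds2$primary))
    expect_identical(copyMatrix(ds$metastasis),
        copyMatrix(ds2$metastasis))
    # diploid spike-in plants founder cells
    ds3 <- generateTwoSiteDataset(N = 60, nCells = 20, generations = 4,
        seed = 3, diploidSpikeIn = 0.25)
    expect_true(all(copyMatrix(ds3$primary)[1:5, ] == 2L))
})
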