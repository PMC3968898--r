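test_that("distance to root is the per-cell Euclidean norm", {
    root <- c(2, 2, 2)
    profiles <- rbind(c(2, 2, 2), c(3, 2, 2), c(5, 6, 2))
    d <- distanceToRoot(profiles, root)
    expect_equal(unname(d), c(0, 1, 5))
    # invariant under a consistent unit permutation
    perm <- c(3, 1, 2)
    expect_equal(sort(distanceToRoot(profiles[, perm], root[perm])),
        sort(d))
    expect_error(distanceToRoot(profiles, c(2, 2)), "share one unit set")
})

test_that("median root profile rounds the pooled per-unit medians", {
    m <- rbind(c(2, 3, 1), c(2, 5, 1), c(2, 4, 2))
    expect_identical(medianRootProfile(m), c(2L, 4L, 1L))
})

test_that("variance test matches hand computation and the ANOVA oracle", {
    # identical deviation sets (1,0,1) vs (1,0,1): F = 0, p = 1
    r <- leveneVarianceTest(c(1, 2, 3), c(4, 5, 6))
    expect_equal(unname(r$statistic), 0)
    expect_equal(r$p.value, 1)
    # general cases agree with an aov()-based Brown-Forsythe oracle
    set.seed(31)
    for (i in 1:5) {
        x <- rnorm(17); y <- rnorm(23, sd = runif(1, 0.5, 2))
        r2 <- leveneVarianceTest(x, y)
        expect_equal(unname(r2$statistic), anovaLeveneF(x, y),
            tolerance = 1e-10)
        rMean <- leveneVarianceTest(x, y, center = "mean")
        expect_equal(unname(rMean$statistic), anovaLeveneF(x, y, mean),
            tolerance = 1e-10)
        # third route: car's reference implementation
        carF <- car::leveneTest(c(x, y),
            factor(rep(c("a", "b"), c(length(x), length(y)))))
        expect_equal(unname(r2$statistic), carF$`F value`[1],
            tolerance = 1e-10)
        expect_equal(r2$p.value, carF$`Pr(>F)`[1], tolerance = 1e-10)
    }
    expect_error(leveneVarianceTest(c(1, 1, 1), c(1, 1, 1)),
        "identical")
})

test_that("variance test statistic is location- and scale-invariant", {
    set.seed(17)
    x <- rgamma(20, 2); y <- rgamma(25, 2, rate = 0.5)
    s0 <- leveneVarianceTest(x, y)$statistic
    expect_equal(leveneVarianceTest(x + 100, y + 100)$statistic, s0)
    expect_equal(leveneVarianceTest(3 * x, 3 * y)$statistic, s0)
})

test_that("permutation p agrees with the F approximation on Gaussians", {
    set.seed(8)
    x <- rnorm(40); y <- rnorm(40, sd = 1.3)
    rF <- leveneVarianceTest(x, y)
    rP <- leveneVarianceTest(x, y, method = "permutation", nPerm = 4000,
        seed = 3)
    expect_lt(abs(rF$p.value - rP$p.value), 0.02)
    expect_equal(rP$p.f.approximation, rF$p.value)
    # permutation p is reproducible from its seed
    rP2 <- leveneVarianceTest(x, y, method = "permutation", nPerm = 4000,
        seed = 3)
    expect_identical(rP$p.value, rP2$p.value)
})

test_that("ploidy tail weight tracks mass beyond the peak", {
    expect_equal(ploidyTailWeight(rep(46, 50)), 0)
    base <- c(rep(46, 80), rep(47, 10))
    w0 <- ploidyTailWeight(base, delta = 0.2)
    expect_equal(w0, 0)
    withTail <- c(base, rep(60, 10))
    expect_gt(ploidyTailWeight(withTail, delta = 0.2), w0)
    # adding further tail cells strictly increases the weight
    more <- c(withTail, rep(70, 5))
    expect_gt(ploidyTailWeight(more, delta = 0.2),
        ploidyTailWeight(withTail, delta = 0.2))
    # mode-based variant exposed and bounded
    wMode <- ploidyTailWeight(withTail, delta = 0.2, peak = "mode")
    expect_gte(wMode, 0); expect_lte(wMode, 1)
})

test_that("aneuploidy-rate estimator recovers simple ratios", {
    u <- defaultUnits(23)
    parents <- matrix(2L, 1, 23)
    kids <- parents; kids[1, 4] <- 3L
    est <- estimateAneuploidyRate(parents, kids)
    expect_equal(unname(est$estimate), 1 / 46)
    expect_true(est$conf.int[1] <= 1 / 46 && 1 / 46 <= est$conf.int[2])
    # no changes: zero estimate
    est0 <- estimateAneuploidyRate(parents, parents)
    expect_equal(unname(est0$estimate), 0)
    expect_error(estimateAneuploidyRate(matrix(0L, 2, 3),
        matrix(0L, 2, 3)), "zero total")
})

test_that("rejection rate grows with the between-site rate ratio", {
    # clonally related cells make the equal-rate pipeline anti-conservative
    # (shared genealogy violates independence), so the meaningful pipeline
    # property is the monotone dose-response of the rejection rate.
    nrep <- 25
    rej <- vapply(c(1, 2, 5), function(ratio) {
        p <- vapply(seq_len(nrep), function(r) {
            ds <- generateTwoSiteDataset(EMetastatic = 0.02 * ratio,
                seed = 40000 + 97 * r + round(1000 * ratio))
            dp <- distanceToRoot(ds$primary, ds$truth$founder)
            dm <- distanceToRoot(ds$metastasis, ds$truth$founder)
            leveneVarianceTest(dp, dm)$p.value
        }, numeric(1))
        mean(p < 0.05)
    }, numeric(1))
    expect_lte(rej[1], rej[2] + 0.1)
    expect_lt(rej[1], rej[3])
    expect_gte(rej[3], 0.8)
})

test_that("compareSites assembles the full report", {
    ds <- generateTwoSiteDataset(N = 150, nCells = 60, generations = 8,
        seed = 21)
    rep <- compareSites(ds$primary, ds$metastasis, permutation = TRUE,
        nPerm = 200, seed = 2)
    expect_s3_class(rep, "data.frame")
    get <- function(k) rep$value[rep$statistic == k]
    expect_equal(get("n_cells_primary"), 60)
    expect_gt(get("var_dist_metastasis"), get("var_dist_primary"))
    expect_true(get("levene_p_f") >= 0 && get("levene_p_f") <= 1)
    expect_true(get("levene_p_permutation") >= 0)
    # root defaults to the recorded founder
    expect_equal(attr(rep, "root"), ds$truth$founder)
})
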