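# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Brute-force karyotype transition probability: enumerate every assignment
# of per-copy outcomes (keep / gain / loss) over all copies of the parent.
# Feasible for total copies <= ~8 (3^8 assignments).
bruteTransitionProb <- function(parentCopies, childCopies, E, g) {
    nCopies <- sum(parentCopies)
    if (nCopies == 0)
        return(as.numeric(all(childCopies == 0)))
    unitOfCopy <- rep(seq_along(parentCopies), parentCopies)
    outcomes <- c(1L, 2L, 0L)          # keep, gain, loss
    probs <- c(1 - E, E * g, E * (1 - g))
    total <- 0
    for (code in 0:(3^nCopies - 1)) {
        digits <- (code %/% 3^(seq_len(nCopies) - 1)) %% 3
        contrib <- outcomes[digits + 1]
        child <- vapply(seq_along(parentCopies),
            function(uu) sum(contrib[unitOfCopy == uu]), numeric(1))
        if (all(child == childCopies))
            total <- total + prod(probs[digits + 1])
    }
    total
}

# Stationary state by long-time power iteration on the linear system
# (independent of both eigen() and the ODE path).
powerIterationStationary <- function(W, iters = 200000, dt = 0.01) {
    n <- nrow(W)
    M <- diag(n) + dt * (W - min(diag(W)) * diag(n))  # non-negative for small dt
    x <- rep(1 / n, n)
    for (i in seq_len(iters)) {
        x <- M %*% x
        x <- x / sum(x)
        if (i %% 1000 == 0) {
            xNew <- M %*% x; xNew <- xNew / sum(xNew)
            if (max(abs(xNew - x)) < 1e-14) return(as.numeric(xNew))
        }
    }
    as.numeric(x)
}

# Two-group Brown-Forsythe / Levene F via the generic ANOVA machinery,
# independent of the package's closed-form implementation.
anovaLeveneF <- function(x, y, center = stats::median) {
    z <- c(abs(x - center(x)), abs(y - center(y)))
    grp <- factor(rep(c("a", "b"), c(length(x), length(y))))
    unname(summary(stats::aov(z ~ grp))[[1]]$`F value`[1])
}

randomSmallInstance <- function() {
    nUnits <- sample(1:3, 1)
    maxCopy <- if (nUnits == 1) sample(4:10, 1) else sample(2:4, 1)
    units <- defaultUnits(nUnits)
    space <- enumerateKaryotypeSpace(units, maxCopy)
    master <- karyotype(sample(1:min(3, maxCopy), nUnits, replace = TRUE),
        units)
    f <- singlePeakLandscape(space, master, AMaster = runif(1, 2, 20),
        AMutant = 1, D = sample(c(0, 0.2), 1), lethalOnNullisomy = FALSE)
    kernel <- replicationKernel(runif(1, 0.01, 0.15), runif(1, 0.2, 0.8))
    W <- buildValueMatrix(f, unclass(buildTransitionMatrix(space, kernel)))
    list(space = space, master = master, fitness = f, kernel = kernel,
        W = W)
}
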