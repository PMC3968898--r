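#' Euclidean distances to a common root profile
#'
#' Per-cell L2 distance between integer copy-number profiles and a shared
#' reference (root) profile — the quantity whose between-site variance
#' carries the adaptive-aneuploidy signal: a population evolving at a
#' higher aneuploidy rate spreads further around the root.
#'
#' @param profiles [CellPopulationSample] or matrix (cells x units).
#' @param root reference copy-number vector (e.g. the founder karyotype,
#'   or [medianRootProfile] of the pooled sample).
#' @return named numeric vector of non-negative distances, one per cell.
#' @examples
#' distanceToRoot(rbind(c(2, 2), c(5, 6)), c(2, 2))  # 0, 5
#' @export
distanceToRoot <- function(profiles, root) {
    if (is(profiles, "CellPopulationSample"))
        profiles <- copyMatrix(profiles)
    root <- if (is(root, "Karyotype")) root@copies else as.numeric(root)
    if (ncol(profiles) != length(root))
        stop("profiles and root must share one unit set")
    sqrt(rowSums(sweep(profiles, 2, root)^2))
}

#' Integer-rounded per-unit median profile
#'
#' The default root when no founder is known: the per-unit median of the
#' pooled profiles, rounded to integers.
#'
#' @param profiles matrix (cells x units) or [CellPopulationSample].
#' @return integer vector, one entry per unit.
#' @export
medianRootProfile <- function(profiles) {
    if (is(profiles, "CellPopulationSample"))
        profiles <- copyMatrix(profiles)
    as.integer(round(apply(profiles, 2, median)))
}

# Brown-Forsythe / Levene one-way F statistic on two groups: absolute
# deviations from the group center, then the standard one-way ANOVA F.
# Lean on purpose: it sits inside calibration and permutation loops.
.leveneStat <- function(x, y, center = median) {
    zx <- abs(x - center(x))
    zy <- abs(y - center(y))
    n1 <- length(zx); n2 <- length(zy); N <- n1 + n2
    m1 <- mean(zx); m2 <- mean(zy)
    mAll <- (n1 * m1 + n2 * m2) / N
    ssb <- n1 * (m1 - mAll)^2 + n2 * (m2 - mAll)^2
    ssw <- sum((zx - m1)^2) + sum((zy - m2)^2)
    if (ssw <= 0) return(c(stat = 0, ssw = 0))
    c(stat = (N - 2) * ssb / ssw, ssw = ssw)
}

#' Levene / Brown-Forsythe test for equality of variance
#'
#' Tests whether two groups share a common spread by a one-way ANOVA on
#' absolute deviations from the group centers. The default is the
#' Brown-Forsythe variant (deviations from group medians), robust to the
#' skewed distance distributions karyotype evolution produces; `center =
#' "mean"` gives the classical Levene test. The p-value comes from the F
#' approximation (df 1, n1+n2-2) or, with `method = "permutation"`, from
#' shuffling group labels: p = (1 + #\{perm >= observed\}) / (1 + nPerm).
#'
#' Degenerate input (all deviations zero in both groups) yields statistic
#' 0 and p = 1 with a warning. The statistic is invariant under common
#' location shifts and common rescaling of both groups.
#'
#' @param group1,group2 numeric vectors, each of length >= 3.
#' @param center "median" (Brown-Forsythe, default) or "mean" (Levene).
#' @param method "f" for the F approximation, "permutation" for the
#'   label-permutation p-value (the F statistic is still reported).
#' @param nPerm number of permutations.
#' @param seed RNG seed for the permutation method.
#' @return an object of class `htest` with fields `statistic` (F),
#'   `parameter` (df), `p.value`, `method`; for the permutation method the
#'   F-approximation p is kept in `p.f.approximation`.
#' @examples
#' leveneVarianceTest(c(1, 2, 3), c(4, 5, 6))   # identical deviations: F=0
#' @export
leveneVarianceTest <- function(group1, group2,
        center = c("median", "mean"), method = c("f", "permutation"),
        nPerm = 10000, seed = 1) {
    center <- match.arg(center)
    method <- match.arg(method)
    stopifnot(length(group1) >= 3, length(group2) >= 3)
    if (length(unique(c(group1, group2))) == 1)
        stop("all values identical in both groups; variance test undefined")
    cf <- if (center == "median") median else mean
    obs <- .leveneStat(group1, group2, cf)
    df1 <- 1; df2 <- length(group1) + length(group2) - 2
    degenerate <- obs["ssw"] == 0 && obs["stat"] == 0
    pF <- if (degenerate) 1 else pf(obs["stat"], df1, df2,
        lower.tail = FALSE)
    if (degenerate)
        warning("all absolute deviations are zero; returning statistic 0, p 1")
    out <- list(statistic = c(F = unname(obs["stat"])),
        parameter = c(df1 = df1, df2 = df2),
        p.value = unname(pF),
        method = paste0(if (center == "median") "Brown-Forsythe"
            else "Levene",
            " test for equality of variance (",
            if (method == "f") "F approximation" else "permutation",
            ")"),
        center = center,
        data.name = paste(deparse(substitute(group1)), "and",
            deparse(substitute(group2))))
    if (method == "permutation") {
        set.seed(seed)
        pooled <- c(group1, group2)
        n1 <- length(group1)
        exceed <- 0L
        for (i in seq_len(nPerm)) {
            idx <- sample.int(length(pooled), n1)
            s <- .leveneStat(pooled[idx], pooled[-idx], cf)["stat"]
            if (s >= obs["stat"]) exceed <- exceed + 1L
        }
        out$p.f.approximation <- out$p.value
        out$p.value <- (1 + exceed) / (1 + nPerm)
        out$n.perm <- nPerm
    }
    class(out) <- "htest"
    out
}

#' Weight of the right tail of a ploidy distribution
#'
#' Locates the ploidy peak of the per-cell total DNA contents and returns
#' the fraction of cells with content beyond `(1 + delta)` times the peak.
#' A population with a higher aneuploidy rate shows a thicker, longer tail
#' beyond its ploidy peak. Two peak locators are available: the median
#' (default — stable on the discrete, sometimes plateaued content
#' distributions copy-number evolution produces) and the histogram mode
#' (bin width by the Freedman-Diaconis rule, falling back to Sturges when
#' the IQR is zero; ties between equally tall bins resolve to the
#' lowest-content bin).
#'
#' @param dnaContents numeric vector of per-cell total DNA contents.
#' @param delta relative offset from the peak defining the tail (default
#'   0.2, i.e. 20% above the peak).
#' @param side only "right" is implemented (the informative side for
#'   aneuploidy-driven spread).
#' @param peak "median" or "mode" (FD-histogram mode).
#' @return fraction in `[0, 1]`.
#' @export
ploidyTailWeight <- function(dnaContents, delta = 0.2, side = "right",
        peak = c("median", "mode")) {
    stopifnot(length(dnaContents) > 0, delta > 0)
    side <- match.arg(side, "right")
    peak <- match.arg(peak)
    n <- length(dnaContents)
    rng <- range(dnaContents)
    if (rng[1] == rng[2]) return(0)
    pk <- if (peak == "median") median(dnaContents) else {
        bw <- 2 * IQR(dnaContents) / n^(1 / 3)
        if (bw <= 0)  # Freedman-Diaconis degenerate: Sturges fallback
            bw <- diff(rng) / (ceiling(log2(n)) + 1)
        breaks <- seq(rng[1] - bw / 2, rng[2] + bw, by = bw)
        h <- hist(dnaContents, breaks = breaks, plot = FALSE)
        h$mids[which.max(h$counts)]
    }
    mean(dnaContents > (1 + delta) * pk)
}

#' Estimate the aneuploidy rate from parent-daughter karyotype pairs
#'
#' \eqn{\hat{E} = \sum_{pairs} L_1(parent, child) / \sum_{pairs} c_{parent}}:
#' observed copy-number changes per parental chromosome copy per division,
#' with a Wilson score interval on the ratio. A lower bound on the true
#' per-copy error rate, because a gain and a loss of the same unit in one
#' division cancel in the L1 count.
#'
#' @param parents,children integer matrices (pairs x units) of matched
#'   parent and daughter profiles.
#' @param conf.level interval coverage (default 0.95).
#' @return an `htest`-like list: `estimate` (\eqn{\hat{E}}), `conf.int`,
#'   `n.copies` (total parental copies), `n.changes` (total L1 change).
#' @export
estimateAneuploidyRate <- function(parents, children, conf.level = 0.95) {
    parents <- as.matrix(parents); children <- as.matrix(children)
    if (!all(dim(parents) == dim(children)))
        stop("parents and children must be matched matrices of equal shape")
    if (nrow(parents) < 1) stop("at least one parent-child pair is required")
    changes <- sum(abs(parents - children))
    copies <- sum(parents)
    if (copies == 0) stop("zero total parental copies")
    pt <- stats::prop.test(min(changes, copies), copies, correct = FALSE,
        conf.level = conf.level)
    out <- list(estimate = c(E = changes / copies),
        conf.int = pt$conf.int,
        n.copies = copies, n.changes = changes,
        method = paste("aneuploidy-rate estimator (L1 changes per parental",
            "copy; Wilson interval; lower bound under within-unit",
            "cancellation)"),
        data.name = "parent-daughter karyotype pairs")
    class(out) <- "htest"
    out
}

#' Two-site aneuploid heterogeneity report
#'
#' The full phenomenological pipeline on a pair of copy-number samples:
#' root-profile distances per site, Brown-Forsythe variance-equality test
#' (F approximation and optional permutation p), ploidy tail weights, and
#' group summaries.
#'
#' @param primary,metastasis [CellPopulationSample]s or matrices (cells x
#'   units).
#' @param root root profile; defaults to the shared founder when recorded
#'   in the samples' metadata, else the pooled median profile.
#' @param units a [ChromosomeUnitSet] for DNA content (default: unit
#'   weights of 1, or the samples' own units).
#' @param delta tail offset for [ploidyTailWeight].
#' @param permutation also compute the permutation p-value.
#' @param nPerm,seed permutation parameters.
#' @return data.frame (one row per statistic) with class
#'   `aneuploidyReport`.
#' @export
compareSites <- function(primary, metastasis, root = NULL, units = NULL,
        delta = 0.2, permutation = FALSE, nPerm = 10000, seed = 1) {
    getMat <- function(x) if (is(x, "CellPopulationSample")) copyMatrix(x)
        else as.matrix(x)
    mp <- getMat(primary); mm <- getMat(metastasis)
    if (ncol(mp) != ncol(mm)) stop("sites must share one unit set")
    if (is.null(root)) {
        root <- if (is(primary, "CellPopulationSample") &&
                !is.null(S4Vectors::metadata(primary)$founder))
            S4Vectors::metadata(primary)$founder
        else medianRootProfile(rbind(mp, mm))
    }
    if (is.null(units)) {
        units <- if (is(primary, "CellPopulationSample"))
            chromosomeUnits(unitIds(primary),
                SummarizedExperiment::rowData(primary)$length)
        else chromosomeUnits(colnames(mp, do.NULL = FALSE))
    }
    dp <- distanceToRoot(mp, root)
    dm <- distanceToRoot(mm, root)
    lev <- leveneVarianceTest(dp, dm)
    levPerm <- if (permutation)
        leveneVarianceTest(dp, dm, method = "permutation", nPerm = nPerm,
            seed = seed)
    rows <- data.frame(
        statistic = c("n_cells_primary", "n_cells_metastasis",
            "var_dist_primary", "var_dist_metastasis",
            "levene_F", "levene_p_f",
            if (permutation) "levene_p_permutation",
            "tail_weight_primary", "tail_weight_metastasis"),
        value = c(nrow(mp), nrow(mm), stats::var(dp), stats::var(dm),
            unname(lev$statistic), lev$p.value,
            if (permutation) levPerm$p.value,
            ploidyTailWeight(totalDNAContent(mp, units), delta),
            ploidyTailWeight(totalDNAContent(mm, units), delta)))
    structure(rows, class = c("aneuploidyReport", "data.frame"),
        root = root)
}
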