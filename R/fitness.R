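#' Single-peak fitness landscape over a karyotype space
#'
#' Assigns the master karyotype growth rate `AMaster` and every other state
#' `AMutant`, with a uniform death rate. A single aneuploid event can cause
#' a large phenotypic change, so the fitness distribution around a
#' chromosomal master sequence is expected to decay sharply from the peak —
#' the class of landscape under which an error threshold exists. With
#' `lethalOnNullisomy` (default on) any state that has lost all copies of
#' some unit gets growth rate zero: loss of every copy of an essential
#' chromosome is not compatible with viability.
#'
#' @param space a [KaryotypeSpace].
#' @param master the master [Karyotype] (must lie in `space`).
#' @param AMaster,AMutant growth rates, `AMaster > AMutant >= 0`.
#' @param D uniform death rate.
#' @param lethalOnNullisomy zero out growth for states with a zero entry.
#' @return a [FitnessAssignment].
#' @export
singlePeakLandscape <- function(space, master, AMaster, AMutant, D = 0,
        lethalOnNullisomy = TRUE) {
    stopifnot(AMaster >= AMutant, AMutant >= 0, D >= 0)
    m <- stateIndex(space, master)
    A <- rep(as.numeric(AMutant), nrow(space@states))
    A[m] <- AMaster
    if (lethalOnNullisomy)
        A[apply(space@states == 0L, 1, any)] <- 0
    new("FitnessAssignment", A = A, D = rep(as.numeric(D), length(A)))
}

#' @rdname accessors
#' @export
setMethod("growthRates", "FitnessAssignment", function(x) x@A)
#' @rdname accessors
#' @export
setMethod("deathRates", "FitnessAssignment", function(x) x@D)
#' @rdname accessors
#' @export
setMethod("excessProduction", "FitnessAssignment", function(x) x@A - x@D)

setMethod("show", "FitnessAssignment", function(object) {
    cat("FitnessAssignment over", length(object@A), "states; A in [",
        min(object@A), ",", max(object@A), "], D in [",
        min(object@D), ",", max(object@D), "]\n")
})

#' Construct a population state
#'
#' @param x non-negative frequencies; normalized to sum to 1 when
#'   `normalize = TRUE`.
#' @param normalize divide by the total rather than insisting the input is
#'   already on the simplex.
#' @return a [PopulationState].
#' @export
populationState <- function(x, normalize = FALSE) {
    x <- as.numeric(x)
    if (normalize) {
        s <- sum(x)
        if (s <= 0) stop("cannot normalize a zero vector")
        x <- x / s
    }
    new("PopulationState", x = x)
}

#' @rdname accessors
#' @export
setMethod("frequencies", "PopulationState", function(x) x@x)

setMethod("show", "PopulationState", function(object) {
    top <- order(object@x, decreasing = TRUE)[seq_len(min(3, length(object@x)))]
    cat("PopulationState over", length(object@x), "states; top frequencies:",
        paste(sprintf("#%d=%.4g", top, object@x[top]), collapse = ", "), "\n")
})

#' Mean excess production of a population
#'
#' \eqn{\bar{E}(t) = \sum_k E_k x_k} with \eqn{E_k = A_k - D_k}: the
#' population-average net reproduction rate that appears as the dilution
#' flux in the replicator-mutator equation.
#'
#' @param x a [PopulationState].
#' @param f a [FitnessAssignment].
#' @return a number.
#' @export
meanExcessProduction <- function(x, f) {
    if (length(x@x) != length(f@A))
        stop("population state and fitness assignment dimensions differ")
    sum((f@A - f@D) * x@x)
}

#' Superiority of a master sequence
#'
#' \eqn{\bar\sigma_m = A_m / (D_m + \bar{E}_{k \ne m})}: the relative
#' fitness index of the master state against the average excess production
#' of its competitors. The competitor mean is normalized by the competitors'
#' total frequency,
#' \eqn{\bar{E}_{k\ne m} = \sum_{k\ne m} E_k x_k / \sum_{k\ne m} x_k},
#' the standard quasispecies definition; it stays finite as competitors
#' vanish and is invariant to rescaling all rates by a common constant.
#'
#' @param x a [PopulationState].
#' @param f a [FitnessAssignment].
#' @param m index of the master state.
#' @return \eqn{\bar\sigma_m > 0}.
#' @export
superiority <- function(x, f, m) {
    if (length(x@x) != length(f@A))
        stop("population state and fitness assignment dimensions differ")
    stopifnot(m >= 1, m <= length(x@x))
    wComp <- sum(x@x[-m])
    if (wComp <= 0)
        stop("superiority is undefined without competitors (x_k = 0 for all k != m)")
    EbarComp <- sum((f@A[-m] - f@D[-m]) * x@x[-m]) / wComp
    denom <- f@D[m] + EbarComp
    if (denom <= 0)
        stop("superiority undefined: D_m + mean competitor excess production <= 0")
    f@A[m] / denom
}
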