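#' Construct a per-copy replication kernel
#'
#' @param perCopyError aneuploidy rate \eqn{E = 1 - \bar{A}}: probability
#'   that a given chromosome copy suffers a gain or loss during one
#'   division. Measured values in cancer cells span 1e-3 to 1e-1.
#' @param gainBias given an error, the probability it is a gain (the copy is
#'   present twice in the daughter) rather than a loss. Default 0.5,
#'   symmetric missegregation.
#' @return a [ReplicationKernel].
#' @examples
#' replicationKernel(0.01)
#' @export
replicationKernel <- function(perCopyError, gainBias = 0.5) {
    new("ReplicationKernel", perCopyError = as.numeric(perCopyError),
        gainBias = as.numeric(gainBias))
}

#' @rdname accessors
#' @export
setMethod("perCopyError", "ReplicationKernel", function(x) x@perCopyError)
#' @rdname accessors
#' @export
setMethod("gainBias", "ReplicationKernel", function(x) x@gainBias)
#' @rdname accessors
#' @export
setMethod("aneuploidFidelity", "ReplicationKernel",
    function(x) 1 - x@perCopyError)

setMethod("show", "ReplicationKernel", function(object) {
    cat("ReplicationKernel: per-copy error E =", object@perCopyError,
        "(fidelity", 1 - object@perCopyError,
        "), gain bias =", object@gainBias, "\n")
})

#' Probability of exact reproduction of a karyotype
#'
#' \eqn{Q_{mm} = \bar{A}^{c_m}}: every one of the \eqn{c_m} chromosome
#' copies must be reproduced exactly once, so fidelity decays geometrically
#' in the sequence length. This is the probability of the error-free
#' division path; it is non-increasing in both the per-copy error and
#' \eqn{c_m}.
#'
#' @param k a [Karyotype] (or its sequence length as an integer).
#' @param kernel a [ReplicationKernel].
#' @return probability in `[0, 1]`.
#' @examples
#' k <- diploidKaryotype()
#' replicationFidelity(k, replicationKernel(0.01))  # 0.99^46
#' @export
replicationFidelity <- function(k, kernel) {
    c_m <- if (is(k, "Karyotype")) sequenceLength(k) else as.numeric(k)
    (1 - kernel@perCopyError)^c_m
}

#' Per-copy outcome distribution
#'
#' One chromosome copy is inherited exactly once with probability
#' \eqn{1-E}; duplicated with probability \eqn{E g}; dropped with
#' probability \eqn{E (1-g)}.
#'
#' @param kernel a [ReplicationKernel].
#' @return named numeric vector `(inherit1, gain, loss)` summing to 1.
#' @export
copyEventDistribution <- function(kernel) {
    E <- kernel@perCopyError
    g <- kernel@gainBias
    c(inherit1 = 1 - E, gain = E * g, loss = E * (1 - g))
}

# Per-unit count transition probabilities under the i.i.d. per-copy model.
# Returns matrix K[j+1, n+1] = P(child has j copies | parent has n copies),
# j, n in 0..maxCount. With a gains and b losses among n copies,
# j = n + a - b, so P(j|n) sums the trinomial over a.
.unitKernelMatrix <- function(kernel, maxCount) {
    E <- kernel@perCopyError
    g <- kernel@gainBias
    K <- matrix(0, nrow = maxCount + 1, ncol = maxCount + 1)
    for (n in 0:maxCount) {
        if (n == 0) { K[1, 1] <- 1; next }
        for (j in 0:min(maxCount, 2 * n)) {
            aRange <- max(0, j - n):floor(j / 2)
            p <- 0
            for (a in aRange) {
                b <- a + n - j
                if (b < 0 || a + b > n) next
                p <- p + choose(n, a) * choose(n - a, b) *
                    (E * g)^a * (E * (1 - g))^b * (1 - E)^(n - a - b)
            }
            K[j + 1, n + 1] <- p
        }
    }
    K
}

#' Exact karyotype-to-karyotype transition probability
#'
#' Probability that a parent cell with karyotype `parent` produces a
#' daughter with karyotype `child` in one division, under the per-copy
#' error model: each copy independently follows [copyEventDistribution],
#' and unit counts convolve the per-copy outcomes. Gain/loss cancellations
#' within a unit are included, so the diagonal entry can exceed the
#' error-free path probability [replicationFidelity]; the two agree exactly
#' for karyotypes with a single copy per unit, where no cancelling path
#' exists.
#'
#' @param parent,child [Karyotype]s over the same unit set.
#' @param kernel a [ReplicationKernel].
#' @return probability in `[0, 1]`.
#' @examples
#' u <- chromosomeUnits("chr1")
#' karyotypeTransitionProbability(karyotype(2L, u), karyotype(3L, u),
#'     replicationKernel(0.1))   # 2 * 0.05 * 0.9 = 0.09
#' @export
karyotypeTransitionProbability <- function(parent, child, kernel) {
    if (!identical(parent@units@unitId, child@units@unitId))
        stop("parent and child must share one unit set")
    maxCount <- max(parent@copies, child@copies, 2L * parent@copies)
    K <- .unitKernelMatrix(kernel, maxCount)
    prod(K[cbind(child@copies + 1L, parent@copies + 1L)])
}

#' Build the karyotype transition matrix over an enumerated space
#'
#' `Q[child, parent]` gives the per-division probability of each daughter
#' karyotype within the enumerated space. Columns are sub-stochastic: the
#' deficit `1 - colSums(Q)` is the probability that a daughter leaves the
#' truncated space (some unit exceeding `maxCopy`), reported via
#' `attr(Q, "escapeMass")` and never renormalized, so Q stays an honest
#' sub-stochastic operator (renormalizing would silently inflate fidelity).
#'
#' @param space a [KaryotypeSpace].
#' @param kernel a [ReplicationKernel].
#' @return numeric matrix with `attr(., "escapeMass")`.
#' @export
buildTransitionMatrix <- function(space, kernel) {
    S <- space@states
    nS <- nrow(S)
    nu <- ncol(S)
    # per-unit kernel up to 2*maxCopy so that escape mass is exact
    K <- .unitKernelMatrix(kernel, 2L * space@maxCopy)
    retained <- K[seq_len(space@maxCopy + 1L), , drop = FALSE]
    Q <- matrix(1, nS, nS)
    for (u in seq_len(nu)) {
        # outer product structure: child count rows vs parent count cols
        Q <- Q * retained[cbind(rep(S[, u], times = nS) + 1L,
            rep(S[, u], each = nS) + 1L)]
    }
    # column sums factorize over units on the full product space
    perUnitRetention <- colSums(retained)
    colRet <- rep(1, nS)
    for (u in seq_len(nu))
        colRet <- colRet * perUnitRetention[S[, u] + 1L]
    structure(Q, escapeMass = 1 - colRet)
}
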