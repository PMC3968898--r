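#' Build the value matrix of the replicator-mutator system
#'
#' \eqn{W_{mk} = A_k Q_{mk}} for \eqn{k \ne m} (rate of production of type
#' m by erroneous reproduction of type k) and
#' \eqn{W_{mm} = A_m Q_{mm} - D_m} (effective excess production of type m).
#'
#' @param f a [FitnessAssignment].
#' @param Q transition matrix `Q[child, parent]` from
#'   [buildTransitionMatrix].
#' @return a square numeric matrix W.
#' @export
buildValueMatrix <- function(f, Q) {
    n <- length(f@A)
    if (!is.matrix(Q) || nrow(Q) != n || ncol(Q) != n)
        stop("Q must be a square matrix conformable with the fitness assignment")
    W <- sweep(unclass(Q)[seq_len(n), seq_len(n)], 2, f@A, `*`)
    diag(W) <- diag(W) - f@D
    W
}

# Dominant eigenpair of W. W + cI is non-negative for large enough c, so
# Perron-Frobenius applies to the shifted matrix and the dominant
# eigenvector of W can be taken non-negative; eigenvalues shift by c,
# eigenvectors are unchanged.
.dominantEigen <- function(W, tol = 1e-8) {
    e <- eigen(W)
    i <- which.max(Re(e$values))
    lam <- e$values[i]
    v <- e$vectors[, i]
    scale <- max(Mod(e$values), 1)
    if (abs(Im(lam)) > tol * scale)
        stop("dominant eigenvalue is complex beyond tolerance; ",
            "stationary state is degenerate")
    v <- Re(v)
    if (sum(v) < 0) v <- -v
    if (any(v < -tol * max(abs(v))))
        stop("dominant eigenvector has mixed signs beyond tolerance; ",
            "stationary state is degenerate")
    v[v < 0] <- 0
    list(lambda = Re(lam), x = v / sum(v))
}

#' Stationary quasispecies distribution
#'
#' The steady state of the replicator-mutator dynamics is the normalized
#' dominant (Perron) eigenvector of the value matrix W; it matches the
#' long-time limit of [integrateReplicatorMutator].
#'
#' @param W value matrix from [buildValueMatrix].
#' @param tol relative tolerance for declaring the dominant eigenpair real
#'   and non-negative.
#' @return a [PopulationState].
#' @export
stationaryDistribution <- function(W, tol = 1e-8) {
    populationState(.dominantEigen(W, tol)$x)
}

#' Integrate the replicator-mutator equation
#'
#' Solves \eqn{dx_m/dt = (W_{mm} - \bar{E}(t)) x_m + \sum_{k\ne m} W_{mk} x_k}
#' on the simplex. The dilution flux is the realized net production
#' \eqn{\phi(t) = \sum_m (Wx)_m}; when Q is column-stochastic this equals
#' \eqn{\bar{E}(t) = \sum_k (A_k - D_k) x_k}, and when Q is sub-stochastic
#' (escape mass to the absorbing out-class) it additionally counts escaped
#' offspring as dead, which is the only choice that keeps \eqn{\sum x = 1}.
#'
#' @param W value matrix.
#' @param x0 initial [PopulationState].
#' @param tEnd integration horizon.
#' @param nOut number of reported time points.
#' @param rtol,atol integrator tolerances (deSolve::lsoda).
#' @return list with `times`, `trajectory` (time points x states, each row
#'   on the simplex), `final` (a [PopulationState]) and `residual`, the max
#'   |dx/dt| at the final point (small when `tEnd` reaches stationarity).
#' @export
integrateReplicatorMutator <- function(W, x0, tEnd = 100, nOut = 50,
        rtol = 1e-10, atol = 1e-12) {
    stopifnot(is(x0, "PopulationState"), length(x0@x) == nrow(W))
    rhs <- function(t, x, parms) {
        flux <- W %*% x
        list(as.numeric(flux) - sum(flux) * x)
    }
    times <- seq(0, tEnd, length.out = nOut + 1)
    sol <- deSolve::ode(y = x0@x, times = times, func = rhs, parms = NULL,
        method = "lsoda", rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
        stop("replicator-mutator integration failed (lsoda istate ",
            attr(sol, "istate")[1], ")")
    traj <- unname(sol[, -1, drop = FALSE])
    drift <- abs(rowSums(traj) - 1)
    if (any(drift > 1e-8))
        stop("integrator left the simplex (max |sum x - 1| = ",
            format(max(drift)), ")")
    xT <- traj[nrow(traj), ]
    xT[xT < 0] <- 0
    res <- rhs(tEnd, xT, NULL)[[1]]
    list(times = times, trajectory = traj,
        final = populationState(xT / sum(xT)),
        residual = max(abs(res)))
}

#' Scan the per-copy error rate for the aneuploid error threshold
#'
#' For each error rate on the grid, records the stationary master-sequence
#' frequency of a single-peak landscape and reads off two operational
#' thresholds on the finite system: the first grid point at which the
#' master frequency falls below the neutral expectation 1/(number of
#' viable states) — the headline number — and the point of steepest
#' descent. The analytic bound \eqn{\ln\bar\sigma/c_m} is attached for
#' comparison; for a single-peak landscape with uniform death rate,
#' \eqn{\bar\sigma = A_{master}/A_{mutant}}.
#'
#' Two model routes are available:
#' \describe{
#'   \item{`"exact"`}{full enumerated dynamics on a [KaryotypeSpace] with
#'     the exact transition kernel, restricted to the viable support
#'     (states with A > 0 — lethal states cannot reproduce, and inflow
#'     into them joins the escape mass). Exhaustive, but it keeps every
#'     return path into the master; in low-dimensional unit sets the
#'     back-mutation flux is substantial and delocalization can be slow or
#'     absent, in which case the detected threshold is honestly reported
#'     as `NA`.}
#'   \item{`"error-class"`}{states binned by L1 distance from the master
#'     (class 0 = master, class d = d accumulated aneuploid defects, last
#'     class absorbing). New defects per division are Binomial(c_m, E) and
#'     back mutation is neglected — the separability assumption under
#'     which the error threshold is derived: an erroneous copy is
#'     exceedingly unlikely to revert to the exact master configuration
#'     when defects can hit many distinct units. This route shows the
#'     sharp transition at \eqn{\bar\sigma (1-E)^{c_m} = 1} and scales to
#'     any c_m; it cannot track nullisomy, which is a within-class
#'     property.}
#' }
#'
#' @param space a [KaryotypeSpace] (required for `method = "exact"`; may
#'   be `NULL` for `"error-class"`).
#' @param master the master [Karyotype].
#' @param errorGrid strictly increasing per-copy error rates in `[0, 1)`.
#' @param AMaster,AMutant,D,lethalOnNullisomy landscape parameters, see
#'   [singlePeakLandscape].
#' @param gainBias see [replicationKernel] (exact route only).
#' @param method `"exact"` or `"error-class"`.
#' @param dMax number of defect classes retained on the error-class route.
#' @return a [ThresholdScanResult].
#' @export
thresholdScan <- function(space, master, errorGrid, AMaster = 10,
        AMutant = 1, D = 0, lethalOnNullisomy = TRUE, gainBias = 0.5,
        method = c("exact", "error-class"), dMax = 50) {
    method <- match.arg(method)
    stopifnot(all(errorGrid >= 0), all(errorGrid < 1),
        !is.unsorted(errorGrid, strictly = TRUE))
    if (method == "error-class")
        return(.errorClassScan(sequenceLength(master), errorGrid,
            AMaster, AMutant, D, dMax))
    f <- singlePeakLandscape(space, master, AMaster, AMutant, D,
        lethalOnNullisomy)
    viable <- which(f@A > 0)
    mFull <- stateIndex(space, master)
    m <- match(mFull, viable)
    nViable <- length(viable)
    fV <- new("FitnessAssignment", A = f@A[viable], D = f@D[viable])
    mf <- lam <- numeric(length(errorGrid))
    for (i in seq_along(errorGrid)) {
        kern <- replicationKernel(errorGrid[i], gainBias)
        Q <- buildTransitionMatrix(space, kern)
        W <- buildValueMatrix(fV,
            unclass(Q)[viable, viable, drop = FALSE])
        eg <- .dominantEigen(W)
        mf[i] <- eg$x[m]
        lam[i] <- eg$lambda
    }
    .scanResult(errorGrid, mf, lam, 1 / nViable,
        log(AMaster / AMutant) / sequenceLength(master))
}

# Aggregated defect-class dynamics: lower-triangular value matrix, last
# class absorbs the binomial tail so columns stay stochastic.
.errorClassScan <- function(cM, errorGrid, AMaster, AMutant, D, dMax) {
    stopifnot(cM >= 1, dMax >= 2)
    A <- c(AMaster, rep(AMutant, dMax))
    Dv <- rep(D, dMax + 1)
    mf <- lam <- numeric(length(errorGrid))
    for (i in seq_along(errorGrid)) {
        E <- errorGrid[i]
        Q <- matrix(0, dMax + 1, dMax + 1)
        for (k in 0:dMax) {
            j <- k:dMax
            p <- stats::dbinom(j - k, cM, E)
            p[length(p)] <- 1 - sum(p[-length(p)])  # absorbing tail class
            Q[j + 1, k + 1] <- p
        }
        W <- buildValueMatrix(new("FitnessAssignment", A = A, D = Dv), Q)
        eg <- .dominantEigen(W)
        mf[i] <- eg$x[1]
        lam[i] <- eg$lambda
    }
    .scanResult(errorGrid, mf, lam, 1 / (dMax + 1),
        log(AMaster / AMutant) / cM)
}

.scanResult <- function(errorGrid, mf, lam, neutral, analytic) {
    below <- which(mf < neutral)
    detected <- if (length(below)) errorGrid[below[1]] else NA_real_
    slope <- diff(mf) / diff(errorGrid)
    steepest <- errorGrid[which.max(abs(slope)) + 1L]
    new("ThresholdScanResult", errorGrid = errorGrid, masterFreq = mf,
        leadingEigenvalue = lam, detectedThreshold = detected,
        steepestThreshold = steepest, analyticThreshold = analytic,
        neutralLevel = neutral)
}

#' @rdname accessors
#' @export
setMethod("detectedThreshold", "ThresholdScanResult",
    function(x) x@detectedThreshold)
#' @rdname accessors
#' @export
setMethod("analyticThreshold", "ThresholdScanResult",
    function(x) x@analyticThreshold)

#' @rdname accessors
#' @export
setMethod("frequencies", "ThresholdScanResult", function(x) x@masterFreq)

setMethod("show", "ThresholdScanResult", function(object) {
    cat("ThresholdScanResult over", length(object@errorGrid),
        "error rates in [", min(object@errorGrid), ",",
        max(object@errorGrid), "]\n")
    cat("  detected threshold (neutral-level crossing):",
        object@detectedThreshold, "\n")
    cat("  steepest-descent point:", object@steepestThreshold, "\n")
    cat("  analytic bound ln(sigma)/c_m:", object@analyticThreshold, "\n")
})

#' Tabulate a threshold scan
#'
#' @param x a [ThresholdScanResult].
#' @return data.frame with columns `error_rate`, `master_freq`,
#'   `leading_eigenvalue`.
#' @export
asScanTable <- function(x) {
    data.frame(error_rate = x@errorGrid, master_freq = x@masterFreq,
        leading_eigenvalue = x@leadingEigenvalue)
}
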