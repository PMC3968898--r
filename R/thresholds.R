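#' Quasispecies viability condition
#'
#' A master sequence can maintain itself at mutation-selection balance iff
#' \eqn{\bar\sigma_m Q_{mm} > 1} (strict): its fidelity-discounted growth
#' must still exceed the average excess production of its competitors.
#'
#' @param sigmaBar superiority \eqn{\bar\sigma_m > 0}.
#' @param Q probability of precise reproduction \eqn{Q_{mm} \in [0,1]}.
#' @return logical.
#' @export
viability <- function(sigmaBar, Q) {
    stopifnot(sigmaBar > 0, Q >= 0, Q <= 1)
    sigmaBar * Q > 1
}

#' Error threshold of a master sequence
#'
#' The maximal per-symbol error rate compatible with maintaining a master
#' sequence of length `len` and superiority `sigmaBar`:
#' \eqn{\ln\bar\sigma_m / \mathrm{len}}. The same formula serves two
#' regimes, distinguished only by what a "symbol" is:
#' \itemize{
#'   \item nucleotide regime: `len` is the genome length \eqn{v_m} in
#'     bases and the bound caps \eqn{1-\bar{q}}, the per-nucleotide error;
#'   \item aneuploid regime: `len` is the chromosomal master sequence
#'     length \eqn{c_m} (sum of copy numbers) and the bound caps
#'     \eqn{E_m = 1-\bar{A}_m}, the per-copy aneuploidy rate.
#' }
#' With \eqn{\bar\sigma \in [10^2, 10^3]} and \eqn{c_m \approx 10^2} the
#' aneuploid threshold is of order \eqn{10^{-2}} — inside the measured
#' cancer aneuploidy-rate range \eqn{[10^{-3}, 10^{-1}]}, so highly
#' aneuploid tumours operate close to the edge of quasispecies viability.
#'
#' The default is the linearized bound \eqn{\ln\bar\sigma/\mathrm{len}};
#' `exact = TRUE` returns \eqn{1 - \bar\sigma^{-1/\mathrm{len}}}, the error
#' rate at which \eqn{\bar\sigma (1-E)^{\mathrm{len}} = 1} exactly. The two
#' agree to first order in the error rate and the difference only matters
#' near the threshold.
#'
#' @param sigmaBar superiority (>= 1 for a meaningful bound; < 1 warns and
#'   yields a negative bound — such a master is never viable).
#' @param len sequence length (\eqn{v_m} or \eqn{c_m}), >= 1.
#' @param exact use the exact form instead of the linearization.
#' @return the threshold error rate.
#' @examples
#' aneuploidThreshold(100, 100)    # ~0.0461, order 1e-2
#' nucleotideThreshold(1000, 3.2e9)
#' @export
errorThreshold <- function(sigmaBar, len, exact = FALSE) {
    stopifnot(len >= 1)
    if (any(sigmaBar < 1))
        warning("sigmaBar < 1: threshold is negative; ",
            "no error rate keeps such a master sequence viable")
    if (exact) 1 - exp(-log(sigmaBar) / len) else log(sigmaBar) / len
}

#' @rdname errorThreshold
#' @param v master sequence length in nucleotides.
#' @export
nucleotideThreshold <- function(sigmaBar, v, exact = FALSE) {
    errorThreshold(sigmaBar, v, exact)
}

#' @rdname errorThreshold
#' @param c chromosomal master sequence length (sum of copy numbers).
#' @export
aneuploidThreshold <- function(sigmaBar, c, exact = FALSE) {
    errorThreshold(sigmaBar, c, exact)
}

#' Reference constants for the two regimes
#'
#' Standard order-of-magnitude inputs for threshold arithmetic in human
#' cells: genome length 3.2e9 bases, of which ~5% is coding/conserved;
#' baseline per-nucleotide error 1e-10..1e-9 per division; mismatch-repair
#' breakdown (MSI) elevates it by 1 to 3 orders of magnitude; plausible
#' superiority range 1e2..1e3 for dominant tumour subpopulations;
#' chromosomal master sequence length ~1e2 for highly aneuploid cells; and
#' measured cancer aneuploidy rates 1e-3..1e-1 per copy per division.
#'
#' @return a named list.
#' @export
regimeDefaults <- function() {
    list(
        genomeLength = 3.2e9,
        codingFraction = 0.05,
        baselineNucleotideError = c(1e-10, 1e-9),
        msiMultiplier = c(10, 1e3),
        sigmaBar = c(1e2, 1e3),
        chromosomalLength = 1e2,
        cancerAneuploidyRate = c(1e-3, 1e-1))
}

#' Viability report for microsatellite-instable error rates
#'
#' The nucleotide-regime stress test: MSI tumours elevate the
#' per-nucleotide error by 1-3 orders of magnitude, yet exist. For every
#' combination of baseline error, MSI multiplier, superiority and master
#' sequence length (whole genome and coding-restricted), the report
#' compares the elevated error rate against the nucleotide error threshold
#' \eqn{\ln\bar\sigma/v} and records whether the combination is viable.
#' A nucleotide-level master sequence fails the threshold inequality across
#' essentially the whole MSI grid — the inconsistency that motivates moving
#' the quasispecies to the karyotype level.
#'
#' @param baselineError per-nucleotide error rates per division.
#' @param msiMultiplier error-elevation factors (1 = intact mismatch
#'   repair).
#' @param sigmaBar superiority values.
#' @param v master sequence lengths in nucleotides (default: whole genome
#'   and the 5% coding restriction).
#' @param exact use the exact threshold form.
#' @return data.frame with one row per combination: `baseline_error`,
#'   `msi_multiplier`, `error_rate`, `sigma_bar`, `v`, `bound`, `viable`;
#'   `attr(., "anyViableMSI")` flags whether any elevated (multiplier > 1)
#'   combination passes.
#' @export
msiViabilityReport <- function(baselineError = c(1e-10, 1e-9),
        msiMultiplier = c(1, 10, 1e2, 1e3),
        sigmaBar = c(1e2, 1e3),
        v = c(3.2e9, 0.05 * 3.2e9),
        exact = FALSE) {
    stopifnot(length(baselineError) > 0, length(msiMultiplier) > 0,
        length(sigmaBar) > 0, length(v) > 0)
    grid <- expand.grid(baseline_error = baselineError,
        msi_multiplier = msiMultiplier, sigma_bar = sigmaBar, v = v,
        KEEP.OUT.ATTRS = FALSE)
    grid$error_rate <- grid$baseline_error * grid$msi_multiplier
    grid$bound <- mapply(function(s, len) errorThreshold(s, len, exact),
        grid$sigma_bar, grid$v)
    grid$viable <- grid$error_rate <= grid$bound
    structure(grid[, c("baseline_error", "msi_multiplier", "error_rate",
            "sigma_bar", "v", "bound", "viable")],
        anyViableMSI = any(grid$viable & grid$msi_multiplier > 1))
}

#' Build a two-regime threshold report
#'
#' @param regime "nucleotide" or "aneuploid".
#' @param sigmaBar superiority.
#' @param len sequence length (\eqn{v_m} or \eqn{c_m}).
#' @param errorRate observed per-symbol error rate (\eqn{1-\bar q} or
#'   \eqn{E_m}).
#' @param exact use the exact threshold form.
#' @return one-row data.frame: `regime`, `sigma_bar`, `length`, `bound`,
#'   `error_rate`, `viable`.
#' @export
thresholdReport <- function(regime = c("aneuploid", "nucleotide"), sigmaBar,
        len, errorRate, exact = FALSE) {
    regime <- match.arg(regime)
    bound <- errorThreshold(sigmaBar, len, exact)
    data.frame(regime = regime, sigma_bar = sigmaBar, length = len,
        bound = bound, error_rate = errorRate,
        viable = errorRate <= bound)
}
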