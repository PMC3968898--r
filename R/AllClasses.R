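#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats median pf rbinom rnorm runif setNames quantile IQR
#' @importFrom graphics hist
#' @importFrom utils read.delim write.table head tail
NULL

#' Set of chromosome units
#'
#' A declared, fixed set of whole-chromosome or chromosome-fragment units over
#' which karyotypes are expressed. Each unit has a short identifier and a
#' physical length in base pairs (or a dimensionless weight of 1 when only
#' copy counts matter). The unit set is frozen at configuration time: events
#' that would split a chromosome mid-simulation are not modelled; arms or
#' fragments expected to segregate independently are declared as units up
#' front.
#'
#' @slot unitId character vector of unique unit labels.
#' @slot length numeric vector of positive unit lengths (base pairs or
#'   weight 1).
#' @export
setClass("ChromosomeUnitSet",
    representation(unitId = "character", length = "numeric"))

setValidity("ChromosomeUnitSet", function(object) {
    if (length(object@unitId) != length(object@length))
        return("unitId and length must have equal length")
    if (anyDuplicated(object@unitId))
        return("unit identifiers must be unique")
    if (length(object@length) && any(!is.finite(object@length) | object@length <= 0))
        return("unit lengths must be finite and > 0")
    TRUE
})

#' Karyotype: a chromosomal master sequence
#'
#' An integer copy-number vector over a declared [ChromosomeUnitSet]. The
#' karyotype is the package's representation of a chromosomal master
#' sequence: the collection of physically distinct whole or fragmented
#' chromosomes in a cell. Its sequence length \eqn{c_m} is the sum of copy
#' numbers (46 for a normal human diploid cell over 23 units).
#'
#' Zero copies of a unit (nullisomy) is representable; whether it is viable
#' is decided by the fitness layer, not here.
#'
#' @slot copies integer vector of non-negative copy numbers, one per unit.
#' @slot units the [ChromosomeUnitSet] the copies refer to.
#' @export
setClass("Karyotype",
    representation(copies = "integer", units = "ChromosomeUnitSet"))

setValidity("Karyotype", function(object) {
    if (length(object@copies) != length(object@units@unitId))
        return("copies must have one entry per declared unit")
    if (any(is.na(object@copies)) || any(object@copies < 0))
        return("copy numbers must be non-negative integers")
    TRUE
})

#' Enumerated karyotype state space
#'
#' The full product space \{0, ..., maxCopy\}^nUnits in a deterministic
#' lexicographic order (first unit most significant, counting upward), used
#' as the finite state space for exact quasispecies dynamics.
#'
#' @slot states integer matrix, one row per karyotype state, one column per
#'   unit.
#' @slot units the shared [ChromosomeUnitSet].
#' @slot maxCopy the per-unit copy cap used for enumeration.
#' @export
setClass("KaryotypeSpace",
    representation(states = "matrix", units = "ChromosomeUnitSet",
        maxCopy = "integer"))

setValidity("KaryotypeSpace", function(object) {
    if (ncol(object@states) != length(object@units@unitId))
        return("state matrix must have one column per unit")
    if (any(object@states < 0) || any(object@states > object@maxCopy))
        return("states must lie in {0..maxCopy}")
    TRUE
})

#' Per-copy aneuploid replication kernel
#'
#' The error model of cell division at the level of physically distinct
#' chromosome copies. Each copy, independently, is inherited exactly once
#' with probability \eqn{1 - E}; with probability \eqn{E} an aneuploid error
#' occurs, and the erroneous copy is either duplicated in the daughter
#' (a gain, probability \code{gainBias} given an error) or dropped (a loss).
#' \eqn{E} is the aneuploidy rate and \eqn{\bar{A} = 1 - E} the aneuploid
#' fidelity: the probability that a copy is reproduced exactly once, with no
#' gain or loss.
#'
#' @slot perCopyError probability of an aneuploid error per chromosome copy
#'   per division (\eqn{E = 1 - \bar{A}}).
#' @slot gainBias fraction of errors that are gains; 0.5 models symmetric
#'   missegregation.
#' @export
setClass("ReplicationKernel",
    representation(perCopyError = "numeric", gainBias = "numeric"))

setValidity("ReplicationKernel", function(object) {
    ok <- function(p) length(p) == 1 && is.finite(p) && p >= 0 && p <= 1
    if (!ok(object@perCopyError)) return("perCopyError must be in [0,1]")
    if (!ok(object@gainBias)) return("gainBias must be in [0,1]")
    TRUE
})

#' Fitness assignment over a karyotype space
#'
#' Growth rate \eqn{A_k}, death rate \eqn{D_k} and derived excess production
#' \eqn{E_k = A_k - D_k} for every state of an enumerated karyotype space.
#'
#' @slot A non-negative growth rates, one per state.
#' @slot D non-negative death rates, one per state.
#' @export
setClass("FitnessAssignment", representation(A = "numeric", D = "numeric"))

setValidity("FitnessAssignment", function(object) {
    if (length(object@A) != length(object@D))
        return("A and D must have equal length")
    if (any(!is.finite(object@A)) || any(object@A < 0))
        return("growth rates A must be finite and >= 0")
    if (any(!is.finite(object@D)) || any(object@D < 0))
        return("death rates D must be finite and >= 0")
    TRUE
})

#' Population state on the simplex
#'
#' Relative frequencies \eqn{x_k} of each karyotype state; non-negative and
#' summing to one within 1e-9.
#'
#' @slot x numeric frequency vector.
#' @export
setClass("PopulationState", representation(x = "numeric"))

setValidity("PopulationState", function(object) {
    if (any(!is.finite(object@x)) || any(object@x < -1e-12))
        return("frequencies must be finite and non-negative")
    if (abs(sum(object@x) - 1) > 1e-9)
        return("frequencies must sum to 1 within 1e-9")
    TRUE
})

#' Result of a numeric error-threshold scan
#'
#' Stationary master-sequence frequency as a function of the per-copy error
#' rate, with two operational readings of the error threshold on the finite
#' system — the first grid point at which the master frequency falls below
#' the neutral expectation 1/(number of viable states) (the headline
#' number), and the point of steepest descent — alongside the analytic bound
#' \eqn{\ln\bar\sigma / c_m}.
#'
#' @slot errorGrid strictly increasing per-copy error rates scanned.
#' @slot masterFreq stationary master frequency at each grid point.
#' @slot leadingEigenvalue dominant eigenvalue of the value matrix at each
#'   grid point.
#' @slot detectedThreshold neutral-level crossing (NA if no crossing on the
#'   grid).
#' @slot steepestThreshold grid point of maximum |slope| of master frequency.
#' @slot analyticThreshold \eqn{\ln\bar\sigma / c_m} for the scanned
#'   landscape.
#' @slot neutralLevel the collapse criterion level 1/(number of viable
#'   states).
#' @export
setClass("ThresholdScanResult",
    representation(errorGrid = "numeric", masterFreq = "numeric",
        leadingEigenvalue = "numeric", detectedThreshold = "numeric",
        steepestThreshold = "numeric", analyticThreshold = "numeric",
        neutralLevel = "numeric"))

setValidity("ThresholdScanResult", function(object) {
    if (length(object@errorGrid) != length(object@masterFreq))
        return("errorGrid and masterFreq lengths differ")
    if (is.unsorted(object@errorGrid, strictly = TRUE))
        return("errorGrid must be strictly increasing")
    if (any(object@masterFreq < -1e-9 | object@masterFreq > 1 + 1e-9))
        return("master frequencies must lie in [0,1]")
    TRUE
})

#' Sample of cells with integer copy-number profiles
#'
#' A \linkS4class{SummarizedExperiment} holding one assay, \code{"copies"},
#' with chromosome units as rows and cells as columns. Metadata records the
#' generation index, the site label (e.g. "primary", "metastasis"), the RNG
#' seed and, for simulated samples, the founder karyotype and per-generation
#' summaries. Stands in for a single-cell CNV sample.
#'
#' @export
setClass("CellPopulationSample", contains = "SummarizedExperiment")

setValidity("CellPopulationSample", function(object) {
    if (!"copies" %in% SummarizedExperiment::assayNames(object))
        return("assay 'copies' is required")
    cp <- SummarizedExperiment::assay(object, "copies")
    if (ncol(cp) < 1) return("sample must contain at least one cell")
    if (any(is.na(cp)) || any(cp < 0) || any(cp != round(cp)))
        return("copy numbers must be non-negative integers")
    TRUE
})
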