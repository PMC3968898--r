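#' Chromosomal master sequence length
#'
#' The length \eqn{c_m} of a chromosomal master sequence is the sum of the
#' copy numbers of each whole or fragmented chromosome: 46 for a normal
#' human diploid karyotype over 23 units; highly aneuploid tumour cells
#' reach the order of 1e2.
#'
#' @param x a [Karyotype], a [CellPopulationSample], or an integer matrix of
#'   profiles (cells in rows, units in columns).
#' @return a non-negative integer, or one per cell for matrix-like input.
#' @examples
#' u <- chromosomeUnits(paste0("chr", 1:23))
#' sequenceLength(karyotype(rep(2L, 23), u))  # 46
#' @export
setGeneric("sequenceLength", function(x) standardGeneric("sequenceLength"))

#' Total DNA content of a karyotype
#'
#' Copy-number vector weighted by unit lengths,
#' \eqn{\sum_u \mathrm{copies}_u \times \mathrm{length}_u}; the quantity a
#' ploidy histogram bins cells by.
#'
#' @param x a [Karyotype], a [CellPopulationSample], or a profile matrix
#'   (cells in rows).
#' @param units a [ChromosomeUnitSet]; taken from `x` when it carries one.
#' @return a non-negative number (or one per cell).
#' @export
setGeneric("totalDNAContent",
    function(x, units) standardGeneric("totalDNAContent"))

#' @rdname accessors
#' @export
setGeneric("unitIds", function(x) standardGeneric("unitIds"))

#' @rdname accessors
#' @export
setGeneric("unitLengths", function(x) standardGeneric("unitLengths"))

#' @rdname accessors
#' @export
setGeneric("copies", function(x) standardGeneric("copies"))

#' @rdname accessors
#' @export
setGeneric("states", function(x) standardGeneric("states"))

#' @rdname accessors
#' @export
setGeneric("perCopyError", function(x) standardGeneric("perCopyError"))

#' @rdname accessors
#' @export
setGeneric("gainBias", function(x) standardGeneric("gainBias"))

#' @rdname accessors
#' @export
setGeneric("aneuploidFidelity",
    function(x) standardGeneric("aneuploidFidelity"))

#' @rdname accessors
#' @export
setGeneric("growthRates", function(x) standardGeneric("growthRates"))

#' @rdname accessors
#' @export
setGeneric("deathRates", function(x) standardGeneric("deathRates"))

#' @rdname accessors
#' @export
setGeneric("excessProduction",
    function(x) standardGeneric("excessProduction"))

#' @rdname accessors
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' @rdname accessors
#' @export
setGeneric("copyMatrix", function(x) standardGeneric("copyMatrix"))

#' @rdname accessors
#' @export
setGeneric("siteLabel", function(x) standardGeneric("siteLabel"))

#' @rdname accessors
#' @export
setGeneric("detectedThreshold",
    function(x) standardGeneric("detectedThreshold"))

#' @rdname accessors
#' @export
setGeneric("analyticThreshold",
    function(x) standardGeneric("analyticThreshold"))
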