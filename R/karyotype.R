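#' Declare a set of chromosome units
#'
#' @param unitId character vector of unique unit labels (e.g. "chr1",
#'   "chr5p").
#' @param length positive unit lengths in base pairs, or 1 (the default) for
#'   dimensionless weights.
#' @return a [ChromosomeUnitSet].
#' @examples
#' chromosomeUnits(c("chr1", "chr2"), c(248e6, 242e6))
#' @export
chromosomeUnits <- function(unitId, length = rep(1, base::length(unitId))) {
    new("ChromosomeUnitSet", unitId = as.character(unitId),
        length = as.numeric(length))
}

#' Diploid-style default unit set
#'
#' Convenience constructor for `n` whole-chromosome units labelled
#' "chr1".."chrn" with unit weight 1; 23 units mirrors a human haploid
#' complement so that a diploid karyotype has sequence length 46.
#'
#' @param n number of units.
#' @return a [ChromosomeUnitSet].
#' @export
defaultUnits <- function(n = 23) chromosomeUnits(paste0("chr", seq_len(n)))

#' Construct a karyotype
#'
#' @param copies non-negative integer copy numbers, one per unit.
#' @param units a [ChromosomeUnitSet].
#' @return a [Karyotype].
#' @examples
#' karyotype(rep(2L, 23), defaultUnits())   # normal diploid
#' @export
karyotype <- function(copies, units) {
    if (is.numeric(copies) && any(copies != round(copies)))
        stop("copy numbers must be integers")
    new("Karyotype", copies = as.integer(copies), units = units)
}

#' Diploid karyotype over a unit set
#' @param units a [ChromosomeUnitSet].
#' @return a [Karyotype] with two copies of every unit.
#' @export
diploidKaryotype <- function(units = defaultUnits()) {
    karyotype(rep(2L, length(units@unitId)), units)
}

#' @rdname accessors
#' @param x an aneuqs object.
#' @export
setMethod("unitIds", "ChromosomeUnitSet", function(x) x@unitId)
#' @rdname accessors
#' @export
setMethod("unitIds", "Karyotype", function(x) x@units@unitId)
#' @rdname accessors
#' @export
setMethod("unitIds", "KaryotypeSpace", function(x) x@units@unitId)
#' @rdname accessors
#' @export
setMethod("unitLengths", "ChromosomeUnitSet", function(x) x@length)
#' @rdname accessors
#' @export
setMethod("copies", "Karyotype", function(x)
    setNames(x@copies, x@units@unitId))
#' @rdname accessors
#' @export
setMethod("states", "KaryotypeSpace", function(x) x@states)

#' @rdname sequenceLength
#' @export
setMethod("sequenceLength", "Karyotype", function(x) sum(x@copies))
#' @rdname sequenceLength
#' @export
setMethod("sequenceLength", "matrix", function(x) rowSums(x))

#' @rdname totalDNAContent
#' @export
setMethod("totalDNAContent", signature("Karyotype", "missing"),
    function(x, units) sum(x@copies * x@units@length))
#' @rdname totalDNAContent
#' @export
setMethod("totalDNAContent", signature("Karyotype", "ChromosomeUnitSet"),
    function(x, units) {
        if (length(units@unitId) != length(x@copies))
            stop("unit set does not match karyotype dimension")
        sum(x@copies * units@length)
    })
#' @rdname totalDNAContent
#' @export
setMethod("totalDNAContent", signature("matrix", "ChromosomeUnitSet"),
    function(x, units) {
        if (ncol(x) != length(units@unitId))
            stop("unit set does not match profile matrix dimension")
        as.numeric(x %*% units@length)
    })

#' Enumerate the full karyotype state space
#'
#' All copy-number vectors in \{0..maxCopy\}^nUnits, in lexicographic order
#' with the first unit most significant (state 1 is the all-zero vector, the
#' last unit cycles fastest is FALSE: the last unit is least significant).
#' The order is deterministic and stable across runs.
#'
#' @param units a [ChromosomeUnitSet].
#' @param maxCopy per-unit copy cap (states above it are handled as escape
#'   mass by the transition kernel).
#' @param cap refuse to enumerate more than this many states; larger systems
#'   should use the error-class approximation of [thresholdScan].
#' @return a [KaryotypeSpace] of (maxCopy+1)^nUnits states.
#' @examples
#' space <- enumerateKaryotypeSpace(chromosomeUnits(c("a", "b")), maxCopy = 2)
#' nrow(states(space))  # 9
#' @export
enumerateKaryotypeSpace <- function(units, maxCopy, cap = 200000L) {
    nu <- length(units@unitId)
    stopifnot(nu >= 1, maxCopy >= 1)
    nStates <- (maxCopy + 1)^nu
    if (nStates > cap)
        stop("state space of ", nStates, " karyotypes exceeds cap ", cap,
            "; enlarge `cap` or use the error-class approximation")
    # lexicographic: first unit most significant
    grid <- expand.grid(rev(replicate(nu, 0:maxCopy, simplify = FALSE)),
        KEEP.OUT.ATTRS = FALSE)
    m <- as.matrix(grid[, rev(seq_len(nu)), drop = FALSE])
    dimnames(m) <- list(NULL, units@unitId)
    storage.mode(m) <- "integer"
    new("KaryotypeSpace", states = m, units = units,
        maxCopy = as.integer(maxCopy))
}

#' Locate a karyotype inside an enumerated space
#'
#' @param space a [KaryotypeSpace].
#' @param k a [Karyotype] or integer vector.
#' @return the row index of `k` in `states(space)`.
#' @export
stateIndex <- function(space, k) {
    v <- if (is(k, "Karyotype")) k@copies else as.integer(k)
    if (length(v) != ncol(space@states))
        stop("karyotype does not match the space's unit set")
    if (any(v < 0) || any(v > space@maxCopy))
        stop("karyotype lies outside the enumerated space")
    # lexicographic rank, first unit most significant
    base <- space@maxCopy + 1L
    idx <- as.integer(round(sum(v * base^((length(v) - 1):0)))) + 1L
    stopifnot(all(space@states[idx, ] == v))
    idx
}

#' Read / write a chromosome-unit table
#'
#' TSV with header `unit_id<TAB>length`, one row per unit.
#'
#' @param path file path.
#' @return `readUnitTable` returns a [ChromosomeUnitSet].
#' @export
readUnitTable <- function(path) {
    d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (!all(c("unit_id", "length") %in% names(d)))
        stop("unit table needs columns 'unit_id' and 'length'")
    chromosomeUnits(d$unit_id, d$length)
}

#' @rdname readUnitTable
#' @param units a [ChromosomeUnitSet] to write.
#' @export
writeUnitTable <- function(units, path) {
    d <- data.frame(unit_id = units@unitId, length = units@length)
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

setMethod("show", "ChromosomeUnitSet", function(object) {
    cat("ChromosomeUnitSet with", length(object@unitId), "units:",
        paste(head(object@unitId, 5), collapse = ", "),
        if (length(object@unitId) > 5) "..." else "", "\n")
})

setMethod("show", "Karyotype", function(object) {
    cat("Karyotype over", length(object@copies), "units; c_m =",
        sum(object@copies), "\n")
    print(setNames(object@copies, object@units@unitId))
})

setMethod("show", "KaryotypeSpace", function(object) {
    cat("KaryotypeSpace:", nrow(object@states), "states over",
        ncol(object@states), "units (maxCopy ", object@maxCopy, ")\n",
        sep = "")
})
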