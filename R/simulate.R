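#' Construct a cell population sample
#'
#' @param profiles integer matrix, cells in rows and units in columns (the
#'   on-disk TSV orientation); stored internally with units as rows.
#' @param units a [ChromosomeUnitSet].
#' @param site site label (e.g. "primary").
#' @param generation generation index of the sample.
#' @param seed RNG seed that produced the sample, if any.
#' @param ... further metadata entries.
#' @return a [CellPopulationSample].
#' @export
cellPopulationSample <- function(profiles, units, site = "sample",
        generation = NA_integer_, seed = NA_integer_, ...) {
    profiles <- as.matrix(profiles)
    if (ncol(profiles) != length(units@unitId))
        stop("profile matrix must have one column per declared unit")
    storage.mode(profiles) <- "integer"
    cp <- t(profiles)
    rownames(cp) <- units@unitId
    if (is.null(colnames(cp)))
        colnames(cp) <- sprintf("cell%03d", seq_len(ncol(cp)))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(copies = cp),
        rowData = S4Vectors::DataFrame(unit_id = units@unitId,
            length = units@length),
        metadata = list(site = site, generation = generation, seed = seed,
            ...))
    new("CellPopulationSample", se)
}

#' @rdname accessors
#' @export
setMethod("copyMatrix", "CellPopulationSample", function(x)
    t(SummarizedExperiment::assay(x, "copies")))

#' @rdname accessors
#' @export
setMethod("siteLabel", "CellPopulationSample", function(x)
    S4Vectors::metadata(x)$site)

#' @rdname accessors
#' @export
setMethod("unitIds", "CellPopulationSample", function(x)
    rownames(SummarizedExperiment::assay(x, "copies")))

#' @rdname sequenceLength
#' @export
setMethod("sequenceLength", "CellPopulationSample", function(x)
    colSums(SummarizedExperiment::assay(x, "copies")))

#' @rdname totalDNAContent
#' @export
setMethod("totalDNAContent", signature("CellPopulationSample", "missing"),
    function(x, units) {
        as.numeric(SummarizedExperiment::rowData(x)$length %*%
            SummarizedExperiment::assay(x, "copies"))
    })

setMethod("show", "CellPopulationSample", function(object) {
    cat("CellPopulationSample:", ncol(object), "cells x", nrow(object),
        "units; site =", S4Vectors::metadata(object)$site,
        "; generation =", S4Vectors::metadata(object)$generation, "\n")
    cs <- sequenceLength(object)
    cat("  sequence length c_m: median", median(cs), ", range [",
        min(cs), ",", max(cs), "]\n")
})

#' Copy-number fitness function for finite-population simulation
#'
#' Returns a function mapping a profile matrix (cells x units) to
#' non-negative fitness values: `AMaster` for cells matching the master
#' karyotype (when given), `AMutant` otherwise; zero for cells with a
#' nullisomic unit (when `lethalOnNullisomy`) or with any unit above
#' `maxCopy` — excess copies are treated as lethal rather than clipped, so
#' no probability mass is silently distorted. With `master = NULL` or
#' `AMaster == AMutant` the landscape is flat apart from the viability
#' constraints.
#'
#' @param master optional master [Karyotype].
#' @param AMaster,AMutant growth rates.
#' @param lethalOnNullisomy zero fitness for cells that lost all copies of
#'   a unit.
#' @param maxCopy per-unit viability cap (default 8).
#' @return function(matrix) -> numeric vector of fitness values.
#' @export
cnFitness <- function(master = NULL, AMaster = 1, AMutant = 1,
        lethalOnNullisomy = TRUE, maxCopy = 8L) {
    masterCopies <- if (is.null(master)) NULL else as.integer(master@copies)
    function(profiles) {
        fit <- rep(as.numeric(AMutant), nrow(profiles))
        if (!is.null(masterCopies)) {
            isMaster <- colSums(t(profiles) != masterCopies) == 0
            fit[isMaster] <- AMaster
        }
        if (lethalOnNullisomy)
            fit[rowSums(profiles == 0L) > 0] <- 0
        fit[rowSums(profiles > maxCopy) > 0] <- 0
        fit
    }
}

# Apply the per-copy error model to every cell of a profile matrix.
# Each of the n copies errs independently with probability E; an error is
# a gain with probability g, else a loss: child = n + gains - losses.
.mutateProfiles <- function(profiles, kernel) {
    n <- as.vector(profiles)
    errs <- rbinom(length(n), n, kernel@perCopyError)
    gains <- rbinom(length(n), errs, kernel@gainBias)
    child <- n + 2L * gains - errs
    matrix(as.integer(child), nrow = nrow(profiles),
        dimnames = dimnames(profiles))
}

#' Advance a population one Wright-Fisher generation
#'
#' Non-overlapping generations: `N` offspring cells are produced by
#' fitness-weighted multinomial sampling of parents, and each offspring
#' karyotype is drawn from the replication kernel applied to its parent.
#' Deterministic given the R RNG state (seed it, or use
#' [simulatePopulation]).
#'
#' @param pop a [CellPopulationSample].
#' @param kernel a [ReplicationKernel].
#' @param fitness a function(profiles matrix) -> non-negative numeric, e.g.
#'   from [cnFitness].
#' @param N offspring population size (default: keep the current size).
#' @return a [CellPopulationSample] at the next generation.
#' @export
wrightFisherGeneration <- function(pop, kernel, fitness, N = ncol(pop)) {
    stopifnot(N >= 1)
    profiles <- copyMatrix(pop)
    fit <- fitness(profiles)
    if (any(fit < 0)) stop("fitness values must be non-negative")
    if (sum(fit) <= 0)
        stop("population extinct: all cells have zero fitness")
    parents <- sample.int(nrow(profiles), N, replace = TRUE, prob = fit)
    offspring <- .mutateProfiles(profiles[parents, , drop = FALSE], kernel)
    rownames(offspring) <- sprintf("cell%03d", seq_len(N))
    md <- S4Vectors::metadata(pop)
    cellPopulationSample(offspring,
        chromosomeUnits(unitIds(pop), SummarizedExperiment::rowData(pop)$length),
        site = md$site,
        generation = if (is.na(md$generation)) 1L else md$generation + 1L,
        seed = md$seed)
}

#' Simulate karyotype evolution in a finite population
#'
#' Evolves `N` copies of the founder karyotype for `generations`
#' Wright-Fisher generations under the per-copy error model, logging a
#' per-generation summary (mean L1 distance to the founder and mean total
#' DNA content). Identical seed and parameters give byte-identical output.
#'
#' @param founder founder [Karyotype].
#' @param kernel a [ReplicationKernel].
#' @param fitness fitness function from [cnFitness] (default: flat with
#'   nullisomy and copy-cap lethality).
#' @param N population size.
#' @param generations number of generations.
#' @param seed RNG seed.
#' @param site site label recorded in the sample.
#' @return a [CellPopulationSample] of the final generation; metadata
#'   entries `founder` and `summary` (data.frame: generation,
#'   mean_l1_to_founder, mean_dna_content).
#' @export
simulatePopulation <- function(founder, kernel, fitness = cnFitness(),
        N = 500, generations = 12, seed = 1, site = "sample") {
    set.seed(seed)
    .evolve(founder, founder@units, kernel, fitness, N, generations, site,
        seed)
}

# Core evolution loop on raw matrices; RNG state is the caller's.
.evolve <- function(founder, units, kernel, fitness, N, generations, site,
        seed) {
    founderCopies <- if (is(founder, "Karyotype")) founder@copies
        else as.integer(founder)
    profiles <- matrix(rep(founderCopies, each = N), nrow = N,
        dimnames = list(NULL, units@unitId))
    storage.mode(profiles) <- "integer"
    summ <- data.frame(generation = seq_len(generations),
        mean_l1_to_founder = NA_real_, mean_dna_content = NA_real_)
    for (g in seq_len(generations)) {
        fit <- fitness(profiles)
        if (sum(fit) <= 0)
            stop("population extinct at generation ", g,
                ": all cells have zero fitness")
        parents <- sample.int(N, N, replace = TRUE, prob = fit)
        profiles <- .mutateProfiles(profiles[parents, , drop = FALSE],
            kernel)
        summ$mean_l1_to_founder[g] <-
            mean(rowSums(abs(sweep(profiles, 2, founderCopies))))
        summ$mean_dna_content[g] <- mean(profiles %*% units@length)
    }
    rownames(profiles) <- sprintf("cell%03d", seq_len(N))
    cellPopulationSample(profiles, units, site = site,
        generation = generations, seed = seed,
        founder = founderCopies, summary = summ)
}

#' Generate a synthetic primary/metastasis two-site dataset
#'
#' Emulates a metastasis proliferating from a single cell of the aneuploid
#' subpopulation of a primary tumour, with the two sites evolving at
#' different aneuploidy rates. The primary population grows from the
#' founder at `EPrimary`; one primary cell (preferring cells that differ
#' from the founder, i.e. the aneuploid subpopulation) then seeds the
#' metastatic population, which evolves at `EMetastatic`; `nCells` cells
#' are sampled from each site without replacement. The returned truth
#' metadata records both error rates and the seed, for parameter-recovery
#' tests.
#'
#' Defaults are the package's reference study conditions: diploid founder
#' over 23 units, `N = 500`, 12 generations per site, 100 cells sampled,
#' `EPrimary = 0.02`, `EMetastatic = 0.1` (both inside the measured cancer
#' range 1e-3..1e-1; ratio 5).
#'
#' @param founder founder [Karyotype].
#' @param EPrimary,EMetastatic per-copy error rates at the two sites.
#' @param generations generations per site.
#' @param N population size per site.
#' @param nCells cells sampled per site (<= N).
#' @param seed RNG seed; the whole dataset is reproducible from it.
#' @param gainBias gain fraction of errors.
#' @param fitness fitness function (default flat with viability
#'   constraints).
#' @param diploidSpikeIn fraction of sampled cells per site replaced by
#'   normal diploid (founder) cells, emulating stromal contamination.
#' @return list of class `TwoSiteDataset`: `primary` and `metastasis`
#'   ([CellPopulationSample]s of the sampled cells) and `truth` (list:
#'   `EPrimary`, `EMetastatic`, `seed`, `generations`, `N`, `nCells`,
#'   `founder`).
#' @export
generateTwoSiteDataset <- function(founder = diploidKaryotype(),
        EPrimary = 0.02, EMetastatic = 0.1, generations = 12, N = 500,
        nCells = 100, seed = 1, gainBias = 0.5, fitness = cnFitness(),
        diploidSpikeIn = 0) {
    stopifnot(EPrimary >= 0, EPrimary < 1, EMetastatic >= 0,
        EMetastatic < 1, nCells <= N, diploidSpikeIn >= 0,
        diploidSpikeIn < 1)
    set.seed(seed)
    units <- founder@units
    primary <- .evolve(founder, units, replicationKernel(EPrimary, gainBias),
        fitness, N, generations, "primary", seed)
    pProfiles <- copyMatrix(primary)
    viable <- which(fitness(pProfiles) > 0)
    if (!length(viable))
        stop("no viable cell in the primary population to seed a metastasis")
    aneuploid <- viable[rowSums(abs(sweep(pProfiles[viable, , drop = FALSE],
        2, founder@copies))) > 0]
    pool <- if (length(aneuploid)) aneuploid else viable
    seedCell <- pool[sample.int(length(pool), 1)]
    metFounder <- pProfiles[seedCell, ]
    metastasis <- .evolve(metFounder, units,
        replicationKernel(EMetastatic, gainBias), fitness, N, generations,
        "metastasis", seed)
    subsample <- function(pop, site) {
        profiles <- copyMatrix(pop)[sample.int(N, nCells), , drop = FALSE]
        if (diploidSpikeIn > 0) {
            k <- round(diploidSpikeIn * nCells)
            if (k > 0)
                profiles[seq_len(k), ] <- rep(founder@copies, each = k)
        }
        rownames(profiles) <- sprintf("%s_cell%03d", site,
            seq_len(nCells))
        cellPopulationSample(profiles, units, site = site,
            generation = generations, seed = seed,
            founder = founder@copies)
    }
    structure(list(
        primary = subsample(primary, "primary"),
        metastasis = subsample(metastasis, "metastasis"),
        truth = list(EPrimary = EPrimary, EMetastatic = EMetastatic,
            seed = seed, generations = generations, N = N,
            nCells = nCells, founder = founder@copies,
            metastasisFounder = as.integer(metFounder),
            diploidSpikeIn = diploidSpikeIn)),
        class = "TwoSiteDataset")
}

#' @export
print.TwoSiteDataset <- function(x, ...) {
    cat("TwoSiteDataset: E_primary =", x$truth$EPrimary,
        ", E_metastatic =", x$truth$EMetastatic,
        ", seed =", x$truth$seed, "\n")
    show(x$primary)
    show(x$metastasis)
    invisible(x)
}
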