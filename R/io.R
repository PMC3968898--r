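#' Read a copy-number matrix file
#'
#' TSV with header `cell_id` then unit identifiers, one row per cell,
#' non-negative integer entries. Cell order is preserved; negative,
#' non-integer or missing entries are rejected with the offending row and
#' column named; ragged rows are a format error.
#'
#' @param path file path.
#' @return integer matrix (cells x units) with cell ids as rownames and
#'   unit ids as colnames.
#' @export
readCNMatrix <- function(path) {
    lines <- readLines(path)
    if (!length(lines)) stop("empty copy-number file: ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    header <- fields[[1]]
    if (header[1] != "cell_id")
        stop("first header column must be 'cell_id'")
    unitIds <- header[-1]
    nu <- length(unitIds)
    body <- fields[-1]
    if (!length(body)) {
        m <- matrix(integer(0), nrow = 0, ncol = nu,
            dimnames = list(NULL, unitIds))
        return(m)
    }
    widths <- lengths(body)
    if (any(widths != nu + 1))
        stop("ragged row ", which(widths != nu + 1)[1] + 1,
            ": expected ", nu + 1, " fields")
    cells <- vapply(body, `[`, character(1), 1)
    vals <- t(vapply(body, function(f) f[-1], character(nu)))
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(is.na(num) | num < 0 | num != round(num))
    if (length(bad)) {
        r <- (bad[1] - 1) %% nrow(vals) + 1
        cl <- (bad[1] - 1) %/% nrow(vals) + 1
        stop("invalid copy number '", vals[bad[1]], "' at cell '",
            cells[r], "', unit '", unitIds[cl],
            "': entries must be non-negative integers")
    }
    m <- matrix(as.integer(num), nrow = length(cells), ncol = nu,
        dimnames = list(cells, unitIds))
    m
}

#' Write a copy-number matrix file
#'
#' Inverse of [readCNMatrix]: TSV with a `cell_id` column then one column
#' per unit, newline-terminated, stable column order, deterministic bytes
#' for identical input.
#'
#' @param m integer matrix (cells x units) or [CellPopulationSample].
#' @param path output path.
#' @param unitIds column labels; defaults to `colnames(m)`.
#' @return `path`, invisibly.
#' @export
writeCNMatrix <- function(m, path, unitIds = NULL) {
    if (is(m, "CellPopulationSample")) m <- copyMatrix(m)
    m <- as.matrix(m)
    if (any(m != round(m)) || any(m < 0))
        stop("copy numbers must be non-negative integers")
    if (is.null(unitIds)) unitIds <- colnames(m, do.NULL = FALSE,
        prefix = "unit")
    cells <- rownames(m)
    if (is.null(cells)) cells <- sprintf("cell%03d", seq_len(nrow(m)))
    con <- file(path, "wb")  # binary mode: LF endings on every platform
    on.exit(close(con))
    writeLines(c(paste(c("cell_id", unitIds), collapse = "\t"),
        if (nrow(m)) paste(cells, apply(m, 1, paste, collapse = "\t"),
            sep = "\t")), con, sep = "\n")
    invisible(path)
}

#' Read a run configuration file
#'
#' YAML (or key: value) configuration with a strict schema: unknown keys
#' are rejected, every value is validated against its documented domain.
#' Recognized keys: `per_copy_error`, `gain_bias`, `A_master`, `A_mutant`,
#' `D`, `lethal_on_nullisomy`, `max_copy`, `n_units`, `founder`,
#' `E_primary`, `E_metastatic`, `generations`, `pop_size`, `n_cells`, `seed`,
#' `e_min`, `e_max`, `e_steps`, `units_file`.
#'
#' @param path configuration file path.
#' @return named list of validated parameters.
#' @export
readRunConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg)) cfg <- list()
    schema <- list(
        per_copy_error = function(v) v >= 0 && v <= 1,
        gain_bias = function(v) v >= 0 && v <= 1,
        A_master = function(v) v >= 0,
        A_mutant = function(v) v >= 0,
        D = function(v) v >= 0,
        lethal_on_nullisomy = is.logical,
        max_copy = function(v) v == round(v) && v >= 1,
        n_units = function(v) v == round(v) && v >= 1,
        founder = function(v) all(v == round(v)) && all(v >= 0),
        E_primary = function(v) v >= 0 && v < 1,
        E_metastatic = function(v) v >= 0 && v < 1,
        generations = function(v) v == round(v) && v >= 1,
        pop_size = function(v) v == round(v) && v >= 1,
        n_cells = function(v) v == round(v) && v >= 1,
        seed = function(v) v == round(v),
        e_min = function(v) v >= 0 && v < 1,
        e_max = function(v) v >= 0 && v < 1,
        e_steps = function(v) v == round(v) && v >= 2,
        units_file = is.character)
    unknown <- setdiff(names(cfg), names(schema))
    if (length(unknown))
        stop("unknown configuration key(s): ",
            paste(unknown, collapse = ", "))
    for (k in names(cfg))
        if (!isTRUE(schema[[k]](cfg[[k]])))
            stop("configuration key '", k, "' outside its domain: ",
                deparse(cfg[[k]]))
    cfg
}
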