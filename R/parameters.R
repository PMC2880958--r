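#' Construct run parameters
#'
#' Defaults are the medium-panel settings that the search is normally run
#' with (1000 ants, two rounds of 150 and 300 iterations at set sizes 6 and
#' 3, `alpha = 1`, `rho = 0.05`, `tau0 = 100`, 1000 retained top sets, 200
#' top-pheromone loci, reporting threshold 0.01).  Use
#' [suggestParameters()] to scale the iteration counts, ant count and
#' evaporation rate to the panel size.
#'
#' @param iAntCount ants per iteration.
#' @param iItCountLarge,iItCountSmall iterations of the large-set and
#'   small-set first-stage rounds.
#' @param alpha pheromone exponent (nonnegative).
#' @param iTopModel number of top-chi-square sets retained per round.
#' @param iTopLoci size of the top-pheromone locus set used in stage two.
#' @param rho pheromone evaporation rate, in (0, 1).
#' @param tau0 initial pheromone level (positive).
#' @param largesetsize,smallsetsize SNP-set sizes of the two rounds; both
#'   must exceed `iEpiModel`.
#' @param iEpiModel number of loci in a reported interaction (>= 2).
#' @param pvalue raw per-test reporting threshold.
#' @param inpFile,outFile input panel and user output file paths.
#' @return a validated [EpiParams-class] object.
#' @export
epiParams <- function(iAntCount = 1000, iItCountLarge = 150,
                      iItCountSmall = 300, alpha = 1, iTopModel = 1000,
                      iTopLoci = 200, rho = 0.05, tau0 = 100,
                      largesetsize = 6, smallsetsize = 3, iEpiModel = 2,
                      pvalue = 0.01, inpFile = NA_character_,
                      outFile = "results.txt") {
    obj <- new("EpiParams",
               iAntCount = as.integer(iAntCount),
               iItCountLarge = as.integer(iItCountLarge),
               iItCountSmall = as.integer(iItCountSmall),
               alpha = as.numeric(alpha),
               iTopModel = as.integer(iTopModel),
               iTopLoci = as.integer(iTopLoci),
               rho = as.numeric(rho), tau0 = as.numeric(tau0),
               largesetsize = as.integer(largesetsize),
               smallsetsize = as.integer(smallsetsize),
               iEpiModel = as.integer(iEpiModel),
               pvalue = as.numeric(pvalue),
               inpFile = as.character(inpFile),
               outFile = as.character(outFile))
    validObject(obj)
    obj
}

setMethod("show", "EpiParams", function(object) {
    cat("EpiParams:\n")
    for (nm in slotNames(object))
        cat(sprintf("  %-14s %s\n", nm, as.character(slot(object, nm))))
})

.paramKeys <- c(iantcount = "iAntCount", iitcountlarge = "iItCountLarge",
                iitcountsmall = "iItCountSmall", alpha = "alpha",
                itopmodel = "iTopModel", itoploci = "iTopLoci",
                rho = "rho", tau0 = "tau0", largesetsize = "largesetsize",
                smallsetsize = "smallsetsize", iepimodel = "iEpiModel",
                pvalue = "pvalue", inpfile = "inpFile", outfile = "outFile")

#' Read a parameters file
#'
#' One `name value` pair per line, in any order; blank lines and `#`
#' comments are ignored; names are matched case-insensitively.  Recognized
#' names are `iAntCount`, `iItCountLarge`, `iItCountSmall`, `alpha`,
#' `iTopModel`, `iTopLoci`, `rho`, `tau0`, `largesetsize`, `smallsetsize`,
#' `iEpiModel`, `pvalue`, `INPFILE` and `OUTFILE`.  Missing names take the
#' [epiParams()] defaults.
#'
#' @param path path to the parameters file (conventionally
#'   `parameters.txt`).
#' @return a validated [EpiParams-class] object.
#' @export
readParameters <- function(path) {
    if (!file.exists(path))
        stop("parameters file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    args <- list()
    for (ln in lines) {
        parts <- strsplit(ln, "[ \t]+")[[1L]]
        if (length(parts) != 2L)
            stop("malformed parameter line (expected 'name value'): ", ln)
        key <- .paramKeys[tolower(parts[1L])]
        if (is.na(key))
            stop("unknown parameter name: ", parts[1L])
        val <- if (key %in% c("inpFile", "outFile")) parts[2L]
               else {
                   v <- suppressWarnings(as.numeric(parts[2L]))
                   if (is.na(v))
                       stop(sprintf("parameter %s has non-numeric value: %s",
                                    parts[1L], parts[2L]))
                   v
               }
        args[[key]] <- val
    }
    do.call(epiParams, args)
}

#' Suggest run parameters from the panel size
#'
#' Applies the scaling rules the search is calibrated with:
#' `iItCountSmall = ceiling(0.1 * L)`, `iItCountLarge` half of that, the
#' ant count between 500 and 5000 growing with `L`, and the evaporation
#' rate between 0.01 and 0.1 shrinking with `L` (smaller panels need faster
#' evaporation).  Set sizes are 6/3 for pairwise interactions and 6/4 for
#' three-locus interactions.
#'
#' @param L number of SNPs in the panel.
#' @param iEpiModel interaction order (default 2).
#' @param ... further arguments passed to [epiParams()] to override
#'   individual suggestions.
#' @return a validated [EpiParams-class] object.
#' @examples
#' suggestParameters(2000)
#' @export
suggestParameters <- function(L, iEpiModel = 2, ...) {
    stopifnot(L >= 1)
    small <- max(1L, as.integer(ceiling(0.1 * L)))
    large <- max(1L, as.integer(round(0.5 * small)))
    args <- list(iItCountSmall = small,
                 iItCountLarge = large,
                 iAntCount = min(5000L, max(500L, as.integer(round(L / 2)))),
                 rho = min(0.1, max(0.01, 100 / L)),
                 largesetsize = max(6L, iEpiModel + 2L),
                 smallsetsize = iEpiModel + 1L,
                 iEpiModel = iEpiModel)
    over <- list(...)
    args[names(over)] <- over
    do.call(epiParams, args)
}
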