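#' Minimize false positives by overlap pruning
#'
#' Greedy pass over the detected interactions, taken in ascending p-value
#' order (ties broken by lexicographic locus order).  An interaction that
#' shares no locus with anything already accepted is added.  One that
#' overlaps existing member(s) replaces them only when its p-value is
#' smaller than every overlapped member's; otherwise it is dropped.  Under
#' the ascending-p processing order the result contains no two
#' interactions sharing a locus, and the best interaction always survives.
#'
#' @param EIall interaction data frame (as produced by [stageTwo()] or
#'   [exhaustiveScan()]), with `locus*` and `pvalue` columns.
#' @return the pruned interaction data frame (`EI_m`).
#' @examples
#' ei <- data.frame(SNP1 = c("A", "B"), SNP2 = c("B", "C"),
#'                  chi2 = c(30, 20), df = 1, pvalue = c(1e-6, 1e-4),
#'                  locus1 = c(1, 2), locus2 = c(2, 3))
#' minimizeFalsePositives(ei)  # only (A, B) survives
#' @export
minimizeFalsePositives <- function(EIall) {
    lc <- grep("^locus[0-9]+$", names(EIall))
    if (!length(lc))
        stop("interaction frame lacks locus columns")
    if (nrow(EIall) == 0L)
        return(EIall)
    o <- do.call(order, c(list(EIall$pvalue), EIall[lc]))
    EIall <- EIall[o, , drop = FALSE]
    loci <- as.matrix(EIall[lc])
    p <- EIall$pvalue
    kept <- integer(0)          # row indices currently in EI_m
    owner <- list()             # per kept row, its locus vector
    for (i in seq_len(nrow(EIall))) {
        li <- loci[i, ]
        over <- which(vapply(owner, function(x) any(x %in% li), logical(1L)))
        if (!length(over)) {
            kept <- c(kept, i)
            owner <- c(owner, list(li))
        } else if (all(p[i] < p[kept[over]])) {
            kept <- c(kept[-over], i)
            owner <- c(owner[-over], list(li))
        }                        # else: dropped, not reported
    }
    out <- EIall[sort(kept), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Write the three output files
#'
#' Writes `AntEpiSeeker.log` (full parameter echo, per-iteration best
#' chi-square of both first-stage rounds, and counts), the file
#' `results_maximized.txt` holding all detected interactions, and the
#' user-specified output file (`params@outFile`) holding the interactions
#' after false-positive minimization.  Interaction rows are tab-delimited:
#' SNP names, chi-square and p-value.
#'
#' @param EIall,EIm interaction data frames.
#' @param harvest a [StageOneResult-class] object (for the log), or `NULL`.
#' @param params the [EpiParams-class] object used for the run.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths of the three files.
#' @export
writeResults <- function(EIall, EIm, harvest, params, dir = ".") {
    if (!dir.exists(dir) &&
        !suppressWarnings(dir.create(dir, recursive = TRUE)))
        stop("cannot create output directory: ", dir)
    writeTable <- function(ei, path) {
        keep <- grep("^(SNP[0-9]+|chi2|pvalue)$", names(ei), value = TRUE)
        ok <- tryCatch({
            write.table(ei[keep], path, sep = "\t", quote = FALSE,
                        row.names = FALSE)
            TRUE
        }, error = function(e) FALSE)
        if (!ok)
            stop("cannot write output file: ", path)
        path
    }
    allPath <- writeTable(EIall, file.path(dir, "results_maximized.txt"))
    outPath <- writeTable(EIm, file.path(dir, params@outFile))
    logPath <- file.path(dir, "AntEpiSeeker.log")
    con <- tryCatch(file(logPath, "w"), error = function(e)
        stop("cannot write output file: ", logPath))
    on.exit(close(con))
    cat("AntEpiSeeker run log\n", file = con)
    cat("parameters:\n", file = con)
    for (nm in slotNames(params))
        cat(sprintf("  %s = %s\n", nm, as.character(slot(params, nm))),
            file = con)
    if (!is.null(harvest)) {
        cat("best chi2 per iteration (large-set round):\n", file = con)
        cat(sprintf("  %d\t%.4f\n", seq_along(harvest@historyLarge),
                    harvest@historyLarge), sep = "", file = con)
        cat("best chi2 per iteration (small-set round):\n", file = con)
        cat(sprintf("  %d\t%.4f\n", seq_along(harvest@historySmall),
                    harvest@historySmall), sep = "", file = con)
        cat(sprintf("suspected sets: %d\n", length(harvest@sets)),
            file = con)
        cat(sprintf("top-pheromone loci: %d\n", length(harvest@topLoci)),
            file = con)
    }
    cat(sprintf("interactions detected: %d\n", nrow(EIall)), file = con)
    cat(sprintf("interactions after minimizing false positives: %d\n",
                nrow(EIm)), file = con)
    invisible(c(log = logPath, all = allPath, minimized = outPath))
}
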