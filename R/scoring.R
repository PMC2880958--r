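#' Genotype-combination by status contingency table
#'
#' Cross-tabulates the joint genotype combination at a set of loci against
#' case/control status.  Only combinations observed in at least one sample
#' appear as rows, so a table for `n` loci has at most `3^n` rows.
#'
#' @param G a [GenotypeData-class] panel.
#' @param loci integer vector of distinct locus indices (1-based).
#' @return integer matrix with one row per observed combination (row names
#'   give the genotype codes, e.g. `"0/2"`), columns `control` and `case`,
#'   and attribute `setSize` = `length(loci)`.
#' @examples
#' gd <- genotypeData(matrix(c(0L, 0L, 1L), ncol = 1,
#'                           dimnames = list(NULL, "S1")),
#'                    status = c(0, 1, 1))
#' contingencyTable(gd, 1)
#' @export
contingencyTable <- function(G, loci) {
    stopifnot(is(G, "GenotypeData"))
    loci <- as.integer(loci)
    if (length(loci) < 1L)
        stop("at least one locus is required")
    if (anyDuplicated(loci))
        stop("loci must be distinct")
    if (any(loci < 1L) || any(loci > nSnps(G)))
        stop("locus index out of range")
    n <- length(loci)
    key <- integer(nSamples(G))
    for (l in loci)
        key <- key * 3L + G@geno[, l]
    ncell <- 3L^n
    st <- G@status
    c0 <- tabulate(key[st == 0L] + 1L, nbins = ncell)
    c1 <- tabulate(key[st == 1L] + 1L, nbins = ncell)
    obs <- which(c0 + c1 > 0L)
    tab <- cbind(control = c0[obs], case = c1[obs])
    combos <- vapply(obs - 1L, function(k) {
        digits <- integer(n)
        for (d in n:1) {
            digits[d] <- k %% 3L
            k <- k %/% 3L
        }
        paste(digits, collapse = "/")
    }, character(1L))
    rownames(tab) <- combos
    attr(tab, "setSize") <- n
    tab
}

#' Pearson chi-square score of a contingency table
#'
#' Computes the plain Pearson chi-square statistic over the observed
#' `K x 2` cells, with expected counts from the row and column margins and
#' `df = K - 1` (no continuity correction, no expected-count filter).
#' Degenerate tables -- a single observed combination, or an empty status
#' column -- score `chi2 = 0`, `p = 1`.
#'
#' @param table a `K x 2` count matrix as returned by
#'   [contingencyTable()] (columns: controls, cases).
#' @return list with elements `chi2`, `df` and `pvalue` (upper-tail
#'   chi-square probability).
#' @examples
#' chi2Score(cbind(control = c(10, 0), case = c(0, 10)))  # chi2 = 20
#' @export
chi2Score <- function(table) {
    table <- as.matrix(table)
    stopifnot(ncol(table) == 2L, all(table >= 0))
    keep <- rowSums(table) > 0
    table <- table[keep, , drop = FALSE]
    K <- nrow(table)
    cs <- colSums(table)
    if (K < 2L || any(cs == 0))
        return(list(chi2 = 0, df = max(1L, K - 1L), pvalue = 1))
    E <- outer(rowSums(table), cs) / sum(table)
    chi2 <- sum((table - E)^2 / E)
    df <- K - 1L
    list(chi2 = chi2, df = df,
         pvalue = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Score many SNP sets at once
#'
#' Vectorized equivalent of [contingencyTable()] plus [chi2Score()] for a
#' batch of equally sized locus sets; this is the scoring path used inside
#' the ACO engine and the stage-two exhaustive search.
#'
#' @param G a [GenotypeData-class] panel.
#' @param sets integer matrix, one locus set per row.
#' @return list of numeric vectors `chi2`, integer `df`, numeric `pvalue`.
#' @export
scoreSnpSets <- function(G, sets) {
    stopifnot(is(G, "GenotypeData"), is.matrix(sets))
    storage.mode(sets) <- "integer"
    sc <- .scoreSetsCpp(G@geno, G@status, sets)
    sc$pvalue <- stats::pchisq(sc$chi2, sc$df, lower.tail = FALSE)
    sc
}

#' Exhaustive scan of all locus combinations
#'
#' Scores every combination of `order` loci with the chi-square test and
#' returns those below the p-value threshold.  The number of combinations
#' grows as `choose(L, order)` -- about 5.00e9 pairs for 100,000 SNPs --
#' so the scan refuses panels whose combination count exceeds `maxCombos`.
#'
#' @param G a [GenotypeData-class] panel.
#' @param order interaction order, 2 or 3.
#' @param threshold keep combinations with `pvalue < threshold`;
#'   `threshold = 1` keeps every combination.
#' @param maxCombos refuse the scan above this many combinations.
#' @return a data frame of interactions, sorted by ascending p-value with
#'   ties broken by locus order: columns `SNP1..SNPn` (names), `chi2`,
#'   `df`, `pvalue`, `locus1..locusn` (indices).
#' @seealso [antEpiSeeker()] for the search that avoids this cost.
#' @export
exhaustiveScan <- function(G, order = 2, threshold = 1, maxCombos = 1e7) {
    stopifnot(is(G, "GenotypeData"))
    order <- as.integer(order)
    if (!order %in% c(2L, 3L))
        stop("only pairwise (2) and three-locus (3) scans are supported")
    L <- nSnps(G)
    nC <- choose(L, order)
    if (nC > maxCombos)
        stop(sprintf(
            "refusing exhaustive scan: %.3g combinations of %d loci exceed maxCombos = %.3g",
            nC, order, maxCombos))
    if (order == 2L) {
        sc <- .pairScanCpp(G@geno, G@status)
        sets <- cbind(sc$locus1, sc$locus2)
        chi2 <- sc$chi2
        df <- sc$df
    } else {
        sets <- t(combn(L, order))
        storage.mode(sets) <- "integer"
        sc <- .scoreSetsCpp(G@geno, G@status, sets)
        chi2 <- sc$chi2
        df <- sc$df
    }
    pvalue <- stats::pchisq(chi2, df, lower.tail = FALSE)
    keep <- if (threshold >= 1) rep(TRUE, length(pvalue))
            else pvalue < threshold
    interactionFrame(G, sets[keep, , drop = FALSE], chi2[keep], df[keep],
                     pvalue[keep])
}

#' Assemble an interaction table
#'
#' Internal helper shared by the scans: builds the standard interaction
#' data frame (SNP names, chi-square, df, p-value, locus indices) sorted by
#' ascending p-value with lexicographic locus order as tie-break.
#'
#' @noRd
interactionFrame <- function(G, sets, chi2, df, pvalue) {
    n <- ncol(sets)
    nm <- snpNames(G)
    out <- data.frame(matrix(nm[sets], ncol = n,
                             dimnames = list(NULL, paste0("SNP", seq_len(n)))),
                      chi2 = as.numeric(chi2), df = as.integer(df),
                      pvalue = as.numeric(pvalue),
                      stringsAsFactors = FALSE)
    loc <- as.data.frame(sets)
    names(loc) <- paste0("locus", seq_len(n))
    out <- cbind(out, loc)
    o <- do.call(order, c(list(out$pvalue), loc))
    out <- out[o, , drop = FALSE]
    rownames(out) <- NULL
    out
}
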