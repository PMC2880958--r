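#' Locus selection probabilities
#'
#' The probability of an ant picking locus `k` is
#' `tau_k^alpha * eta_k / sum_j tau_j^alpha * eta_j`, where `tau` are the
#' current pheromone levels and `eta` is prior information per locus
#' (all 1 by default: every locus is treated equally).
#'
#' @param tau numeric vector of positive pheromone levels.
#' @param alpha nonnegative pheromone exponent.
#' @param eta optional positive prior weights (default all 1).
#' @return numeric probability vector summing to 1.
#' @examples
#' selectionProbabilities(c(2, 1, 1))  # 0.5 0.25 0.25
#' @export
selectionProbabilities <- function(tau, alpha = 1, eta = NULL) {
    stopifnot(all(tau > 0), alpha >= 0)
    if (is.null(eta))
        eta <- rep(1, length(tau))
    stopifnot(length(eta) == length(tau), all(eta > 0))
    w <- tau^alpha * eta
    w / sum(w)
}

#' Sample a SNP set without replacement
#'
#' Draws `n` distinct loci sequentially, each draw proportional to the
#' remaining loci's probabilities (sequential renormalization).  Uses the
#' R random number generator, so results are reproducible under
#' [set.seed()].
#'
#' @param probs probability vector over loci.
#' @param n set size (`n <= length(probs)`).
#' @return sorted integer vector of `n` distinct locus indices.
#' @export
sampleSnpSet <- function(probs, n) {
    stopifnot(n >= 1, all(probs >= 0))
    if (n > length(probs) || sum(probs > 0) < n)
        stop("cannot sample ", n, " distinct loci from ",
             sum(probs > 0), " with positive probability")
    as.integer(.sampleSetsCpp(as.numeric(probs), as.integer(n), 1L)[1L, ])
}

#' Pheromone update
#'
#' Applies one synchronous update: evaporation
#' `tau' = (1 - rho) * tau` followed by the deposits of all ants of the
#' iteration, where each locus in an ant's set `S_m` receives
#' `0.1 * chi2(S_m)` and loci outside the set receive nothing.
#'
#' @param tau numeric vector of current pheromone levels.
#' @param sets the ants' locus sets: an integer matrix (one set per row) or
#'   a list of integer vectors.
#' @param chi2 numeric vector of the sets' chi-square scores.
#' @param rho evaporation rate in (0, 1).
#' @return updated pheromone vector.
#' @examples
#' updatePheromones(rep(100, 3), matrix(c(1L, 2L), nrow = 1),
#'                  chi2 = 50, rho = 0.05)  # 100 100 95
#' @export
updatePheromones <- function(tau, sets, chi2, rho) {
    stopifnot(rho > 0, rho < 1, all(chi2 >= 0))
    if (is.list(sets))
        sets <- do.call(rbind, sets)
    tau2 <- (1 - rho) * tau
    if (length(chi2)) {
        stopifnot(nrow(sets) == length(chi2))
        dep <- rowsum(rep(0.1 * chi2, ncol(sets)), as.vector(sets))
        idx <- as.integer(rownames(dep))
        tau2[idx] <- tau2[idx] + dep[, 1L]
    }
    tau2
}

#' Run the generic ant colony optimization
#'
#' Iterative pheromone-guided search for high-scoring SNP sets.  Each
#' iteration computes the selection probabilities once, samples
#' `iAntCount` sets of `setSize` loci, scores each with the chi-square
#' test, and applies one synchronous pheromone update (evaporation plus
#' the summed deposits of all ants).  The best distinct sets seen anywhere
#' in the run are retained, at most `iTopModel` of them (every distinct
#' set when `keepAll = TRUE`, which is how the generic-ACO baseline
#' reports all sampled sets).
#'
#' @param G a [GenotypeData-class] panel.
#' @param setSize number of loci per sampled set.
#' @param iterations number of iterations (>= 1).
#' @param params an [EpiParams-class] object supplying `iAntCount`,
#'   `alpha`, `rho`, `tau0` and `iTopModel`.
#' @param keepAll retain every distinct sampled set instead of the top
#'   `iTopModel`.
#' @return an [AcoResult-class] object.
#' @export
runAco <- function(G, setSize, iterations, params, keepAll = FALSE) {
    stopifnot(is(G, "GenotypeData"), is(params, "EpiParams"),
              iterations >= 1)
    L <- nSnps(G)
    n <- as.integer(setSize)
    if (n > L)
        stop("set size ", n, " exceeds the number of SNPs ", L)
    tau <- rep(params@tau0, L)
    limit <- if (keepAll) Inf else params@iTopModel
    setsList <- vector("list", iterations)
    chiList <- vector("list", iterations)
    dfList <- vector("list", iterations)
    best <- numeric(iterations)
    for (it in seq_len(iterations)) {
        probs <- selectionProbabilities(tau, params@alpha)
        sets <- .sampleSetsCpp(probs, n, params@iAntCount)
        sc <- .scoreSetsCpp(G@geno, G@status, sets)
        best[it] <- max(sc$chi2)
        setsList[[it]] <- sets
        chiList[[it]] <- sc$chi2
        dfList[[it]] <- sc$df
        tau <- updatePheromones(tau, sets, sc$chi2, params@rho)
    }
    # one global pass: a locus tuple is counted once (its score is
    # deterministic given the set), then the best `limit` distinct sets are
    # kept in decreasing chi-square order, ties broken lexicographically
    allSets <- do.call(rbind, setsList)
    allChi <- unlist(chiList)
    allDf <- unlist(dfList)
    keys <- do.call(paste, c(as.data.frame(allSets), list(sep = "_")))
    first <- !duplicated(keys)
    allSets <- allSets[first, , drop = FALSE]
    allChi <- allChi[first]
    allDf <- allDf[first]
    o <- do.call(order, c(list(-allChi), as.data.frame(allSets)))
    if (length(o) > limit)
        o <- o[seq_len(limit)]
    allSets <- allSets[o, , drop = FALSE]
    allChi <- allChi[o]
    allDf <- allDf[o]
    new("AcoResult", sets = allSets, chi2 = allChi, df = as.integer(allDf),
        pvalue = stats::pchisq(allChi, allDf, lower.tail = FALSE),
        finalTau = tau, bestHistory = best)
}

#' @rdname AcoResult-class
#' @export
setMethod("topSets", "AcoResult", function(x) {
    df <- as.data.frame(x@sets)
    names(df) <- paste0("locus", seq_len(ncol(x@sets)))
    cbind(df, data.frame(chi2 = x@chi2, df = x@df, pvalue = x@pvalue))
})

#' @rdname AcoResult-class
#' @export
setMethod("finalTau", "AcoResult", function(x) x@finalTau)

setMethod("show", "AcoResult", function(object) {
    cat(sprintf("AcoResult: %d top sets of size %d over %d loci; best chi2 = %.2f\n",
                nrow(object@sets), ncol(object@sets),
                length(object@finalTau),
                if (length(object@chi2)) max(object@chi2) else NA_real_))
})
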