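#' Stage one: two ACO rounds at two set sizes
#'
#' Runs the ACO twice from a fresh pheromone field: once with a relatively
#' large SNP-set size (sensitive to strong signals) for `iItCountLarge`
#' iterations, and once with a relatively small size (sensitive to weak
#' signals) for `iItCountSmall` iterations.  Each round contributes its
#' top-`iTopModel` suspected sets.  The reduced locus set for stage two is
#' ranked by pheromone level across the rounds: a locus ranks as well as
#' its best rank in either round's final pheromone vector (so the loci
#' favoured by either round are both represented and neither round's
#' pheromone scale dominates), and the `iTopLoci` best-ranked loci are
#' kept.
#'
#' @param G a [GenotypeData-class] panel.
#' @param params an [EpiParams-class] object.
#' @return a [StageOneResult-class] harvest.
#' @export
stageOne <- function(G, params) {
    stopifnot(is(G, "GenotypeData"), is(params, "EpiParams"))
    r1 <- runAco(G, params@largesetsize, params@iItCountLarge, params)
    r2 <- runAco(G, params@smallsetsize, params@iItCountSmall, params)
    # rank within each round (1 = highest pheromone), combine by the best
    # rank either round assigns; ties broken by the rank sum, then by index
    rk1 <- rank(-r1@finalTau, ties.method = "first")
    rk2 <- rank(-r2@finalTau, ties.method = "first")
    k <- min(params@iTopLoci, nSnps(G))
    topLoci <- sort(order(pmin(rk1, rk2), rk1 + rk2)[seq_len(k)])
    sets <- c(lapply(seq_len(nrow(r1@sets)), function(i) r1@sets[i, ]),
              lapply(seq_len(nrow(r2@sets)), function(i) r2@sets[i, ]))
    new("StageOneResult", sets = sets,
        chi2 = c(r1@chi2, r2@chi2), df = c(r1@df, r2@df),
        pvalue = c(r1@pvalue, r2@pvalue), topLoci = as.integer(topLoci),
        tauLarge = r1@finalTau, tauSmall = r2@finalTau,
        historyLarge = r1@bestHistory, historySmall = r2@bestHistory)
}

#' @rdname StageOneResult-class
#' @export
setMethod("suspectedSets", "StageOneResult", function(x) x@sets)

#' @rdname StageOneResult-class
#' @export
setMethod("topPheromoneLoci", "StageOneResult", function(x) x@topLoci)

setMethod("show", "StageOneResult", function(object) {
    cat(sprintf("StageOneResult: %d suspected sets, %d top-pheromone loci\n",
                length(object@sets), length(object@topLoci)))
})

#' Stage two: exhaustive search inside the harvest
#'
#' Enumerates every `iEpiModel`-sized subset of each suspected set and of
#' the top-pheromone locus set, deduplicates, scores each candidate with
#' the chi-square test, and reports those with `pvalue < params@pvalue`
#' sorted by ascending p-value.  The candidate count is bounded by
#' `2 * iTopModel * choose(largesetsize, iEpiModel) +
#' choose(iTopLoci, iEpiModel)`, which is what makes the search cheap
#' compared to all `choose(L, iEpiModel)` combinations.
#'
#' @param G a [GenotypeData-class] panel.
#' @param harvest a [StageOneResult-class] object from [stageOne()].
#' @param params an [EpiParams-class] object.
#' @return interaction data frame (`EI_all`), as in [exhaustiveScan()].
#' @export
stageTwo <- function(G, harvest, params) {
    stopifnot(is(G, "GenotypeData"), is(harvest, "StageOneResult"),
              is(params, "EpiParams"))
    k <- params@iEpiModel
    cand <- lapply(harvest@sets, function(s)
        if (length(s) >= k) combn(sort(s), k) else NULL)
    if (length(harvest@topLoci) >= k)
        cand <- c(cand, list(combn(sort(harvest@topLoci), k)))
    cand <- cand[!vapply(cand, is.null, logical(1L))]
    if (!length(cand))
        stop("stage-one harvest is empty")
    sets <- t(do.call(cbind, cand))
    storage.mode(sets) <- "integer"
    keys <- do.call(paste, c(as.data.frame(sets), list(sep = "_")))
    sets <- sets[!duplicated(keys), , drop = FALSE]
    sc <- scoreSnpSets(G, sets)
    keep <- if (params@pvalue >= 1) rep(TRUE, length(sc$pvalue))
            else sc$pvalue < params@pvalue
    interactionFrame(G, sets[keep, , drop = FALSE], sc$chi2[keep],
                     sc$df[keep], sc$pvalue[keep])
}

#' Run the full AntEpiSeeker search
#'
#' Two-stage search for epistatic interactions: [stageOne()] harvests
#' suspected SNP sets and top-pheromone loci, [stageTwo()] exhaustively
#' tests the interaction-sized subsets of the harvest (`EI_all`), and
#' [minimizeFalsePositives()] prunes locus-overlapping reports (`EI_m`).
#' When `outputDir` is given, the three conventional output files are
#' written there: `AntEpiSeeker.log` (parameter echo and per-iteration
#' traces), `results_maximized.txt` (all detected interactions) and the
#' user output file `params@outFile` (interactions with minimized false
#' positives).
#'
#' @param G a [GenotypeData-class] panel.
#' @param params an [EpiParams-class] object.
#' @param seed optional integer seed for reproducibility.
#' @param outputDir optional directory for the three output files.
#' @return invisibly, a list with elements `EIall`, `EIm` (interaction
#'   data frames) and `stageOne` (the [StageOneResult-class] harvest).
#' @examples
#' \donttest{
#' set.seed(7)
#' sp <- simulateCaseControl(epiModel("multiplicative", lam = 1, maf = 0.5),
#'                           L = 30, nCase = 300, nControl = 300)
#' res <- antEpiSeeker(simPanel(sp), suggestParameters(30), seed = 1)
#' head(res$EIm)
#' }
#' @export
antEpiSeeker <- function(G, params, seed = NULL, outputDir = NULL) {
    stopifnot(is(G, "GenotypeData"), is(params, "EpiParams"))
    if (!is.null(seed))
        set.seed(seed)
    harvest <- stageOne(G, params)
    ei_all <- stageTwo(G, harvest, params)
    ei_m <- minimizeFalsePositives(ei_all)
    if (!is.null(outputDir))
        writeResults(ei_all, ei_m, harvest, params, outputDir)
    invisible(list(EIall = ei_all, EIm = ei_m, stageOne = harvest))
}
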