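#' Case-control genotype panel
#'
#' Container for a biallelic SNP panel with case/control labels.  Genotypes
#' are stored as a samples-by-SNPs integer matrix of minor-allele counts
#' (0, 1, 2); SNP names are the (unique) column names.  Status is 0 for
#' controls and 1 for cases.
#'
#' @slot geno integer matrix, N samples x L SNPs, entries in `{0, 1, 2}`,
#'   with unique column names (the SNP identifiers).
#' @slot status integer vector of length N in `{0, 1}` (0 = control,
#'   1 = case); at least one of each is required.
#'
#' @seealso [genotypeData()], [readGenotypes()]
#' @export
setClass("GenotypeData",
         representation(geno = "matrix", status = "integer"))

setValidity("GenotypeData", function(object) {
    g <- object@geno
    st <- object@status
    msg <- character(0)
    if (!is.integer(g))
        msg <- c(msg, "genotypes must be stored as an integer matrix")
    if (ncol(g) < 1L)
        msg <- c(msg, "at least one SNP is required")
    if (nrow(g) < 2L)
        msg <- c(msg, "at least two samples are required")
    if (length(st) != nrow(g))
        msg <- c(msg, "status length must equal the number of samples")
    if (anyNA(g) || (length(g) && (min(g) < 0L || max(g) > 2L)))
        msg <- c(msg, "genotype codes must all be 0, 1 or 2")
    if (anyNA(st) || !all(st %in% c(0L, 1L)))
        msg <- c(msg, "status codes must all be 0 (control) or 1 (case)")
    else if (!any(st == 1L) || !any(st == 0L))
        msg <- c(msg, "panel must contain at least one case and one control")
    nm <- colnames(g)
    if (is.null(nm) || anyNA(nm) || any(nm == ""))
        msg <- c(msg, "every SNP must be named")
    else if (anyDuplicated(nm))
        msg <- c(msg, sprintf("duplicated SNP name(s): %s",
                              paste(unique(nm[duplicated(nm)]), collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Run parameters for the AntEpiSeeker search
#'
#' Holds every named parameter of the search.  `largesetsize` and
#' `smallsetsize` are the SNP-set sizes of the two first-stage ACO rounds and
#' must both exceed `iEpiModel`, the number of loci in a reported
#' interaction.  `rho` is the pheromone evaporation rate and must lie
#' strictly between 0 and 1.
#'
#' @slot iAntCount positive integer, ants per iteration.
#' @slot iItCountLarge positive integer, iterations of the large-set round.
#' @slot iItCountSmall positive integer, iterations of the small-set round.
#' @slot alpha nonnegative numeric, pheromone exponent.
#' @slot iTopModel positive integer, number of retained top-chi-square sets
#'   per round.
#' @slot iTopLoci positive integer, size of the top-pheromone locus set.
#' @slot rho numeric in (0, 1), evaporation rate.
#' @slot tau0 positive numeric, initial pheromone level.
#' @slot largesetsize,smallsetsize integers greater than `iEpiModel`.
#' @slot iEpiModel integer >= 2, interaction order.
#' @slot pvalue numeric in (0, 1), raw per-test reporting threshold.
#' @slot inpFile,outFile character paths (may be `NA`).
#'
#' @seealso [epiParams()], [readParameters()], [suggestParameters()]
#' @export
setClass("EpiParams",
         representation(iAntCount = "integer", iItCountLarge = "integer",
                        iItCountSmall = "integer", alpha = "numeric",
                        iTopModel = "integer", iTopLoci = "integer",
                        rho = "numeric", tau0 = "numeric",
                        largesetsize = "integer", smallsetsize = "integer",
                        iEpiModel = "integer", pvalue = "numeric",
                        inpFile = "character", outFile = "character"))

setValidity("EpiParams", function(object) {
    msg <- character(0)
    pos <- function(x, nm) if (length(x) != 1L || is.na(x) || x < 1L)
        sprintf("%s must be a positive integer", nm) else character(0)
    msg <- c(msg,
             pos(object@iAntCount, "iAntCount"),
             pos(object@iItCountLarge, "iItCountLarge"),
             pos(object@iItCountSmall, "iItCountSmall"),
             pos(object@iTopModel, "iTopModel"),
             pos(object@iTopLoci, "iTopLoci"))
    if (is.na(object@alpha) || object@alpha < 0)
        msg <- c(msg, "alpha must be nonnegative")
    if (is.na(object@rho) || object@rho <= 0 || object@rho >= 1)
        msg <- c(msg, "rho must lie strictly between 0 and 1")
    if (is.na(object@tau0) || object@tau0 <= 0)
        msg <- c(msg, "tau0 must be positive")
    if (is.na(object@iEpiModel) || object@iEpiModel < 2L)
        msg <- c(msg, "iEpiModel must be an integer >= 2")
    if (is.na(object@largesetsize) || object@largesetsize <= object@iEpiModel)
        msg <- c(msg, "largesetsize must be greater than iEpiModel")
    if (is.na(object@smallsetsize) || object@smallsetsize <= object@iEpiModel)
        msg <- c(msg, "smallsetsize must be greater than iEpiModel")
    if (is.na(object@pvalue) || object@pvalue <= 0 || object@pvalue > 1)
        msg <- c(msg, "pvalue must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Two-locus epistasis disease model
#'
#' One disease model in the Marchini family.  The odds of disease for joint
#' genotype (g1, g2) are `gamma * (1 + theta)^e` with exponent
#' `e = g1 + g2` (additive), `e = g1 * g2` (multiplicative) or
#' `e = 1` when both loci carry at least one risk allele (threshold);
#' penetrance is `odds / (1 + odds)`.  `gamma` and `theta` are solved by
#' [calibrateModel()] so that the population prevalence matches `prevalence`
#' and the marginal per-locus effect size equals `lam` (operationally: the
#' heterozygote odds ratio of the marginal single-locus penetrance table is
#' `1 + lam`).
#'
#' @slot model one of `"additive"`, `"multiplicative"`, `"threshold"`.
#' @slot lam nonnegative numeric, marginal effect size.
#' @slot maf numeric in (0, 0.5], minor (risk) allele frequency per locus.
#' @slot r2 numeric in (0, 1], squared allelic correlation between each
#'   causal locus and its genotyped marker.
#' @slot prevalence numeric in (0, 1), population disease prevalence.
#' @slot gamma,theta numeric odds parameters (`NA` until calibrated).
#'
#' @seealso [epiModel()], [calibrateModel()], [penetranceTable()]
#' @export
setClass("EpiModelSpec",
         representation(model = "character", lam = "numeric", maf = "numeric",
                        r2 = "numeric", prevalence = "numeric",
                        gamma = "numeric", theta = "numeric"))

setValidity("EpiModelSpec", function(object) {
    msg <- character(0)
    if (!object@model %in% c("additive", "multiplicative", "threshold"))
        msg <- c(msg, "model must be additive, multiplicative or threshold")
    if (is.na(object@lam) || object@lam < 0)
        msg <- c(msg, "lam must be nonnegative")
    if (is.na(object@maf) || object@maf <= 0 || object@maf > 0.5)
        msg <- c(msg, "maf must lie in (0, 0.5]")
    if (is.na(object@r2) || object@r2 <= 0 || object@r2 > 1)
        msg <- c(msg, "r2 must lie in (0, 1]")
    if (is.na(object@prevalence) || object@prevalence <= 0 ||
        object@prevalence >= 1)
        msg <- c(msg, "prevalence must lie in (0, 1)")
    if (!is.na(object@gamma) && object@gamma <= 0)
        msg <- c(msg, "gamma must be positive")
    if (!is.na(object@theta) && object@theta < 0)
        msg <- c(msg, "theta must be nonnegative")
    if (length(msg)) msg else TRUE
})

#' Simulated case-control panel with planted truth
#'
#' @slot panel a [GenotypeData-class] object.
#' @slot truth list of sorted integer locus tuples: the marker pairs tagging
#'   the planted interactions (empty for null panels).
#' @slot specs list of [EpiModelSpec-class] objects, one per truth tuple.
#'
#' @seealso [simulateNull()], [simulateCaseControl()], [embedInteractions()]
#' @export
setClass("SimulatedPanel",
         representation(panel = "GenotypeData", truth = "list",
                        specs = "list"))

setValidity("SimulatedPanel", function(object) {
    if (length(object@truth) != length(object@specs))
        return("truth and specs must have the same length")
    L <- ncol(object@panel@geno)
    for (tr in object@truth) {
        if (anyDuplicated(tr) || any(tr < 1L) || any(tr > L))
            return("truth loci must be distinct and within the panel")
        if (is.unsorted(tr))
            return("truth loci must be sorted")
    }
    TRUE
})

#' Result of one ACO run
#'
#' The best distinct SNP sets seen over all iterations (at most `iTopModel`,
#' in decreasing chi-square order) together with the final pheromone vector
#' and the per-iteration best chi-square trace.
#'
#' @slot sets integer matrix, one sorted locus tuple per row.
#' @slot chi2,pvalue numeric vectors, one entry per row of `sets`.
#' @slot df integer vector of chi-square degrees of freedom.
#' @slot finalTau numeric vector of length L, pheromone levels after the
#'   last iteration.
#' @slot bestHistory numeric vector, best chi-square per iteration.
#'
#' @seealso [runAco()]
#' @export
setClass("AcoResult",
         representation(sets = "matrix", chi2 = "numeric", df = "integer",
                        pvalue = "numeric", finalTau = "numeric",
                        bestHistory = "numeric"))

setValidity("AcoResult", function(object) {
    m <- nrow(object@sets)
    if (length(object@chi2) != m || length(object@df) != m ||
        length(object@pvalue) != m)
        return("score vectors must match the number of sets")
    if (m > 1L && is.unsorted(rev(object@chi2)))
        return("sets must be sorted by decreasing chi-square")
    if (any(object@finalTau <= 0))
        return("pheromone levels must stay positive")
    TRUE
})

#' Harvest of the first AntEpiSeeker stage
#'
#' The suspected SNP sets from the large-set and small-set ACO rounds and
#' the loci with top-ranking pheromone levels, which together define the
#' stage-two exhaustive search space.
#'
#' @slot sets list of sorted integer locus vectors (sizes `largesetsize`
#'   or `smallsetsize`).
#' @slot chi2,pvalue numeric vectors parallel to `sets`.
#' @slot df integer vector parallel to `sets`.
#' @slot topLoci sorted integer vector of top-pheromone loci.
#' @slot tauLarge,tauSmall final pheromone vectors of the two rounds.
#' @slot historyLarge,historySmall per-iteration best chi-square traces.
#'
#' @seealso [stageOne()], [stageTwo()]
#' @export
setClass("StageOneResult",
         representation(sets = "list", chi2 = "numeric", df = "integer",
                        pvalue = "numeric", topLoci = "integer",
                        tauLarge = "numeric", tauSmall = "numeric",
                        historyLarge = "numeric", historySmall = "numeric"))

setValidity("StageOneResult", function(object) {
    if (anyDuplicated(object@topLoci))
        return("top-pheromone loci must be distinct")
    if (length(object@sets) != length(object@chi2))
        return("chi2 must be parallel to sets")
    TRUE
})

#' Evaluation report for a simulation experiment
#'
#' @slot experiment one of `"power"`, `"null"`, `"largescale"`.
#' @slot metrics named list of summary quantities (powers, FP rates,
#'   TPR/FDR), flat enough to serialize as JSON.
#' @slot perReplicate data frame of per-replicate bookkeeping.
#'
#' @seealso [runExperiment()]
#' @export
setClass("EvaluationReport",
         representation(experiment = "character", metrics = "list",
                        perReplicate = "data.frame"))
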