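.lociKeys <- function(reported) {
    lc <- grep("^locus[0-9]+$", names(reported))
    if (!length(lc))
        stop("interaction frame lacks locus columns")
    do.call(paste, c(reported[lc], list(sep = "_")))
}

.tupleKey <- function(tuple) paste(sort(as.integer(tuple)), collapse = "_")

#' Detection power across replicate datasets
#'
#' A replicate counts as a successful identification when every planted
#' truth tuple appears among its reported interactions with
#' `pvalue < alpha / choose(L, order)` -- i.e. at significance `alpha`
#' after Bonferroni correction over all order-sized locus combinations.
#' Power is the fraction of successful replicates.
#'
#' @param results list of interaction data frames, one per replicate.
#' @param truths list (one per replicate) of truth tuples: either a single
#'   integer vector or a list of integer vectors.
#' @param L number of SNPs in the panels.
#' @param order interaction order (default 2).
#' @param alpha nominal significance level before correction.
#' @return list with `power` and the logical per-replicate `detected`
#'   vector.
#' @export
detectionPower <- function(results, truths, L, order = 2, alpha = 0.01) {
    stopifnot(length(results) == length(truths), length(results) >= 1)
    cutoff <- alpha / choose(L, order)
    detected <- vapply(seq_along(results), function(i) {
        rep_i <- results[[i]]
        tr <- truths[[i]]
        if (!is.list(tr))
            tr <- list(tr)
        keys <- .lociKeys(rep_i)
        sig <- rep_i$pvalue < cutoff
        all(vapply(tr, function(tt) any(sig & keys == .tupleKey(tt)),
                   logical(1L)))
    }, logical(1L))
    list(power = mean(detected), detected = detected)
}

#' Null false-positive rate
#'
#' Fraction of all `choose(L, order)` locus combinations reported below a
#' p-value threshold on a panel with no genetic effects.
#'
#' @param reported interaction data frame from a null panel.
#' @param L number of SNPs.
#' @param threshold p-value threshold.
#' @param order interaction order (default 2).
#' @return the false-positive rate.
#' @export
nullFpRate <- function(reported, L, threshold, order = 2) {
    sum(reported$pvalue < threshold) / choose(L, order)
}

#' True-positive rate and false discovery rate
#'
#' A reported tuple matches a truth tuple only on exact locus equality.
#' TPR is the fraction of truth tuples recovered; FDR the fraction of
#' reported tuples that are not truths (0 for an empty report).
#'
#' @param reported interaction data frame.
#' @param truth list of truth tuples (integer vectors).
#' @return list with `tpr` and `fdr`.
#' @export
tprFdr <- function(reported, truth) {
    stopifnot(length(truth) >= 1)
    repKeys <- unique(.lociKeys(reported))
    truthKeys <- vapply(truth, .tupleKey, character(1L))
    tpr <- mean(truthKeys %in% repKeys)
    fdr <- if (!length(repKeys)) 0 else mean(!repKeys %in% truthKeys)
    list(tpr = tpr, fdr = fdr)
}

#' Generic-ACO baseline search
#'
#' The single-stage baseline: the same ACO engine run directly at set size
#' `iEpiModel` (no larger harvest sets, no stage two), conventionally for
#' 900 iterations, reporting every distinct sampled set with
#' `pvalue < threshold`.
#'
#' @param G a [GenotypeData-class] panel.
#' @param params an [EpiParams-class] object.
#' @param iterations iteration count (default 900).
#' @param threshold reporting threshold (defaults to `params@pvalue`).
#' @return interaction data frame.
#' @export
genericAco <- function(G, params, iterations = 900,
                       threshold = params@pvalue) {
    res <- runAco(G, params@iEpiModel, iterations, params, keepAll = TRUE)
    keep <- res@pvalue < threshold
    interactionFrame(G, res@sets[keep, , drop = FALSE], res@chi2[keep],
                     res@df[keep], res@pvalue[keep])
}

#' @rdname EvaluationReport-class
#' @export
setMethod("metrics", "EvaluationReport", function(x) x@metrics)

setMethod("show", "EvaluationReport", function(object) {
    cat(sprintf("EvaluationReport (%s experiment)\n", object@experiment))
    str(object@metrics, give.attr = FALSE)
})

.powerExperiment <- function(nReplicates, L, nCase, nControl, models, maf,
                             r2, genericIterations) {
    params <- suggestParameters(L)
    perRep <- list()
    metrics <- list()
    for (model in models) {
        resAes <- vector("list", nReplicates)
        resGen <- vector("list", nReplicates)
        truths <- vector("list", nReplicates)
        for (r in seq_len(nReplicates)) {
            sp <- simulateCaseControl(epiModel(model, maf = maf, r2 = r2),
                                      L, nCase, nControl)
            G <- simPanel(sp)
            truths[[r]] <- truthLoci(sp)[[1L]]
            resAes[[r]] <- antEpiSeeker(G, params)$EIall
            resGen[[r]] <- genericAco(G, params,
                                      iterations = genericIterations)
        }
        pAes <- detectionPower(resAes, truths, L)
        pGen <- detectionPower(resGen, truths, L)
        metrics[[paste0("power_antepiseeker_", model)]] <- pAes$power
        metrics[[paste0("power_generic_aco_", model)]] <- pGen$power
        perRep[[model]] <- data.frame(
            model = model, replicate = seq_len(nReplicates),
            detected_antepiseeker = pAes$detected,
            detected_generic = pGen$detected,
            n_reported_antepiseeker = vapply(resAes, nrow, integer(1L)),
            n_reported_generic = vapply(resGen, nrow, integer(1L)))
    }
    metrics$power_antepiseeker <-
        mean(unlist(metrics[paste0("power_antepiseeker_", models)]))
    metrics$power_generic_aco <-
        mean(unlist(metrics[paste0("power_generic_aco_", models)]))
    list(metrics = metrics, perReplicate = do.call(rbind, perRep))
}

.nullExperiment <- function(L, nCase, nControl, thresholds, methods,
                            genericIterations) {
    sp <- simulateNull(L, nCase, nControl)
    G <- simPanel(sp)
    metrics <- list(thresholds = thresholds)
    if ("exhaustive" %in% methods) {
        scan <- exhaustiveScan(G, order = 2, threshold = 1,
                               maxCombos = choose(L, 2) + 1)
        metrics$fp_exhaustive <- vapply(
            thresholds, function(t) nullFpRate(scan, L, t), numeric(1L))
    }
    if ("antepiseeker" %in% methods) {
        params <- suggestParameters(L)
        res <- antEpiSeeker(G, params)
        metrics$fp_ei_all <- vapply(
            thresholds, function(t) nullFpRate(res$EIall, L, t), numeric(1L))
        metrics$fp_ei_m <- vapply(
            thresholds, function(t) nullFpRate(res$EIm, L, t), numeric(1L))
    }
    if ("generic_aco" %in% methods) {
        params <- suggestParameters(L)
        gen <- genericAco(G, params, iterations = genericIterations,
                          threshold = max(thresholds))
        metrics$fp_generic_aco <- vapply(
            thresholds, function(t) nullFpRate(gen, L, t), numeric(1L))
    }
    list(metrics = metrics, perReplicate = data.frame())
}

.largescaleExperiment <- function(L, nCase, nControl, nInteractions,
                                  pvalue, genericIterations) {
    models <- c("additive", "multiplicative", "threshold")
    mafs <- c(0.1, 0.2, 0.5)
    specs <- lapply(seq_len(nInteractions), function(i)
        epiModel(models[(i - 1L) %% 3L + 1L],
                 maf = mafs[((i - 1L) %/% 3L) %% 3L + 1L]))
    sp <- embedInteractions(specs, L, nCase, nControl)
    G <- simPanel(sp)
    truth <- truthLoci(sp)
    # the large-panel study runs with the same parameter settings as the
    # replicated power study, only the reporting threshold changes
    params <- epiParams(pvalue = pvalue)
    res <- antEpiSeeker(G, params)
    gen <- genericAco(G, params, iterations = genericIterations,
                      threshold = pvalue)
    tfAll <- tprFdr(res$EIall, truth)
    tfM <- tprFdr(res$EIm, truth)
    tfGen <- tprFdr(gen, truth)
    metrics <- list(
        tpr_antepiseeker = tfAll$tpr, fdr_antepiseeker = tfAll$fdr,
        tpr_antepiseeker_minimized = tfM$tpr,
        fdr_antepiseeker_minimized = tfM$fdr,
        tpr_generic_aco = tfGen$tpr, fdr_generic_aco = tfGen$fdr,
        n_reported_all = nrow(res$EIall), n_reported_minimized = nrow(res$EIm),
        n_reported_generic = nrow(gen), n_interactions = nInteractions)
    list(metrics = metrics, perReplicate = data.frame())
}

#' Run a canned simulation experiment
#'
#' Orchestrates the three evaluation designs at desk scale:
#' \describe{
#'   \item{`power`}{replicated single-interaction panels; detection power
#'     of the two-stage search and the generic-ACO baseline at
#'     Bonferroni-corrected significance 0.01.}
#'   \item{`null`}{one panel without genetic effects; false-positive rates
#'     of the exhaustive pair scan and/or the two-stage search (before and
#'     after false-positive minimization) at several thresholds.}
#'   \item{`largescale`}{one large panel with many planted interactions;
#'     TPR/FDR of the two-stage search (before and after minimization)
#'     and of the generic-ACO baseline.}
#' }
#' Defaults are desk-scale versions of the full study designs (which use
#' 50 replicates of 2000-SNP panels and a 73k-SNP panel with 132
#' interactions); pass `L`, `nReplicates` or `nInteractions` to rescale.
#'
#' @param experiment one of `"power"`, `"null"`, `"largescale"`.
#' @param seed optional integer seed.
#' @param out optional path for a flat JSON copy of the metrics (requires
#'   the jsonlite package).
#' @param nReplicates replicates for the power experiment.
#' @param L panel size; defaults to 1000 (power), 2000 (null), 5000
#'   (largescale).
#' @param nCase,nControl sample sizes (default 2000 each).
#' @param models disease models for the power experiment.
#' @param maf,r2 causal-locus settings for the power experiment.
#' @param thresholds p-value thresholds for the null experiment.
#' @param methods methods to evaluate in the null experiment.
#' @param nInteractions planted interactions in the largescale experiment.
#' @param pvalue reporting threshold for the largescale experiment.
#' @param genericIterations iterations of the generic-ACO baseline.
#' @return an [EvaluationReport-class] object.
#' @export
runExperiment <- function(experiment = c("power", "null", "largescale"),
                          seed = NULL, out = NULL, nReplicates = 10,
                          L = NULL, nCase = 2000, nControl = 2000,
                          models = c("multiplicative", "threshold"),
                          maf = 0.5, r2 = 1,
                          thresholds = c(1e-5, 1e-4, 1e-3, 1e-2),
                          methods = c("exhaustive", "antepiseeker"),
                          nInteractions = 20, pvalue = 1e-4,
                          genericIterations = 900) {
    experiment <- match.arg(experiment)
    if (!is.null(seed))
        set.seed(seed)
    if (is.null(L))
        L <- switch(experiment, power = 1000, null = 2000,
                    largescale = 5000)
    res <- switch(experiment,
        power = .powerExperiment(nReplicates, L, nCase, nControl, models,
                                 maf, r2, genericIterations),
        null = .nullExperiment(L, nCase, nControl, thresholds, methods,
                               genericIterations),
        largescale = .largescaleExperiment(L, nCase, nControl,
                                           nInteractions, pvalue,
                                           genericIterations))
    report <- new("EvaluationReport", experiment = experiment,
                  metrics = res$metrics, perReplicate = res$perReplicate)
    if (!is.null(out)) {
        if (!requireNamespace("jsonlite", quietly = TRUE))
            stop("writing a JSON report requires the jsonlite package")
        jsonlite::write_json(report@metrics, out, auto_unbox = TRUE,
                             digits = NA)
    }
    report
}
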