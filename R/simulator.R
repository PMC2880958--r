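#' Specify a two-locus epistasis disease model
#'
#' @param model `"additive"`, `"multiplicative"` or `"threshold"`.
#' @param lam marginal effect size; defaults to 0.3 for the additive model
#'   and 0.2 for the multiplicative and threshold models.
#' @param maf minor (risk) allele frequency per causal locus, in (0, 0.5].
#' @param r2 squared allelic correlation between each causal locus and its
#'   genotyped marker (1 = the marker is the causal locus).
#' @param prevalence population disease prevalence used for calibration.
#' @return an uncalibrated [EpiModelSpec-class] object; see
#'   [calibrateModel()].
#' @examples
#' spec <- calibrateModel(epiModel("threshold", lam = 0.2, maf = 0.5))
#' penetranceTable(spec)
#' @export
epiModel <- function(model = c("additive", "multiplicative", "threshold"),
                     lam = NULL, maf = 0.2, r2 = 1, prevalence = 0.01) {
    model <- match.arg(model)
    if (is.null(lam))
        lam <- if (model == "additive") 0.3 else 0.2
    obj <- new("EpiModelSpec", model = model, lam = as.numeric(lam),
               maf = as.numeric(maf), r2 = as.numeric(r2),
               prevalence = as.numeric(prevalence),
               gamma = NA_real_, theta = NA_real_)
    validObject(obj)
    obj
}

setMethod("show", "EpiModelSpec", function(object) {
    cat(sprintf(
        "EpiModelSpec: %s, lam = %g, maf = %g, r2 = %g, prevalence = %g%s\n",
        object@model, object@lam, object@maf, object@r2, object@prevalence,
        if (is.na(object@theta)) " (uncalibrated)"
        else sprintf(", gamma = %.4g, theta = %.4g", object@gamma,
                     object@theta)))
})

.hweProbs <- function(f) c((1 - f)^2, 2 * f * (1 - f), f^2)

.oddsExponent <- function(model) {
    switch(model,
           additive       = outer(0:2, 0:2, "+"),
           multiplicative = outer(0:2, 0:2, "*"),
           threshold      = outer(0:2 >= 1, 0:2 >= 1, "&") + 0)
}

#' Two-locus penetrance table
#'
#' Evaluates `P(disease | g1, g2) = odds / (1 + odds)` with
#' `odds = gamma * (1 + theta)^e` and the model-specific exponent
#' (`g1 + g2` additive, `g1 * g2` multiplicative, indicator of both loci
#' carrying a risk allele for threshold).
#'
#' @param spec a calibrated [EpiModelSpec-class] object (or one with
#'   `gamma` and `theta` set by hand).
#' @return 3 x 3 numeric matrix of penetrances, rows = genotype of locus 1,
#'   columns = genotype of locus 2.
#' @export
penetranceTable <- function(spec) {
    stopifnot(is(spec, "EpiModelSpec"))
    if (is.na(spec@gamma) || is.na(spec@theta))
        stop("model is not calibrated; run calibrateModel() first")
    e <- .oddsExponent(spec@model)
    odds <- spec@gamma * (1 + spec@theta)^e
    pen <- odds / (1 + odds)
    dimnames(pen) <- list(g1 = 0:2, g2 = 0:2)
    pen
}

.penFromPars <- function(model, gamma, theta) {
    odds <- gamma * (1 + theta)^.oddsExponent(model)
    odds / (1 + odds)
}

# gamma making the population prevalence match, for fixed theta
.solveGamma <- function(model, theta, maf, prevalence) {
    pg <- .hweProbs(maf)
    joint <- pg %o% pg
    f <- function(lg) sum(joint * .penFromPars(model, exp(lg), theta)) -
        prevalence
    r <- uniroot(f, lower = log(prevalence) - 25, upper = 10,
                 tol = 1e-13, extendInt = "upX")
    exp(r$root)
}

# marginal heterozygote odds ratio of locus 1 for fixed theta (gamma solved
# so prevalence is held at its target throughout)
.marginalHetOR <- function(model, theta, maf, prevalence) {
    gamma <- .solveGamma(model, theta, maf, prevalence)
    pg <- .hweProbs(maf)
    marg <- as.vector(.penFromPars(model, gamma, theta) %*% pg)
    odds <- marg / (1 - marg)
    odds[2L] / odds[1L]
}

#' Calibrate a disease model to its marginal effect size
#'
#' Solves the odds parameters numerically: `theta` so that the marginal
#' per-locus effect equals `lam` -- operationally, the heterozygote odds
#' ratio of the marginal single-locus penetrance table equals `1 + lam`
#' under Hardy-Weinberg genotype frequencies -- and `gamma` so that the
#' population prevalence equals `spec@prevalence`.  Both solves are
#' bracketed root finds converged well below relative tolerance `1e-8`.
#'
#' @param spec an [EpiModelSpec-class] object.
#' @return the spec with `gamma` and `theta` filled in.
#' @export
calibrateModel <- function(spec) {
    stopifnot(is(spec, "EpiModelSpec"))
    if (spec@lam == 0) {
        theta <- 0
    } else {
        f <- function(th) .marginalHetOR(spec@model, th, spec@maf,
                                         spec@prevalence) - (1 + spec@lam)
        hi <- 1
        for (i in 1:60) {
            if (f(hi) > 0)
                break
            hi <- hi * 2
        }
        if (f(hi) <= 0)
            stop(sprintf(
                "calibration failed: no theta in (0, %g] reaches marginal effect lam = %g (model %s, maf %g)",
                hi, spec@lam, spec@model, spec@maf))
        theta <- uniroot(f, lower = 0, upper = hi, tol = 1e-12)$root
    }
    gamma <- .solveGamma(spec@model, theta, spec@maf, spec@prevalence)
    spec@theta <- theta
    spec@gamma <- gamma
    validObject(spec)
    spec
}

#' Haplotype frequencies linking a causal locus to its marker
#'
#' Builds the two-locus haplotype distribution of a marker in linkage
#' disequilibrium `r2` with a causal locus of the same minor allele
#' frequency: `p11 = maf^2 + sqrt(r2) * maf * (1 - maf)`, so the squared
#' correlation of the allele indicators is exactly `r2`.
#'
#' @param maf shared minor allele frequency, in (0, 0.5].
#' @param r2 squared allelic correlation, in (0, 1].
#' @return 2 x 2 matrix of haplotype frequencies; rows = causal allele
#'   (0/1), columns = marker allele (0/1).
#' @examples
#' markerHaplotypes(0.2, 1)   # marker identical to the causal locus
#' @export
markerHaplotypes <- function(maf, r2) {
    stopifnot(maf > 0, maf <= 0.5, r2 > 0, r2 <= 1)
    r <- sqrt(r2)
    D <- r * maf * (1 - maf)
    h <- matrix(c((1 - maf)^2 + D, maf * (1 - maf) - D,
                  maf * (1 - maf) - D, maf^2 + D), 2L, 2L,
                dimnames = list(causal = 0:1, marker = 0:1))
    if (any(h < -1e-12))
        stop("infeasible haplotype frequencies for maf = ", maf,
             ", r2 = ", r2)
    pmax(h, 0)
}

# marker genotypes given causal genotypes: each causal chromosome carries
# the marker allele with the LD-conditional probability
.markerFromCausal <- function(g, maf, r2) {
    if (r2 == 1)
        return(g)
    h <- markerHaplotypes(maf, r2)
    p1 <- h[2L, 2L] / maf                  # P(marker = 1 | causal = 1)
    p0 <- h[1L, 2L] / (1 - maf)            # P(marker = 1 | causal = 0)
    a1 <- as.integer(g >= 1L)              # allele on first chromosome
    a2 <- as.integer(g == 2L)              # allele on second chromosome
    m1 <- rbinom(length(g), 1L, ifelse(a1 == 1L, p1, p0))
    m2 <- rbinom(length(g), 1L, ifelse(a2 == 1L, p1, p0))
    as.integer(m1 + m2)
}

# independent HWE background SNPs, MAF ~ U[mafLow, mafHigh]
.backgroundSnps <- function(n, L, mafLow, mafHigh) {
    mafs <- runif(L, mafLow, mafHigh)
    matrix(rbinom(n * L, 2L, rep(mafs, each = n)), nrow = n, ncol = L)
}

.assemblePanel <- function(causalCols, positions, status, L,
                           mafLow = 0.1, mafHigh = 0.5) {
    n <- length(status)
    geno <- matrix(0L, n, L)
    bg <- setdiff(seq_len(L), positions)
    geno[, bg] <- .backgroundSnps(n, length(bg), mafLow, mafHigh)
    for (i in seq_along(positions))
        geno[, positions[i]] <- causalCols[[i]]
    genotypeData(geno, status, snpNames = sprintf("SNP%d", seq_len(L)))
}

#' Simulate a null case-control panel
#'
#' All SNPs are generated independently of each other and of the status
#' labels, under Hardy-Weinberg equilibrium with minor allele frequencies
#' drawn uniformly from `[mafLow, mafHigh]`.
#'
#' @param L number of SNPs.
#' @param nCase,nControl numbers of cases and controls.
#' @param mafLow,mafHigh bounds of the uniform MAF distribution.
#' @return a [SimulatedPanel-class] with empty truth.
#' @examples
#' sp <- simulateNull(50, 100, 100)
#' nSnps(simPanel(sp))
#' @export
simulateNull <- function(L, nCase, nControl, mafLow = 0.1, mafHigh = 0.5) {
    stopifnot(L >= 1, nCase >= 1, nControl >= 1,
              mafLow > 0, mafLow <= mafHigh, mafHigh <= 0.5)
    status <- rep(c(1L, 0L), c(nCase, nControl))
    geno <- .backgroundSnps(nCase + nControl, L, mafLow, mafHigh)
    panel <- genotypeData(geno, status,
                          snpNames = sprintf("SNP%d", seq_len(L)))
    new("SimulatedPanel", panel = panel, truth = list(), specs = list())
}

#' Simulate a panel with one planted two-locus interaction
#'
#' Causal genotypes are drawn under Hardy-Weinberg equilibrium, disease
#' status by the model's penetrance table, and samples are
#' rejection-sampled until the case and control quotas are met.  When
#' `r2 < 1` the panel carries the LD markers tagging the causal loci (the
#' causal loci themselves are not genotyped); when `r2 = 1` the markers
#' coincide with the causal loci.  The remaining `L - 2` SNPs are
#' independent HWE background with MAF uniform in `[0.1, 0.5]`, and the
#' pair is placed at random positions recorded in the truth.
#'
#' @param spec an [EpiModelSpec-class] object (calibrated automatically if
#'   needed).
#' @param L total number of SNPs (>= 2).
#' @param nCase,nControl numbers of cases and controls.
#' @param maxDraws budget of candidate individuals for rejection sampling.
#' @return a [SimulatedPanel-class] whose truth holds the marker pair.
#' @export
simulateCaseControl <- function(spec, L, nCase, nControl,
                                maxDraws = 5e7) {
    stopifnot(is(spec, "EpiModelSpec"), L >= 2, nCase >= 1, nControl >= 1)
    if (is.na(spec@theta))
        spec <- calibrateModel(spec)
    pen <- penetranceTable(spec)
    pg <- .hweProbs(spec@maf)
    g1c <- integer(0); g2c <- integer(0)    # accepted cases
    g1t <- integer(0); g2t <- integer(0)    # accepted controls
    drawn <- 0
    prev <- sum((pg %o% pg) * pen)
    while (length(g1c) < nCase || length(g1t) < nControl) {
        needC <- nCase - length(g1c)
        needT <- nControl - length(g1t)
        nb <- ceiling(max(needC / max(prev, 1e-4),
                          needT / max(1 - prev, 1e-4)) * 1.2) + 100
        nb <- min(nb, 2e6)
        if (drawn + nb > maxDraws)
            stop(sprintf(
                "case/control quota unreachable within %g draws (prevalence %.3g); check the model calibration",
                maxDraws, prev))
        drawn <- drawn + nb
        a <- sample.int(3L, nb, replace = TRUE, prob = pg) - 1L
        b <- sample.int(3L, nb, replace = TRUE, prob = pg) - 1L
        y <- rbinom(nb, 1L, pen[cbind(a + 1L, b + 1L)])
        isC <- y == 1L
        if (needC > 0L) {
            idx <- which(isC)[seq_len(min(needC, sum(isC)))]
            g1c <- c(g1c, a[idx]); g2c <- c(g2c, b[idx])
        }
        if (needT > 0L) {
            idx <- which(!isC)[seq_len(min(needT, sum(!isC)))]
            g1t <- c(g1t, a[idx]); g2t <- c(g2t, b[idx])
        }
    }
    g1 <- c(g1c, g1t)
    g2 <- c(g2c, g2t)
    status <- rep(c(1L, 0L), c(nCase, nControl))
    m1 <- .markerFromCausal(g1, spec@maf, spec@r2)
    m2 <- .markerFromCausal(g2, spec@maf, spec@r2)
    pos <- sample.int(L, 2L)
    panel <- .assemblePanel(list(m1, m2), pos, status, L)
    new("SimulatedPanel", panel = panel, truth = list(sort(pos)),
        specs = list(spec))
}

#' Plant several interactions in one panel
#'
#' Builds a retrospective multi-interaction panel in the spirit of a
#' label-first design: status labels are fixed (cases then controls), and
#' for every interaction the two-locus causal genotypes of *all*
#' individuals are drawn conditional on their status via Bayes' rule from
#' the model's penetrance table and HWE genotype frequencies.  Interaction
#' pairs occupy disjoint random positions; everything else is independent
#' HWE background.
#'
#' @param specs list of [EpiModelSpec-class] objects, one per interaction
#'   (calibrated automatically if needed).
#' @param L total number of SNPs (`>= 2 * length(specs)`).
#' @param nCase,nControl numbers of cases and controls.
#' @return a [SimulatedPanel-class] whose truth lists all marker pairs.
#' @export
embedInteractions <- function(specs, L, nCase, nControl) {
    if (is(specs, "EpiModelSpec"))
        specs <- list(specs)
    nInt <- length(specs)
    stopifnot(nInt >= 1, nCase >= 1, nControl >= 1)
    if (2L * nInt > L)
        stop("cannot place ", nInt, " disjoint pairs in ", L, " SNPs")
    status <- rep(c(1L, 0L), c(nCase, nControl))
    n <- nCase + nControl
    pos <- sample.int(L, 2L * nInt)
    causalCols <- vector("list", 2L * nInt)
    truth <- vector("list", nInt)
    for (i in seq_len(nInt)) {
        spec <- specs[[i]]
        if (is.na(spec@theta))
            spec <- calibrateModel(spec)
        specs[[i]] <- spec
        pen <- penetranceTable(spec)
        pg <- .hweProbs(spec@maf)
        joint <- pg %o% pg
        wCase <- as.vector(joint * pen)
        wCtrl <- as.vector(joint * (1 - pen))
        cell <- integer(n)
        cell[status == 1L] <- sample.int(9L, nCase, replace = TRUE,
                                         prob = wCase / sum(wCase))
        cell[status == 0L] <- sample.int(9L, nControl, replace = TRUE,
                                         prob = wCtrl / sum(wCtrl))
        g1 <- (cell - 1L) %%  3L
        g2 <- (cell - 1L) %/% 3L
        p <- pos[c(2L * i - 1L, 2L * i)]
        causalCols[[2L * i - 1L]] <- .markerFromCausal(g1, spec@maf, spec@r2)
        causalCols[[2L * i]]      <- .markerFromCausal(g2, spec@maf, spec@r2)
        truth[[i]] <- sort(p)
    }
    panel <- .assemblePanel(causalCols, pos, status, L)
    new("SimulatedPanel", panel = panel, truth = truth, specs = specs)
}

#' @rdname SimulatedPanel-class
#' @export
setMethod("simPanel", "SimulatedPanel", function(x) x@panel)

#' @rdname SimulatedPanel-class
#' @export
setMethod("truthLoci", "SimulatedPanel", function(x) x@truth)

#' @rdname SimulatedPanel-class
#' @export
setMethod("modelSpecs", "SimulatedPanel", function(x) x@specs)

setMethod("show", "SimulatedPanel", function(object) {
    cat(sprintf("SimulatedPanel: %d SNPs x %d samples, %d planted interaction(s)\n",
                ncol(object@panel@geno), nrow(object@panel@geno),
                length(object@truth)))
})
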