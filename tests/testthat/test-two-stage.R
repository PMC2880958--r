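smallParams <- function(...)
    epiParams(iAntCount = 50, iItCountLarge = 5, iItCountSmall = 10,
              rho = 0.1, ...)

test_that("stage one harvests sets from both rounds and clamps top loci", {
    gd <- randomPanel(30, 40, 40, seed = 61)
    set.seed(2)
    h1 <- stageOne(gd, smallParams(iTopModel = 1, iTopLoci = 200))
    expect_lte(length(suspectedSets(h1)), 2L)   # one per round
    sizes <- lengths(suspectedSets(h1))
    expect_true(all(sizes %in% c(3L, 6L)))
    # iTopLoci larger than the panel: every locus is kept
    expect_equal(sort(topPheromoneLoci(h1)), 1:30)

    set.seed(2)
    h <- stageOne(gd, smallParams(iTopLoci = 10))
    expect_equal(length(topPheromoneLoci(h)), 10L)
    expect_false(anyDuplicated(topPheromoneLoci(h)) > 0)
})

test_that("stage two enumerates subsets of the harvest", {
    gd <- randomPanel(30, 40, 40, seed = 62)
    mkHarvest <- function(sets, topLoci)
        new("StageOneResult", sets = sets,
            chi2 = numeric(length(sets)), df = integer(length(sets)),
            pvalue = numeric(length(sets)), topLoci = as.integer(topLoci),
            tauLarge = rep(100, 30), tauSmall = rep(100, 30),
            historyLarge = numeric(0), historySmall = numeric(0))
    p1 <- smallParams(pvalue = 1)
    # one suspected 6-set, no pheromone loci: C(6,2) = 15 candidates
    ei <- stageTwo(gd, mkHarvest(list(1:6), integer(0)), p1)
    expect_equal(nrow(ei), 15L)
    # pheromone loci only: C(20,2) = 190 candidates
    ei2 <- stageTwo(gd, mkHarvest(list(), 1:20), p1)
    expect_equal(nrow(ei2), 190L)
    # overlapping sources are deduplicated
    ei3 <- stageTwo(gd, mkHarvest(list(1:6), 1:6), p1)
    expect_equal(nrow(ei3), 15L)
    # reported p-values honour the threshold and come sorted
    p2 <- smallParams(pvalue = 0.2)
    ei4 <- stageTwo(gd, mkHarvest(list(), 1:20), p2)
    expect_true(all(ei4$pvalue < 0.2))
    expect_false(is.unsorted(ei4$pvalue))
    expect_true(all(ei4$pvalue %in% ei2$pvalue))
})

test_that("stage two candidate count respects the combinatorial bound", {
    gd <- randomPanel(40, 50, 50, seed = 63)
    params <- smallParams(iTopModel = 20, iTopLoci = 10, pvalue = 1)
    set.seed(3)
    h <- stageOne(gd, params)
    ei <- stageTwo(gd, h, params)
    bound <- params@iTopModel * 2 * choose(params@largesetsize, 2) +
        choose(params@iTopLoci, 2)
    expect_lte(nrow(ei), bound)
})

test_that("with the full panel as pheromone set, stage two equals the exhaustive scan", {
    gd <- randomPanel(18, 60, 60, seed = 64)
    params <- smallParams(iTopLoci = 18, pvalue = 1)
    h <- new("StageOneResult", sets = list(), chi2 = numeric(0),
             df = integer(0), pvalue = numeric(0), topLoci = 1:18,
             tauLarge = rep(100, 18), tauSmall = rep(100, 18),
             historyLarge = numeric(0), historySmall = numeric(0))
    ei <- stageTwo(gd, h, params)
    scan <- exhaustiveScan(gd, 2, threshold = 1)
    expect_equal(ei, scan)
})

test_that("the full search is deterministic given a seed and self-consistent", {
    sp <- {
        set.seed(65)
        simulateCaseControl(epiModel("multiplicative", lam = 1, maf = 0.3),
                            L = 40, nCase = 200, nControl = 200)
    }
    G <- simPanel(sp)
    params <- smallParams(pvalue = 0.05, iTopLoci = 15)
    a <- antEpiSeeker(G, params, seed = 99)
    b <- antEpiSeeker(G, params, seed = 99)
    expect_identical(a$EIall, b$EIall)
    expect_identical(a$EIm, b$EIm)
    # EI_m is a subset of EI_all and every report clears the threshold
    keys <- function(d) paste(d$locus1, d$locus2)
    expect_true(all(keys(a$EIm) %in% keys(a$EIall)))
    expect_true(all(a$EIall$pvalue < params@pvalue))

    # an absurdly strict threshold reports nothing
    none <- antEpiSeeker(G, smallParams(pvalue = 1e-30), seed = 99)
    expect_equal(nrow(none$EIall), 0L)
    expect_equal(nrow(none$EIm), 0L)
})

test_that("a strongly planted pair lands in the suspected harvest and EI_m", {
    spec <- calibrateModel(epiModel("multiplicative", lam = 2, maf = 0.5))
    params <- epiParams(iAntCount = 100, iItCountLarge = 10,
                        iItCountSmall = 20, rho = 0.1, iTopLoci = 20,
                        pvalue = 0.01)
    found <- 0L
    inEim <- 0L
    for (s in 1:20) {
        set.seed(600 + s)
        sp <- simulateCaseControl(spec, L = 60, nCase = 300, nControl = 300)
        tr <- truthLoci(sp)[[1]]
        res <- antEpiSeeker(simPanel(sp), params)
        h <- res$stageOne
        joint <- any(vapply(suspectedSets(h),
                            function(s) all(tr %in% s), logical(1))) ||
            all(tr %in% topPheromoneLoci(h))
        found <- found + joint
        inEim <- inEim +
            any(res$EIm$locus1 == tr[1] & res$EIm$locus2 == tr[2])
    }
    expect_gte(found, 16)   # >= 80% of 20 seeded runs
    expect_gte(inEim, 11)   # majority of runs carry the pair through EI_m
})
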