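test_that("penetrance tables follow the model-specific odds exponents", {
    flat <- epiModel("additive", lam = 0.3)
    flat@gamma <- 0.02; flat@theta <- 0
    expect_equal(unname(penetranceTable(flat)),
                 matrix(0.02 / 1.02, 3, 3))

    mult <- epiModel("multiplicative", lam = 0.2)
    mult@gamma <- 0.01; mult@theta <- 0.5
    pen <- penetranceTable(mult)
    # no risk without both loci: the g1 = 0 row and g2 = 0 column are flat
    expect_equal(unname(pen[1, ]), rep(0.01 / 1.01, 3))
    expect_equal(unname(pen[, 1]), rep(0.01 / 1.01, 3))
    expect_equal(pen["2", "2"], 0.01 * 1.5^4 / (1 + 0.01 * 1.5^4))

    thr <- epiModel("threshold", lam = 0.2)
    thr@gamma <- 0.01; thr@theta <- 1
    pent <- penetranceTable(thr)
    expect_equal(unname(pent[1, ]), rep(0.00990099, 3), tolerance = 1e-6)
    expect_equal(unname(pent[2:3, 2:3]),
                 matrix(0.01960784, 2, 2), tolerance = 1e-6)

    expect_error(penetranceTable(epiModel("additive")), "calibrat")
})

test_that("calibration hits the prevalence and marginal effect contracts", {
    for (model in c("additive", "multiplicative", "threshold"))
        for (maf in c(0.1, 0.2, 0.5)) {
            spec <- calibrateModel(epiModel(model, maf = maf))
            pen <- penetranceTable(spec)
            pg <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
            # self-consistency: prevalence recomputed from the table
            expect_equal(sum((pg %o% pg) * pen), spec@prevalence,
                         tolerance = 1e-6)
            # marginal heterozygote odds ratio equals 1 + lam
            marg <- as.vector(pen %*% pg)
            odds <- marg / (1 - marg)
            expect_equal(odds[2] / odds[1], 1 + spec@lam, tolerance = 1e-6)
        }

    # a null effect collapses to the flat table at the prevalence
    s0 <- calibrateModel(epiModel("multiplicative", lam = 0, maf = 0.3))
    expect_equal(s0@theta, 0)
    expect_equal(unname(penetranceTable(s0)), matrix(0.01, 3, 3),
                 tolerance = 1e-8)

    # a larger marginal effect needs a larger interaction parameter
    thetas <- vapply(c(0.1, 0.2, 0.4, 0.8), function(l)
        calibrateModel(epiModel("threshold", lam = l, maf = 0.3))@theta,
        numeric(1))
    expect_true(all(diff(thetas) > 0))
})

test_that("marker haplotype frequencies realize the requested LD", {
    # perfect LD: the marker is the causal allele
    h1 <- markerHaplotypes(0.2, 1)
    expect_equal(h1[2, 2], 0.2)
    expect_equal(h1[2, 1], 0)
    expect_equal(sum(h1), 1)

    h <- markerHaplotypes(0.2, 0.7)
    expect_equal(sum(h), 1)
    expect_true(all(h >= 0))
    expect_equal(unname(rowSums(h)), c(0.8, 0.2))   # causal MAF preserved
    expect_equal(unname(colSums(h)), c(0.8, 0.2))   # marker MAF matches
    # Monte-Carlo check of the squared allele correlation
    set.seed(11)
    n <- 2e5
    causal <- rbinom(n, 1, 0.2)
    p1 <- h[2, 2] / 0.2
    p0 <- h[1, 2] / 0.8
    marker <- rbinom(n, 1, ifelse(causal == 1, p1, p0))
    expect_equal(cor(causal, marker)^2, 0.7, tolerance = 0.02)
})

test_that("null panels are Hardy-Weinberg with the stated MAF range and no signal", {
    set.seed(12)
    sp <- simulateNull(300, 500, 500)
    G <- simPanel(sp)
    expect_equal(length(truthLoci(sp)), 0L)
    g <- genotypes(G)
    fhat <- colMeans(g) / 2
    expect_true(all(fhat > 0.1 - 0.05 & fhat < 0.5 + 0.05))
    # HWE goodness of fit per SNP (1 df after estimating the frequency):
    # gross departures would show as a pile of tiny p-values
    hwp <- vapply(seq_len(ncol(g)), function(j) {
        f <- fhat[j]
        obs <- tabulate(g[, j] + 1L, 3)
        exp <- 1000 * c((1 - f)^2, 2 * f * (1 - f), f^2)
        stats::pchisq(sum((obs - exp)^2 / exp), 1, lower.tail = FALSE)
    }, numeric(1))
    expect_lt(mean(hwp < 0.001), 0.01)
    # genotype-status association is null-calibrated: single-SNP chi-square
    # p-values are uniform across the panel
    sc <- scoreSnpSets(G, matrix(seq_len(300), ncol = 1))
    expect_gt(stats::ks.test(sc$pvalue, "punif")$p.value, 0.001)
})

test_that("planted panels carry the interaction at the truth markers", {
    spec <- calibrateModel(epiModel("multiplicative", lam = 1, maf = 0.3))
    set.seed(13)
    sp <- simulateCaseControl(spec, L = 50, nCase = 1500, nControl = 1500)
    G <- simPanel(sp)
    tr <- truthLoci(sp)[[1]]
    expect_equal(length(tr), 2L)
    expect_equal(dim(genotypes(G)), c(3000L, 50L))
    expect_equal(sum(sampleStatus(G)), 1500)

    # case-group joint genotype distribution matches Bayes' rule from the
    # penetrance table under HWE priors (r2 = 1: markers are causal)
    pen <- penetranceTable(spec)
    pg <- c(0.49, 0.42, 0.09)
    q <- (pg %o% pg) * pen
    q <- q / sum(q)
    g <- genotypes(G)[sampleStatus(G) == 1L, tr]
    obs <- table(factor(g[, 1], 0:2), factor(g[, 2], 0:2)) / 1500
    expect_lt(max(abs(obs - q)), 4 * sqrt(max(q) * (1 - max(q)) / 1500) + 0.01)

    # risk genotypes are enriched among cases relative to HWE expectation
    riskHWE <- (pg[2] + pg[3])^2
    riskCase <- mean(g[, 1] >= 1 & g[, 2] >= 1)
    expect_gt(riskCase, riskHWE)

    # controls stay close to the population distribution (prevalence 1%)
    gc <- genotypes(G)[sampleStatus(G) == 0L, tr]
    expect_lt(abs(mean(gc[, 1]) / 2 - 0.3), 0.03)

    # determinism under a fixed seed
    set.seed(13)
    sp2 <- simulateCaseControl(spec, L = 50, nCase = 1500, nControl = 1500)
    expect_identical(genotypes(simPanel(sp2)), genotypes(G))
})

test_that("LD markers attenuate but keep the association (r2 < 1)", {
    spec <- calibrateModel(epiModel("multiplicative", lam = 1, maf = 0.2,
                                    r2 = 0.7))
    set.seed(14)
    sp <- simulateCaseControl(spec, L = 10, nCase = 1000, nControl = 1000)
    tr <- truthLoci(sp)[[1]]
    g <- genotypes(simPanel(sp))
    # marker MAF among controls matches the population MAF (cases are
    # ascertained and enriched for the risk allele)
    ctrl <- sampleStatus(simPanel(sp)) == 0L
    expect_lt(abs(mean(g[ctrl, tr]) / 2 - 0.2), 0.03)
    # the marker pair still shows the signal
    sc <- scoreSnpSets(simPanel(sp), matrix(tr, 1))
    expect_lt(sc$pvalue, 1e-4)
})

test_that("multi-interaction panels plant disjoint detectable pairs", {
    specs <- lapply(c(0.2, 0.5, 0.2, 0.5, 0.2), function(f)
        epiModel("multiplicative", lam = 1, maf = f))
    set.seed(15)
    sp <- embedInteractions(specs, L = 300, nCase = 1000, nControl = 1000)
    truth <- truthLoci(sp)
    expect_equal(length(truth), 5L)
    expect_false(anyDuplicated(unlist(truth)) > 0)
    # every truth pair is far more associated than background pairs
    sc <- scoreSnpSets(simPanel(sp), do.call(rbind, truth))
    set.seed(16)
    bg <- t(replicate(200, sort(sample(setdiff(1:300, unlist(truth)), 2))))
    scBg <- scoreSnpSets(simPanel(sp), bg)
    expect_lt(max(sc$pvalue), 1e-6)
    expect_gt(median(scBg$pvalue), 0.1)

    # one interaction reduces to the single-pair generator distributionally:
    # case-group risk-carrier fraction agrees between the two constructions
    spec <- calibrateModel(epiModel("multiplicative", lam = 1, maf = 0.3))
    set.seed(17)
    one <- embedInteractions(list(spec), L = 20, nCase = 2000, nControl = 50)
    g1 <- genotypes(simPanel(one))[sampleStatus(simPanel(one)) == 1L,
                                   truthLoci(one)[[1]]]
    set.seed(18)
    two <- simulateCaseControl(spec, L = 20, nCase = 2000, nControl = 50)
    g2 <- genotypes(simPanel(two))[sampleStatus(simPanel(two)) == 1L,
                                   truthLoci(two)[[1]]]
    f1 <- mean(g1[, 1] >= 1 & g1[, 2] >= 1)
    f2 <- mean(g2[, 1] >= 1 & g2[, 2] >= 1)
    expect_lt(abs(f1 - f2), 4 * sqrt(0.25 / 2000) * sqrt(2))

    expect_error(embedInteractions(specs, L = 9, 100, 100), "disjoint")
})
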