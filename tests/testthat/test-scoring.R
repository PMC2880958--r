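test_that("contingency tables count observed genotype combinations", {
    gd <- literalPanel(list(c(0, 0), c(0, 1), c(1, 1)))
    tab <- contingencyTable(gd, 1)
    expect_equal(unname(tab), cbind(c(1L, 0L), c(1L, 1L)),
                 ignore_attr = TRUE)
    expect_equal(rownames(tab), c("0", "1"))
    expect_equal(attr(tab, "setSize"), 1L)

    # unobserved combinations are dropped: 2 SNPs covering 2 of 9 combos
    gd2 <- literalPanel(list(c(0, 0, 1), c(0, 0, 0), c(2, 2, 1),
                             c(2, 2, 0)))
    tab2 <- contingencyTable(gd2, c(1, 2))
    expect_equal(nrow(tab2), 2L)
    expect_equal(sum(tab2), 4)
    expect_setequal(rownames(tab2), c("0/0", "2/2"))

    expect_error(contingencyTable(gd2, c(1, 1)), "distinct")
    expect_error(contingencyTable(gd2, integer(0)), "at least one")
    expect_error(contingencyTable(gd2, 9), "range")
})

test_that("chi-square score matches hand computation and oracle", {
    # perfectly separating table: E = 5 everywhere, chi2 = 4 * 25/5 = 20
    r <- chi2Score(cbind(control = c(10, 0), case = c(0, 10)))
    expect_equal(r$chi2, 20)
    expect_equal(r$df, 1L)
    expect_equal(r$pvalue, pchisq(20, 1, lower.tail = FALSE))
    expect_equal(r$pvalue, 7.744216e-06, tolerance = 1e-6)

    # proportional rows: identical case/control ratio -> independence
    r0 <- chi2Score(cbind(c(10, 20, 5), c(20, 40, 10)))
    expect_equal(r0$chi2, 0)
    expect_equal(r0$pvalue, 1)

    # degenerate tables: one row, or an empty status column
    expect_equal(chi2Score(cbind(7, 3))$chi2, 0)
    expect_equal(chi2Score(cbind(c(5, 5), c(0, 0)))$pvalue, 1)

    # 9-row random table against an independent brute-force oracle
    set.seed(5)
    for (i in 1:20) {
        tab <- matrix(rpois(18, 12), 9, 2)
        tab[1, ] <- tab[1, ] + 1   # keep both columns nonzero
        expect_equal(chi2Score(tab)$chi2, chi2Oracle(tab),
                     tolerance = 1e-10)
    }
})

test_that("chi-square p-value agrees with a label-permutation oracle", {
    # moderate-signal table, counts large enough for the asymptotic
    # approximation, so the Monte-Carlo permutation tail pins it down
    tab <- cbind(control = c(60, 40), case = c(40, 60))
    r <- chi2Score(tab)
    set.seed(77)
    lab <- rep(c(0, 1), c(100, 100))
    grp <- rep(c(0, 1), c(100, 100))  # row membership of the 200 samples
    B <- 20000
    hits <- 0
    for (b in seq_len(B)) {
        pl <- sample(lab)
        t2 <- cbind(tabulate(grp[pl == 0] + 1L, 2),
                    tabulate(grp[pl == 1] + 1L, 2))
        if (chi2Oracle(t2) >= r$chi2 - 1e-12)
            hits <- hits + 1
    }
    mc <- hits / B
    se <- sqrt(mc * (1 - mc) / B)
    # the chi-square approximation should sit within a few MC standard
    # errors of the exact permutation tail (discreteness allows some slack)
    expect_lt(abs(mc - r$pvalue), 4 * se + 0.003)
})

test_that("chi-square score is invariant to row order and decreases under smoothing", {
    set.seed(6)
    tab <- matrix(rpois(18, 9) + 1, 9, 2)
    base <- chi2Score(tab)$chi2
    for (i in 1:5)
        expect_equal(chi2Score(tab[sample(9), ])$chi2, base)
    # regularization sanity: adding a constant to all cells pulls a
    # non-independent table toward independence
    tab2 <- cbind(c(10, 0), c(0, 10))
    expect_lt(chi2Score(tab2 + 5)$chi2, chi2Score(tab2)$chi2)
})

test_that("batch set scoring agrees with the per-set R path", {
    gd <- randomPanel(12, 30, 30, seed = 55)
    set.seed(9)
    sets <- t(replicate(40, sort(sample.int(12, 3))))
    sc <- scoreSnpSets(gd, sets)
    for (i in seq_len(nrow(sets))) {
        ref <- chi2Score(contingencyTable(gd, sets[i, ]))
        expect_equal(sc$chi2[i], ref$chi2, tolerance = 1e-12)
        expect_equal(sc$df[i], ref$df)
        expect_equal(sc$pvalue[i], ref$pvalue, tolerance = 1e-12)
    }
})

test_that("exhaustive scan enumerates, filters, sorts and refuses", {
    gd3 <- randomPanel(3, 10, 10, seed = 7)
    scan3 <- exhaustiveScan(gd3, 2, threshold = 1)
    expect_equal(nrow(scan3), 3L)

    gd20 <- randomPanel(20, 40, 40, seed = 8)
    scan <- exhaustiveScan(gd20, 2, threshold = 1)
    expect_equal(nrow(scan), choose(20, 2))
    expect_false(is.unsorted(scan$pvalue))
    # agrees with the per-pair scoring path
    i <- c(1, 50, 190)
    for (k in i) {
        ref <- chi2Score(contingencyTable(gd20,
                                          c(scan$locus1[k], scan$locus2[k])))
        expect_equal(scan$chi2[k], ref$chi2, tolerance = 1e-12)
    }
    # three-locus scan enumerates C(L, 3)
    expect_equal(nrow(exhaustiveScan(gd3, 3, threshold = 1)), 1L)

    # an infeasible scan is refused, reporting the combination count
    big <- genotypeData(matrix(0L, 2, 100000,
                               dimnames = list(NULL, sprintf("S%d", 1:100000))),
                        c(1, 0))
    expect_error(exhaustiveScan(big, 2), "5e\\+09")
})
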