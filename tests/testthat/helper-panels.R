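# small fixture builders shared across the suite; all panels are generated
# in code so tests stay text-only and seed-reproducible

# random null panel with MAF ~ U[0.1, 0.5] background
randomPanel <- function(L, nCase, nControl, seed = NULL) {
    if (!is.null(seed))
        set.seed(seed)
    simPanel(simulateNull(L, nCase, nControl))
}

# a panel written out by hand, row per sample, last element = status
literalPanel <- function(rows, snp = NULL) {
    m <- do.call(rbind, rows)
    g <- m[, -ncol(m), drop = FALSE]
    if (is.null(snp))
        snp <- paste0("S", seq_len(ncol(g)))
    genotypeData(g, m[, ncol(m)], snpNames = snp)
}

# write a genotype CSV from text lines
writeCsv <- function(lines) {
    f <- tempfile(fileext = ".csv")
    writeLines(lines, f)
    f
}

# independent chi-square oracle: explicit Pearson formula with loops,
# sharing no code with the package's scoring path
chi2Oracle <- function(tab) {
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    n <- sum(tab)
    chi2 <- 0
    for (i in seq_len(nrow(tab)))
        for (j in seq_len(ncol(tab))) {
            e <- sum(tab[i, ]) * sum(tab[, j]) / n
            chi2 <- chi2 + (tab[i, j] - e)^2 / e
        }
    chi2
}

# interaction frame from explicit loci/p rows, for postprocess tests
eiFrame <- function(loci, pvalue, chi2 = NULL) {
    loci <- if (length(loci)) do.call(rbind, loci)
            else matrix(integer(0), 0, 2)
    if (is.null(chi2))
        chi2 <- -log10(pvalue)
    df <- data.frame(SNP1 = sprintf("SNP%d", loci[, 1]),
                     SNP2 = sprintf("SNP%d", loci[, 2]),
                     chi2 = chi2, df = rep(8L, length(pvalue)),
                     pvalue = pvalue,
                     locus1 = loci[, 1], locus2 = loci[, 2],
                     stringsAsFactors = FALSE)
    df[order(df$pvalue, df$locus1, df$locus2), ]
}
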