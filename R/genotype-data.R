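#' Construct a case-control genotype panel
#'
#' @param geno matrix of genotype codes (0/1/2), samples in rows, SNPs in
#'   columns.  Coerced to integer storage.
#' @param status vector of sample status codes, 0 = control, 1 = case.
#' @param snpNames optional character vector of SNP identifiers; defaults to
#'   the column names of `geno`.
#'
#' @return a validated [GenotypeData-class] object.
#' @examples
#' g <- matrix(c(0L, 2L, 1L, 0L, 2L, 0L), nrow = 2,
#'             dimnames = list(NULL, c("S1", "S2", "S3")))
#' gd <- genotypeData(g, status = c(1, 0))
#' nSnps(gd)
#' @export
genotypeData <- function(geno, status, snpNames = colnames(geno)) {
    geno <- as.matrix(geno)
    if (!is.integer(geno)) {
        mode(geno) <- "integer"
    }
    if (!is.null(snpNames))
        colnames(geno) <- as.character(snpNames)
    rownames(geno) <- NULL
    obj <- new("GenotypeData", geno = geno, status = as.integer(status))
    validObject(obj)
    obj
}

#' @rdname GenotypeData-class
#' @export
setMethod("snpNames", "GenotypeData", function(x) colnames(x@geno))

#' @rdname GenotypeData-class
#' @export
setMethod("genotypes", "GenotypeData", function(x) x@geno)

#' @rdname GenotypeData-class
#' @export
setMethod("sampleStatus", "GenotypeData", function(x) x@status)

#' @rdname GenotypeData-class
#' @export
setMethod("nSnps", "GenotypeData", function(x) ncol(x@geno))

#' @rdname GenotypeData-class
#' @export
setMethod("nSamples", "GenotypeData", function(x) nrow(x@geno))

setMethod("show", "GenotypeData", function(object) {
    cat(sprintf("GenotypeData: %d SNPs x %d samples (%d cases, %d controls)\n",
                ncol(object@geno), nrow(object@geno),
                sum(object@status == 1L), sum(object@status == 0L)))
})

#' Read a genotype panel from the comma-delimited dialect
#'
#' The first row names the SNPs; every subsequent row is one sample, coded
#' 0/1/2 per SNP, with the sample status (0 = control, 1 = case) in the last
#' column.  The header may either name only the SNPs or carry one extra
#' trailing label for the status column (e.g. `"Class"`), which is ignored.
#'
#' @param path path to the CSV file.
#' @return a [GenotypeData-class] object.
#' @seealso [writeGenotypes()]
#' @export
readGenotypes <- function(path) {
    if (!file.exists(path))
        stop("genotype file not found: ", path)
    hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
    hdr <- trimws(hdr)
    dt <- data.table::fread(path, skip = 1L, header = FALSE, sep = ",",
                            data.table = FALSE, showProgress = FALSE)
    if (nrow(dt) < 1L)
        stop("genotype file has no data rows: ", path)
    if (ncol(dt) == length(hdr) + 1L) {
        snp <- hdr                       # header names only the SNPs
    } else if (ncol(dt) == length(hdr) && length(hdr) >= 2L) {
        snp <- hdr[-length(hdr)]         # trailing status label, ignored
    } else {
        stop(sprintf(
            "malformed genotype file: %d header field(s) but %d data column(s)",
            length(hdr), ncol(dt)))
    }
    L <- length(snp)
    g <- suppressWarnings(
        vapply(seq_len(L), function(j) as.numeric(dt[[j]]), numeric(nrow(dt))))
    g <- matrix(g, nrow = nrow(dt), ncol = L)
    bad <- which(is.na(g) | !(g %in% c(0, 1, 2)))
    if (length(bad)) {
        rc <- arrayInd(bad[1L], dim(g))
        stop(sprintf(
            "invalid genotype code at data row %d, column %d (%s): %s",
            rc[1L], rc[2L], snp[rc[2L]], as.character(dt[rc[1L], rc[2L]])))
    }
    status <- suppressWarnings(as.numeric(dt[[ncol(dt)]]))
    badst <- which(is.na(status) | !(status %in% c(0, 1)))
    if (length(badst))
        stop(sprintf("invalid status code at data row %d: %s",
                     badst[1L], as.character(dt[badst[1L], ncol(dt)])))
    genotypeData(g, status, snpNames = snp)
}

#' Write a genotype panel in the comma-delimited dialect
#'
#' Inverse of [readGenotypes()]: SNP names in the header, one row per
#' sample, status appended as a final `Class` column.
#'
#' @param x a [GenotypeData-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(x, path) {
    stopifnot(is(x, "GenotypeData"))
    df <- as.data.frame(x@geno)
    df[["Class"]] <- x@status
    data.table::fwrite(df, path, sep = ",", col.names = TRUE)
    invisible(path)
}
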