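#' Standardize allele dosages
#'
#' Maps dosages \eqn{d \in \{0,1,2\}} to \eqn{(d - 2p_i)/\sqrt{2p_i(1-p_i)}}
#' column by column, the scaling under which a marker in Hardy-Weinberg
#' proportions has mean 0 and variance 1.
#'
#' @param dosages numeric matrix (individuals x markers), entries in
#'   \[0, 2\]; imputed (fractional) dosages are allowed.
#' @param alleleFreq numeric vector of per-column allele frequencies,
#'   strictly inside (0, 1).
#' @return numeric matrix of the same dimension.
#' @examples
#' standardizeDosages(matrix(c(0, 1, 2), 3, 1), 0.5)
#' @export
standardizeDosages <- function(dosages, alleleFreq) {
  dosages <- as.matrix(dosages)
  if (length(alleleFreq) != ncol(dosages))
    stop("alleleFreq length must equal the number of dosage columns")
  if (any(alleleFreq <= 0 | alleleFreq >= 1))
    stop("allele frequencies must lie strictly in (0, 1); ",
         "filter monomorphic markers first")
  denom <- sqrt(2 * alleleFreq * (1 - alleleFreq))
  sweep(sweep(dosages, 2, 2 * alleleFreq, "-"), 2, denom, "/")
}

#' Construct a GenotypeMatrix from raw dosages
#'
#' Computes allele frequencies as column mean dosage / 2 over non-missing
#' entries, drops monomorphic (or all-missing) markers with a warning,
#' mean-imputes missing dosages to \eqn{2p_i} for the standardized matrix,
#' and standardizes.
#'
#' @param dosages numeric/integer matrix, individuals x markers, entries in
#'   \{0, 1, 2, NA\}.
#' @param markerIds,individualIds optional dimension names; taken from
#'   `dimnames(dosages)` when absent, generated when missing entirely.
#' @return a [GenotypeMatrix-class].
#' @examples
#' g <- GenotypeMatrix(matrix(c(0, 1, 2, 1, 1, 1), nrow = 3))
#' alleleFreq(g)
#' @export
GenotypeMatrix <- function(dosages, markerIds = NULL, individualIds = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(markerIds))
    markerIds <- colnames(dosages) %||% paste0("m", seq_len(ncol(dosages)))
  if (is.null(individualIds))
    individualIds <- rownames(dosages) %||% paste0("id", seq_len(nrow(dosages)))
  dimnames(dosages) <- list(individualIds, markerIds)

  nobs <- colSums(!is.na(dosages))
  p <- colSums(dosages, na.rm = TRUE) / (2 * pmax(nobs, 1L))
  mono <- nobs == 0L | p <= 0 | p >= 1
  if (any(mono)) {
    warning(sum(mono), " monomorphic or all-missing marker(s) dropped: ",
            paste(utils::head(markerIds[mono], 5), collapse = ", "),
            if (sum(mono) > 5) ", ...")
  }
  dropped <- markerIds[mono]
  dosages <- dosages[, !mono, drop = FALSE]
  p <- p[!mono]
  imputed <- dosages
  if (anyNA(imputed)) {
    for (i in which(colSums(is.na(imputed)) > 0)) {
      imputed[is.na(imputed[, i]), i] <- 2 * p[i]
    }
  }
  new("GenotypeMatrix", dosages = dosages, alleleFreq = unname(p),
      standardized = standardizeDosages(imputed, p),
      droppedMarkers = dropped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read genotypes from file
#'
#' Two dialects are supported.  `matrix-tsv`: a tab-separated file whose
#' header row lists marker ids, followed by one row per individual (id then
#' dosages in \{0, 1, 2, NA\}); lines starting with `#` are ignored.  `vcf`:
#' biallelic SNP records whose GT field is converted to the ALT-allele
#' dosage; non-biallelic records are skipped with a warning.
#'
#' @param path file path.
#' @param dialect `"matrix-tsv"` (default) or `"vcf"`.
#' @return a [GenotypeMatrix-class].
#' @seealso [writeGenotypes()] for the exact inverse of the TSV dialect.
#' @export
readGenotypes <- function(path, dialect = c("matrix-tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "vcf") return(readGenotypesVcf(path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) < 2) stop("genotype file needs a header and data rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  markerIds <- header[-1]
  m <- length(markerIds)
  rows <- fields[-1]
  bad <- which(lengths(rows) != m + 1L)
  if (length(bad))
    stop("malformed genotype row (expected ", m + 1L, " fields) at line ",
         bad[1] + 1L)
  ids <- vapply(rows, `[[`, "", 1L)
  d <- matrix(NA_real_, length(rows), m, dimnames = list(ids, markerIds))
  for (j in seq_along(rows)) {
    v <- rows[[j]][-1]
    v[v == "NA"] <- NA
    d[j, ] <- as.numeric(v)
  }
  if (any(!is.na(d) & !(d %in% c(0, 1, 2))))
    stop("dosages must be 0, 1, 2 or NA")
  GenotypeMatrix(d)
}

readGenotypesVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biallelic <- !grepl(",", alt) & nchar(alt) == 1L & nchar(ref) == 1L
  if (any(!biallelic))
    warning(sum(!biallelic), " non-biallelic VCF record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  ids <- paste(fix[biallelic, "CHROM"], fix[biallelic, "POS"], sep = ":")
  rn <- rownames(gt)
  if (!is.null(rn)) {
    named <- !is.na(fix[biallelic, "ID"]) & fix[biallelic, "ID"] != "."
    ids[named] <- fix[biallelic, "ID"][named]
  }
  dose <- function(x) {
    a <- strsplit(gsub("\\|", "/", x), "/", fixed = FALSE)
    vapply(a, function(al) {
      if (any(is.na(al)) || any(al == ".")) return(NA_real_)
      sum(al == "1")
    }, 0)
  }
  d <- t(apply(gt, 1, dose))
  if (ncol(gt) == 1L) d <- matrix(d, ncol = 1L)
  GenotypeMatrix(t(d), markerIds = ids, individualIds = colnames(gt))
}

#' Write genotypes in the matrix-TSV dialect
#'
#' The exact inverse of [readGenotypes()]'s `matrix-tsv` dialect: header of
#' marker ids, one row per individual, missing dosages written as `NA`.
#'
#' @param x a [GenotypeMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(x, path) {
  d <- dosages(x)
  out <- c(paste(c("id", colnames(d)), collapse = "\t"),
           vapply(seq_len(nrow(d)), function(j) {
             v <- d[j, ]
             s <- ifelse(is.na(v), "NA", format(v, trim = TRUE,
                                                scientific = FALSE))
             paste(c(rownames(d)[j], s), collapse = "\t")
           }, ""))
  writeLines(out, path)
  invisible(path)
}

#' Read a phenotype table
#'
#' Two-column TSV (id, value); `#` comment lines ignored.
#'
#' @param path file path.
#' @return named numeric vector of trait records.
#' @export
readPhenotypes <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("phenotype file needs columns id and value")
  setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
}

#' Write a phenotype table
#' @param y named numeric vector of records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePhenotypes <- function(y, path) {
  write.table(data.frame(id = names(y), value = unname(y)), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn GenotypeMatrix-class marker ids.
#' @param x a GenotypeMatrix.
#' @export
setMethod("markerIds", "GenotypeMatrix", function(x) colnames(x@dosages))

#' @describeIn GenotypeMatrix-class individual ids.
#' @export
setMethod("individualIds", "GenotypeMatrix", function(x) rownames(x@dosages))

#' @describeIn GenotypeMatrix-class raw dosage matrix.
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@dosages)

#' @describeIn GenotypeMatrix-class allele frequencies.
#' @export
setMethod("alleleFreq", "GenotypeMatrix",
          function(x) setNames(x@alleleFreq, colnames(x@dosages)))

#' @describeIn GenotypeMatrix-class standardized design matrix.
#' @export
setMethod("standardized", "GenotypeMatrix", function(x) x@standardized)

#' Subset a GenotypeMatrix by individuals
#'
#' Row subsetting keeps the allele frequencies (and hence the column
#' scaling) of the full object, so training and evaluation subsets share one
#' standardization — required for predictions to be comparable.
#'
#' @param x a [GenotypeMatrix-class].
#' @param i individual ids, indices or a logical vector.
#' @param j,drop,... unused (column subsetting is not supported; rebuild via
#'   [GenotypeMatrix()] instead, because frequencies are per-marker).
#' @return a [GenotypeMatrix-class] with the selected rows.
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (!missing(j)) stop("column subsetting not supported; see ?GenotypeMatrix")
  initialize(x, dosages = x@dosages[i, , drop = FALSE],
             standardized = x@standardized[i, , drop = FALSE])
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@dosages), "individuals x",
      ncol(object@dosages), "markers\n")
  cat("  allele freq range:",
      paste(signif(range(object@alleleFreq), 3), collapse = " - "), "\n")
  if (length(object@droppedMarkers))
    cat("  dropped markers:", length(object@droppedMarkers), "\n")
  if (anyNA(object@dosages))
    cat("  missing dosages:", sum(is.na(object@dosages)),
        "(mean-imputed for standardization)\n")
})
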