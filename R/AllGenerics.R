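#' Marker ids of an object
#' @param x an object with markers.
#' @return character vector of marker identifiers.
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' Individual ids of an object
#' @param x an object with individuals.
#' @return character vector of individual identifiers.
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' Raw allele dosages
#' @param x a [GenotypeMatrix-class].
#' @return numeric matrix of dosages (0/1/2, `NA` for missing).
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' Allele frequencies
#' @param x a [GenotypeMatrix-class].
#' @return numeric vector of frequencies of the counted allele.
#' @export
setGeneric("alleleFreq", function(x) standardGeneric("alleleFreq"))

#' Standardized genotype design matrix
#' @param x a [GenotypeMatrix-class].
#' @return numeric matrix of standardized genotypes.
#' @export
setGeneric("standardized", function(x) standardGeneric("standardized"))

#' Estimated marker effects
#' @param x a fit object.
#' @return named numeric vector of per-marker effect estimates.
#' @export
setGeneric("markerEffects", function(x) standardGeneric("markerEffects"))

#' Posterior probability of the big-variance component
#' @param x a fit object.
#' @return named numeric vector in \[0, 1\].
#' @export
setGeneric("probBig", function(x) standardGeneric("probBig"))

#' Pedigree records
#' @param x a [Pedigree-class].
#' @return the underlying data.frame of pedigree records.
#' @export
setGeneric("pedRecords", function(x) standardGeneric("pedRecords"))
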