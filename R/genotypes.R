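#' Genotype matrix container
#'
#' Holds biallelic SNP dosages for a set of individuals in a delimited
#' genomic region: a `samples` vector, a `loci` tibble (chrom, pos, id,
#' ref, alt, in genomic order) and an integer dosage matrix
#' (individuals x loci) coded 0 = homozygous reference, 1 = heterozygous,
#' 2 = homozygous alternate, `NA` = missing.
#'
#' @param samples character vector of unique individual IDs.
#' @param loci tibble with columns `chrom`, `pos`, `id`, `ref`, `alt`.
#' @param dosages integer matrix, `length(samples)` rows and
#'   `nrow(loci)` columns; values in \{0, 1, 2, NA\}.
#'
#' @return An object of class `hap_genotypes`.
#' @export
hap_genotypes <- function(samples, loci, dosages) {
  samples <- as.character(samples)
  if (anyDuplicated(samples)) {
    abort("sample IDs must be unique")
  }
  loci <- as_tibble(loci)
  needed <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(needed %in% names(loci))) {
    abort(paste0("loci must have columns: ", paste(needed, collapse = ", ")))
  }
  if (anyDuplicated(loci$id)) {
    abort("locus IDs must be unique")
  }
  # genomic order within chromosome is an invariant of the container
  ord <- order(loci$chrom, loci$pos)
  loci <- loci[ord, ]
  dosages <- as.matrix(dosages)[, ord, drop = FALSE]
  storage.mode(dosages) <- "integer"
  if (nrow(dosages) != length(samples) || ncol(dosages) != nrow(loci)) {
    abort("dosage matrix dimensions must match samples x loci")
  }
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && !all(bad %in% 0:2)) {
    abort("dosages must be 0, 1, 2 or NA")
  }
  dimnames(dosages) <- list(samples, loci$id)
  structure(
    list(samples = samples, loci = loci, dosages = dosages),
    class = "hap_genotypes"
  )
}

#' @export
print.hap_genotypes <- function(x, ...) {
  rng <- range(x$loci$pos)
  cat(sprintf(
    "<hap_genotypes> %d individuals x %d biallelic SNPs (%s:%d-%d)\n",
    length(x$samples), nrow(x$loci), x$loci$chrom[1], rng[1], rng[2]
  ))
  invisible(x)
}

#' @export
dim.hap_genotypes <- function(x) dim(x$dosages)

#' Coerce phenotype input to the canonical two-column tibble
#'
#' Accepts a named numeric vector or a two-column data frame
#' (individual ID, numeric value) and returns a tibble with columns
#' `sample` and `value`.
#'
#' @param x named numeric vector or two-column data frame.
#' @return tibble with columns `sample` (character) and `value` (numeric).
#' @export
as_phenotype <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) {
    out <- tibble(sample = names(x), value = unname(x))
  } else if (is.data.frame(x) && ncol(x) >= 2) {
    out <- tibble(sample = as.character(x[[1]]), value = as.numeric(x[[2]]))
  } else {
    abort("phenotype must be a named numeric vector or a two-column table")
  }
  if (anyDuplicated(out$sample)) abort("duplicate individual IDs in phenotype")
  out
}

#' Coerce metadata input to the canonical two-column tibble
#'
#' @param x named character vector or two-column data frame
#'   (individual ID, categorical label).
#' @return tibble with columns `sample` and `group` (both character).
#' @export
as_metadata <- function(x) {
  if (is.null(x)) return(tibble(sample = character(), group = character()))
  if (is.atomic(x) && !is.null(names(x))) {
    out <- tibble(sample = names(x), group = as.character(unname(x)))
  } else if (is.data.frame(x) && ncol(x) >= 2) {
    out <- tibble(sample = as.character(x[[1]]), group = as.character(x[[2]]))
  } else {
    abort("metadata must be a named vector or a two-column table")
  }
  if (anyDuplicated(out$sample)) abort("duplicate individual IDs in metadata")
  out
}

#' Metadata label for a set of individuals, with "Misc" fallback
#'
#' Individuals absent from the metadata table receive the label "Misc".
#'
#' @param samples character vector of individual IDs.
#' @param metadata tibble from [as_metadata()], or `NULL`.
#' @return character vector of labels, one per sample.
#' @export
metadata_labels <- function(samples, metadata = NULL) {
  meta <- as_metadata(metadata)
  lab <- meta$group[match(samples, meta$sample)]
  lab[is.na(lab)] <- "Misc"
  lab
}
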