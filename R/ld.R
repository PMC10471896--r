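# Pairwise linkage disequilibrium (R^2) from dosages, and intra-Marker-
# Group linkage summaries.

#' Compute the pairwise R^2 LD matrix from genotype dosages
#'
#' Entry (i, j) is the squared Pearson correlation of the dosage vectors
#' of loci i and j over individuals non-missing at both loci (composite /
#' dosage r^2, the statistic plink's `--r2 square` reports for unphased
#' data). Pairs with fewer than two complete observations, or with a
#' monomorphic member, are set to 0 and counted; the diagonal is set
#' to 1.
#'
#' @param g a [hap_genotypes()] object with at least 2 loci and 2 samples.
#' @return `hap_ld` matrix (loci x loci).
#' @export
compute_ld_matrix <- function(g) {
  stopifnot(inherits(g, "hap_genotypes"))
  d <- g$dosages
  if (ncol(d) < 2 || nrow(d) < 2) abort("need at least 2 loci and 2 samples")
  sds <- apply(d, 2, sd, na.rm = TRUE)
  if (all(is.na(sds) | sds == 0)) {
    abort("all loci are monomorphic; LD is undefined")
  }
  r <- suppressWarnings(cor(d, use = "pairwise.complete.obs"))
  r2 <- r^2
  n_undef <- sum(is.na(r2[upper.tri(r2)]))
  if (n_undef > 0) {
    inform(sprintf(
      "compute_ld_matrix: %d undefined pair(s) (monomorphic or <2 complete obs) set to 0",
      n_undef
    ))
  }
  r2[is.na(r2)] <- 0
  diag(r2) <- 1
  r2[r2 > 1] <- 1
  as_ld_matrix(r2, g$loci$id)
}

#' Intra-Marker-Group linkage distributions
#'
#' For each Marker Group (noise excluded) collects the off-diagonal R^2
#' values among its member loci — the raw material of the dashboard's
#' intra-MG linkage boxplot. A k-SNP group yields k(k-1)/2 values;
#' singletons yield none.
#'
#' @param ld `hap_ld` matrix.
#' @param mgs a `hap_mgs` object from [cluster_snps()] over the same loci.
#' @return tibble with columns `mg`, `n_pairs`, `median_r2`, `iqr_r2`
#'   and a list-column `r2` holding the pairwise values.
#' @export
intra_mg_linkage <- function(ld, mgs) {
  stopifnot(inherits(mgs, "hap_mgs"))
  loci <- rownames(ld)
  if (!all(mgs$assignment$id %in% loci)) {
    abort("Marker Groups refer to loci absent from the LD matrix")
  }
  groups <- mgs$groups
  out <- lapply(seq_len(nrow(groups)), function(i) {
    members <- groups$loci[[i]]
    sub <- unclass(ld)[members, members, drop = FALSE]
    vals <- sub[upper.tri(sub)]
    tibble(
      mg = groups$mg[i],
      n_pairs = length(vals),
      median_r2 = if (length(vals)) median(vals) else NA_real_,
      iqr_r2 = if (length(vals)) unname(diff(quantile(vals, c(0.25, 0.75)))) else NA_real_,
      r2 = list(vals)
    )
  })
  dplyr::bind_rows(out)
}
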