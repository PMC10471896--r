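# Descriptive phenotype-association scores for SNPs, Marker Groups and
# haplotype groups, plus metadata composition.
#
# The score is a weighted-mean difference between the alternate- and
# reference-allele pools, assuming additive heterozygote effects:
# homozygotes carry two copies of their allele and enter their pool with
# weight 2, heterozygotes carry one copy of each and enter both pools
# with weight 1. No p-values: the statistic is descriptive by design.

# Shared engine: columns of `m` are markers (dosage-coded 0/1/2/NA),
# `pheno` is the canonical two-column tibble. Individuals without
# phenotype are dropped up front; missing genotypes drop an individual
# at that marker only.
weighted_allele_scores <- function(m, pheno) {
  samples <- rownames(m)
  keep <- samples %in% pheno$sample
  if (!any(keep)) abort("no phenotyped individuals overlap the genotypes")
  m <- m[keep, , drop = FALSE]
  ph <- pheno$value[match(samples[keep], pheno$sample)]

  is0 <- !is.na(m) & m == 0L
  is1 <- !is.na(m) & m == 1L
  is2 <- !is.na(m) & m == 2L
  n0 <- colSums(is0); n1 <- colSums(is1); n2 <- colSums(is2)
  ref_w <- 2 * n0 + n1
  alt_w <- 2 * n2 + n1
  ref_sum <- 2 * colSums(is0 * ph) + colSums(is1 * ph)
  alt_sum <- 2 * colSums(is2 * ph) + colSums(is1 * ph)
  score <- alt_sum / alt_w - ref_sum / ref_w
  flagged <- ref_w == 0 | alt_w == 0
  score[flagged] <- NA_real_
  tibble(
    marker = colnames(m), n0 = as.integer(n0), n1 = as.integer(n1),
    n2 = as.integer(n2), score = as.numeric(score), flagged = flagged
  )
}

#' Per-SNP phenotype-association scores
#'
#' For each locus, the reference pool holds hom-ref individuals with
#' weight 2 and heterozygotes with weight 1; the alternate pool holds
#' hom-alt with weight 2 and heterozygotes with weight 1. The score is
#' weighted mean(phenotype, alt pool) minus weighted mean(phenotype,
#' ref pool), in phenotype units. Loci with an empty pool get `NA` and
#' are flagged.
#'
#' @param g a [hap_genotypes()] object.
#' @param pheno phenotype, coerced via [as_phenotype()].
#' @return tibble: `id`, `chrom`, `pos`, allelic counts `n0`/`n1`/`n2`
#'   (among phenotyped, genotyped individuals), `score`, `flagged`.
#' @export
snp_phenotype_association <- function(g, pheno) {
  stopifnot(inherits(g, "hap_genotypes"))
  pheno <- as_phenotype(pheno)
  res <- weighted_allele_scores(g$dosages, pheno)
  dplyr::bind_cols(
    g$loci[match(res$marker, g$loci$id), c("id", "chrom", "pos")],
    res[, c("n0", "n1", "n2", "score", "flagged")]
  )
}

#' Per-Marker-Group phenotype-association scores
#'
#' The identical weighted-pool formula applied to the Marker-Group
#' allele matrix in place of SNP dosages.
#'
#' @param alleles matrix from [assign_mg_alleles()].
#' @param pheno phenotype, coerced via [as_phenotype()].
#' @return tibble: `mg`, `n0`, `n1`, `n2`, `score`, `flagged`.
#' @export
mg_association <- function(alleles, pheno) {
  pheno <- as_phenotype(pheno)
  res <- weighted_allele_scores(as.matrix(alleles), pheno)
  dplyr::rename(res, mg = "marker")
}

#' Per-haplotype phenotype and metadata summaries
#'
#' For every labelled haplotype: group size, phenotype summary
#' (mean/median/quartiles/sd over phenotyped members) and metadata
#' composition (counts per category, absent individuals under "Misc").
#' With `isolate_groups`, phenotype statistics are restricted to members
#' whose metadata label is in the set; sizes and metadata counts still
#' describe all members.
#'
#' @param result a `hap_result` from [run_haplotyping()].
#' @param isolate_groups optional character vector of metadata labels to
#'   which phenotype statistics are restricted. Labels absent from the
#'   data raise a warning and are ignored.
#' @return list of class `hap_summaries`: `stats` (tibble per haplotype:
#'   `label`, `n`, `n_pheno`, `mean`, `median`, `q25`, `q75`, `sd`) and
#'   `meta` (long tibble: `label`, `group`, `n`).
#' @export
haplotype_summaries <- function(result, isolate_groups = NULL) {
  stopifnot(inherits(result, "hap_result"))
  ht <- result$hap_table
  assign <- ht$assignment[ht$assignment$label != "UNASSIGNED", ]
  labels <- ht$haps$label
  meta_lab <- metadata_labels(assign$sample, result$metadata)

  if (!is.null(isolate_groups)) {
    present <- unique(metadata_labels(result$hap_table$assignment$sample, result$metadata))
    absent <- setdiff(isolate_groups, present)
    if (length(absent)) {
      warn(paste0(
        "isolate_groups label(s) absent from metadata, ignored: ",
        paste(absent, collapse = ", ")
      ))
      isolate_groups <- setdiff(isolate_groups, absent)
    }
    if (!length(isolate_groups)) isolate_groups <- NULL
  }

  pheno <- result$phenotype
  stats <- dplyr::bind_rows(lapply(labels, function(lab) {
    members <- assign$sample[assign$label == lab]
    use <- members
    if (!is.null(isolate_groups)) {
      use <- members[meta_lab[assign$label == lab] %in% isolate_groups]
    }
    vals <- if (is.null(pheno)) numeric(0) else {
      pheno$value[match(use, pheno$sample)]
    }
    vals <- vals[!is.na(vals)]
    tibble(
      label = lab, n = length(members), n_pheno = length(vals),
      mean = if (length(vals)) mean(vals) else NA_real_,
      median = if (length(vals)) median(vals) else NA_real_,
      q25 = if (length(vals)) unname(quantile(vals, 0.25)) else NA_real_,
      q75 = if (length(vals)) unname(quantile(vals, 0.75)) else NA_real_,
      sd = if (length(vals) > 1) sd(vals) else NA_real_
    )
  }))

  meta <- dplyr::count(
    tibble(label = assign$label, group = meta_lab),
    .data$label, .data$group, name = "n"
  )
  structure(list(stats = stats, meta = meta, isolate_groups = isolate_groups),
    class = "hap_summaries")
}

#' @export
print.hap_summaries <- function(x, ...) {
  cat("<hap_summaries>\n")
  print(x$stats)
  invisible(x)
}

#' Marker-Group summary table (dashboard corner table)
#'
#' @param result a `hap_result`.
#' @param snp_assoc optional precomputed [snp_phenotype_association()]
#'   tibble; computed here when `NULL` and a phenotype is attached.
#' @return tibble: `mg`, `n_snps`, `bp_min`, `bp_max`, `mean_score`.
#' @export
mg_summary <- function(result, snp_assoc = NULL) {
  stopifnot(inherits(result, "hap_result"))
  loci <- result$genotypes_loci
  groups <- result$mgs$groups
  dplyr::bind_rows(lapply(seq_len(nrow(groups)), function(i) {
    ids <- groups$loci[[i]]
    pos <- loci$pos[match(ids, loci$id)]
    sc <- if (!is.null(snp_assoc)) {
      snp_assoc$score[match(ids, snp_assoc$id)]
    } else {
      NA_real_
    }
    tibble(
      mg = groups$mg[i], n_snps = length(ids),
      bp_min = min(pos), bp_max = max(pos),
      mean_score = if (all(is.na(sc))) NA_real_ else mean(sc, na.rm = TRUE)
    )
  }))
}
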