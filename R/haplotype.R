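# Collapse individuals onto Marker-Group alleles and label the frequent
# allele combinations as haplotype groups.

#' Assign each individual its modal allelic state per Marker Group
#'
#' For every individual and Marker Group, the assigned allele is the
#' arithmetic mode of the individual's non-missing dosages (0/1/2) over
#' the group's member SNPs. Ties are broken towards the dosage closest
#' to the group-wide mean dosage (computed over all individuals and
#' member SNPs); a residual tie goes to the lower dosage. Individuals
#' missing every member SNP are unresolved (`NA`).
#'
#' @param g a [hap_genotypes()] object.
#' @param mgs a `hap_mgs` object whose loci are a subset of `g`'s.
#' @return integer matrix (individuals x Marker Groups) in \{0, 1, 2, NA\},
#'   columns named `MG1`, `MG2`, ...; noise SNPs play no part.
#' @export
assign_mg_alleles <- function(g, mgs) {
  stopifnot(inherits(g, "hap_genotypes"), inherits(mgs, "hap_mgs"))
  if (!all(mgs$assignment$id %in% g$loci$id)) {
    abort("Marker Groups refer to loci absent from the genotype matrix")
  }
  n <- length(g$samples)
  k <- nrow(mgs$groups)
  out <- matrix(NA_integer_, n, k, dimnames = list(g$samples, mgs$groups$mg))
  for (j in seq_len(k)) {
    sub <- g$dosages[, mgs$groups$loci[[j]], drop = FALSE]
    counts <- cbind(
      rowSums(sub == 0L, na.rm = TRUE),
      rowSums(sub == 1L, na.rm = TRUE),
      rowSums(sub == 2L, na.rm = TRUE)
    )
    mg_mean <- mean(sub, na.rm = TRUE)
    out[, j] <- mode_with_tiebreak(counts, mg_mean)
  }
  out
}

# counts: n x 3 matrix of per-individual counts of dosages 0/1/2.
# Mode; ties -> dosage nearest mg_mean; then lower dosage. All-zero -> NA.
mode_with_tiebreak <- function(counts, mg_mean) {
  # candidate dosages ranked once: distance to the group mean, then value
  pref <- order(abs(0:2 - mg_mean), 0:2)
  best <- pmax(counts[, 1], counts[, 2], counts[, 3])
  res <- rep(NA_integer_, nrow(counts))
  for (d in rev(pref)) {
    hit <- counts[, d] == best & best > 0L
    res[hit] <- d - 1L # later (more preferred) passes overwrite
  }
  res
}

#' Tabulate, filter and label haplotype combinations
#'
#' Individuals with a complete (no-`NA`) Marker-Group allele vector are
#' grouped by identical vectors. Combinations carried by at least
#' `min_hap` individuals are labelled `A`, `B`, ... by descending count
#' (ties: lexicographic allele vector); everyone else is `UNASSIGNED`.
#' Marker Groups whose allele is identical across all labelled rows are
#' invariant and dropped from the retained-MG list. At most 26 labels
#' exist; overflow keeps the 26 largest with a warning.
#'
#' @param alleles matrix from [assign_mg_alleles()].
#' @param min_hap minimum number of individuals per labelled haplotype
#'   (default 9).
#' @return A `hap_table` object: list with `haps` (tibble: `label`, `n`,
#'   one column per Marker Group), `retained_mgs` (character),
#'   `assignment` (tibble: `sample`, `label`).
#' @export
build_haplotypes <- function(alleles, min_hap = 9) {
  if (!is.numeric(min_hap) || min_hap < 1) abort("min_hap must be >= 1")
  alleles <- as.matrix(alleles)
  if (ncol(alleles) < 1) abort("need at least one Marker Group column")
  mgs <- colnames(alleles)
  if (is.null(mgs)) mgs <- paste0("MG", seq_len(ncol(alleles)))

  complete <- !apply(alleles, 1, anyNA)
  key <- rep(NA_character_, nrow(alleles))
  key[complete] <- apply(alleles[complete, , drop = FALSE], 1, paste, collapse = "")

  tab <- table(key[complete])
  eligible <- tab[tab >= min_hap]
  ord <- order(-as.integer(eligible), names(eligible))
  eligible <- eligible[ord]
  if (length(eligible) > 26) {
    warn(sprintf(
      "%d combinations exceed min_hap; only the 26 largest receive labels A-Z",
      length(eligible)
    ))
    eligible <- eligible[1:26]
  }
  labels <- LETTERS[seq_along(eligible)]

  haps <- tibble(label = labels, n = as.integer(eligible))
  allele_rows <- do.call(rbind, lapply(names(eligible), function(k) {
    as.integer(strsplit(k, "")[[1]])
  }))
  if (is.null(allele_rows)) allele_rows <- matrix(integer(0), 0, length(mgs))
  colnames(allele_rows) <- mgs
  haps <- dplyr::bind_cols(haps, as_tibble(allele_rows))

  if (nrow(haps) == 0) {
    retained <- character(0)
    warn("no haplotype combination reaches min_hap; all individuals UNASSIGNED")
  } else {
    variant <- vapply(mgs, function(m) length(unique(haps[[m]])) > 1, logical(1))
    retained <- mgs[variant]
    if (!length(retained)) {
      warn("all Marker Groups are invariant across the labelled haplotypes")
    }
  }

  lab_for_key <- setNames(labels, names(eligible))
  assignment <- tibble(
    sample = rownames(alleles) %||% paste0("ind", seq_len(nrow(alleles))),
    label = dplyr::coalesce(unname(lab_for_key[key]), "UNASSIGNED")
  )
  structure(
    list(haps = haps, retained_mgs = retained, assignment = assignment,
         min_hap = min_hap),
    class = "hap_table"
  )
}

#' @export
print.hap_table <- function(x, ...) {
  cat(sprintf(
    "<hap_table> %d labelled haplotype(s) (min_hap = %d), %d retained / %d Marker Groups, %d UNASSIGNED\n",
    nrow(x$haps), x$min_hap, length(x$retained_mgs),
    ncol(x$haps) - 2L, sum(x$assignment$label == "UNASSIGNED")
  ))
  if (nrow(x$haps)) print(x$haps)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full local-haplotyping pipeline across an epsilon grid
#'
#' For each epsilon in the grid: cluster SNPs into Marker Groups
#' ([cluster_snps()]), collapse individuals onto modal Marker-Group
#' alleles ([assign_mg_alleles()]) and label the frequent combinations
#' as haplotypes ([build_haplotypes()]). The LD matrix is computed from
#' the genotypes when not supplied.
#'
#' @param g a [hap_genotypes()] object.
#' @param ld optional `hap_ld` matrix over the same loci; computed via
#'   [compute_ld_matrix()] when `NULL`.
#' @param phenotype optional phenotype (see [as_phenotype()]).
#' @param metadata optional metadata (see [as_metadata()]).
#' @param epsilon_grid DBSCAN radii to scan (default 0.2-1.0).
#' @param min_hap minimum individuals per labelled haplotype (default 9).
#' @param min_points DBSCAN core threshold (default 5).
#' @return A `hap_run` object: named list `results` of `hap_result`
#'   (one per epsilon: `epsilon`, `mgs`, `mg_alleles`, `hap_table`,
#'   `genotypes_loci`, `phenotype`, `metadata`), plus the shared inputs.
#' @export
run_haplotyping <- function(g, ld = NULL, phenotype = NULL, metadata = NULL,
                            epsilon_grid = c(0.2, 0.4, 0.6, 0.8, 1.0),
                            min_hap = 9, min_points = 5) {
  stopifnot(inherits(g, "hap_genotypes"))
  if (is.null(ld)) {
    ld <- compute_ld_matrix(g)
  } else if (!identical(rownames(ld), g$loci$id)) {
    abort("LD matrix loci do not match the genotype loci")
  }
  pheno <- if (!is.null(phenotype)) as_phenotype(phenotype) else NULL
  meta <- if (!is.null(metadata)) as_metadata(metadata) else NULL
  if (!is.null(pheno)) {
    extra <- setdiff(pheno$sample, g$samples)
    missing <- setdiff(g$samples, pheno$sample)
    if (length(extra) || length(missing)) {
      warn(sprintf(
        "phenotype/genotype sample mismatch: %d phenotyped individual(s) absent from the VCF, %d VCF individual(s) lack phenotype; using the intersection for associations",
        length(extra), length(missing)
      ))
      pheno <- pheno[pheno$sample %in% g$samples, ]
    }
  }

  scans <- scan_epsilon(ld, epsilon_grid, min_points)
  results <- lapply(scans, function(mgs) {
    alleles <- assign_mg_alleles(g, mgs)
    ht <- if (ncol(alleles) > 0) {
      build_haplotypes(alleles, min_hap)
    } else {
      # no Marker Groups at this epsilon: everyone is unassigned
      structure(
        list(
          haps = tibble(label = character(), n = integer()),
          retained_mgs = character(0),
          assignment = tibble(sample = g$samples, label = "UNASSIGNED"),
          min_hap = min_hap
        ),
        class = "hap_table"
      )
    }
    structure(
      list(epsilon = mgs$epsilon, mgs = mgs, mg_alleles = alleles,
           hap_table = ht, genotypes_loci = g$loci,
           phenotype = pheno, metadata = meta),
      class = "hap_result"
    )
  })
  structure(
    list(results = results, epsilons = sort(unique(epsilon_grid)),
         genotypes = g, ld = ld, phenotype = pheno, metadata = meta,
         min_hap = min_hap, min_points = min_points),
    class = "hap_run"
  )
}

#' @export
print.hap_run <- function(x, ...) {
  cat(sprintf(
    "<hap_run> %d individuals x %d SNPs, %d epsilon level(s): %s\n",
    length(x$genotypes$samples), nrow(x$genotypes$loci),
    length(x$results), paste(names(x$results), collapse = ", ")
  ))
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    cat(sprintf(
      "  eps %-6s %2d MG(s), %2d haplotype(s), %3d UNASSIGNED\n",
      nm, nrow(r$mgs$groups), nrow(r$hap_table$haps),
      sum(r$hap_table$assignment$label == "UNASSIGNED")
    ))
  }
  invisible(x)
}

#' @export
print.hap_result <- function(x, ...) {
  cat(sprintf(
    "<hap_result> epsilon = %g: %d Marker Group(s), %d labelled haplotype(s)\n",
    x$epsilon, nrow(x$mgs$groups), nrow(x$hap_table$haps)
  ))
  invisible(x)
}
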