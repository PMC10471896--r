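# Synthetic populations with planted Marker-Group blocks, haplotype
# combinations, phenotype effects and metadata labels, plus the ground
# truth needed to validate every pipeline stage.

#' Specify a synthetic population
#'
#' Individuals carry two haplotype-template copies drawn from the
#' template frequencies; with probability `inbreeding` the two copies
#' are identical by descent (default 0.98, a predominantly selfing
#' population such as a domesticated legume panel — heterozygotes occur
#' but are rare). SNPs inside a planted block copy the block allele of
#' each copy with a per-copy flip probability calibrated in closed form
#' so the pairwise within-block dosage R^2 hits `r2`; noise SNPs are
#' independent with allele frequencies uniform in \[0.1, 0.9\].
#' Phenotype is the mean of the two copies' template effects plus
#' Gaussian noise, so a homozygote's expectation equals its template
#' effect. Each template maps to one metadata label, contaminated at a
#' fixed rate.
#'
#' @param n_individuals population size (default 200).
#' @param blocks data frame with columns `n_snps`, `r2` (target pairwise
#'   within-block R^2 in \[0, 1\]), `span_bp`; default three blocks of
#'   20 SNPs at R^2 0.9.
#' @param n_noise number of unlinked noise SNPs (default 15).
#' @param templates 0/1 matrix, one row per haplotype template, one
#'   column per block (per-copy allele).
#' @param frequencies template population frequencies, summing to 1
#'   (default 0.5/0.3/0.2).
#' @param effects per-template phenotype effects (default 0, +2, -1).
#' @param sigma phenotype noise standard deviation (default 0.5).
#' @param meta_labels one metadata label per template.
#' @param contamination probability an individual receives a random
#'   other label (default 0.1).
#' @param inbreeding probability the two copies are identical by
#'   descent (default 0.98).
#' @param chrom,start chromosome name and region start (bp).
#' @param seed RNG seed; every draw derives from it.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_individuals = 200,
                         blocks = data.frame(n_snps = c(20, 20, 20),
                                             r2 = 0.9, span_bp = 5000),
                         n_noise = 15,
                         templates = rbind(c(0, 0, 0), c(1, 0, 1), c(1, 1, 0)),
                         frequencies = c(0.5, 0.3, 0.2),
                         effects = c(0, 2, -1),
                         sigma = 0.5,
                         meta_labels = c("PopA", "PopB", "PopC"),
                         contamination = 0.1,
                         inbreeding = 0.98,
                         chrom = "chr1", start = 1e6,
                         seed = 1) {
  blocks <- as.data.frame(blocks)
  templates <- as.matrix(templates)
  if (abs(sum(frequencies) - 1) > 1e-8) abort("template frequencies must sum to 1")
  if (any(blocks$r2 < 0 | blocks$r2 > 1)) abort("R^2 targets must lie in [0, 1]")
  if (n_individuals < 1 || any(blocks$n_snps < 1)) abort("counts must be positive")
  if (ncol(templates) != nrow(blocks)) {
    abort("templates must have one column per block")
  }
  if (nrow(templates) != length(frequencies) ||
      length(effects) != length(frequencies) ||
      length(meta_labels) != length(frequencies)) {
    abort("templates, frequencies, effects and meta_labels must agree in length")
  }
  if (!all(templates %in% 0:1)) abort("template alleles must be 0/1 (per copy)")
  structure(
    list(
      n_individuals = n_individuals, blocks = blocks, n_noise = n_noise,
      templates = templates, frequencies = frequencies, effects = effects,
      sigma = sigma, meta_labels = meta_labels, contamination = contamination,
      inbreeding = inbreeding, chrom = chrom, start = start, seed = seed
    ),
    class = "fixture_spec"
  )
}

# Closed-form per-copy flip probability hitting a target pairwise
# within-block dosage R^2. With per-copy flip probability q, block
# alt-allele frequency p and inbreeding F, the correlation between two
# block SNPs is r = tV / ((1 - t)/2 + tV), t = (1 - 2q)^2,
# V = Var(copy1 + copy2 allele) = 2 p (1 - p) (1 + F). Solving for t at
# r = sqrt(target) gives the flip probability.
flip_prob_for_r2 <- function(r2_target, p, inbreeding) {
  if (p <= 0 || p >= 1) {
    abort("planted block is invariant across templates; R^2 calibration infeasible")
  }
  r <- sqrt(r2_target)
  if (r == 0) return(0.5)
  V <- 2 * p * (1 - p) * (1 + inbreeding)
  t <- (r / 2) / (V * (1 - r) + r / 2)
  (1 - sqrt(t)) / 2
}

#' Generate a synthetic population from a specification
#'
#' Draws the population, computes its LD matrix and, when `dir` is
#' given, writes the four input files in exactly the dialects the
#' readers consume (plain VCF 4.2, plink-square LD text, two-column
#' TSVs) plus a `truth.json` ground-truth record. Fully reproducible
#' from `spec$seed`.
#'
#' @param spec a [fixture_spec()].
#' @param dir optional output directory.
#' @return list with `genotypes` ([hap_genotypes()]), `ld` (`hap_ld`),
#'   `phenotype`, `metadata` (tibbles), `truth` (list: `loci` tibble
#'   id/block, `individuals` tibble sample/copy templates/planted
#'   combination, `flip_prob`, `effects`, `seed`) and `paths` (written
#'   files, or `NULL`).
#' @export
generate_population <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n <- spec$n_individuals
  H <- length(spec$frequencies)
  B <- nrow(spec$blocks)

  c1 <- sample.int(H, n, replace = TRUE, prob = spec$frequencies)
  ibd <- runif(n) < spec$inbreeding
  c2 <- ifelse(ibd, c1, sample.int(H, n, replace = TRUE, prob = spec$frequencies))

  p_blk <- as.vector(spec$frequencies %*% spec$templates)
  q_blk <- vapply(seq_len(B), function(b) {
    flip_prob_for_r2(spec$blocks$r2[b], p_blk[b], spec$inbreeding)
  }, numeric(1))

  # positions: blocks laid out left to right with gaps, noise scattered
  gap <- 2000
  blk_start <- spec$start + cumsum(c(0, spec$blocks$span_bp[-B] + gap))
  region_end <- blk_start[B] + spec$blocks$span_bp[B]

  loci_list <- list()
  dos_list <- list()
  for (b in seq_len(B)) {
    k <- spec$blocks$n_snps[b]
    a1 <- spec$templates[c1, b]
    a2 <- spec$templates[c2, b]
    dos <- matrix(0L, n, k)
    for (s in seq_len(k)) {
      f1 <- runif(n) < q_blk[b]
      f2 <- runif(n) < q_blk[b]
      dos[, s] <- as.integer(xor(a1 == 1, f1)) + as.integer(xor(a2 == 1, f2))
    }
    pos <- sort(sample.int(spec$blocks$span_bp[b], k)) + blk_start[b] - 1L
    loci_list[[b]] <- tibble(pos = as.integer(pos), block = paste0("block", b))
    dos_list[[b]] <- dos
  }
  if (spec$n_noise > 0) {
    k <- spec$n_noise
    p_noise <- runif(k, 0.1, 0.9)
    dos <- sapply(seq_len(k), function(s) {
      as.integer(runif(n) < p_noise[s]) + as.integer(runif(n) < p_noise[s])
    })
    pos <- sort(sample(seq(spec$start, region_end), k))
    loci_list[[B + 1]] <- tibble(pos = as.integer(pos), block = "noise")
    dos_list[[B + 1]] <- dos
  }

  loci <- dplyr::bind_rows(loci_list)
  dosages <- do.call(cbind, dos_list)
  # unique positions, then genomic order
  while (anyDuplicated(loci$pos)) {
    dup <- which(duplicated(loci$pos))
    loci$pos[dup] <- loci$pos[dup] + 1L
  }
  ord <- order(loci$pos)
  loci <- loci[ord, ]
  dosages <- dosages[, ord, drop = FALSE]

  alleles <- t(sapply(seq_len(nrow(loci)), function(i) {
    sample(c("A", "C", "G", "T"), 2)
  }))
  samples <- sprintf("ind%03d", seq_len(n))
  loci_tbl <- tibble(
    chrom = spec$chrom, pos = loci$pos,
    id = paste0(spec$chrom, "_", loci$pos),
    ref = alleles[, 1], alt = alleles[, 2]
  )
  g <- hap_genotypes(samples, loci_tbl, dosages)

  phen_mean <- (spec$effects[c1] + spec$effects[c2]) / 2
  phenotype <- tibble(sample = samples,
    value = phen_mean + rnorm(n, 0, spec$sigma))

  base_lab <- spec$meta_labels[c1]
  contam <- runif(n) < spec$contamination
  other <- vapply(seq_len(n), function(i) {
    pool <- setdiff(spec$meta_labels, base_lab[i])
    if (length(pool)) sample(pool, 1) else base_lab[i]
  }, character(1))
  metadata <- tibble(sample = samples,
    group = ifelse(contam, other, base_lab))

  combo <- apply(spec$templates[c1, , drop = FALSE] +
    spec$templates[c2, , drop = FALSE], 1, paste, collapse = "")
  truth <- list(
    loci = tibble(id = loci_tbl$id, block = loci$block),
    individuals = tibble(
      sample = samples, copy1 = c1, copy2 = c2, combination = combo
    ),
    flip_prob = q_blk, effects = spec$effects,
    frequencies = spec$frequencies, inbreeding = spec$inbreeding,
    seed = spec$seed
  )

  ld <- compute_ld_matrix(g)

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      vcf = file.path(dir, "population.vcf"),
      ld = file.path(dir, "ld_matrix.tsv"),
      phenotype = file.path(dir, "phenotype.tsv"),
      metadata = file.path(dir, "metadata.tsv"),
      truth = file.path(dir, "truth.json")
    )
    write_vcf(g, paths[["vcf"]])
    write_ld_matrix(ld, paths[["ld"]])
    write_two_col_tsv(phenotype, paths[["phenotype"]])
    write_two_col_tsv(metadata, paths[["metadata"]])
    jsonlite::write_json(
      list(
        loci = truth$loci, individuals = truth$individuals,
        flip_prob = truth$flip_prob, effects = truth$effects,
        frequencies = truth$frequencies, inbreeding = truth$inbreeding,
        seed = truth$seed
      ),
      paths[["truth"]], auto_unbox = TRUE, digits = NA
    )
  }
  list(genotypes = g, ld = ld, phenotype = phenotype, metadata = metadata,
       truth = truth, paths = paths)
}
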