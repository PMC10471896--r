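# Programmatic fixtures shared across tests.

# random valid genotype container
rand_genotypes <- function(n_samples, n_loci, miss_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- runif(n_loci, 0.1, 0.9)
  d <- sapply(seq_len(n_loci), function(j) {
    rbinom(n_samples, 2, p[j])
  })
  if (miss_rate > 0) d[runif(length(d)) < miss_rate] <- NA
  hap_genotypes(
    samples = sprintf("s%03d", seq_len(n_samples)),
    loci = tibble::tibble(
      chrom = "chr1", pos = sort(sample.int(1e6, n_loci)),
      id = sprintf("snp%03d", seq_len(n_loci)),
      ref = "A", alt = "G"
    ),
    dosages = d
  )
}

# random valid LD matrix (symmetric, unit diagonal, [0,1])
rand_ld <- function(n_loci, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(runif(n_loci^2), n_loci)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  localhap::as_ld_matrix(m, sprintf("snp%03d", seq_len(n_loci)))
}

# block-diagonal LD matrix: perfect within-block R^2, zero between
block_ld <- function(sizes) {
  n <- sum(sizes)
  m <- matrix(0, n, n)
  at <- 0
  for (k in sizes) {
    m[at + seq_len(k), at + seq_len(k)] <- 1
    at <- at + k
  }
  localhap::as_ld_matrix(m, sprintf("snp%03d", seq_len(n)))
}

# tiny plain-text VCF written from explicit fields
write_test_vcf <- function(path, rows, samples = c("a", "b", "c")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, rows), path)
  path
}

# minimal stand-in for a hap_run built from explicit per-level
# individual -> label assignments (for controlled clustering-tree tests)
fake_run_hap <- function(assignments, epsilons = seq_along(assignments),
                         phenotype = NULL) {
  results <- lapply(seq_along(assignments), function(i) {
    a <- assignments[[i]]
    structure(
      list(
        epsilon = epsilons[i],
        hap_table = list(assignment = tibble::tibble(
          sample = names(a), label = unname(a)
        )),
        mgs = NULL
      ),
      class = "hap_result"
    )
  })
  names(results) <- as.character(epsilons)
  structure(
    list(results = results, epsilons = epsilons, phenotype = phenotype),
    class = "hap_run"
  )
}

# force a Marker-Group structure over explicit loci sets (bypasses DBSCAN)
mgs_from_blocks <- function(g, blocks) {
  labs <- rep("NOISE", nrow(g$loci))
  for (i in seq_along(blocks)) labs[match(blocks[[i]], g$loci$id)] <- paste0("MG", i)
  structure(
    list(
      epsilon = 1, min_points = 1,
      assignment = tibble::tibble(id = g$loci$id, mg = labs),
      groups = tibble::tibble(
        mg = paste0("MG", seq_along(blocks)),
        n_snps = unname(lengths(blocks)),
        loci = blocks
      )
    ),
    class = "hap_mgs"
  )
}

# Marker-Group allele vectors of the labelled haplotypes, expressed as
# planted-block combination strings (NA when a block is not represented)
labelled_combos <- function(res, truth) {
  memb <- res$mgs$assignment
  blocks <- truth$loci$block[match(memb$id, truth$loci$id)]
  mg_ids <- res$mgs$groups$mg
  haps <- res$hap_table$haps
  if (!length(mg_ids) || nrow(haps) == 0) return(character(0))
  mg_block <- vapply(mg_ids, function(m) {
    names(which.max(table(blocks[memb$mg == m])))
  }, character(1))
  n_blocks <- length(setdiff(unique(truth$loci$block), "noise"))
  vapply(seq_len(nrow(haps)), function(i) {
    v <- rep(NA_integer_, n_blocks)
    for (j in seq_along(mg_ids)) {
      b <- mg_block[j]
      if (b != "noise") {
        v[as.integer(sub("block", "", b))] <- haps[[mg_ids[j]]][i]
      }
    }
    if (anyNA(v)) NA_character_ else paste(v, collapse = "")
  }, character(1))
}

# Fraction of individuals whose assigned haplotype matches their planted
# Marker-Group combination; UNASSIGNED individuals count as mismatches.
haplotype_agreement <- function(res, truth) {
  lab_combo <- labelled_combos(res, truth)
  if (!length(lab_combo)) return(0)
  assign <- res$hap_table$assignment
  pred <- lab_combo[match(assign$label, res$hap_table$haps$label)]
  planted <- truth$individuals$combination[
    match(assign$sample, truth$individuals$sample)]
  mean(!is.na(pred) & pred == planted)
}

# small planted population used by many visual/integration tests
small_pop <- function(seed = 11, n = 120) {
  localhap::generate_population(localhap::fixture_spec(
    n_individuals = n,
    blocks = data.frame(n_snps = c(8, 8, 8), r2 = 0.95, span_bp = 2000),
    n_noise = 6, seed = seed
  ))
}
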