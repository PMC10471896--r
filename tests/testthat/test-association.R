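# Weighted-pool phenotype association scores and group summaries.

assoc_g <- function(d, samples = sprintf("s%d", seq_len(nrow(d)))) {
  hap_genotypes(samples,
    tibble::tibble(chrom = "c", pos = seq_len(ncol(d)) * 10,
      id = paste0("l", seq_len(ncol(d))), ref = "A", alt = "G"), d)
}

test_that("the weighted-pool worked example reproduces exactly", {
  # hom-refs with phenotypes {1, 3}, one het {10}, one hom-alt {6}:
  # ref pool (2*1 + 2*3 + 1*10)/5 = 3.6, alt pool (2*6 + 1*10)/3 = 22/3
  g <- assoc_g(matrix(c(0, 0, 1, 2), ncol = 1))
  ph <- tibble::tibble(sample = paste0("s", 1:4), value = c(1, 3, 10, 6))
  res <- snp_phenotype_association(g, ph)
  expect_equal(res$score, 22 / 3 - 3.6, tolerance = 1e-12)
  expect_equal(c(res$n0, res$n1, res$n2), c(2L, 1L, 1L))
})

test_that("a constant phenotype scores 0 at every polymorphic locus", {
  g <- rand_genotypes(30, 6, seed = 5)
  ph <- tibble::tibble(sample = g$samples, value = 7)
  res <- snp_phenotype_association(g, ph)
  expect_equal(res$score[!res$flagged], rep(0, sum(!res$flagged)))
})

test_that("empty pools are flagged, no phenotype overlap errors", {
  g <- assoc_g(matrix(c(0, 0, 0, 0), ncol = 1))
  ph <- tibble::tibble(sample = paste0("s", 1:4), value = 1:4)
  res <- snp_phenotype_association(g, ph)
  expect_true(res$flagged)
  expect_true(is.na(res$score))
  expect_error(
    snp_phenotype_association(g, tibble::tibble(sample = "x", value = 1)),
    "overlap"
  )
})

test_that("swapping ref/alt encodings negates the score exactly", {
  for (seed in 1:10) {
    g <- rand_genotypes(40, 5, miss_rate = 0.1, seed = seed)
    ph <- tibble::tibble(sample = g$samples, value = rnorm(40))
    a <- snp_phenotype_association(g, ph)
    g2 <- g
    g2$dosages <- 2L - g$dosages
    b <- snp_phenotype_association(g2, ph)
    expect_equal(a$score, -b$score, tolerance = 1e-12)
  }
})

test_that("without hets the score is the plain difference of pool means", {
  set.seed(8)
  d <- matrix(sample(c(0L, 2L), 60, TRUE), 20, 3)
  g <- assoc_g(d)
  ph <- tibble::tibble(sample = g$samples, value = rnorm(20))
  res <- snp_phenotype_association(g, ph)
  for (j in 1:3) {
    plain <- mean(ph$value[d[, j] == 2]) - mean(ph$value[d[, j] == 0])
    expect_equal(res$score[j], plain, tolerance = 1e-12)
  }
})

test_that("scores are location-invariant and scale-equivariant", {
  for (seed in 1:10) {
    g <- rand_genotypes(30, 4, seed = seed)
    v <- rnorm(30)
    a <- snp_phenotype_association(g, tibble::tibble(sample = g$samples, value = v))
    b <- snp_phenotype_association(g, tibble::tibble(sample = g$samples, value = v + 100))
    cc <- snp_phenotype_association(g, tibble::tibble(sample = g$samples, value = v * -2.5))
    expect_equal(a$score, b$score, tolerance = 1e-9)
    expect_equal(cc$score, a$score * -2.5, tolerance = 1e-9)
  }
})

test_that("MG association equals SNP association on the same column", {
  g <- rand_genotypes(50, 3, seed = 3)
  ph <- tibble::tibble(sample = g$samples, value = rnorm(50))
  snp <- snp_phenotype_association(g, ph)
  al <- g$dosages
  colnames(al) <- paste0("MG", 1:3)
  mg <- mg_association(al, ph)
  expect_equal(mg$score, snp$score, tolerance = 1e-12)
  expect_equal(mg$n1, snp$n1)
})

test_that("planted effects are recovered within 3 SE over replicates", {
  set.seed(99)
  n <- 120
  dos <- matrix(rbinom(n, 2, 0.4), ncol = 1,
    dimnames = list(sprintf("s%d", 1:n), "l1"))
  g <- assoc_g(dos)
  beta <- 1.5
  noiseless <- snp_phenotype_association(
    g, tibble::tibble(sample = g$samples, value = beta * dos[, 1])
  )$score
  reps <- vapply(1:100, function(i) {
    ph <- tibble::tibble(sample = g$samples,
      value = beta * dos[, 1] + rnorm(n, 0, 1))
    snp_phenotype_association(g, ph)$score
  }, numeric(1))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - noiseless), 3 * se)
})

test_that("haplotype summaries report counts, phenotype stats and Misc", {
  pop <- small_pop(seed = 41, n = 150)
  run <- run_haplotyping(pop$genotypes, pop$ld, pop$phenotype,
    epsilon_grid = 0.6) # no metadata attached
  sm <- haplotype_summaries(run$results[[1]])
  expect_equal(sum(sm$stats$n),
    sum(run$results[[1]]$hap_table$haps$n))
  expect_true(all(sm$meta$group == "Misc"))
  # metadata counts sum to group n
  run2 <- run_haplotyping(pop$genotypes, pop$ld, pop$phenotype, pop$metadata,
    epsilon_grid = 0.6)
  sm2 <- haplotype_summaries(run2$results[[1]])
  per_label <- tapply(sm2$meta$n, sm2$meta$label, sum)
  expect_equal(as.vector(per_label[sm2$stats$label]), sm2$stats$n)
})

test_that("isolate_groups restricts phenotype stats, not counts", {
  pop <- small_pop(seed = 43, n = 150)
  run <- run_haplotyping(pop$genotypes, pop$ld, pop$phenotype, pop$metadata,
    epsilon_grid = 0.6)
  res <- run$results[[1]]
  all_labels <- unique(pop$metadata$group)
  sm_all <- haplotype_summaries(res)
  sm_iso <- haplotype_summaries(res, isolate_groups = all_labels)
  expect_equal(sm_iso$stats, sm_all$stats) # no-op restriction
  sm_one <- haplotype_summaries(res, isolate_groups = all_labels[1])
  expect_equal(sm_one$stats$n, sm_all$stats$n) # counts unchanged
  expect_true(any(sm_one$stats$n_pheno < sm_all$stats$n_pheno))
  expect_warning(haplotype_summaries(res, isolate_groups = "Atlantis"),
    "Atlantis")
})

test_that("planted haplotype effects appear in group phenotype means", {
  spec <- localhap::fixture_spec(n_individuals = 300, sigma = 0.5, seed = 47)
  pop <- localhap::generate_population(spec)
  run <- run_haplotyping(pop$genotypes, pop$ld, pop$phenotype, pop$metadata,
    epsilon_grid = 0.6)
  sm <- haplotype_summaries(run$results[[1]])
  # map each labelled haplotype to its planted template via majority
  tt <- pop$truth$individuals
  assign <- run$results[[1]]$hap_table$assignment
  for (i in seq_len(nrow(sm$stats))) {
    members <- assign$sample[assign$label == sm$stats$label[i]]
    tmpl <- as.integer(names(which.max(table(tt$copy1[match(members, tt$sample)]))))
    planted <- spec$effects[tmpl]
    se <- sm$stats$sd[i] / sqrt(sm$stats$n_pheno[i])
    expect_lt(abs(sm$stats$mean[i] - planted), 3 * se)
  }
})
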