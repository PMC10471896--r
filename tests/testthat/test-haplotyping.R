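# Mode collapse onto Marker-Group alleles, haplotype tabulation and the
# pipeline driver.

test_that("a single-SNP Marker Group copies the SNP dosage", {
  g <- rand_genotypes(15, 4, seed = 1)
  mgs <- mgs_from_blocks(g, list("snp001"))
  al <- assign_mg_alleles(g, mgs)
  expect_equal(unname(al[, "MG1"]), unname(g$dosages[, "snp001"]))
})

test_that("strict majority wins; all-missing is unresolved", {
  d <- rbind(c(0, 0, 2), c(2, 2, 1), c(NA, NA, NA), c(1, NA, 1))
  g <- hap_genotypes(paste0("s", 1:4),
    tibble::tibble(chrom = "c", pos = 1:3, id = paste0("l", 1:3),
      ref = "A", alt = "G"), d)
  mgs <- mgs_from_blocks(g, list(c("l1", "l2", "l3")))
  al <- assign_mg_alleles(g, mgs)
  expect_equal(unname(al[, 1]), c(0L, 2L, NA, 1L))
})

test_that("mode ties break towards the group-wide mean dosage", {
  # individual 1 is split 1x0 / 1x2; the group mean decides
  d <- rbind(c(0, 2), c(2, 2), c(2, 2), c(2, 0))
  g <- hap_genotypes(paste0("s", 1:4),
    tibble::tibble(chrom = "c", pos = 1:2, id = c("l1", "l2"),
      ref = "A", alt = "G"), d)
  mgs <- mgs_from_blocks(g, list(c("l1", "l2")))
  al <- assign_mg_alleles(g, mgs)
  # group mean = 12/8 = 1.5 -> dosage 2 is nearer than 0
  expect_equal(unname(al[1, 1]), 2L)
  # symmetric case: mean below 1 pulls towards 0
  d2 <- rbind(c(0, 2), c(0, 0), c(0, 0), c(2, 0))
  g2 <- hap_genotypes(paste0("s", 1:4),
    tibble::tibble(chrom = "c", pos = 1:2, id = c("l1", "l2"),
      ref = "A", alt = "G"), d2)
  al2 <- assign_mg_alleles(g2, mgs_from_blocks(g2, list(c("l1", "l2"))))
  expect_equal(unname(al2[1, 1]), 0L)
})

test_that("modal alleles match the brute-force oracle on random data", {
  for (seed in 1:10) {
    set.seed(seed)
    g <- rand_genotypes(sample(20:80, 1), 12, miss_rate = 0.15)
    blocks <- split(g$loci$id, rep(1:3, each = 4))
    names(blocks) <- NULL
    mgs <- mgs_from_blocks(g, blocks)
    got <- assign_mg_alleles(g, mgs)
    want <- oracle_mg_alleles(g$dosages, blocks, paste0("MG", 1:3))
    expect_identical(got, want)
  }
})

test_that("degenerate single-haplotype input labels everyone A", {
  al <- matrix(1L, 20, 3, dimnames = list(paste0("s", 1:20), paste0("MG", 1:3)))
  expect_warning(ht <- build_haplotypes(al, min_hap = 9), "invariant")
  expect_equal(ht$haps$label, "A")
  expect_equal(ht$haps$n, 20L)
  expect_equal(ht$retained_mgs, character(0))
  expect_true(all(ht$assignment$label == "A"))
})

test_that("min_hap cuts combinations exactly at the threshold", {
  al <- matrix(0L, 22, 2, dimnames = list(paste0("s", 1:22), c("MG1", "MG2")))
  al[11:19, 2] <- 2L # 9 individuals
  al[20:22, 1] <- 2L # 3 individuals
  ht <- build_haplotypes(al, min_hap = 9)
  expect_equal(ht$haps$label, c("A", "B"))
  expect_equal(ht$haps$n, c(10L, 9L))
  expect_equal(sum(ht$assignment$label == "UNASSIGNED"), 3L)
  # retained MGs: MG1 is invariant (0 in both labelled rows), MG2 varies
  expect_equal(ht$retained_mgs, "MG2")
})

test_that("minHap larger than n empties the table", {
  al <- matrix(0L, 5, 1, dimnames = list(paste0("s", 1:5), "MG1"))
  expect_warning(ht <- build_haplotypes(al, min_hap = 9), "UNASSIGNED")
  expect_equal(nrow(ht$haps), 0L)
  expect_true(all(ht$assignment$label == "UNASSIGNED"))
  expect_error(build_haplotypes(al, min_hap = 0), "min_hap")
})

test_that("ties in count order lexicographically by allele vector", {
  al <- matrix(0L, 20, 2, dimnames = list(paste0("s", 1:20), c("MG1", "MG2")))
  al[1:10, ] <- 2L    # "22" x10
  al[11:20, 2] <- 2L  # "02" x10
  ht <- build_haplotypes(al, min_hap = 5)
  expect_equal(ht$haps$label, c("A", "B"))
  expect_equal(ht$haps$MG1, c(0L, 2L)) # "02" sorts before "22"
})

test_that("label overflow truncates at 26 with a warning", {
  combos <- expand.grid(0:2, 0:2, 0:2) # 27 distinct combinations
  al <- as.matrix(combos[rep(1:27, each = 3), ])
  dimnames(al) <- list(paste0("s", seq_len(nrow(al))), paste0("MG", 1:3))
  storage.mode(al) <- "integer"
  expect_warning(ht <- build_haplotypes(al, min_hap = 2), "26")
  expect_equal(nrow(ht$haps), 26L)
  expect_equal(sum(ht$assignment$label == "UNASSIGNED"), 3L)
})

test_that("haplotype tables match the brute-force row-grouping oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(30:120, 1)
    k <- sample(2:5, 1)
    al <- matrix(sample(0:2, n * k, replace = TRUE, prob = c(0.5, 0.1, 0.4)),
      n, k, dimnames = list(paste0("s", 1:n), paste0("MG", 1:k)))
    al[runif(n * k) < 0.05] <- NA
    storage.mode(al) <- "integer"
    mh <- sample(2:6, 1)
    ht <- suppressWarnings(build_haplotypes(al, min_hap = mh))
    want <- oracle_hap_assignment(al, mh)
    expect_equal(ht$assignment$label, want$labels)
    expect_equal(ht$haps$n, unname(want$table$n))
  }
})

test_that("every individual lands in exactly one label or UNASSIGNED", {
  pop <- small_pop(seed = 23)
  run <- run_haplotyping(pop$genotypes, pop$ld, pop$phenotype,
    epsilon_grid = c(0.4, 0.8), min_hap = 5)
  for (res in run$results) {
    a <- res$hap_table$assignment
    expect_equal(sort(a$sample), sort(pop$genotypes$samples))
    expect_equal(sum(res$hap_table$haps$n) +
      sum(a$label == "UNASSIGNED"), length(pop$genotypes$samples))
  }
})

test_that("build_haplotypes is idempotent", {
  set.seed(42)
  al <- matrix(sample(0:2, 200, TRUE), 50, 4,
    dimnames = list(paste0("s", 1:50), paste0("MG", 1:4)))
  storage.mode(al) <- "integer"
  h1 <- suppressWarnings(build_haplotypes(al, 3))
  h2 <- suppressWarnings(build_haplotypes(al, 3))
  expect_identical(h1, h2)
})

test_that("run_haplotyping composes the stages and recovers planted counts", {
  pop <- small_pop(seed = 29, n = 200)
  run <- run_haplotyping(pop$genotypes, pop$ld, pop$phenotype, pop$metadata)
  combo <- pop$truth$individuals$combination
  planted <- sort(as.integer(table(combo)), decreasing = TRUE)
  # at some epsilon the labelled counts equal the planted combination counts
  hit <- any(vapply(run$results, function(res) {
    got <- res$hap_table$haps$n
    length(got) == sum(planted >= 9) &&
      all(got == planted[planted >= 9])
  }, logical(1)))
  expect_true(hit)

  # single-epsilon run equals manual stage composition
  one <- run_haplotyping(pop$genotypes, pop$ld, epsilon_grid = 0.6)
  mgs <- cluster_snps(pop$ld, 0.6, 5)
  al <- assign_mg_alleles(pop$genotypes, mgs)
  expect_equal(one$results[[1]]$hap_table$haps, build_haplotypes(al, 9)$haps)
})

test_that("phenotype/genotype sample mismatch warns and intersects", {
  pop <- small_pop(seed = 31, n = 40)
  ph <- rbind(pop$phenotype, tibble::tibble(sample = "ghost", value = 1))
  expect_warning(
    run <- run_haplotyping(pop$genotypes, pop$ld, ph,
      epsilon_grid = c(0.4, 0.6), min_hap = 5),
    "mismatch"
  )
  expect_false("ghost" %in% run$phenotype$sample)
})
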