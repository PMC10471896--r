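# Multi-resolution clustering tree across epsilon levels.

test_that("identical partitions give a perfect matching", {
  a <- setNames(rep(c("A", "B"), each = 5), paste0("s", 1:10))
  run <- fake_run_hap(list(a, a))
  tree <- build_clustering_tree(run, "hap")
  expect_equal(nrow(tree$nodes), 4L)
  for (i in seq_len(nrow(tree$edges))) {
    e <- tree$edges[i, ]
    from <- tree$nodes$size[tree$nodes$level == e$from_level &
      tree$nodes$label == e$from_label]
    to <- tree$nodes$size[tree$nodes$level == e$from_level + 1 &
      tree$nodes$label == e$to_label]
    expect_equal(e$weight, from)
    expect_equal(e$weight, to)
  }
})

test_that("a merge event yields two in-edges carrying the part sizes", {
  lvl1 <- setNames(c(rep("A", 6), rep("B", 4)), paste0("s", 1:10))
  lvl2 <- setNames(rep("A", 10), paste0("s", 1:10))
  tree <- build_clustering_tree(fake_run_hap(list(lvl1, lvl2)), "hap")
  e <- tree$edges
  expect_equal(nrow(e), 2L)
  expect_equal(sort(e$weight), c(4L, 6L))
  expect_true(all(e$to_label == "A"))
})

test_that("single level input is refused with grid advice", {
  a <- setNames(rep("A", 5), paste0("s", 1:5))
  expect_error(build_clustering_tree(fake_run_hap(list(a)), "hap"), "grid")
})

test_that("edge weights equal brute-force set intersections (random runs)", {
  for (seed in 1:10) {
    set.seed(seed)
    samples <- paste0("s", 1:40)
    assigns <- lapply(1:4, function(l) {
      setNames(sample(c(LETTERS[1:3], "UNASSIGNED"), 40, TRUE), samples)
    })
    tree <- build_clustering_tree(fake_run_hap(assigns), "hap")
    for (i in seq_len(nrow(tree$edges))) {
      e <- tree$edges[i, ]
      want <- sum(assigns[[e$from_level]] == e$from_label &
        assigns[[e$from_level + 1]] == e$to_label)
      expect_equal(e$weight, want)
    }
    # conservation with sink nodes: out-weights sum to node size
    for (l in 1:3) {
      lv <- tree$nodes[tree$nodes$level == l, ]
      for (j in seq_len(nrow(lv))) {
        out <- tree$edges$weight[tree$edges$from_level == l &
          tree$edges$from_label == lv$label[j]]
        expect_equal(sum(out), lv$size[j])
      }
    }
  }
})

test_that("reversed epsilon grid produces the identical tree", {
  pop <- small_pop(seed = 51)
  run_f <- run_haplotyping(pop$genotypes, pop$ld, pop$phenotype,
    epsilon_grid = c(0.3, 0.6, 0.9), min_hap = 5)
  run_r <- run_haplotyping(pop$genotypes, pop$ld, pop$phenotype,
    epsilon_grid = c(0.9, 0.6, 0.3), min_hap = 5)
  expect_equal(build_clustering_tree(run_f, "hap"),
    build_clustering_tree(run_r, "hap"))
  expect_equal(build_clustering_tree(run_f, "MG"),
    build_clustering_tree(run_r, "MG"))
})

test_that("MG-mode nodes carry sizes in SNPs and mean member association", {
  pop <- small_pop(seed = 53)
  run <- run_haplotyping(pop$genotypes, pop$ld, pop$phenotype,
    epsilon_grid = c(0.4, 0.8), min_hap = 5)
  tree <- build_clustering_tree(run, "MG")
  sa <- snp_phenotype_association(pop$genotypes, pop$phenotype)
  for (l in 1:2) {
    res <- run$results[[l]]
    lv <- tree$nodes[tree$nodes$level == l, ]
    expect_equal(sum(lv$size), nrow(pop$genotypes$loci))
    for (j in seq_len(nrow(lv))) {
      members <- res$mgs$assignment$id[res$mgs$assignment$mg == lv$label[j]]
      expect_equal(lv$stat[j],
        mean(sa$score[match(members, sa$id)], na.rm = TRUE))
    }
  }
})

test_that("tree rendering writes a figure and exports consistent TSVs", {
  pop <- small_pop(seed = 57)
  run <- run_haplotyping(pop$genotypes, pop$ld, pop$phenotype,
    epsilon_grid = c(0.4, 0.8), min_hap = 5)
  tree <- build_clustering_tree(run, "hap")
  d <- withr::local_tempdir()
  f <- file.path(d, "tree.png")
  p <- render_clustering_tree(tree, f)
  expect_true(file.exists(f) && file.size(f) > 0)
  paths <- write_tree_tables(tree, d)
  nodes <- utils::read.table(paths[1], header = TRUE, sep = "\t")
  expect_equal(nrow(nodes), nrow(tree$nodes))
  # identical tree -> identical plot data (determinism of the layout)
  b1 <- ggplot2::ggplot_build(plot_clustering_tree(tree))$data
  b2 <- ggplot2::ggplot_build(plot_clustering_tree(tree))$data
  expect_identical(b1, b2)
})
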