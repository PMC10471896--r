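# Multi-resolution clustering tree across epsilon levels: the decision
# aid for choosing the DBSCAN radius. Preferred here over the KNN
# distance plot because it shows the effect of epsilon on each cluster
# separately instead of a single outlier-sensitive mean-distance curve.

#' Build the clustering tree over epsilon levels
#'
#' Connects Marker Groups (type `"MG"`, members = SNPs) or haplotype
#' populations (type `"hap"`, members = individuals) identified at
#' consecutive epsilon levels. Edge weight is the number of shared
#' members. Noise SNPs / unassigned individuals form an explicit sink
#' node (`NOISE` / `UNASSIGNED`) at every level, so in haplotype mode
#' the out-edge weights of every node sum exactly to its size. Node
#' statistics: mean member-SNP association score (MG mode) or mean
#' member phenotype (haplotype mode); `NA` without a phenotype.
#'
#' @param run a `hap_run` from [run_haplotyping()] with >= 2 epsilon
#'   levels.
#' @param type `"hap"` (default) or `"MG"`.
#' @return A `hap_tree` object: list with `type`, `levels` (epsilons,
#'   ascending), `nodes` (tibble: `level`, `epsilon`, `label`, `size`,
#'   `stat`) and `edges` (tibble: `from_level`, `from_label`,
#'   `to_label`, `weight`).
#' @export
build_clustering_tree <- function(run, type = c("hap", "MG")) {
  stopifnot(inherits(run, "hap_run"))
  type <- match.arg(type)
  if (length(run$results) < 2) {
    abort("clustering tree needs >= 2 epsilon levels; provide an epsilon grid")
  }
  eps <- vapply(run$results, function(r) r$epsilon, numeric(1))
  ord <- order(eps)
  results <- run$results[ord]
  eps <- eps[ord]

  snp_stat <- NULL
  if (type == "MG" && !is.null(run$phenotype)) {
    sa <- snp_phenotype_association(run$genotypes, run$phenotype)
    snp_stat <- setNames(sa$score, sa$id)
  }
  pheno_stat <- NULL
  if (type == "hap" && !is.null(run$phenotype)) {
    pheno_stat <- setNames(run$phenotype$value, run$phenotype$sample)
  }

  members_at <- function(r) {
    if (type == "MG") {
      split(r$mgs$assignment$id, r$mgs$assignment$mg)
    } else {
      split(r$hap_table$assignment$sample, r$hap_table$assignment$label)
    }
  }
  sink_label <- if (type == "MG") "NOISE" else "UNASSIGNED"
  order_labels <- function(labs) {
    main <- setdiff(labs, sink_label)
    if (type == "MG") {
      main <- main[order(as.integer(sub("^MG", "", main)))]
    } else {
      main <- sort(main)
    }
    c(main, intersect(sink_label, labs))
  }

  node_stat <- function(members) {
    vals <- if (type == "MG") {
      if (is.null(snp_stat)) NA_real_ else snp_stat[members]
    } else {
      if (is.null(pheno_stat)) NA_real_ else pheno_stat[members]
    }
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }

  nodes <- list()
  edges <- list()
  lvl_members <- lapply(results, members_at)
  for (l in seq_along(results)) {
    mem <- lvl_members[[l]]
    labs <- order_labels(names(mem))
    nodes[[l]] <- tibble(
      level = l, epsilon = eps[l], label = labs,
      size = vapply(labs, function(x) length(mem[[x]]), integer(1), USE.NAMES = FALSE),
      stat = vapply(labs, function(x) node_stat(mem[[x]]), numeric(1), USE.NAMES = FALSE)
    )
    if (l > 1) {
      prev <- lvl_members[[l - 1]]
      e <- expand.grid(
        from_label = names(prev), to_label = names(mem),
        stringsAsFactors = FALSE
      )
      e$weight <- mapply(
        function(a, b) length(intersect(prev[[a]], mem[[b]])),
        e$from_label, e$to_label
      )
      e <- e[e$weight >= 1, , drop = FALSE]
      edges[[l]] <- tibble(
        from_level = l - 1L, from_label = e$from_label,
        to_label = e$to_label, weight = as.integer(e$weight)
      )
    }
  }
  structure(
    list(
      type = type, levels = eps,
      nodes = dplyr::bind_rows(nodes),
      edges = dplyr::bind_rows(edges)
    ),
    class = "hap_tree"
  )
}

#' @export
print.hap_tree <- function(x, ...) {
  cat(sprintf(
    "<hap_tree> %s mode, %d levels (eps %s), %d nodes, %d edges\n",
    x$type, length(x$levels), paste(format_eps(x$levels), collapse = "/"),
    nrow(x$nodes), nrow(x$edges)
  ))
  invisible(x)
}

# deterministic layered layout: one row per epsilon, nodes spread
# horizontally in label order
tree_layout <- function(tree) {
  nodes <- dplyr::group_by(tree$nodes, .data$level)
  nodes <- dplyr::mutate(nodes,
    x = seq_along(.data$label) - (dplyr::n() + 1) / 2,
    y = .data$level[1]
  )
  dplyr::ungroup(nodes)
}

#' Plot the clustering tree
#'
#' Layered ggplot: one row per epsilon (small radii at the bottom),
#' node size encodes member count, node colour the phenotype statistic,
#' edge width the number of shared members.
#'
#' @param tree a `hap_tree` from [build_clustering_tree()].
#' @return a ggplot object.
#' @export
plot_clustering_tree <- function(tree) {
  stopifnot(inherits(tree, "hap_tree"))
  lay <- tree_layout(tree)
  ed <- dplyr::left_join(
    tree$edges,
    setNames(lay[, c("level", "label", "x", "y")], c("from_level", "from_label", "x0", "y0")),
    by = c("from_level", "from_label")
  )
  to <- lay[, c("level", "label", "x", "y")]
  names(to) <- c("to_level", "to_label", "x1", "y1")
  ed$to_level <- ed$from_level + 1L
  ed <- dplyr::left_join(ed, to, by = c("to_level", "to_label"))

  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
        yend = .data$y1, linewidth = .data$weight),
      colour = "grey55", alpha = 0.6
    ) +
    ggplot2::geom_point(
      data = lay,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$size,
        colour = .data$stat)
    ) +
    ggplot2::geom_text(
      data = lay,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      vjust = -1.4, size = 3
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 2.5), name = "shared") +
    ggplot2::scale_size(range = c(2, 9), name = if (tree$type == "MG") "nSNP" else "nIndividuals") +
    ggplot2::scale_colour_gradient2(low = "#2166AC", mid = "grey85",
      high = "#B2182B", midpoint = 0, name = "phenotype\nassociation",
      na.value = "grey40") +
    ggplot2::scale_y_continuous(
      breaks = seq_along(tree$levels),
      labels = format_eps(tree$levels), name = "epsilon"
    ) +
    ggplot2::labs(x = NULL, title = sprintf("Clustering tree (%s)", tree$type)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_blank(),
      panel.grid.major.x = ggplot2::element_blank(),
      panel.grid.minor = ggplot2::element_blank()
    )
}

#' Render the clustering tree to a figure file
#'
#' @param tree a `hap_tree`.
#' @param path output figure path; format by extension (png/pdf/svg).
#' @param width,height figure size in inches.
#' @return the ggplot, invisibly.
#' @export
render_clustering_tree <- function(tree, path, width = 7, height = 6) {
  p <- plot_clustering_tree(tree)
  save_figure(p, path, width, height)
  invisible(p)
}

#' Export the clustering tree as node/edge TSV tables
#'
#' @param tree a `hap_tree`.
#' @param dir output directory.
#' @param prefix filename prefix (default the tree type).
#' @return paths written, invisibly.
#' @export
write_tree_tables <- function(tree, dir, prefix = tree$type) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(prefix, c("_tree_nodes.tsv", "_tree_edges.tsv")))
  utils::write.table(tree$nodes, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tree$edges, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

# figure writer shared by tree and dashboard; device from extension
save_figure <- function(plot, path, width, height) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "pdf", "svg")) {
    abort(paste0("unsupported figure format '.", ext, "' (use png, pdf or svg)"))
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ggplot2::ggsave(path, plot, width = width, height = height,
    dpi = 150, device = ext)
  invisible(path)
}
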