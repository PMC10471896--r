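# 2-D UMAP embedding of SNP linkage profiles, coloured by Marker Group.

#' UMAP of SNPs by linkage profile
#'
#' Embeds the rows of the LD matrix (each SNP's linkage profile) into
#' two dimensions with UMAP, so SNPs co-locate by linkage. Single-
#' threaded SGD and a fixed seed make the coordinates reproducible.
#'
#' @param ld `hap_ld` matrix with >= 4 loci.
#' @param mgs optional `hap_mgs`; points are coloured by Marker Group,
#'   noise in grey.
#' @param seed random seed (default 42).
#' @param n_neighbors UMAP neighbourhood size; default
#'   `min(15, n_loci - 1)`.
#' @param min_dist UMAP minimum embedding distance (default 0.1).
#' @param path optional figure path (png/pdf/svg).
#' @return tibble with columns `id`, `mg`, `u1`, `u2`; the ggplot is
#'   attached as attribute `"plot"`.
#' @export
umap_snps <- function(ld, mgs = NULL, seed = 42,
                      n_neighbors = NULL, min_dist = 0.1, path = NULL) {
  n <- nrow(ld)
  if (n < 4) abort("need >= 4 loci for a UMAP embedding")
  if (is.null(n_neighbors)) n_neighbors <- min(15, n - 1)
  if (n_neighbors >= n) {
    abort(sprintf(
      "n_neighbors (%d) must be smaller than the number of loci (%d); pass a smaller n_neighbors",
      n_neighbors, n
    ))
  }
  set.seed(seed)
  coords <- uwot::umap(
    unclass(ld),
    n_neighbors = n_neighbors, min_dist = min_dist,
    init = "pca", n_threads = 1, n_sgd_threads = 1
  )
  mg <- if (!is.null(mgs)) {
    mgs$assignment$mg[match(rownames(ld), mgs$assignment$id)]
  } else {
    rep(NA_character_, n)
  }
  out <- tibble(id = rownames(ld), mg = mg,
    u1 = coords[, 1], u2 = coords[, 2])

  plot_df <- dplyr::mutate(out, mg = ifelse(is.na(.data$mg), "NOISE", .data$mg))
  p <- ggplot2::ggplot(plot_df,
    ggplot2::aes(x = .data$u1, y = .data$u2, colour = .data$mg)) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::scale_colour_manual(
      values = mg_palette(unique(plot_df$mg)), name = NULL
    ) +
    ggplot2::labs(x = "UMAP1", y = "UMAP2",
      title = "SNPs co-located by linkage profile") +
    ggplot2::theme_minimal()
  if (!is.null(path)) save_figure(p, path, width = 6, height = 5)
  attr(out, "plot") <- p
  out
}

# stable palette: hues for MGs, grey for noise
mg_palette <- function(labels) {
  main <- setdiff(labels, "NOISE")
  main <- main[order(suppressWarnings(as.integer(sub("^MG", "", main))))]
  cols <- grDevices::hcl(
    h = seq(15, 375, length.out = length(main) + 1)[seq_along(main)],
    c = 80, l = 55
  )
  setNames(c(cols, "grey70"), c(main, "NOISE"))
}
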