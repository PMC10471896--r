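# The composite haplotype dashboard: an UpSet-style central matrix of
# the Marker-Group alleles defining each haplotype, flanked by panels
# describing individuals/haplotypes (vertical) and Marker Groups/SNPs
# (horizontal). Every panel is a view over a tabular export — the plots
# never recompute a number the side-car tables do not carry.

#' Assemble all dashboard panel tables for one haplotyping result
#'
#' @param result a `hap_result` with >= 1 labelled haplotype and >= 1
#'   retained Marker Group.
#' @param isolate_groups optional metadata labels restricting the
#'   phenotype-distribution panel (see [haplotype_summaries()]).
#' @param ld optional `hap_ld` matrix (for the intra-MG linkage panel).
#' @param genotypes optional [hap_genotypes()] (for the SNP association
#'   panel); both are carried by the `hap_run` and filled in by
#'   [render_dashboard()] automatically when you pass the run.
#' @return named list of tibbles: `center`, `top`, `pheno`, `meta`,
#'   `left_freq`, `left_pos`, `right_assoc`, `right_linkage`,
#'   `hap_summary`, `snp_summary`.
#' @export
dashboard_data <- function(result, isolate_groups = NULL, ld = NULL,
                           genotypes = NULL) {
  stopifnot(inherits(result, "hap_result"))
  ht <- result$hap_table
  if (nrow(ht$haps) == 0) {
    abort("no labelled haplotypes at this epsilon; lower min_hap or choose another epsilon")
  }
  retained <- ht$retained_mgs
  if (!length(retained)) {
    abort("all Marker Groups are invariant across haplotypes; nothing to draw")
  }

  center <- tidyr::pivot_longer(
    ht$haps[, c("label", retained)],
    cols = dplyr::all_of(retained), names_to = "mg", values_to = "allele"
  )

  top <- ht$haps[, c("label", "n")]

  summaries <- haplotype_summaries(result, isolate_groups)
  assign <- ht$assignment[ht$assignment$label != "UNASSIGNED", ]
  pheno_panel <- tibble(label = character(), value = numeric())
  if (!is.null(result$phenotype)) {
    keep <- assign$sample
    if (!is.null(summaries$isolate_groups)) {
      keep <- keep[metadata_labels(keep, result$metadata) %in% summaries$isolate_groups]
    }
    v <- result$phenotype$value[match(keep, result$phenotype$sample)]
    lab <- assign$label[match(keep, assign$sample)]
    ok <- !is.na(v)
    pheno_panel <- tibble(label = lab[ok], value = v[ok])
  }

  alleles <- result$mg_alleles[, retained, drop = FALSE]
  left_freq <- dplyr::count(
    tibble(
      mg = rep(retained, each = nrow(alleles)),
      state = as.vector(alleles)
    ),
    .data$mg, .data$state, name = "n"
  )
  left_freq <- left_freq[!is.na(left_freq$state), ]

  loci <- result$genotypes_loci
  memb <- result$mgs$assignment
  memb <- memb[memb$mg %in% retained, ]
  left_pos <- tibble(
    mg = memb$mg, id = memb$id,
    pos = loci$pos[match(memb$id, loci$id)]
  )

  snp_assoc <- NULL
  right_assoc <- tibble(mg = character(), id = character(), score = numeric())
  if (!is.null(genotypes) && !is.null(result$phenotype)) {
    snp_assoc <- snp_phenotype_association(genotypes, result$phenotype)
    right_assoc <- tibble(
      mg = memb$mg, id = memb$id,
      score = snp_assoc$score[match(memb$id, snp_assoc$id)]
    )
  }

  right_linkage <- tibble(mg = character(), r2 = numeric())
  if (!is.null(ld)) {
    il <- intra_mg_linkage(ld, result$mgs)
    il <- il[il$mg %in% retained, ]
    right_linkage <- tidyr::unnest(il[, c("mg", "r2")], cols = "r2")
  }

  hap_summary <- summaries$stats[, c("label", "n", "mean")]
  names(hap_summary) <- c("label", "n", "mean_pheno")

  snp_summary <- mg_summary(result, snp_assoc)
  snp_summary <- snp_summary[snp_summary$mg %in% retained, ]

  list(
    center = center, top = top, pheno = pheno_panel, meta = summaries$meta,
    left_freq = left_freq, left_pos = left_pos,
    right_assoc = right_assoc, right_linkage = right_linkage,
    hap_summary = hap_summary, snp_summary = snp_summary
  )
}

mg_axis <- function(mgs) {
  factor(mgs, levels = mgs[order(as.integer(sub("^MG", "", mgs)))] |> unique())
}

#' Render the composite haplotype dashboard
#'
#' Central matrix: haplotypes (rows, label order) x retained Marker
#' Groups (columns, MG1 first); glyph fill encodes the allelic state
#' (open = hom-ref, half = het, filled = hom-alt). Top: haplotype
#' frequencies. Bottom: per-haplotype phenotype distributions
#' (honouring `isolate_groups`) and metadata composition. Left:
#' Marker-Group allelic-state frequencies or SNP positions
#' (`plot_left`). Right: per-MG SNP association distributions or
#' intra-MG linkage boxplots (`plot_right`). Corner tables summarise
#' haplotypes (bottom-left) and Marker Groups (top-right).
#'
#' @param x a `hap_run` (uses `epsilon`) or a single `hap_result`.
#' @param epsilon which epsilon level of a `hap_run` to draw (default:
#'   first level).
#' @param path optional figure path (png/pdf/svg); side-car TSVs with
#'   every panel table are written next to it.
#' @param plot_left `"allele_freq"` or `"position"`.
#' @param plot_right `"association"` or `"linkage"`.
#' @param isolate_groups optional metadata labels restricting phenotype
#'   panels.
#' @param width,height figure size in inches.
#' @return invisibly, a list with `plot` (patchwork), `data` (panel
#'   tables) and `paths` (files written, if any).
#' @export
render_dashboard <- function(x, epsilon = NULL, path = NULL,
                             plot_left = c("allele_freq", "position"),
                             plot_right = c("association", "linkage"),
                             isolate_groups = NULL,
                             width = 11, height = 9) {
  plot_left <- match.arg(plot_left)
  plot_right <- match.arg(plot_right)
  if (inherits(x, "hap_run")) {
    nm <- if (is.null(epsilon)) 1L else format_eps(epsilon)
    result <- x$results[[nm]]
    if (is.null(result)) abort(paste0("no results at epsilon ", epsilon))
    ld <- x$ld
    genotypes <- x$genotypes
  } else {
    result <- x
    ld <- NULL
    genotypes <- NULL
  }
  dat <- dashboard_data(result, isolate_groups, ld, genotypes)

  hap_lev <- rev(dat$top$label) # A on the top row
  mg_lev <- levels(mg_axis(unique(dat$center$mg)))
  state_lab <- c("0" = "hom-ref", "1" = "het", "2" = "hom-alt")
  state_fill <- c("hom-ref" = "white", "het" = "grey60", "hom-alt" = "grey10")

  base_theme <- ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(panel.grid.minor = ggplot2::element_blank(),
      legend.position = "bottom")

  center_df <- dplyr::mutate(dat$center,
    label = factor(.data$label, levels = hap_lev),
    mg = factor(.data$mg, levels = mg_lev),
    state = factor(state_lab[as.character(.data$allele)], levels = state_lab)
  )
  p_center <- ggplot2::ggplot(center_df,
    ggplot2::aes(x = .data$mg, y = .data$label, fill = .data$state)) +
    ggplot2::geom_point(shape = 21, size = 5, colour = "grey20") +
    ggplot2::scale_fill_manual(values = state_fill, name = NULL, drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL) + base_theme

  p_top <- ggplot2::ggplot(dat$top,
    ggplot2::aes(x = factor(.data$label, levels = rev(hap_lev)), y = .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.3, size = 2.7) +
    ggplot2::labs(x = NULL, y = "nIndividuals") + base_theme +
    ggplot2::coord_flip() +
    ggplot2::scale_x_discrete(limits = hap_lev)

  # vertical (haplotype) panels keep haplotypes on the y axis so they
  # line up with the central matrix rows when stacked to its right
  p_pheno <- if (nrow(dat$pheno)) {
    ggplot2::ggplot(dat$pheno,
      ggplot2::aes(x = factor(.data$label, levels = hap_lev), y = .data$value)) +
      ggplot2::geom_boxplot(outlier.size = 0.6, fill = "grey90") +
      ggplot2::labs(x = NULL, y = "phenotype") + base_theme +
      ggplot2::coord_flip() +
      ggplot2::scale_x_discrete(limits = hap_lev)
  } else {
    empty_panel("no phenotype")
  }

  p_meta <- if (nrow(dat$meta)) {
    ggplot2::ggplot(dat$meta,
      ggplot2::aes(x = factor(.data$label, levels = hap_lev), y = .data$n,
        fill = .data$group)) +
      ggplot2::geom_col(position = "fill") +
      ggplot2::scale_fill_brewer(palette = "Set2", name = NULL) +
      ggplot2::labs(x = NULL, y = "metadata fraction") + base_theme +
      ggplot2::coord_flip() +
      ggplot2::scale_x_discrete(limits = hap_lev)
  } else {
    empty_panel("no metadata")
  }

  p_left <- if (plot_left == "allele_freq") {
    lf <- dplyr::mutate(dat$left_freq,
      mg = factor(.data$mg, levels = mg_lev),
      state = factor(state_lab[as.character(.data$state)], levels = state_lab))
    ggplot2::ggplot(lf,
      ggplot2::aes(x = .data$mg, y = .data$n, fill = .data$state)) +
      ggplot2::geom_col(position = "fill", colour = "grey30", linewidth = 0.2) +
      ggplot2::scale_fill_manual(values = state_fill, name = NULL) +
      ggplot2::labs(x = NULL, y = "allele-state fraction") + base_theme
  } else {
    ggplot2::ggplot(dplyr::mutate(dat$left_pos, mg = factor(.data$mg, levels = mg_lev)),
      ggplot2::aes(x = .data$mg, y = .data$pos)) +
      ggplot2::geom_jitter(width = 0.15, height = 0, size = 0.7, colour = "grey25") +
      ggplot2::labs(x = NULL, y = "position (bp)") + base_theme
  }

  p_right <- if (plot_right == "association" && nrow(dat$right_assoc)) {
    ggplot2::ggplot(dplyr::mutate(dat$right_assoc, mg = factor(.data$mg, levels = mg_lev)),
      ggplot2::aes(x = .data$mg, y = .data$score)) +
      ggplot2::geom_boxplot(outlier.size = 0.6, fill = "grey90") +
      ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
      ggplot2::labs(x = NULL, y = "SNP association") + base_theme
  } else if (plot_right == "linkage" && nrow(dat$right_linkage)) {
    ggplot2::ggplot(dplyr::mutate(dat$right_linkage, mg = factor(.data$mg, levels = mg_lev)),
      ggplot2::aes(x = .data$mg, y = .data$r2)) +
      ggplot2::geom_boxplot(outlier.size = 0.6, fill = "grey90") +
      ggplot2::labs(x = NULL, y = expression("intra-MG" ~ R^2)) + base_theme
  } else {
    empty_panel(paste0("no data for plot_right = ", plot_right))
  }

  p_hap_tab <- table_panel(dat$hap_summary, digits = 2)
  p_snp_tab <- table_panel(dat$snp_summary, digits = 2)

  design <- "F#A#\nLCRT\nL#P#\nL#M#"
  p <- patchwork::wrap_plots(
    A = p_top, C = p_center, L = p_left, R = p_right,
    P = p_pheno, M = p_meta, F = p_snp_tab, T = p_hap_tab,
    design = design,
    widths = c(1.2, 2, 1.2, 1.2), heights = c(1, 2, 1, 1),
    guides = "collect"
  ) & ggplot2::theme(legend.position = "bottom")

  paths <- NULL
  if (!is.null(path)) {
    save_figure(p, path, width, height)
    stem <- tools::file_path_sans_ext(path)
    paths <- vapply(names(dat), function(nm) {
      f <- paste0(stem, "_", nm, ".tsv")
      utils::write.table(dat[[nm]], f, sep = "\t", quote = FALSE, row.names = FALSE)
      f
    }, character(1))
    paths <- c(path, paths)
  }
  invisible(list(plot = p, data = dat, paths = paths))
}

empty_panel <- function(label) {
  ggplot2::ggplot() +
    ggplot2::annotate("text", x = 0, y = 0, label = label, size = 3, colour = "grey50") +
    ggplot2::theme_void()
}

# small corner table rendered as text
table_panel <- function(df, digits = 2) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) round(v, digits))
  lines <- c(
    paste(names(df), collapse = "  "),
    apply(df, 1, function(r) paste(r, collapse = "  "))
  )
  ggplot2::ggplot() +
    ggplot2::annotate("text", x = 0, y = seq(length(lines), 1),
      label = lines, hjust = 0, size = 2.6, family = "mono") +
    ggplot2::xlim(0, 10) +
    ggplot2::theme_void()
}
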