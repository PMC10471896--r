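# Marker-Group definition: DBSCAN over LD-profile rows.
#
# Each SNP is represented by its row of the R^2 matrix (its linkage
# profile); profiles are compared with Euclidean distance. DBSCAN is
# implemented here directly: no clustering backend in the dependency
# stack provides it, and the neighbourhood semantics (self counted in
# the core threshold, border ties resolved by genomic order) need to be
# pinned down for reproducibility.

# Core DBSCAN on a precomputed distance matrix. Returns integer labels,
# 0 = noise. minPts counts the point itself. Border points (non-core
# with >= 1 core neighbour) take the cluster of their lowest-index core
# neighbour; row order is genomic order, so the rule is reproducible.
dbscan_labels <- function(D, eps, min_pts) {
  n <- nrow(D)
  nb <- D <= eps
  core <- rowSums(nb) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    while (length(queue)) {
      j <- queue[[1L]]
      queue <- queue[-1L]
      reach <- which(nb[j, ] & core & labels == 0L)
      if (length(reach)) {
        labels[reach] <- cl
        queue <- c(queue, reach)
      }
    }
  }
  for (i in which(!core)) {
    cn <- which(nb[i, ] & core)
    if (length(cn)) labels[i] <- labels[cn[1L]]
  }
  labels
}

#' Cluster SNPs into Marker Groups by DBSCAN over linkage profiles
#'
#' Rows of the LD matrix are the feature vectors; DBSCAN runs with
#' Euclidean distance, radius `epsilon` and core threshold `min_points`
#' (the point itself counts towards its own neighbourhood). Clusters are
#' relabelled `MG1`, `MG2`, ... by descending member count, ties broken
#' by the smallest minimum member position (genomic order); unclustered
#' loci are labelled `NOISE`.
#'
#' @param ld `hap_ld` matrix.
#' @param epsilon DBSCAN radius, > 0. Controls the number and size of
#'   Marker Groups (and hence haplotypes).
#' @param min_points DBSCAN core-point threshold (default 5).
#' @return A `hap_mgs` object: list with `epsilon`, `min_points`,
#'   `assignment` (tibble `id`, `mg`) and `groups` (tibble `mg`,
#'   `n_snps`, list-column `loci`).
#' @export
cluster_snps <- function(ld, epsilon, min_points = 5) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0) {
    abort("epsilon must be a single positive number")
  }
  if (min_points < 1) abort("min_points must be >= 1")
  loci <- rownames(ld)
  n <- length(loci)
  if (n < min_points) {
    abort(sprintf("need at least min_points (%d) loci, got %d", min_points, n))
  }
  D <- as.matrix(dist(unclass(ld)))
  raw <- dbscan_labels(D, epsilon, min_points)

  ids <- sort(unique(raw[raw > 0L]))
  if (length(ids)) {
    size <- vapply(ids, function(k) sum(raw == k), integer(1))
    first <- vapply(ids, function(k) min(which(raw == k)), integer(1))
    ord <- order(-size, first)
    rank <- match(raw, ids[ord]) # NA for noise
    mg <- ifelse(is.na(rank), "NOISE", paste0("MG", rank))
  } else {
    mg <- rep("NOISE", n)
  }

  assignment <- tibble(id = loci, mg = mg)
  grp_ids <- unique(mg[mg != "NOISE"])
  grp_ids <- grp_ids[order(as.integer(sub("^MG", "", grp_ids)))]
  grp_sizes <- vapply(grp_ids, function(k) sum(mg == k), integer(1))
  grp_loci <- lapply(grp_ids, function(k) loci[mg == k])
  groups <- tibble(mg = grp_ids, n_snps = unname(grp_sizes), loci = grp_loci)
  structure(
    list(epsilon = epsilon, min_points = min_points,
         assignment = assignment, groups = groups),
    class = "hap_mgs"
  )
}

#' @export
print.hap_mgs <- function(x, ...) {
  cat(sprintf(
    "<hap_mgs> epsilon = %g, min_points = %d: %d Marker Group(s), %d noise SNP(s)\n",
    x$epsilon, x$min_points, nrow(x$groups), sum(x$assignment$mg == "NOISE")
  ))
  invisible(x)
}

#' Cluster SNPs across a grid of epsilon values
#'
#' @param ld `hap_ld` matrix.
#' @param epsilon_grid strictly positive epsilon values; sorted
#'   internally, duplicates dropped.
#' @param min_points DBSCAN core threshold shared across the grid.
#' @return named list of `hap_mgs`, one per grid value, names formatted
#'   from the epsilon values.
#' @export
scan_epsilon <- function(ld, epsilon_grid = c(0.2, 0.4, 0.6, 0.8, 1.0),
                         min_points = 5) {
  if (!length(epsilon_grid)) abort("epsilon grid must be non-empty")
  grid <- sort(unique(epsilon_grid))
  out <- lapply(grid, function(e) cluster_snps(ld, e, min_points))
  names(out) <- format_eps(grid)
  out
}

format_eps <- function(e) format(e, trim = TRUE, scientific = FALSE)
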