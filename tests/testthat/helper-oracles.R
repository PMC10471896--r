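# Independent, deliberately naive reference implementations used to
# cross-check the package. These never share code with R/.

# --- DBSCAN oracle: core points, igraph components over the core
# graph, border points to the lowest-index core neighbour. ---
oracle_dbscan <- function(features, eps, min_pts) {
  n <- nrow(features)
  D <- t(vapply(seq_len(n), function(i) {
    sqrt(rowSums((features - matrix(features[i, ], n, ncol(features),
      byrow = TRUE))^2))
  }, numeric(n)))
  core <- which(vapply(seq_len(n), function(i) sum(D[i, ] <= eps) >= min_pts, logical(1)))
  labels <- integer(n)
  if (length(core)) {
    adj <- D[core, core, drop = FALSE] <= eps
    gr <- igraph::graph_from_adjacency_matrix(adj, mode = "max", diag = FALSE)
    comp <- igraph::components(gr)$membership
    labels[core] <- comp
    for (i in setdiff(seq_len(n), core)) {
      cn <- core[D[i, core] <= eps]
      if (length(cn)) labels[i] <- labels[min(cn)]
    }
  }
  labels
}

# canonical form of a partition-with-noise: clusters renumbered by first
# occurrence, noise stays 0; equal canonical vectors <=> identical partitions
canonical_partition <- function(labels) {
  labels <- as.character(labels)
  noise <- labels %in% c("0", "NOISE")
  out <- integer(length(labels))
  nxt <- 0L
  seen <- character(0)
  for (i in seq_along(labels)) {
    if (noise[i]) next
    k <- match(labels[i], seen)
    if (is.na(k)) {
      seen <- c(seen, labels[i])
      k <- length(seen)
    }
    out[i] <- k
  }
  out
}

# --- two-locus r^2 oracle from raw sums (pairwise-complete) ---
oracle_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) return(0)
  sx <- sum(x); sy <- sum(y)
  vx <- n * sum(x^2) - sx^2
  vy <- n * sum(y^2) - sy^2
  if (vx == 0 || vy == 0) return(0)
  cv <- n * sum(x * y) - sx * sy
  (cv / sqrt(vx * vy))^2
}

# --- per-cell arithmetic mode with the declared tie rules ---
oracle_mode_cell <- function(values, mg_mean) {
  values <- values[!is.na(values)]
  if (!length(values)) return(NA_integer_)
  cnt <- c(sum(values == 0), sum(values == 1), sum(values == 2))
  cands <- which(cnt == max(cnt)) - 1L
  if (length(cands) > 1) {
    d <- abs(cands - mg_mean)
    cands <- cands[d == min(d)]
    cands <- min(cands)
  }
  as.integer(cands)
}

oracle_mg_alleles <- function(dosages, mg_loci_list, mg_names) {
  out <- matrix(NA_integer_, nrow(dosages), length(mg_loci_list),
    dimnames = list(rownames(dosages), mg_names))
  for (j in seq_along(mg_loci_list)) {
    sub <- dosages[, mg_loci_list[[j]], drop = FALSE]
    m <- mean(sub, na.rm = TRUE)
    for (i in seq_len(nrow(sub))) {
      out[i, j] <- oracle_mode_cell(sub[i, ], m)
    }
  }
  out
}

# --- brute-force haplotype table: enumerate unique complete rows,
# filter by min_hap, order by count then lexicographic key ---
oracle_hap_assignment <- function(alleles, min_hap) {
  n <- nrow(alleles)
  keys <- character(n)
  for (i in seq_len(n)) {
    row <- alleles[i, ]
    keys[i] <- if (any(is.na(row))) NA_character_ else paste(row, collapse = "")
  }
  counts <- list()
  for (k in keys[!is.na(keys)]) {
    counts[[k]] <- (counts[[k]] %||% 0L) + 1L
  }
  df <- data.frame(key = names(counts), n = unlist(counts),
    stringsAsFactors = FALSE)
  df <- df[df$n >= min_hap, , drop = FALSE]
  df <- df[order(-df$n, df$key), , drop = FALSE]
  if (nrow(df) > 26) df <- df[1:26, , drop = FALSE]
  df$label <- LETTERS[seq_len(nrow(df))]
  lab <- rep("UNASSIGNED", n)
  for (i in seq_len(n)) {
    if (!is.na(keys[i])) {
      hit <- match(keys[i], df$key)
      if (!is.na(hit)) lab[i] <- df$label[hit]
    }
  }
  list(table = df, labels = lab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
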