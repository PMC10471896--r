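# Input/output for the four input classes (VCF region, LD matrix,
# phenotype, metadata) and tabular result exports.

GT_DOSAGE <- c(
  "0/0" = 0L, "0|0" = 0L,
  "0/1" = 1L, "1/0" = 1L, "0|1" = 1L, "1|0" = 1L,
  "1/1" = 2L, "1|1" = 2L
)

#' Read biallelic SNPs from a VCF, optionally delimited to a region
#'
#' Reads a VCF 4.x file (plain or gzipped) and returns a [hap_genotypes()]
#' object containing only biallelic SNP records. Indels, multi-allelic
#' records and records outside the region are skipped (a count is
#' reported). Phased and unphased genotypes are treated identically;
#' half-calls (e.g. `0/.`) and missing calls become `NA`.
#'
#' @param path path to a `.vcf` or `.vcf.gz` file.
#' @param region optional `"chrom:start-end"` string, 1-based inclusive.
#' @return A [hap_genotypes()] object.
#' @export
read_vcf_region <- function(path, region = NULL) {
  if (!file.exists(path)) abort(paste0("cannot read VCF: ", path))
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(paste0("failed to parse VCF '", path, "': ", conditionMessage(e)))
  )
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  fix$POS <- as.integer(fix$POS)

  keep <- rep(TRUE, nrow(fix))
  if (!is.null(region)) {
    reg <- parse_region(region)
    keep <- fix$CHROM == reg$chrom & fix$POS >= reg$start & fix$POS <= reg$end
  }
  snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skip <- sum(keep & !snp)
  if (n_skip > 0) {
    inform(sprintf("read_vcf_region: skipped %d non-biallelic-SNP record(s)", n_skip))
  }
  sel <- which(keep & snp)
  if (!length(sel)) {
    abort(paste0(
      "no biallelic SNPs found",
      if (!is.null(region)) paste0(" in region ", region) else ""
    ))
  }

  gt <- vcfR::extract.gt(vcf[sel, ], element = "GT")
  dos <- matrix(GT_DOSAGE[as.vector(gt)],
    nrow = nrow(gt), ncol = ncol(gt), dimnames = dimnames(gt)
  )
  n_half <- sum(!is.na(gt) & !(as.vector(gt) %in% names(GT_DOSAGE)) &
    as.vector(gt) != "./." & as.vector(gt) != ".|.")
  if (n_half > 0) {
    inform(sprintf("read_vcf_region: %d half/irregular call(s) treated as missing", n_half))
  }

  ids <- fix$ID[sel]
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM[sel], "_", fix$POS[sel])[is.na(ids) | ids == "."]
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_dup")

  g <- hap_genotypes(
    samples = colnames(gt),
    loci = tibble(
      chrom = fix$CHROM[sel], pos = fix$POS[sel], id = ids,
      ref = fix$REF[sel], alt = fix$ALT[sel]
    ),
    dosages = t(dos)
  )
  attr(g, "n_skipped") <- n_skip
  g
}

parse_region <- function(region) {
  m <- regmatches(region, regexec("^(.+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4) {
    abort(paste0("region must look like 'chrom:start-end', got '", region, "'"))
  }
  list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

#' Write a genotype matrix as a plain-text VCF 4.2 file
#'
#' Minimal inverse of [read_vcf_region()]: emits one biallelic SNP row per
#' locus with unphased GT calls (`0/0`, `0/1`, `1/1`, `./.`).
#'
#' @param g a [hap_genotypes()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "hap_genotypes"))
  gt_str <- c("0/0", "0/1", "1/1")[g$dosages + 1L]
  gt_str[is.na(gt_str)] <- "./."
  gt <- matrix(gt_str, nrow = nrow(g$dosages))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
      g$samples
    ), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(g$loci)), function(j) {
    paste(c(
      g$loci$chrom[j], g$loci$pos[j], g$loci$id[j], g$loci$ref[j],
      g$loci$alt[j], ".", "PASS", ".", "GT", gt[, j]
    ), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a square pairwise-LD (R^2) matrix
#'
#' Accepts whitespace/tab-delimited square numeric text in the plink
#' `--r2 square` dialect, with or without a header row/column of locus
#' IDs. The matrix is validated against the expected loci, symmetrised
#' (tolerance 1e-6) and clamped to \[0, 1\].
#'
#' @param path path to the matrix file.
#' @param loci ordered character vector of locus IDs the matrix describes.
#' @return numeric matrix with `loci` as dimnames, class `hap_ld`.
#' @export
read_ld_matrix <- function(path, loci) {
  if (!file.exists(path)) abort(paste0("cannot read LD matrix: ", path))
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
    colClasses = "character", fill = TRUE)
  raw <- as.matrix(raw)
  num1 <- suppressWarnings(as.numeric(raw[1, ]))
  has_header <- anyNA(num1)
  if (has_header) {
    ids <- raw[1, ]
    raw <- raw[-1, , drop = FALSE]
    # header may or may not include a leading corner cell / row-ID column
    col1 <- suppressWarnings(as.numeric(raw[, 1]))
    if (anyNA(col1)) {
      raw <- raw[, -1, drop = FALSE]
      ids <- ids[-1][seq_len(ncol(raw))]
    } else {
      ids <- ids[seq_len(ncol(raw))]
    }
  }
  m <- matrix(suppressWarnings(as.numeric(raw)), nrow = nrow(raw))
  if (anyNA(m)) abort("LD matrix contains non-numeric entries")
  if (nrow(m) != ncol(m)) {
    abort(sprintf("LD matrix is not square: %d x %d", nrow(m), ncol(m)))
  }
  if (nrow(m) != length(loci)) {
    abort(sprintf(
      "LD matrix dimension (%d) does not match number of loci (%d)",
      nrow(m), length(loci)
    ))
  }
  as_ld_matrix(m, loci)
}

#' Validate and brand a numeric matrix as an LD matrix
#'
#' @param m square numeric matrix of pairwise R^2 values.
#' @param loci ordered locus IDs, one per row/column.
#' @return matrix of class `hap_ld` with loci dimnames.
#' @export
as_ld_matrix <- function(m, loci) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) abort("LD matrix must be square")
  if (nrow(m) != length(loci)) abort("LD matrix dimension must equal loci count")
  if (any(m < -1e-9 | m > 1 + 1e-9)) {
    abort("LD matrix values must lie in [0, 1]")
  }
  asym <- max(abs(m - t(m)))
  if (asym > 1e-6) {
    abort(sprintf("LD matrix is asymmetric (max |M - t(M)| = %g)", asym))
  }
  m <- (m + t(m)) / 2
  m[m < 0] <- 0
  m[m > 1] <- 1
  dimnames(m) <- list(loci, loci)
  class(m) <- c("hap_ld", class(m))
  m
}

#' Write an LD matrix in the plink-square text dialect
#'
#' Tab-delimited, no header, full precision; [read_ld_matrix()] restores
#' it to within 1e-9.
#'
#' @param ld matrix from [compute_ld_matrix()] or [as_ld_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  txt <- apply(unclass(ld), 1, function(r) paste(sprintf("%.12g", r), collapse = "\t"))
  writeLines(txt, path)
  invisible(path)
}

# Shared two-column reader. Delimiter auto-detected among tab/comma/
# whitespace; optional header row.
read_two_col <- function(path, kind) {
  if (!file.exists(path)) abort(paste0("cannot read ", kind, " file: ", path))
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  df <- utils::read.table(path, header = FALSE, sep = sep,
    stringsAsFactors = FALSE, colClasses = "character",
    strip.white = TRUE)
  if (ncol(df) < 2) abort(paste0(kind, " file must have two columns"))
  df <- df[, 1:2]
  header_words <- c("id", "ind", "indiv", "individual", "sample", "line", "genotype")
  drop_header <- if (kind == "phenotype") {
    is.na(suppressWarnings(as.numeric(df[[2]][1])))
  } else {
    tolower(df[[1]][1]) %in% header_words
  }
  if (drop_header && nrow(df) > 1) df <- df[-1, , drop = FALSE]
  if (anyDuplicated(df[[1]])) {
    dup <- unique(df[[1]][duplicated(df[[1]])])
    abort(paste0("duplicate individual ID(s) in ", kind, " file: ",
      paste(head(dup, 5), collapse = ", ")))
  }
  df
}

#' Read a phenotype table (individual, numeric value)
#'
#' @param path two-column delimited text; header optional; delimiter
#'   auto-detected among tab, comma and whitespace.
#' @return tibble with columns `sample`, `value`.
#' @export
read_phenotype <- function(path) {
  df <- read_two_col(path, "phenotype")
  val <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(val)) {
    row <- which(is.na(val))[1]
    abort(sprintf("non-numeric phenotype value '%s' at data row %d", df[[2]][row], row))
  }
  tibble(sample = df[[1]], value = val)
}

#' Read a metadata table (individual, categorical label)
#'
#' @inheritParams read_phenotype
#' @return tibble with columns `sample`, `group`.
#' @export
read_metadata <- function(path) {
  df <- read_two_col(path, "metadata")
  tibble(sample = df[[1]], group = df[[2]])
}

#' Write phenotype / metadata tables as two-column TSV
#'
#' @param x tibble from [as_phenotype()] or [as_metadata()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_two_col_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export the tabular results of one haplotyping resolution
#'
#' Writes three TSV files into `dir`: the labelled haplotype table
#' (`haplotypes.tsv`), the individual assignments (`assignments.tsv`)
#' and the Marker-Group membership of every SNP (`mg_membership.tsv`).
#'
#' @param result a `hap_result` from [run_haplotyping()] (one epsilon).
#' @param dir output directory, created if needed.
#' @param prefix optional filename prefix (e.g. the epsilon value).
#' @return character vector of paths written, invisibly.
#' @export
export_results <- function(result, dir, prefix = "") {
  stopifnot(inherits(result, "hap_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(name) file.path(dir, paste0(prefix, name))
  ht <- result$hap_table
  paths <- c(p("haplotypes.tsv"), p("assignments.tsv"), p("mg_membership.tsv"))
  utils::write.table(ht$haps, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ht$assignment, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  memb <- dplyr::left_join(result$mgs$assignment,
    result$genotypes_loci[, c("id", "chrom", "pos")],
    by = "id"
  )
  utils::write.table(memb, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
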