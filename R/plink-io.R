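#' Read a PLINK bed/bim/fam fileset
#'
#' Reads the binary `bed` genotype file (magic bytes `0x6c 0x1b`, 2 bits
#' per genotype) together with its `bim` variant table and `fam` sample
#' table. Dosages count copies of the A1 allele: `2` hom A1, `1` het, `0`
#' hom A2, `NA` missing. Both variant-major and sample-major layouts are
#' handled.
#'
#' @param prefix Path prefix; `prefix.bed`, `prefix.bim` and `prefix.fam`
#'   must all exist.
#' @return A list with `genotypes` (samples x variants matrix, `NA` for
#'   missing), `bim` and `fam` tibbles.
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  miss <- paths[!file.exists(paths)]
  if (length(miss) > 0) {
    abort(paste0("Missing PLINK file(s): ", paste(miss, collapse = ", ")))
  }
  bim <- utils::read.table(paths[2], col.names = c("chr", "id", "cm", "pos",
                                                   "a1", "a2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(paths[3], col.names = c("fid", "iid", "pat", "mat",
                                                   "sex", "pheno"),
                           colClasses = c("character", "character", "character",
                                          "character", "integer", "numeric"))
  n <- nrow(fam)
  L <- nrow(bim)
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    abort("Not a PLINK bed file (magic bytes do not match).")
  }
  snp_major <- raw[3] == as.raw(0x01)
  if (!snp_major && raw[3] != as.raw(0x00)) {
    abort("Unrecognised bed mode byte.")
  }
  body <- raw[-(1:3)]
  per <- if (snp_major) n else L
  bytes_per_rec <- ceiling(per / 4)
  n_rec <- if (snp_major) L else n
  if (length(body) != bytes_per_rec * n_rec) {
    abort("bed payload size inconsistent with bim/fam sample and variant counts.")
  }
  # 2-bit codes per byte, low bits first: 00 -> 2, 10 -> 1, 11 -> 0, 01 -> NA
  lut <- bed_lut()
  vals <- lut[, as.integer(body) + 1L]           # 4 x n_bytes
  dim(vals) <- c(4 * bytes_per_rec, n_rec)
  vals <- vals[seq_len(per), , drop = FALSE]
  G <- if (snp_major) vals else t(vals)
  dimnames(G) <- list(fam$iid, bim$id)
  list(genotypes = G, bim = as_tibble(bim), fam = as_tibble(fam))
}

bed_lut <- function() {
  code <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  b <- 0:255
  rbind(code[as.character(bitwAnd(b, 3L))],
        code[as.character(bitwAnd(bitwShiftR(b, 2L), 3L))],
        code[as.character(bitwAnd(bitwShiftR(b, 4L), 3L))],
        code[as.character(bitwAnd(bitwShiftR(b, 6L), 3L))])
}

#' Write a PLINK bed/bim/fam fileset
#'
#' Inverse of [read_plink()]: writes a samples-by-variants dosage matrix in
#' variant-major bed format (A1-allele counts; `NA` becomes the missing
#' code), with minimal bim/fam metadata generated when not supplied.
#'
#' @param G Samples x variants dosage matrix with values in
#'   `{0, 1, 2, NA}`.
#' @param prefix Output path prefix.
#' @param bim,fam Optional metadata data frames in the column layout
#'   returned by [read_plink()].
#' @return The prefix, invisibly.
#' @export
write_plink <- function(G, prefix, bim = NULL, fam = NULL) {
  G <- as.matrix(G)
  n <- nrow(G)
  L <- ncol(G)
  if (!all(G %in% c(0, 1, 2) | is.na(G))) {
    abort("bed output requires hard-call dosages in {0, 1, 2, NA}.")
  }
  if (is.null(bim)) {
    ids <- colnames(G) %||% paste0("snp", seq_len(L))
    bim <- data.frame(chr = "1", id = ids, cm = 0, pos = seq_len(L),
                      a1 = "A", a2 = "B")
  }
  if (is.null(fam)) {
    iid <- rownames(G) %||% paste0("id", seq_len(n))
    fam <- data.frame(fid = iid, iid = iid, pat = "0", mat = "0",
                      sex = 0L, pheno = -9)
  }
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  # dosage -> 2-bit code: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  codes <- matrix(3L, 4 * ceiling(n / 4), L)
  g2c <- function(g) {
    out <- integer(length(g))
    out[is.na(g)] <- 1L
    out[!is.na(g) & g == 2] <- 0L
    out[!is.na(g) & g == 1] <- 2L
    out[!is.na(g) & g == 0] <- 3L
    out
  }
  codes[seq_len(n), ] <- apply(G, 2, g2c)
  dim(codes) <- c(4, length(codes) / 4)
  bytes <- as.raw(codes[1, ] + bitwShiftL(codes[2, ], 2L) +
                  bitwShiftL(codes[3, ], 4L) + bitwShiftL(codes[4, ], 6L))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(bytes, con)
  invisible(prefix)
}

#' Read or write a plain-text dosage table
#'
#' A desk-scale dialect alongside PLINK binary: a TSV with sample IDs in
#' the first column and one column per variant.
#'
#' @param path File path.
#' @return `read_dosage_tsv()`: samples x variants numeric matrix with
#'   sample IDs as row names.
#' @export
read_dosage_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  G <- as.matrix(d[, -1, drop = FALSE])
  rownames(G) <- as.character(d[[1]])
  storage.mode(G) <- "double"
  G
}

#' @rdname read_dosage_tsv
#' @param G Samples x variants dosage matrix.
#' @export
write_dosage_tsv <- function(G, path) {
  out <- data.frame(iid = rownames(G) %||% paste0("id", seq_len(nrow(G))),
                    G, check.names = FALSE)
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Exact-frequency Hardy-Weinberg goodness-of-fit test
#'
#' One-degree-of-freedom Pearson chi-squared test of observed genotype
#' counts against Hardy-Weinberg expectations computed from the sample
#' allele frequency.
#'
#' @param n0,n1,n2 Counts of dosage-0, dosage-1 and dosage-2 genotypes.
#' @return The p-value; `1` by convention for monomorphic counts.
#' @export
hwe_test <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n < 1) abort("Need at least one genotype.")
  q <- (n1 + 2 * n2) / (2 * n)
  if (q <= 0 || q >= 1) return(1)
  e <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  chisq <- sum((c(n0, n1, n2) - e)^2 / e)
  pchisq(chisq, df = 1, lower.tail = FALSE)
}

#' Variant quality-control filtering
#'
#' Removes variants with missing rate above `miss_max`, Hardy-Weinberg
#' test p-value below `hwe_min_p`, or minor allele frequency below
#' `maf_min` (all strict comparisons, so a variant exactly at a boundary
#' is retained).
#'
#' @param G Samples x variants dosage matrix (`NA` missing).
#' @param miss_max Maximum tolerated per-variant missing rate.
#' @param hwe_min_p Minimum tolerated HWE p-value.
#' @param maf_min Minimum tolerated MAF.
#' @return A list with the filtered `genotypes` and a per-variant `report`
#'   tibble (`id`, `missing_rate`, `maf`, `hwe_p`, pass flags).
#' @export
qc_filter <- function(G, miss_max = 0.05, hwe_min_p = 1e-10,
                      maf_min = 0.05) {
  G <- as.matrix(G)
  L <- ncol(G)
  ids <- colnames(G) %||% paste0("snp", seq_len(L))
  miss <- colMeans(is.na(G))
  af <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[is.nan(af)] <- 0
  hwe_p <- vapply(seq_len(L), function(l) {
    g <- G[, l]
    g <- g[!is.na(g)]
    if (length(g) == 0 || !all(g %in% c(0, 1, 2))) return(NA_real_)
    hwe_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))
  pass_missing <- !(miss > miss_max)
  pass_hwe <- is.na(hwe_p) | !(hwe_p < hwe_min_p)
  pass_maf <- !(maf < maf_min)
  pass <- pass_missing & pass_hwe & pass_maf
  if (!any(pass)) abort("All variants were removed by quality control.")
  report <- tibble(id = ids, missing_rate = miss, maf = maf, hwe_p = hwe_p,
                   pass_missing = pass_missing, pass_hwe = pass_hwe,
                   pass_maf = pass_maf, pass = pass)
  list(genotypes = G[, pass, drop = FALSE], report = report)
}

#' Align genotype samples with a phenotype table by ID
#'
#' Joins on sample IDs, never on row order. Samples present on only one
#' side are dropped with a message; if no IDs match at all, an error lists
#' the unmatched IDs.
#'
#' @param G Samples x variants dosage matrix with sample IDs as row names.
#' @param data Phenotype/covariate data frame.
#' @param id Name of the ID column in `data`.
#' @return A list with the row-aligned `genotypes` and `data`.
#' @export
align_samples <- function(G, data, id = "iid") {
  gids <- rownames(G)
  if (is.null(gids)) abort("`G` must have sample IDs as row names.")
  pids <- as.character(data[[id]])
  common <- intersect(gids, pids)
  if (length(common) == 0) {
    abort(paste0("No sample IDs match between genotypes and phenotype ",
                 "table. Unmatched genotype IDs: ",
                 paste(utils::head(gids, 5), collapse = ", "),
                 "; unmatched phenotype IDs: ",
                 paste(utils::head(pids, 5), collapse = ", ")))
  }
  dropped <- (length(gids) - length(common)) + (length(pids) - length(common))
  if (dropped > 0) {
    rlang::inform(paste0("Dropped ", dropped,
                         " sample(s) without a match on both sides."))
  }
  list(genotypes = G[common, , drop = FALSE],
       data = data[match(common, pids), , drop = FALSE])
}
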