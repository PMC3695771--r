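# SNP-major chunked byte container for genotype dosages.
#
# Layout on disk: a directory holding
#   dosage.bin -- one unsigned byte per (SNP, individual) cell, SNP-major
#                 (all individuals of SNP j are contiguous), value =
#                 round(dose * 100) in 0..200, sentinel 255 = missing
#   meta.json  -- StoreMetadata as JSON
# A whole-file memory image is never required: conversion streams the
# row-per-person text in bounded individual blocks, and reads seek straight
# to the requested SNP range.

STORE_SCALE <- 100L
STORE_SENTINEL <- 255L

#' Construct store metadata
#'
#' Describes a SNP-major dosage container: its dimensions, the SNP and
#' individual identifiers, the chunk shape used while converting, and the
#' byte encoding (dose times 100 in one unsigned byte, 255 = missing).
#'
#' @param n_individuals Number of individuals (columns of a stored SNP record).
#' @param n_snps Number of SNPs (records).
#' @param snp_ids Character vector of SNP identifiers, length `n_snps`.
#' @param individual_ids Character vector of individual identifiers, length
#'   `n_individuals`.
#' @param chunk_snps,chunk_individuals Block sizes used for the bounded-memory
#'   transposition passes; must not exceed the corresponding dimension.
#' @return A `snp_store_meta` object.
#' @export
snp_store_meta <- function(n_individuals, n_snps,
                           snp_ids = paste0("snp_", seq_len(n_snps)),
                           individual_ids = paste0("id_", seq_len(n_individuals)),
                           chunk_snps = min(1000L, n_snps),
                           chunk_individuals = min(1000L, n_individuals)) {
  n_individuals <- as.integer(n_individuals)
  n_snps <- as.integer(n_snps)
  if (n_individuals < 1L || n_snps < 1L)
    stop("store must have at least one individual and one SNP")
  if (length(snp_ids) != n_snps)
    stop("snp_ids length (", length(snp_ids), ") != n_snps (", n_snps, ")")
  if (length(individual_ids) != n_individuals)
    stop("individual_ids length (", length(individual_ids),
         ") != n_individuals (", n_individuals, ")")
  chunk_snps <- as.integer(chunk_snps)
  chunk_individuals <- as.integer(chunk_individuals)
  if (chunk_snps < 1L || chunk_snps > n_snps)
    stop("chunk_snps must be in [1, n_snps]")
  if (chunk_individuals < 1L || chunk_individuals > n_individuals)
    stop("chunk_individuals must be in [1, n_individuals]")
  structure(list(
    n_individuals = n_individuals,
    n_snps = n_snps,
    snp_ids = as.character(snp_ids),
    individual_ids = as.character(individual_ids),
    chunk_snps = chunk_snps,
    chunk_individuals = chunk_individuals,
    encoding = list(scale = STORE_SCALE, missing_sentinel = STORE_SENTINEL),
    layout = "snp-major"
  ), class = "snp_store_meta")
}

#' Construct a genotype block
#'
#' A dense individuals-by-SNPs dose matrix for a contiguous SNP range.
#' Non-missing doses must lie in \[0, 2\]. Missing entries carry
#' `missing_code`, which is `NA` for blocks read back from a store and `3`
#' (the conventional raw-genotype missing code) for decoded BED data.
#'
#' @param doses Numeric matrix, individuals in rows, SNPs in columns.
#' @param snp_offset 0-based index of the first SNP in the parent container.
#' @param snp_ids SNP identifiers, one per column.
#' @param missing_code In-memory missing marker (`NA` or a numeric code
#'   outside \[0, 2\]).
#' @return A `genotype_block` object.
#' @export
genotype_block <- function(doses, snp_offset = 0L,
                           snp_ids = paste0("snp_", snp_offset + seq_len(ncol(doses))),
                           missing_code = NA_real_) {
  doses <- as.matrix(doses)
  if (length(snp_ids) != ncol(doses))
    stop("snp_ids length != number of SNP columns")
  if (nrow(doses) < 1L || ncol(doses) < 1L)
    stop("genotype block must be non-empty")
  if (!is.na(missing_code) && missing_code >= 0 && missing_code <= 2)
    stop("missing_code must lie outside [0, 2]")
  obs <- if (is.na(missing_code)) !is.na(doses) else doses != missing_code
  dd <- doses[obs]
  if (length(dd) && (min(dd) < 0 || max(dd) > 2))
    stop("non-missing doses must lie in [0, 2]")
  structure(list(doses = doses, snp_offset = as.integer(snp_offset),
                 snp_ids = as.character(snp_ids), missing_code = missing_code),
            class = "genotype_block")
}

#' @export
print.genotype_block <- function(x, ...) {
  cat(sprintf("<genotype_block> %d individuals x %d SNPs (offset %d, missing code %s)\n",
              nrow(x$doses), ncol(x$doses), x$snp_offset,
              ifelse(is.na(x$missing_code), "NA", format(x$missing_code))))
  invisible(x)
}

#' Logical matrix of missing entries in a block
#' @param block A `genotype_block`.
#' @return Logical matrix, `TRUE` where the dose is missing.
#' @export
block_missing <- function(block) {
  if (is.na(block$missing_code)) is.na(block$doses)
  else block$doses == block$missing_code
}

# Accept either a genotype_block or a bare matrix.
dose_matrix <- function(x) {
  if (inherits(x, "genotype_block")) x$doses else as.matrix(x)
}

meta_path <- function(store_path) file.path(store_path, "meta.json")
dosage_path <- function(store_path) file.path(store_path, "dosage.bin")

write_store_meta <- function(meta, store_path) {
  jsonlite::write_json(unclass(meta), meta_path(store_path),
                       auto_unbox = TRUE, digits = NA)
}

#' Read container metadata
#' @param store_path Path to the store directory.
#' @return A `snp_store_meta` object.
#' @export
read_store_meta <- function(store_path) {
  mp <- meta_path(store_path)
  if (!file.exists(mp))
    stop("no genotype store at '", store_path, "' (missing meta.json)")
  m <- jsonlite::read_json(mp, simplifyVector = TRUE)
  snp_store_meta(m$n_individuals, m$n_snps, m$snp_ids, m$individual_ids,
                 m$chunk_snps, m$chunk_individuals)
}

encode_doses <- function(doses, missing_code = NA_real_) {
  miss <- if (is.na(missing_code)) is.na(doses) else doses == missing_code
  bad <- !miss & (doses < 0 | doses > 2)
  if (any(bad)) stop("dose outside [0, 2] cannot be encoded")
  v <- as.integer(round(doses * STORE_SCALE))
  v[miss] <- STORE_SENTINEL
  as.raw(v)
}

decode_bytes <- function(bytes) {
  v <- as.integer(bytes)
  d <- v / STORE_SCALE
  d[v == STORE_SENTINEL] <- NA_real_
  d
}

#' Write an in-memory dose matrix as a SNP-major store
#'
#' Convenience constructor used by the simulator and the converters once a
#' block is in memory; each dose is stored as `round(dose * 100)` in one
#' unsigned byte, missing as 255.
#'
#' @param doses Individuals-by-SNPs matrix or `genotype_block`.
#' @param store_path Directory to create.
#' @inheritParams snp_store_meta
#' @param missing_code Value marking missing doses in `doses`.
#' @return The store's `snp_store_meta`, invisibly.
#' @export
write_snp_store <- function(doses, store_path,
                            snp_ids = NULL, individual_ids = NULL,
                            chunk_snps = NULL, chunk_individuals = NULL,
                            missing_code = NA_real_) {
  if (inherits(doses, "genotype_block")) {
    if (is.null(snp_ids)) snp_ids <- doses$snp_ids
    missing_code <- doses$missing_code
    doses <- doses$doses
  }
  doses <- as.matrix(doses)
  n <- nrow(doses); m <- ncol(doses)
  args <- list(n_individuals = n, n_snps = m)
  if (!is.null(snp_ids)) args$snp_ids <- snp_ids
  if (!is.null(individual_ids)) args$individual_ids <- individual_ids
  if (!is.null(chunk_snps)) args$chunk_snps <- chunk_snps
  if (!is.null(chunk_individuals)) args$chunk_individuals <- chunk_individuals
  meta <- do.call(snp_store_meta, args)
  dir.create(store_path, showWarnings = FALSE, recursive = TRUE)
  con <- file(dosage_path(store_path), "wb")
  on.exit(close(con))
  # column-major flattening of an n x m matrix IS the SNP-major byte order
  writeBin(encode_doses(doses, missing_code), con)
  write_store_meta(meta, store_path)
  invisible(meta)
}

#' Read a block of SNPs for all individuals
#'
#' Seeks straight to the requested SNP-major records; only the bytes of the
#' requested range are touched. Sentinel bytes come back as `NA`.
#'
#' @param store_path Store directory.
#' @param snp_start 0-based index of the first SNP (inclusive).
#' @param snp_end 0-based exclusive end index.
#' @return A `genotype_block` with `missing_code = NA`.
#' @export
read_block <- function(store_path, snp_start, snp_end) {
  meta <- read_store_meta(store_path)
  snp_start <- as.integer(snp_start); snp_end <- as.integer(snp_end)
  if (snp_start < 0L || snp_end > meta$n_snps || snp_start >= snp_end)
    stop("invalid SNP range [", snp_start, ", ", snp_end,
         ") for store with ", meta$n_snps, " SNPs")
  b <- snp_end - snp_start
  n <- meta$n_individuals
  con <- file(dosage_path(store_path), "rb")
  on.exit(close(con))
  seek(con, where = as.numeric(snp_start) * n, origin = "start")
  bytes <- readBin(con, what = "raw", n = b * n)
  if (length(bytes) != b * n)
    stop("truncated dosage file: expected ", b * n, " bytes, got ", length(bytes))
  doses <- matrix(decode_bytes(bytes), nrow = n, ncol = b)
  rownames(doses) <- meta$individual_ids
  genotype_block(doses, snp_offset = snp_start,
                 snp_ids = meta$snp_ids[(snp_start + 1L):snp_end],
                 missing_code = NA_real_)
}

#' Partition a store into consecutive SNP blocks
#'
#' @param store_path Store directory.
#' @param block_size SNPs per block (last block may be smaller).
#' @return List of `genotype_block`s covering all SNPs exactly once, in order.
#' @export
iterate_blocks <- function(store_path, block_size) {
  block_size <- as.integer(block_size)
  if (block_size < 1L) stop("block_size must be >= 1")
  meta <- read_store_meta(store_path)
  starts <- seq(0L, meta$n_snps - 1L, by = block_size)
  lapply(starts, function(s) read_block(store_path, s, min(s + block_size, meta$n_snps)))
}

# 0-based [start, end) index pairs covering m items in blocks of block_size
block_ranges <- function(m, block_size) {
  starts <- seq(0L, m - 1L, by = as.integer(block_size))
  lapply(starts, function(s) c(s, min(s + block_size, m)))
}

#' Convert a row-per-person dosage text file into a SNP-major store
#'
#' The input has one record per individual carrying `n_snps` dose fields in
#' \[0, 2\] (the layout of MACH-style `mldose` files). Transposition to the
#' SNP-major container is done in bounded-memory passes over blocks of
#' `chunk_individuals` records; the full matrix is never materialized.
#'
#' @param text_path Input text file.
#' @param store_path Output store directory.
#' @param meta `snp_store_meta` describing the container to produce.
#' @param skip Leading non-numeric ID fields per record to skip (default 2,
#'   MACH-like).
#' @param sep Field delimiter; `""` (default) means any whitespace.
#' @param na_strings Tokens treated as a missing dose.
#' @return `meta`, invisibly, after the container is written.
#' @export
convert_dosage_text <- function(text_path, store_path, meta,
                                skip = 2L, sep = "", na_strings = c("NA", ".")) {
  if (!file.exists(text_path)) stop("input file '", text_path, "' not found")
  n <- meta$n_individuals; m <- meta$n_snps
  dir.create(store_path, showWarnings = FALSE, recursive = TRUE)
  # preallocate the byte file so partial SNP records can be patched per pass
  con <- file(dosage_path(store_path), "w+b")
  on.exit(close(con), add = TRUE)
  seek(con, where = as.numeric(n) * m - 1, origin = "start", rw = "write")
  writeBin(as.raw(STORE_SENTINEL), con)
  tin <- file(text_path, "r")
  on.exit(close(tin), add = TRUE)
  done <- 0L
  while (done < n) {
    take <- min(meta$chunk_individuals, n - done)
    lines <- readLines(tin, n = take)
    if (length(lines) < take)
      stop("expected ", n, " records, file ended after ", done + length(lines))
    fields <- if (identical(sep, "")) strsplit(trimws(lines), "[ \t]+")
              else strsplit(lines, sep, fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != skip + m))
      stop("ragged record ", done + which(nf != skip + m)[1], ": expected ",
           skip + m, " fields, found ", nf[nf != skip + m][1])
    vals <- vapply(fields, function(f) {
      x <- f[(skip + 1L):(skip + m)]
      v <- suppressWarnings(as.numeric(x))
      v[x %in% na_strings] <- NA_real_
      v
    }, numeric(m))                      # m x take
    bad <- which(!is.na(vals) & (vals < 0 | vals > 2), arr.ind = TRUE)
    if (nrow(bad)) {
      stop("dose ", vals[bad[1, 1], bad[1, 2]], " outside [0, 2] in record ",
           done + bad[1, 2], ", SNP column ", bad[1, 1])
    }
    enc <- matrix(encode_doses(vals), nrow = m)    # rows = SNPs
    for (j in seq_len(m)) {
      seek(con, where = as.numeric(j - 1L) * n + done, origin = "start",
           rw = "write")
      writeBin(enc[j, ], con)
    }
    done <- done + take
  }
  write_store_meta(meta, store_path)
  invisible(meta)
}
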