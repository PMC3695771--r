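# PLINK v1 BED/BIM/FAM input.
#
# BED stores genotypes 2 bits per cell. In SNP-major mode each SNP occupies
# ceil(n/4) bytes; within a byte the least-significant pair belongs to the
# first individual. Pair values: 00 = homozygous A1 (dose 2), 10 = het
# (dose 1), 11 = homozygous A2 (dose 0), 01 = missing. Missing is carried in
# memory as code 3, outside the dose range.

PLINK_MAGIC <- as.raw(c(0x6c, 0x1b))
BED_MISSING <- 3

# dose of the A1 allele for every (byte value, within-byte position),
# built by base-4 digit extraction; 256 x 4
bed_dose_table <- function() {
  pair_dose <- c(2, BED_MISSING, 1, 0)  # pair values 0,1,2,3
  bytes <- 0:255
  vapply(1:4, function(pos) pair_dose[(bytes %/% 4L^(pos - 1L)) %% 4L + 1L],
         numeric(256))
}

.bed_table <- bed_dose_table()

#' Decode a PLINK v1 BED byte stream
#'
#' @param bed Path to a `.bed` file, or a raw vector with its bytes.
#' @param n_individuals,n_snps Dimensions, normally taken from the `.fam` and
#'   `.bim` files.
#' @param block_size SNPs per returned block.
#' @param allele_count Which allele the dose counts: `"a1"` (default, the
#'   first allele of the `.bim` record) or `"a2"` (flips dose to `2 - dose`).
#' @param snp_ids Optional SNP identifiers.
#' @return List of `genotype_block`s with doses in \{0, 1, 2\} and missing
#'   code 3.
#' @export
decode_plink_bed <- function(bed, n_individuals, n_snps,
                             block_size = n_snps,
                             allele_count = c("a1", "a2"),
                             snp_ids = paste0("snp_", seq_len(n_snps))) {
  allele_count <- match.arg(allele_count)
  raw <- if (is.raw(bed)) bed else readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1] != PLINK_MAGIC[1] || raw[2] != PLINK_MAGIC[2])
    stop("not a PLINK BED stream: bad magic bytes")
  if (raw[3] == as.raw(0x00))
    stop("individual-major BED files are not supported; re-export SNP-major")
  if (raw[3] != as.raw(0x01))
    stop("unknown BED mode byte: ", as.integer(raw[3]))
  bpsnp <- ceiling(n_individuals / 4)
  body <- raw[-(1:3)]
  if (length(body) != bpsnp * n_snps)
    stop("truncated BED stream: expected ", bpsnp * n_snps,
         " genotype bytes, found ", length(body))
  lapply(block_ranges(n_snps, block_size), function(r) {
    j0 <- r[1]; j1 <- r[2]; b <- j1 - j0
    bytes <- as.integer(body[(j0 * bpsnp + 1L):(j1 * bpsnp)])
    B <- matrix(bytes, nrow = bpsnp, ncol = b)
    D <- matrix(0, nrow = 4L * bpsnp, ncol = b)
    for (pos in 1:4)
      D[seq(pos, by = 4L, length.out = bpsnp), ] <-
        .bed_table[as.vector(B) + 1L + (pos - 1L) * 256L]
    D <- D[seq_len(n_individuals), , drop = FALSE]  # drop padding pairs
    if (allele_count == "a2") {
      flip <- D != BED_MISSING
      D[flip] <- 2 - D[flip]
    }
    genotype_block(D, snp_offset = j0, snp_ids = snp_ids[(j0 + 1L):j1],
                   missing_code = BED_MISSING)
  })
}

#' Read a PLINK .bim variant table
#' @param path Path to the `.bim` file.
#' @return Data frame with chrom, snp_id, cm, pos, a1, a2.
#' @export
read_bim <- function(path) {
  bim <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos", "a1", "a2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  bim
}

#' Read a PLINK .fam sample table
#' @param path Path to the `.fam` file.
#' @return Data frame with fid, iid, pat, mat, sex, pheno.
#' @export
read_fam <- function(path) {
  utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"),
                    colClasses = c("character", "character", "character",
                                   "character", "integer", "character"))
}

#' Convert a PLINK BED/BIM/FAM trio into a SNP-major dosage store
#'
#' Decodes the 2-bit genotypes block by block and writes them to the byte
#' container (dose times 100; missing code 3 becomes sentinel 255).
#'
#' @param bed_prefix Path prefix of the trio (`<prefix>.bed/.bim/.fam`).
#' @param store_path Output store directory.
#' @param block_size SNPs decoded per pass.
#' @inheritParams decode_plink_bed
#' @return The store's `snp_store_meta`, invisibly.
#' @export
convert_plink <- function(bed_prefix, store_path, block_size = 1000L,
                          allele_count = c("a1", "a2")) {
  allele_count <- match.arg(allele_count)
  bim <- read_bim(paste0(bed_prefix, ".bim"))
  fam <- read_fam(paste0(bed_prefix, ".fam"))
  n <- nrow(fam); m <- nrow(bim)
  meta <- snp_store_meta(n, m, snp_ids = bim$snp_id, individual_ids = fam$iid,
                         chunk_snps = min(block_size, m),
                         chunk_individuals = n)
  blocks <- decode_plink_bed(paste0(bed_prefix, ".bed"), n, m,
                             block_size = block_size,
                             allele_count = allele_count, snp_ids = bim$snp_id)
  dir.create(store_path, showWarnings = FALSE, recursive = TRUE)
  con <- file(dosage_path(store_path), "wb")
  on.exit(close(con))
  for (blk in blocks)
    writeBin(encode_doses(blk$doses, blk$missing_code), con)
  write_store_meta(meta, store_path)
  invisible(meta)
}
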