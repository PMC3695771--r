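# SNP-major container and PLINK BED decoding.

test_that("BED decoding matches an exhaustive independent byte table", {
  oracle <- bed_byte_table_oracle()
  # all 256 byte values as one 4-individual stream, one SNP per byte
  stream <- c(as.raw(c(0x6c, 0x1b, 0x01)), as.raw(0:255))
  blocks <- decode_plink_bed(stream, n_individuals = 4, n_snps = 256)
  expect_length(blocks, 1)
  decoded <- blocks[[1]]$doses          # 4 x 256
  expect_equal(unname(t(decoded)), oracle)
})

test_that("BED decode handles the documented example bytes and padding", {
  stream <- c(as.raw(c(0x6c, 0x1b, 0x01)), as.raw(c(0x00, 0xD8)))
  blk <- decode_plink_bed(stream, n_individuals = 4, n_snps = 2)[[1]]
  expect_equal(blk$doses[, 1], c(2, 2, 2, 2))
  expect_equal(blk$doses[, 2], c(2, 1, 3, 0))   # (00,10,01,11) pairs from LSB
  expect_equal(blk$missing_code, 3)
  # padding bits beyond n_individuals are discarded
  blk3 <- decode_plink_bed(c(as.raw(c(0x6c, 0x1b, 0x01)), as.raw(0xD8)),
                           n_individuals = 3, n_snps = 1)[[1]]
  expect_equal(nrow(blk3$doses), 3)
  # a2 orientation flips non-missing doses
  flip <- decode_plink_bed(stream, 4, 2, allele_count = "a2")[[1]]
  expect_equal(flip$doses[, 2], c(0, 1, 3, 2))
})

test_that("malformed BED streams are rejected with clear errors", {
  good <- make_bed_stream(matrix(c(0, 1, 2, 3), 4, 1))
  expect_error(decode_plink_bed(as.raw(c(0x00, 0x1b, 0x01, 0x00)), 4, 1),
               "magic")
  bad_mode <- good; bad_mode[3] <- as.raw(0x00)
  expect_error(decode_plink_bed(bad_mode, 4, 1), "individual-major")
  expect_error(decode_plink_bed(good, 4, 2), "truncated")
})

test_that("dosage quantization is exact at scale points and bounded by 0.005", {
  td <- tempfile("dose")
  lines <- c("p1 X 1.000 0.239", "p2 X 2.000 0.005")
  writeLines(lines, td)
  meta <- snp_store_meta(2, 2, snp_ids = c("a", "b"),
                         individual_ids = c("p1", "p2"))
  sp <- tempfile("st")
  convert_dosage_text(td, sp, meta)
  blk <- read_block(sp, 0, 2)
  expect_identical(unname(blk$doses[1, ]), c(1.00, 0.24))
  expect_lt(abs(blk$doses[1, 2] - 0.239), 0.005 + 1e-12)
})

test_that("row-per-person text converts to the transposed store within 0.005", {
  set.seed(41)
  n <- 6; m <- 10
  M <- matrix(round(stats::runif(n * m, 0, 2), 3), n, m)
  M[2, 5] <- NA
  txt <- tempfile("mldose")
  writeLines(vapply(seq_len(n), function(i)
    paste(c(paste0("id", i), "DOSE",
            ifelse(is.na(M[i, ]), "NA", sprintf("%.3f", M[i, ]))),
          collapse = " "), character(1)), txt)
  meta <- snp_store_meta(n, m, individual_ids = paste0("id", 1:n),
                         chunk_individuals = 2L, chunk_snps = 3L)
  sp <- tempfile("st")
  convert_dosage_text(txt, sp, meta)
  got <- read_block(sp, 0, m)$doses
  expect_true(all(abs(got[!is.na(M)] - M[!is.na(M)]) <= 0.005 + 1e-12))
  expect_true(is.na(got[2, 5]))

  bad <- tempfile(); writeLines(c("i1 X 0.5 0.5", "i2 X 0.5"), bad)
  meta2 <- snp_store_meta(2, 2)
  expect_error(convert_dosage_text(bad, tempfile(), meta2), "ragged")
  bad2 <- tempfile(); writeLines(c("i1 X 0.5 2.4", "i2 X 0.5 0.1"), bad2)
  expect_error(convert_dosage_text(bad2, tempfile(), meta2), "outside \\[0, 2\\]")
})

test_that("block reads are pure, range-checked, and consistent under partitioning", {
  st <- make_random_store(7, 23, seed = 9)
  whole <- read_block(st$path, 0, 23)
  expect_equal(unname(whole$doses), st$doses, tolerance = 1e-12)
  expect_equal(read_block(st$path, 3, 11)$doses,
               read_block(st$path, 3, 11)$doses)
  left <- read_block(st$path, 0, 10); right <- read_block(st$path, 10, 23)
  expect_equal(cbind(left$doses, right$doses), whole$doses)
  expect_error(read_block(st$path, 4, 4), "invalid SNP range")
  expect_error(read_block(st$path, -1, 4), "invalid SNP range")
  expect_error(read_block(st$path, 0, 24), "invalid SNP range")
  expect_error(read_block(tempfile("nope"), 0, 1), "no genotype store")
})

test_that("iterate_blocks tiles the store exactly once in order", {
  st <- make_random_store(5, 10, seed = 2)
  blocks <- iterate_blocks(st$path, 4)
  expect_equal(vapply(blocks, function(b) ncol(b$doses), numeric(1)), c(4, 4, 2))
  expect_length(iterate_blocks(st$path, 100), 1)
  ids <- unlist(lapply(blocks, `[[`, "snp_ids"))
  expect_identical(ids, read_store_meta(st$path)$snp_ids)
  expect_error(iterate_blocks(st$path, 0), "block_size")
})

test_that("a PLINK trio converts to a store preserving genotypes and missing", {
  set.seed(17)
  D <- matrix(sample(c(0, 1, 2, 3), 9 * 12, replace = TRUE,
                     prob = c(.3, .3, .3, .1)), 9, 12)
  prefix <- write_bed_trio(D)
  sp <- tempfile("st")
  meta <- convert_plink(prefix, sp, block_size = 5)
  expect_equal(meta$n_individuals, 9)
  expect_equal(meta$snp_ids, paste0("rs", 1:12))
  got <- read_block(sp, 0, 12)$doses
  expect_equal(unname(got[D != 3]), D[D != 3])
  expect_true(all(is.na(got[D == 3])))
})

test_that("metadata and block constructors enforce their invariants", {
  expect_error(snp_store_meta(0, 5), "at least one")
  expect_error(snp_store_meta(4, 5, snp_ids = "only_one"), "snp_ids length")
  expect_error(snp_store_meta(4, 5, chunk_snps = 9), "chunk_snps")
  m <- snp_store_meta(4, 5)
  expect_identical(m$layout, "snp-major")
  expect_identical(m$encoding$scale, 100L)
  expect_identical(m$encoding$missing_sentinel, 255L)
  expect_error(genotype_block(matrix(2.5, 2, 2)), "\\[0, 2\\]")
  expect_error(genotype_block(matrix(1, 2, 2), missing_code = 1), "outside")
})
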