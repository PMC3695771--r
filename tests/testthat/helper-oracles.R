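# Independent reference computations and fixture builders shared by tests.

# Exhaustive BED lookup built from the bit-pair specification via intToBits:
# within a byte the least-significant pair belongs to the first individual;
# pair (b1 b0) = 00 -> dose 2, 10 -> 1, 11 -> 0, 01 -> missing (code 3).
bed_byte_table_oracle <- function() {
  tab <- matrix(NA_real_, 256, 4)
  for (v in 0:255) {
    bits <- as.integer(intToBits(v))[1:8]
    for (pos in 1:4) {
      b0 <- bits[2 * pos - 1]
      b1 <- bits[2 * pos]
      tab[v + 1, pos] <-
        if (b1 == 0 && b0 == 0) 2
        else if (b1 == 1 && b0 == 0) 1
        else if (b1 == 1 && b0 == 1) 0
        else 3
    }
  }
  tab
}

# raw BED stream for a doses matrix (values 0/1/2/3), SNP-major v1
make_bed_stream <- function(doses) {
  n <- nrow(doses); m <- ncol(doses)
  bpsnp <- ceiling(n / 4)
  pair_of_dose <- c(`2` = 0L, `1` = 2L, `0` = 3L, `3` = 1L)
  bytes <- raw(0)
  for (j in seq_len(m)) {
    col <- c(doses[, j], rep(0, 4 * bpsnp - n))
    for (b in seq_len(bpsnp)) {
      q <- pair_of_dose[as.character(col[(4 * b - 3):(4 * b)])]
      bytes <- c(bytes, as.raw(q[1] + 4L * q[2] + 16L * q[3] + 64L * q[4]))
    }
  }
  c(as.raw(c(0x6c, 0x1b, 0x01)), bytes)
}

# write a BED/BIM/FAM trio for a doses matrix; returns the prefix
write_bed_trio <- function(doses, dir = tempfile("trio")) {
  dir.create(dir)
  prefix <- file.path(dir, "geno")
  writeBin(make_bed_stream(doses), paste0(prefix, ".bed"))
  m <- ncol(doses); n <- nrow(doses)
  write.table(data.frame(1, paste0("rs", seq_len(m)), 0, seq_len(m), "A", "G"),
              paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(paste0("f", seq_len(n)), paste0("p", seq_len(n)),
                         0, 0, 1, -9),
              paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  prefix
}

# random store on disk; returns list(path, doses)
make_random_store <- function(n, m, seed, path = tempfile("store")) {
  set.seed(seed)
  doses <- matrix(round(stats::runif(n * m, 0, 2), 2), n, m)
  write_snp_store(doses, path)
  list(path = path, doses = doses)
}

# log10 two-sided normal p by the Mills-ratio asymptotic expansion of the
# tail: log Phi(-t) ~ -t^2/2 - log t - log sqrt(2 pi) + log(1 - 1/t^2 + ...)
log10p_asymptotic_oracle <- function(t) {
  stopifnot(t >= 10)
  series <- 1 - 1 / t^2 + 3 / t^4 - 15 / t^6 + 105 / t^8
  (log(2) - t^2 / 2 - log(t) - 0.5 * log(2 * pi) + log(series)) / log(10)
}

# textbook weighted one-step coefficients, kept deliberately plain
irls_step_oracle <- function(y, A, beta) {
  eta <- drop(A %*% beta)
  p <- 1 / (1 + exp(-eta))
  w <- p * (1 - p)
  z <- eta + (y - p) / w
  drop(solve(t(A) %*% (A * w), t(A) %*% (w * z)))
}
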