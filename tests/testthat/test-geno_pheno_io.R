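# Genotype/phenotype IO, QC, imputation, centering, GRM, water traits.

make_panel <- function(n, m, miss_frac = 0, seed = 1) {
  set.seed(seed)
  p <- runif(m, 0.05, 0.5)
  d <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  if (miss_frac > 0) d[runif(n * m) < miss_frac] <- NA
  geno_matrix(d, sprintf("a%03d", 1:n),
              data.frame(snp_id = sprintf("s%04d", 1:m),
                         chromosome = rep_len(as.character(1:3), m),
                         position_bp = seq_len(m) * 100L,
                         ref_allele = "A", alt_allele = "B"))
}

test_that("dosage TSV round trip and allele frequencies", {
  g <- geno_matrix(matrix(c(0, 1, 2, 2, 1, 0), 3, 2),
                   c("x", "y", "z"),
                   data.frame(snp_id = c("s1", "s2"), chromosome = "1",
                              position_bp = c(10L, 20L),
                              ref_allele = "A", alt_allele = "B"))
  expect_equal(unname(g$allele_freq), c(0.5, 0.5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dosage_tsv(g, path)
  g2 <- read_genotypes(path, format = "dosage-tsv")
  expect_equal(unname(g2$dosages), unname(g$dosages))
  expect_equal(g2$accession_ids, g$accession_ids)

  # missing entries survive the round trip
  gm <- make_panel(8, 5, miss_frac = 0.2, seed = 3)
  write_dosage_tsv(gm, path)
  expect_equal(unname(read_genotypes(path)$dosages), unname(gm$dosages))
})

test_that("dosage TSV rejects out-of-range and non-numeric cells", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts2", "a\t0\t3", "b\t1\t2"), path)
  expect_error(read_genotypes(path), "not in \\{0, 1, 2, NA\\}")
  writeLines(c("id\ts1", "a\tfoo"), path)
  expect_error(read_genotypes(path), "non-numeric")
})

test_that("PLINK bed/bim/fam round trip preserves dosages and metadata", {
  for (n in c(5, 8)) {             # n = 5 exercises the padding bits
    g <- make_panel(n, 7, miss_frac = 0.15, seed = n)
    prefix <- file.path(withr::local_tempdir(), "panel")
    write_plink(g, prefix)
    g2 <- read_genotypes(prefix, format = "plink-bed")
    expect_identical(unname(g2$dosages), unname(g$dosages))
    expect_equal(g2$snps$snp_id, g$snps$snp_id)
    expect_equal(g2$snps$position_bp, g$snps$position_bp)
    expect_equal(g2$accession_ids, g$accession_ids)
  }
})

test_that("PLINK reader errors name the problem", {
  dir <- withr::local_tempdir()
  g <- make_panel(4, 3)
  write_plink(g, file.path(dir, "ok"))
  file.remove(file.path(dir, "ok.fam"))
  expect_error(read_genotypes(file.path(dir, "ok"), format = "plink-bed"),
               "missing.*fam")
  write_plink(g, file.path(dir, "bad"))
  writeLines(c("1 s1 0 100 B A", "1 s2 0"), file.path(dir, "bad.bim"))
  expect_error(read_genotypes(file.path(dir, "bad"), format = "plink-bed"),
               "malformed bim line 2")
})

test_that("duplicate snp ids are rejected", {
  expect_error(
    geno_matrix(matrix(0:1, 2, 2), c("a", "b"),
                data.frame(snp_id = c("s1", "s1"), chromosome = "1",
                           position_bp = c(1L, 2L), ref_allele = "A",
                           alt_allele = "B")),
    "duplicated snp_id")
})

test_that("qc_filter keeps exactly the SNPs passing both thresholds", {
  # MAF example: {0.04, 0.30}
  set.seed(19)
  d <- cbind(c(rep(0, 46), rep(1, 4)), rbinom(50, 2, 0.3))
  maf2 <- function() min(mean(d[, 2]) / 2, 1 - mean(d[, 2]) / 2)
  while (maf2() < 0.2) d[, 2] <- rbinom(50, 2, 0.3)
  g <- geno_matrix(d, sprintf("a%02d", 1:50),
                   data.frame(snp_id = c("rare", "common"), chromosome = "1",
                              position_bp = c(1L, 2L), ref_allele = "A",
                              alt_allele = "B"))
  expect_equal(qc_filter(g)$snps$snp_id, "common")

  # call-rate example: 6% missing (0.94 <= 0.95) is removed
  d2 <- matrix(rbinom(200, 2, 0.4), 100, 2)
  d2[1:6, 1] <- NA
  g2 <- geno_matrix(d2, sprintf("a%03d", 1:100),
                    data.frame(snp_id = c("gappy", "full"), chromosome = "1",
                               position_bp = c(1L, 2L), ref_allele = "A",
                               alt_allele = "B"))
  expect_equal(qc_filter(g2)$snps$snp_id, "full")
})

test_that("qc_filter matches a brute-force column scan and is idempotent", {
  g <- make_panel(60, 200, miss_frac = 0.04, seed = 11)
  kept <- qc_filter(g, 0.95, 0.05)
  # brute force, column by column
  expected <- 0
  for (j in seq_len(200)) {
    x <- g$dosages[, j]
    cr <- mean(!is.na(x))
    p <- mean(x, na.rm = TRUE) / 2
    if (cr > 0.95 && min(p, 1 - p) > 0.05) expected <- expected + 1
  }
  expect_equal(ncol(kept$dosages), expected)
  expect_equal(kept$accession_ids, g$accession_ids)
  twice <- qc_filter(kept, 0.95, 0.05)
  expect_identical(twice$dosages, kept$dosages)
  rare <- geno_matrix(matrix(c(rep(0, 48), 1, 1), 50, 1),
                      sprintf("a%02d", 1:50),
                      data.frame(snp_id = "rare", chromosome = "1",
                                 position_bp = 1L, ref_allele = "A",
                                 alt_allele = "B"))
  expect_error(qc_filter(rare), "empty panel")
})

test_that("impute_mean fills 2p and errors on all-missing SNPs", {
  d <- matrix(c(0, 2, NA, 1, 1, 1), 3, 2)
  g <- geno_matrix(d, c("a", "b", "c"),
                   data.frame(snp_id = c("s1", "s2"), chromosome = "1",
                              position_bp = c(1L, 2L), ref_allele = "A",
                              alt_allele = "B"))
  gi <- impute_mean(g)
  expect_equal(gi$dosages[3, 1], 1.0)      # 2 * 0.5
  expect_false(anyNA(gi$dosages))

  g2 <- make_panel(10, 5, seed = 2)
  expect_identical(impute_mean(g2)$dosages, g2$dosages)  # nothing missing

  d3 <- matrix(c(NA, NA, NA, 0, 1, 2), 3, 2)
  g3 <- geno_matrix(d3, c("a", "b", "c"),
                    data.frame(snp_id = c("s1", "s2"), chromosome = "1",
                               position_bp = c(1L, 2L), ref_allele = "A",
                               alt_allele = "B"))
  expect_error(impute_mean(g3), "qc_filter")
})

test_that("center_markers subtracts 2p and refuses missing data", {
  g <- geno_matrix(matrix(c(0, 1, 2), 3, 1), c("a", "b", "c"),
                   data.frame(snp_id = "s1", chromosome = "1",
                              position_bp = 1L, ref_allele = "A",
                              alt_allele = "B"))
  expect_equal(unname(center_markers(g)[, 1]), c(-1, 0, 1))

  gmono <- geno_matrix(matrix(2, 3, 1), c("a", "b", "c"),
                       data.frame(snp_id = "s1", chromosome = "1",
                                  position_bp = 1L, ref_allele = "A",
                                  alt_allele = "B"))
  expect_equal(unname(center_markers(gmono)[, 1]), c(0, 0, 0))

  W <- center_markers(make_panel(40, 100, seed = 4))
  expect_lt(max(abs(colMeans(W))), 1e-12)

  gna <- make_panel(10, 5, miss_frac = 0.2, seed = 5)
  expect_error(center_markers(gna), "impute_mean")
})

test_that("compute_grm matches hand arithmetic and a double-loop oracle", {
  g <- geno_matrix(matrix(c(0, 1, 2), 3, 1), c("a", "b", "c"),
                   data.frame(snp_id = "s1", chromosome = "1",
                              position_bp = 1L, ref_allele = "A",
                              alt_allele = "B"))
  G <- compute_grm(center_markers(g))
  expect_equal(unname(G$matrix),
               matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3, 3))

  W <- center_markers(make_panel(10, 50, seed = 6))
  G2 <- compute_grm(W)
  expect_identical(G2$matrix, t(G2$matrix))
  p <- attr(W, "allele_freq")
  denom <- 2 * sum(p * (1 - p))
  naive <- matrix(0, 10, 10)
  for (i in 1:10) for (k in 1:10) naive[i, k] <- sum(W[i, ] * W[k, ]) / denom
  expect_lt(max(abs(unname(G2$matrix) - naive)), 1e-10)

  # invariance to SNP (column) order
  set.seed(7)
  perm <- sample(ncol(W))
  Wp <- W[, perm]
  attr(Wp, "allele_freq") <- p[perm]
  expect_equal(compute_grm(Wp)$matrix, G2$matrix, tolerance = 1e-12)

  gmono <- geno_matrix(matrix(2, 3, 1), c("a", "b", "c"),
                       data.frame(snp_id = "s1", chromosome = "1",
                                  position_bp = 1L, ref_allele = "A",
                                  alt_allele = "B"))
  expect_error(compute_grm(center_markers(gmono)), "monomorphic")
})

test_that("GRM diagonal averages 1 under Hardy-Weinberg genotypes", {
  g <- make_panel(50, 5000, seed = 8)
  G <- compute_grm(center_markers(g))
  expect_lt(abs(mean(diag(G$matrix)) - 1), 0.05)
})

test_that("derive_water_traits computes WU and WUE and flags degenerate rows", {
  w <- rbind(c(100, 90), c(80, 80))
  psa <- rbind(c(40, 50), c(30, 35))
  expect_warning(res <- derive_water_traits(w, psa, day = 2),
                 "non-positive water use")
  expect_equal(res$WU[1], 10)
  expect_equal(res$WUE[1], 5)
  expect_true(is.na(res$WU[2]) && is.na(res$WUE[2]))

  # 5-record fixture vs row-wise hand computation
  set.seed(9)
  w5 <- matrix(100 - cumsum(runif(15, 1, 5)), 5, 3)
  psa5 <- matrix(runif(15, 10, 60), 5, 3)
  res5 <- derive_water_traits(w5, psa5, day = 3)
  for (i in 1:5) {
    wu <- w5[i, 2] - w5[i, 3]
    expect_equal(res5$WU[i], wu)
    expect_equal(res5$WUE[i], psa5[i, 3] / wu)
  }
})

test_that("phenotype reader rejects duplicated accession ids", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession_id\tPSA", "a\t1.0", "a\t2.0"), path)
  expect_error(read_phenotypes(path), "duplicated accession_id")
})
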