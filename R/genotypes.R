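# Genotype and phenotype handling: PLINK/TSV readers, marker QC, mean
# imputation, centering and the genomic relationship matrix (GRM), and the
# derivation of the two water traits from raw pot weights and shoot area.

#' Construct a genotype matrix object
#'
#' Container for an accession-by-SNP allele dosage matrix (counts of the
#' alternative allele, 0/1/2, `NA` for missing) with marker metadata and
#' alternative-allele frequencies.
#'
#' @param dosages numeric matrix, accessions in rows, SNPs in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param accession_ids character vector of row identifiers.
#' @param snps data.frame with columns `snp_id`, `chromosome`, `position_bp`,
#'   `ref_allele`, `alt_allele` (one row per SNP column).
#' @return An object of class `geno_matrix` with elements `dosages`,
#'   `accession_ids`, `snps` and `allele_freq` (per-SNP alternative-allele
#'   frequency computed from non-missing entries).
#' @export
geno_matrix <- function(dosages, accession_ids, snps) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  assert_that(length(accession_ids) == nrow(dosages),
              "accession_ids length must match nrow(dosages)")
  assert_that(nrow(snps) == ncol(dosages),
              "snps must have one row per dosage column")
  ok <- is.na(dosages) | dosages %in% c(0, 1, 2)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop2(sprintf("dosage entry [%d, %d] = %s is not in {0, 1, 2, NA}",
                  bad[1], bad[2], format(dosages[bad[1], bad[2]])))
  }
  if (anyDuplicated(snps$snp_id)) {
    stop2("duplicated snp_id: ",
          paste(unique(snps$snp_id[duplicated(snps$snp_id)]), collapse = ", "))
  }
  assert_that(all(snps$position_bp >= 1), "position_bp must be >= 1")
  rownames(dosages) <- accession_ids
  colnames(dosages) <- snps$snp_id
  obj <- list(dosages = dosages,
              accession_ids = as.character(accession_ids),
              snps = as.data.frame(snps, stringsAsFactors = FALSE),
              allele_freq = colMeans(dosages, na.rm = TRUE) / 2)
  class(obj) <- "geno_matrix"
  obj
}

#' @export
print.geno_matrix <- function(x, ...) {
  nmiss <- sum(is.na(x$dosages))
  cat(sprintf("geno_matrix: %d accessions x %d SNPs (%s missing calls)\n",
              nrow(x$dosages), ncol(x$dosages), format(nmiss, big.mark = ",")))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

snp_info <- function(snp_id, chromosome, position_bp,
                     ref_allele = "A", alt_allele = "B") {
  data.frame(snp_id = as.character(snp_id),
             chromosome = as.character(chromosome),
             position_bp = as.integer(position_bp),
             ref_allele = as.character(ref_allele),
             alt_allele = as.character(alt_allele),
             stringsAsFactors = FALSE)
}

#' Read genotypes from PLINK or a dosage TSV
#'
#' @param path for `format = "plink-bed"`, the prefix or `.bed` path of a
#'   PLINK bed/bim/fam triplet (SNP-major bed v1.00); for
#'   `format = "dosage-tsv"`, a tab-separated file whose header names the
#'   SNPs, whose first column is the accession identifier and whose cells are
#'   0/1/2 dosages (`NA` for missing).
#' @param format `"auto"` (by extension), `"plink-bed"` or `"dosage-tsv"`.
#' @return A [geno_matrix()].
#' @details Dosages count copies of the alternative allele (PLINK bim allele
#'   1, typically the minor allele), so effect signs downstream refer to that
#'   allele.
#' @export
read_genotypes <- function(path, format = c("auto", "plink-bed", "dosage-tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path) ||
                  file.exists(paste0(path, ".bed"))) "plink-bed" else "dosage-tsv"
  }
  switch(format,
         "plink-bed" = read_plink(path),
         "dosage-tsv" = read_dosage_tsv(path))
}

read_dosage_tsv <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1), data.table = FALSE)
  assert_that(ncol(dt) >= 2, "dosage TSV needs an id column plus >= 1 SNP")
  ids <- dt[[1]]
  mat <- as.matrix(dt[, -1, drop = FALSE])
  if (is.character(mat)) {
    suppressWarnings(num <- matrix(as.numeric(mat), nrow(mat), ncol(mat)))
    bad <- which(is.na(num) & !is.na(mat) & mat != "NA", arr.ind = TRUE)
    if (nrow(bad)) {
      stop2(sprintf("non-numeric dosage '%s' at row %d, SNP '%s'",
                    mat[bad[1, 1], bad[1, 2]], bad[1, 1],
                    colnames(dt)[-1][bad[1, 2]]))
    }
    mat <- num
  }
  bad <- which(!(is.na(mat) | mat %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop2(sprintf("dosage %s at row %d, SNP '%s' is not in {0, 1, 2, NA}",
                  format(mat[bad[1, 1], bad[1, 2]]), bad[1, 1],
                  colnames(dt)[-1][bad[1, 2]]))
  }
  ids_snp <- colnames(dt)[-1]
  geno_matrix(mat, ids, snp_info(ids_snp, chromosome = "0",
                                 position_bp = seq_along(ids_snp)))
}

# PLINK 1 binary: magic 0x6c 0x1b, mode 0x01 (SNP-major), then one byte per 4
# accessions per SNP.  Two-bit codes: 00 hom allele1 (dosage 2), 10 het (1),
# 11 hom allele2 (0), 01 missing.
read_plink <- function(prefix) {
  prefix <- sub("\\.bed$", "", prefix)
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files)) {
    stop2("incomplete PLINK triplet, missing: ",
          paste(missing_files, collapse = ", "))
  }
  fam <- read_plink_table(paths[3], n_min = 2, what = "fam")
  bim <- read_plink_table(paths[2], n_min = 6, what = "bim")
  n <- nrow(fam)
  m <- nrow(bim)
  bed <- readBin(paths[1], "raw", n = file.size(paths[1]))
  assert_that(length(bed) >= 3 && bed[1] == as.raw(0x6c) &&
                bed[2] == as.raw(0x1b), "not a PLINK bed v1.00 file (bad magic)")
  assert_that(bed[3] == as.raw(0x01), "only SNP-major bed files are supported")
  bytes_per_snp <- ceiling(n / 4)
  assert_that(length(bed) == 3 + bytes_per_snp * m,
              "bed file size inconsistent with bim/fam dimensions")
  body <- bed[-(1:3)]
  # decode all two-bit fields at once
  codes <- rawToBits(body)                     # little-endian bit order
  b1 <- as.integer(codes[seq(1, length(codes), by = 2)])
  b2 <- as.integer(codes[seq(2, length(codes), by = 2)])
  code <- b1 + 2L * b2                         # 0=hom1, 1=missing, 2=het, 3=hom2
  dose <- c(2, NA, 1, 0)[code + 1L]
  dose <- matrix(dose, nrow = 4 * bytes_per_snp, ncol = m)[seq_len(n), , drop = FALSE]
  snps <- snp_info(bim[[2]], bim[[1]], as.integer(bim[[4]]),
                   ref_allele = bim[[6]], alt_allele = bim[[5]])
  geno_matrix(dose, fam[[2]], snps)
}

read_plink_table <- function(path, n_min, what) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(parts)
  if (any(nf < n_min)) {
    stop2(sprintf("malformed %s line %d in %s: expected >= %d fields, got %d",
                  what, which(nf < n_min)[1], path, n_min, nf[which(nf < n_min)[1]]))
  }
  as.data.frame(do.call(rbind, lapply(parts, `[`, seq_len(min(nf)))),
                stringsAsFactors = FALSE)
}

#' Write a genotype matrix as a PLINK bed/bim/fam triplet
#'
#' @param g a [geno_matrix()].
#' @param prefix output path prefix (writes `prefix.bed/.bim/.fam`).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  n <- nrow(g$dosages); m <- ncol(g$dosages)
  fam <- data.frame(g$accession_ids, g$accession_ids, 0, 0, 0, -9)
  write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  bim <- data.frame(g$snps$chromosome, g$snps$snp_id, 0, g$snps$position_bp,
                    g$snps$alt_allele, g$snps$ref_allele)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  code_of <- c(`2` = 0L, `1` = 2L, `0` = 3L)   # see read_plink
  bytes_per_snp <- ceiling(n / 4)
  pad <- 4 * bytes_per_snp - n
  d <- g$dosages
  codes <- matrix(1L, 4 * bytes_per_snp, m)    # pad bits read back as missing
  codes[seq_len(n), ] <- ifelse(is.na(d), 1L, code_of[as.character(d)])
  b1 <- codes %% 2L
  b2 <- codes %/% 2L
  # interleave the two bits of each code, column-major, little-endian per byte
  bitstream <- as.vector(rbind(as.vector(b1), as.vector(b2)))
  raw_body <- packBits(as.logical(bitstream), type = "raw")
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(raw_body, con)
  invisible(prefix)
}

#' Write a genotype matrix as a dosage TSV
#'
#' @inheritParams write_plink
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(g, path) {
  df <- data.frame(accession_id = g$accession_ids, g$dosages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' @param path TSV with an `accession_id` column (first column) and one
#'   numeric column per trait.
#' @return data.frame with `accession_id` plus trait columns.
#' @export
read_phenotypes <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1), data.table = FALSE)
  names(df)[1] <- "accession_id"
  if (anyDuplicated(df$accession_id)) {
    stop2("duplicated accession_id in phenotype file: ",
          paste(unique(df$accession_id[duplicated(df$accession_id)]),
                collapse = ", "))
  }
  df
}

#' Filter SNPs on call rate and minor allele frequency
#'
#' Keeps SNPs whose call rate is strictly above `min_call_rate` and whose
#' minor allele frequency is strictly above `min_maf` (the removal rule
#' "call rate <= threshold or MAF <= threshold" read literally). Allele
#' frequencies are recomputed on the retained panel.
#'
#' @param g a [geno_matrix()].
#' @param min_call_rate fraction in (0, 1); default 0.95.
#' @param min_maf fraction in (0, 1); default 0.05.
#' @return Filtered [geno_matrix()].
#' @export
qc_filter <- function(g, min_call_rate = 0.95, min_maf = 0.05) {
  assert_that(min_call_rate > 0 && min_call_rate < 1,
              "min_call_rate must be in (0, 1)")
  assert_that(min_maf > 0 && min_maf < 1, "min_maf must be in (0, 1)")
  call_rate <- colMeans(!is.na(g$dosages))
  p <- colMeans(g$dosages, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0                       # all-missing SNP
  keep <- call_rate > min_call_rate & maf > min_maf
  if (!any(keep)) stop2("qc_filter removed every SNP (empty panel)")
  geno_matrix(g$dosages[, keep, drop = FALSE], g$accession_ids,
              g$snps[keep, , drop = FALSE])
}

#' Replace missing dosages by their SNP mean
#'
#' Missing calls at SNP j become `2 * p_j` where `p_j` is the
#' alternative-allele frequency among the non-missing calls.
#'
#' @param g a [geno_matrix()].
#' @return A `geno_matrix` with no missing entries. Entries are no longer
#'   restricted to 0/1/2, so downstream code works with the `dosages` matrix
#'   directly.
#' @export
impute_mean <- function(g) {
  d <- g$dosages
  if (!anyNA(d)) return(g)
  all_missing <- colSums(!is.na(d)) == 0
  if (any(all_missing)) {
    stop2("SNP(s) with no observed calls: ",
          paste(head(g$snps$snp_id[all_missing], 5), collapse = ", "),
          " - run qc_filter() first")
  }
  fill <- 2 * g$allele_freq
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- fill[idx[, 2]]
  out <- g
  out$dosages <- d
  out$allele_freq <- colMeans(d) / 2
  out
}

#' Center marker dosages
#'
#' Returns the centered marker incidence matrix `W` with
#' `W[i, j] = dosage[i, j] - 2 p_j`, the standard parameterization for the
#' VanRaden genomic relationship matrix.
#'
#' @param g a [geno_matrix()] without missing entries (run [impute_mean()]
#'   first).
#' @return n x m numeric matrix with (near) zero column means; attribute
#'   `allele_freq` carries the frequencies used.
#' @export
center_markers <- function(g) {
  if (anyNA(g$dosages)) {
    stop2("dosages contain missing entries; run impute_mean() before centering")
  }
  p <- colMeans(g$dosages) / 2
  W <- sweep(g$dosages, 2, 2 * p, `-`)
  attr(W, "allele_freq") <- p
  W
}

#' Genomic relationship matrix (VanRaden)
#'
#' `G = W W' / (2 * sum_j p_j (1 - p_j))` from the centered marker matrix.
#'
#' @param W centered marker matrix from [center_markers()].
#' @param allele_freq per-SNP allele frequencies; defaults to the
#'   `allele_freq` attribute of `W`.
#' @return Object of class `grm`: list with `matrix` (n x n, symmetric) and
#'   `accession_ids`.
#' @export
compute_grm <- function(W, allele_freq = attr(W, "allele_freq")) {
  assert_that(!is.null(allele_freq), "allele_freq missing")
  denom <- 2 * sum(allele_freq * (1 - allele_freq))
  if (denom <= 0) stop2("all SNPs are monomorphic; GRM undefined")
  G <- tcrossprod(W) / denom
  G <- (G + t(G)) / 2
  obj <- list(matrix = G, accession_ids = rownames(W) %||%
                as.character(seq_len(nrow(W))))
  dimnames(obj$matrix) <- list(obj$accession_ids, obj$accession_ids)
  class(obj) <- "grm"
  obj
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d accessions, mean diagonal %.3f\n",
              nrow(x$matrix), mean(diag(x$matrix))))
  invisible(x)
}

#' Derive water use and water use efficiency
#'
#' Water use on day `r` is the pot-weight loss since the previous day,
#' `WU = weight[, r - 1] - weight[, r]`; water use efficiency is the ratio of
#' projected shoot area to water use, `WUE = psa[, r] / WU`. Records with
#' non-positive water use are flagged missing with a warning (the ratio is
#' undefined there).
#'
#' @param pot_weights records x day matrix of pot weights (grams).
#' @param psa records x day matrix of projected shoot area (pixels).
#' @param day day index `r` (>= 2) at which to evaluate.
#' @return data.frame with columns `WU` and `WUE`.
#' @export
derive_water_traits <- function(pot_weights, psa, day) {
  pot_weights <- as.matrix(pot_weights)
  psa <- as.matrix(psa)
  assert_that(day >= 2 && day <= ncol(pot_weights), "day must be in [2, ncol]")
  assert_that(nrow(pot_weights) == nrow(psa), "record counts differ")
  wu <- pot_weights[, day - 1] - pot_weights[, day]
  wue <- psa[, day] / wu
  bad <- !is.na(wu) & wu <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with non-positive water use flagged missing",
            call. = FALSE)
    wu[bad] <- NA_real_
    wue[bad] <- NA_real_
  }
  data.frame(WU = wu, WUE = wue)
}

# Inner-join alignment of genotypes/GRM rows with a phenotype table.
align_ids <- function(geno_ids, pheno_ids) {
  if (anyDuplicated(geno_ids) || anyDuplicated(pheno_ids)) {
    stop2("duplicated accession ids prevent an unambiguous join")
  }
  common <- intersect(geno_ids, pheno_ids)
  if (!length(common)) stop2("no accession ids shared between inputs")
  common
}
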