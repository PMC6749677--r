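# Generative model for validation: independent biallelic SNPs in
# Hardy-Weinberg proportions, a polygenic term drawn through the realized
# GRM, optional sparse QTL, and trait propagation through a known recursive
# DAG.  Every run is reproducible from the scenario seed.

#' Define a simulation scenario
#'
#' @param n_accessions panel size.
#' @param m_snps number of SNPs.
#' @param maf_range allele-frequency range (uniform), within (0, 0.5].
#' @param trait_names character vector (length t).
#' @param lambda_true t x t strictly-lower-triangular (under some trait
#'   order) matrix of structural coefficients, entry `[child, parent]`;
#'   defaults to all zero.
#' @param h2_true length-t heritabilities of the structural-residual traits
#'   (before network propagation).
#' @param sigma_g_corr t x t genetic correlation matrix of the polygenic
#'   components of the structural residuals (default identity: observed-trait
#'   genetic correlations then arise from propagation through the DAG, which
#'   keeps the recursive system identifiable).
#' @param n_qtl_per_trait number of sparse QTL per trait (default 0: purely
#'   polygenic).
#' @param qtl_effect per-QTL allele-substitution effect, in structural-trait
#'   SD units (default 0.5).
#' @param u_var length-t variances of the structural-residual traits (before
#'   propagation; default 1). A value of 0 makes that trait a deterministic
#'   function of its parents (useful for noise-free propagation checks).
#' @param seed RNG seed.
#' @return Object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_accessions, m_snps, maf_range = c(0.05, 0.5),
                         trait_names = c("T1", "T2"), lambda_true = NULL,
                         h2_true = rep(0.5, length(trait_names)),
                         sigma_g_corr = NULL, n_qtl_per_trait = 0,
                         qtl_effect = 0.5, u_var = rep(1, length(trait_names)),
                         seed = 1) {
  t <- length(trait_names)
  lambda_true <- lambda_true %||% matrix(0, t, t,
                                         dimnames = list(trait_names,
                                                         trait_names))
  dimnames(lambda_true) <- list(trait_names, trait_names)
  sigma_g_corr <- sigma_g_corr %||% diag(t)
  dimnames(sigma_g_corr) <- list(trait_names, trait_names)
  assert_that(maf_range[1] > 0 && maf_range[2] <= 0.5 &&
                maf_range[1] <= maf_range[2], "maf_range must be in (0, 0.5]")
  assert_that(all(h2_true >= 0 & h2_true <= 1), "h2 must be in [0, 1]")
  assert_that(min(eigen(sigma_g_corr, symmetric = TRUE,
                        only.values = TRUE)$values) > 0,
              "sigma_g_corr must be positive definite")
  adj <- lambda_true != 0
  assert_that(is_acyclic(adj), "lambda_true must describe an acyclic system")
  assert_that(all(u_var >= 0), "u_var must be non-negative")
  structure(list(n_accessions = n_accessions, m_snps = m_snps,
                 maf_range = maf_range, trait_names = trait_names,
                 lambda_true = lambda_true, h2_true = setNames(h2_true,
                                                               trait_names),
                 sigma_g_corr = sigma_g_corr,
                 n_qtl_per_trait = n_qtl_per_trait, qtl_effect = qtl_effect,
                 u_var = setNames(u_var, trait_names),
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' The default four-trait validation scenario
#'
#' A panel shaped like a rice diversity panel: 341 accessions, 10,000 SNPs
#' (MAF uniform on (0.05, 0.5]), four traits PSA, RB, WU, WUE propagated
#' through the DAG PSA -> WU, PSA -> WUE, RB -> WUE with structural
#' coefficients 0.761, 0.963 and 0.045, and structural-residual
#' heritabilities (0.677, 0.733, 0.643, 0.576).
#'
#' @param m_snps number of SNPs (default 10000).
#' @param seed RNG seed (default 341).
#' @param ... overrides passed to [sim_scenario()].
#' @return A `sim_scenario`.
#' @export
rice_like_scenario <- function(m_snps = 10000, seed = 341, ...) {
  traits <- c("PSA", "RB", "WU", "WUE")
  lambda <- matrix(0, 4, 4, dimnames = list(traits, traits))
  lambda["WU", "PSA"] <- 0.761
  lambda["WUE", "PSA"] <- 0.963
  lambda["WUE", "RB"] <- 0.045
  sim_scenario(n_accessions = 341, m_snps = m_snps,
               maf_range = c(0.05, 0.5), trait_names = traits,
               lambda_true = lambda,
               h2_true = c(0.677, 0.733, 0.643, 0.576),
               seed = seed, ...)
}

#' Simulate genotypes
#'
#' Allele frequencies `p_j ~ Uniform(maf_range)`, dosages
#' `Binomial(2, p_j)` independently across SNPs and accessions
#' (Hardy-Weinberg, no linkage disequilibrium). SNPs are laid out on 12
#' chromosomes round-robin with increasing positions.
#'
#' @param scenario a [sim_scenario()].
#' @return A [geno_matrix()]; deterministic given `scenario$seed`.
#' @export
simulate_genotypes <- function(scenario) {
  set.seed(scenario$seed)
  n <- scenario$n_accessions
  m <- scenario$m_snps
  p <- runif(m, scenario$maf_range[1], scenario$maf_range[2])
  d <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  chrom <- rep_len(1:12, m)
  pos <- integer(m)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- seq_along(idx) * 1000L
  }
  geno_matrix(d, sprintf("acc%04d", seq_len(n)),
              snp_info(sprintf("SNP-%d.%d.", chrom, pos), chrom, pos))
}

#' Simulate traits over a genotype panel
#'
#' Structural-residual trait `u_i = g_i + q_i + e_i`: polygenic `g` drawn
#' with covariance `sigma_g_corr (x) G` through the realized GRM, optional
#' QTL contributions `q` from designated SNPs, and Gaussian noise `e` scaled
#' so the realized heritability `var(g + q) / var(u)` matches `h2_true`.
#' Observed traits propagate through the DAG in topological order:
#' `y_i = sum_k lambda[i, k] y_k + u_i`.
#'
#' @param g a [geno_matrix()] from [simulate_genotypes()].
#' @param scenario the matching [sim_scenario()].
#' @return list with `pheno` (data.frame `accession_id` + traits), and
#'   `truth` (QTL ids/effects per trait, `lambda`, the structural residuals
#'   `u`, polygenic values, realized heritabilities).
#' @export
simulate_traits <- function(g, scenario) {
  assert_that(nrow(g$dosages) == scenario$n_accessions,
              "genotype panel does not match scenario dimensions")
  set.seed(scenario$seed + 1L)
  n <- scenario$n_accessions
  traits <- scenario$trait_names
  t_ <- length(traits)
  W <- center_markers(impute_mean(g))
  grm <- compute_grm(W)
  eg <- grm_eigen(grm)
  # polygenic draw: U diag(sqrt(d)) E chol(corr)' has cov corr (x) G
  E <- matrix(rnorm(n * t_), n, t_)
  gen <- eg$U %*% (sqrt(eg$d) * E) %*% chol(scenario$sigma_g_corr)
  colnames(gen) <- traits

  qtl <- setNames(vector("list", t_), traits)
  qcontrib <- matrix(0, n, t_, dimnames = list(NULL, traits))
  if (scenario$n_qtl_per_trait > 0) {
    for (tr in traits) {
      pick <- sample.int(ncol(W), scenario$n_qtl_per_trait)
      eff <- rep(scenario$qtl_effect, length(pick)) *
        sample(c(-1, 1), length(pick), replace = TRUE)
      qcontrib[, tr] <- W[, pick, drop = FALSE] %*% eff
      qtl[[tr]] <- data.frame(snp_id = g$snps$snp_id[pick], effect = eff,
                              stringsAsFactors = FALSE)
    }
  }
  genetic <- gen + qcontrib
  u <- matrix(0, n, t_, dimnames = list(NULL, traits))
  h2 <- scenario$h2_true
  uv <- scenario$u_var %||% rep(1, t_)
  for (k in seq_len(t_)) {
    if (uv[k] == 0) {              # deterministic node: parents only
      genetic[, k] <- 0
      next
    }
    # rescale the genetic part to h2 * u_var, then add noise (1 - h2) * u_var
    vg_raw <- var(genetic[, k])
    if (vg_raw > 0) {
      genetic[, k] <- genetic[, k] * sqrt(h2[k] * uv[k] / vg_raw)
    }
    ve <- (1 - h2[k]) * uv[k]
    u[, k] <- genetic[, k] + rnorm(n, sd = sqrt(ve))
  }
  adj <- t(scenario$lambda_true != 0)   # lambda is [child, parent]; adj is [from, to]
  y <- u
  for (tr in topological_order(adj)) {
    pa <- parents_of(adj, tr)
    if (length(pa)) {
      y[, tr] <- y[, pa, drop = FALSE] %*% scenario$lambda_true[tr, pa] + u[, tr]
    }
  }
  realized_h2 <- vapply(seq_len(t_), function(k) {
    vu <- var(u[, k])
    if (vu > 0) var(genetic[, k]) / vu else NA_real_
  }, 0)
  list(pheno = data.frame(accession_id = g$accession_ids, y,
                          check.names = FALSE, stringsAsFactors = FALSE),
       truth = list(qtl = qtl, lambda = scenario$lambda_true,
                    sigma_g_corr = scenario$sigma_g_corr,
                    u = u, polygenic = gen,
                    realized_h2 = setNames(realized_h2, traits)))
}

#' Write a simulated dataset to disk
#'
#' Writes the PLINK triplet (or dosage TSV), the phenotype TSV and a JSON
#' truth record, the same formats the readers consume.
#'
#' @param g a [geno_matrix()].
#' @param sim result of [simulate_traits()].
#' @param dir output directory.
#' @param format `"plink-bed"` or `"dosage-tsv"`.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(g, sim, dir, format = c("plink-bed", "dosage-tsv")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "plink-bed") {
    write_plink(g, file.path(dir, "genotypes"))
  } else {
    write_dosage_tsv(g, file.path(dir, "genotypes.tsv"))
  }
  data.table::fwrite(sim$pheno, file.path(dir, "phenotypes.tsv"), sep = "\t")
  truth <- sim$truth
  truth$u <- NULL; truth$polygenic <- NULL
  truth$lambda <- as.data.frame(truth$lambda)
  truth$sigma_g_corr <- as.data.frame(truth$sigma_g_corr)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "columns")
  invisible(dir)
}
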