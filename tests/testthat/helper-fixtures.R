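# Shared fixture: a small genotyped panel with correlated multi-trait
# phenotypes and known plug-in covariance components.

make_assoc_fixture <- function(n, m, t, seed, h2 = 0.5, rho_g = 0.4,
                               rho_e = 0.2) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.5)
  d <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  g <- geno_matrix(d, sprintf("a%03d", 1:n),
                   data.frame(snp_id = sprintf("s%03d", 1:m),
                              chromosome = rep_len(as.character(1:2), m),
                              position_bp = seq_len(m) * 50L,
                              ref_allele = "A", alt_allele = "B"))
  grm <- compute_grm(center_markers(g))
  K <- grm$matrix + 1e-6 * diag(n)
  Rg <- matrix(rho_g, t, t); diag(Rg) <- 1
  Re <- matrix(rho_e, t, t); diag(Re) <- 1
  gmat <- crossprod(chol(K), matrix(rnorm(n * t), n, t)) %*% chol(Rg) * sqrt(h2)
  Y <- gmat + matrix(rnorm(n * t), n, t) %*% chol(Re) * sqrt(1 - h2)
  colnames(Y) <- paste0("tr", seq_len(t))
  comp <- cov_components(h2 * Rg, (1 - h2) * Re, colnames(Y))
  list(g = g, grm = grm,
       pheno = data.frame(accession_id = g$accession_ids, Y,
                          stringsAsFactors = FALSE),
       comp = comp, Y = Y)
}
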