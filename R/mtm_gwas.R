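# Multi-trait GWAS.  Each SNP j is tested with the multivariate model
#   y = (I_t (x) w_j) s_j + Zg + e,  Var = Sigma_g (x) G + Sigma_e (x) I,
# phenotypes mean-centered per trait.  With G = U D U', the nt x nt
# covariance is block diagonal in the eigenbasis (V*_i = d_i Sigma_g +
# Sigma_e), so after a one-off O(n^3) setup each SNP costs O(n t^2):
#   A = sum_i w*_i^2 V*_i^{-1},  rhs = sum_i w*_i V*_i^{-1} y*_i,
#   s_hat = A^{-1} rhs,  Cov(s_hat) = A^{-1}.

# Precompute the eigen-space quantities shared by every SNP.
mtm_context <- function(pheno, grm, comp, traits = NULL) {
  traits <- traits %||% comp$trait_names
  ids <- align_ids(grm$accession_ids, pheno$accession_id)
  Y <- as.matrix(pheno[match(ids, pheno$accession_id), traits, drop = FALSE])
  Y <- scale(Y, center = TRUE, scale = FALSE)   # null-mean assumption
  G <- grm$matrix[match(ids, grm$accession_ids),
                  match(ids, grm$accession_ids), drop = FALSE]
  eg <- grm_eigen(list(matrix = G))
  n <- nrow(Y); t <- ncol(Y)
  ystar <- crossprod(eg$U, Y)
  Sg <- comp$sigma_g[traits, traits, drop = FALSE]
  Se <- comp$sigma_e[traits, traits, drop = FALSE]
  vinv <- matrix(0, n, t * t)   # row i = vec of (d_i Sg + Se)^{-1}
  q <- matrix(0, n, t)          # row i = V*_i^{-1} y*_i
  for (i in seq_len(n)) {
    Vi_inv <- solve(eg$d[i] * Sg + Se)
    vinv[i, ] <- as.vector(Vi_inv)
    q[i, ] <- Vi_inv %*% ystar[i, ]
  }
  list(ids = ids, traits = traits, U = eg$U, d = eg$d,
       ystar = ystar, vinv = vinv, q = q, n = n, t = t)
}

solve_snp <- function(ctx, wstar) {
  A <- matrix(colSums(wstar^2 * ctx$vinv), ctx$t, ctx$t)
  rhs <- colSums(wstar * ctx$q)
  Ainv <- solve(A)
  eff <- as.vector(Ainv %*% rhs)
  se <- sqrt(diag(Ainv))
  z <- eff / se
  list(effect = eff, se = se, p = 2 * pnorm(-abs(z)))
}

#' Multivariate GLS effect of a single SNP
#'
#' @param w length-n marker dosage vector aligned to `pheno` rows (raw 0/1/2
#'   or imputed dosages; it is centered internally).
#' @param pheno data.frame with `accession_id` and trait columns.
#' @param grm a `grm` object.
#' @param comp [cov_components()] (or the `components` element of an
#'   `mt_gblup_fit`), the two-stage plug-in covariance estimates.
#' @param traits optional subset/order of traits.
#' @return list with `effects`, `std_errors`, `p_values` (named by trait), or
#'   all-`NA` with a warning for a monomorphic marker.
#' @export
gls_snp_effect <- function(w, pheno, grm, comp, traits = NULL) {
  ctx <- mtm_context(pheno, grm, comp, traits)
  assert_that(length(w) == ctx$n, "marker vector length must match accessions")
  wc <- w - mean(w)
  if (all(abs(wc) < .Machine$double.eps^0.5)) {
    warning("monomorphic marker: effects undefined, returning NA",
            call. = FALSE)
    na <- setNames(rep(NA_real_, ctx$t), ctx$traits)
    return(list(effects = na, std_errors = na, p_values = na))
  }
  res <- solve_snp(ctx, as.vector(crossprod(ctx$U, wc)))
  list(effects = setNames(res$effect, ctx$traits),
       std_errors = setNames(res$se, ctx$traits),
       p_values = setNames(res$p, ctx$traits))
}

#' Genome-wide multi-trait association scan
#'
#' Fits the per-SNP multivariate GLS model for every SNP in the panel
#' (monomorphic SNPs yield `NA` rows with a warning). The whole scan shares
#' one eigendecomposition of the GRM and is vectorised across SNPs.
#'
#' @param g a [geno_matrix()] (imputed; missing dosages are not allowed).
#' @param pheno data.frame with `accession_id` and trait columns.
#' @param grm a `grm` object.
#' @param comp [cov_components()] plug-in estimates.
#' @param traits optional subset/order of traits.
#' @param verbose log progress to stderr.
#' @return data.frame of class `mtm_assoc`: `snp_id`, `chromosome`,
#'   `position_bp`, then `effect_<trait>`, `se_<trait>`, `p_<trait>` per
#'   trait, SNPs in input order.
#' @export
run_mtm_gwas <- function(g, pheno, grm, comp, traits = NULL, verbose = FALSE) {
  assert_that(!anyNA(g$dosages), "missing dosages: run impute_mean() first")
  ctx <- mtm_context(pheno, grm, comp, traits)
  D <- g$dosages[match(ctx$ids, g$accession_ids), , drop = FALSE]
  assert_that(!anyNA(D[, 1]), "genotypes do not cover the phenotyped panel")
  m <- ncol(D)
  Wc <- scale(D, center = TRUE, scale = FALSE)
  mono <- apply(Wc, 2, function(x) all(abs(x) < .Machine$double.eps^0.5))
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) skipped (NA effects)",
            call. = FALSE)
  }
  if (verbose) message("MTM-GWAS: ", m, " SNPs x ", ctx$t, " traits on ",
                       ctx$n, " accessions")
  WS <- crossprod(ctx$U, Wc)              # n x m
  A_all <- crossprod(WS^2, ctx$vinv)      # m x t^2
  rhs_all <- crossprod(WS, ctx$q)         # m x t
  t_ <- ctx$t
  eff <- se <- pv <- matrix(NA_real_, m, t_)
  for (j in seq_len(m)) {
    if (mono[j]) next
    Ainv <- solve(matrix(A_all[j, ], t_, t_))
    eff[j, ] <- Ainv %*% rhs_all[j, ]
    se[j, ] <- sqrt(diag(Ainv))
  }
  pv <- 2 * pnorm(-abs(eff / se))
  out <- data.frame(snp_id = g$snps$snp_id, chromosome = g$snps$chromosome,
                    position_bp = g$snps$position_bp,
                    stringsAsFactors = FALSE)
  for (k in seq_len(t_)) {
    out[[paste0("effect_", ctx$traits[k])]] <- eff[, k]
    out[[paste0("se_", ctx$traits[k])]] <- se[, k]
    out[[paste0("p_", ctx$traits[k])]] <- pv[, k]
  }
  attr(out, "traits") <- ctx$traits
  class(out) <- c("mtm_assoc", "data.frame")
  out
}

#' Top SNPs for one trait by association p-value
#'
#' @param assoc an `mtm_assoc` table from [run_mtm_gwas()].
#' @param trait trait name.
#' @param k number of SNPs to return (default 50).
#' @return The `k` rows of `assoc` with the smallest `p_<trait>`, ties broken
#'   by (chromosome, position_bp); `NA` p-values rank last and are dropped
#'   from the top set whenever enough finite ones exist.
#' @export
rank_top_snps <- function(assoc, trait, k = 50) {
  pcol <- paste0("p_", trait)
  if (!pcol %in% names(assoc)) stop2("unknown trait: ", trait)
  assert_that(k >= 0 && k <= nrow(assoc), "k must be in [0, number of SNPs]")
  if (k == 0) return(assoc[integer(0), , drop = FALSE])
  ord <- order(assoc[[pcol]], assoc$chromosome, assoc$position_bp,
               na.last = TRUE)
  out <- assoc[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}
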