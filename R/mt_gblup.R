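# Bayesian multi-trait GBLUP.  The Gibbs sampler itself lives in
# src/gibbs_mtgblup.cpp; this file handles configuration, input alignment,
# the eigendecomposition of the GRM, posterior summaries and diagnostics.

#' MCMC configuration for [fit_mt_gblup()]
#'
#' Defaults follow common practice for this model class: 25,000 burn-in
#' iterations, 150,000 sampling iterations thinned by 2 (75,000 retained
#' draws). The inverse-Wishart priors on the genetic and residual covariance
#' matrices are weakly informative: `df = t + 2` and scale
#' `0.5 * diag(sample phenotypic variances)` unless overridden.
#'
#' @param n_burnin burn-in iterations (discarded).
#' @param n_iter post-burn-in iterations; `floor(n_iter / thin)` draws are
#'   retained.
#' @param thin thinning interval (>= 1).
#' @param seed integer seed for the sampler.
#' @param iw_df_g,iw_df_e prior degrees of freedom (default `t + 2`, filled in
#'   at fit time when `NULL`).
#' @param iw_scale_g,iw_scale_e t x t prior scale matrices (default
#'   `0.5 * diag(var(y))`, filled in at fit time when `NULL`).
#' @return Object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_burnin = 25000, n_iter = 150000, thin = 2,
                        seed = 1, iw_df_g = NULL, iw_df_e = NULL,
                        iw_scale_g = NULL, iw_scale_e = NULL) {
  assert_that(n_iter > 0, "n_iter must be > 0")
  assert_that(thin >= 1, "thin must be >= 1")
  assert_that(n_burnin >= 0, "n_burnin must be >= 0")
  structure(list(n_burnin = as.integer(n_burnin), n_iter = as.integer(n_iter),
                 thin = as.integer(thin), seed = as.integer(seed),
                 iw_df_g = iw_df_g, iw_df_e = iw_df_e,
                 iw_scale_g = iw_scale_g, iw_scale_e = iw_scale_e),
            class = "mcmc_config")
}

# Eigendecomposition of the GRM with the package-wide jitter rule: when the
# smallest eigenvalue is below 1e-8 * largest (centered-marker G is rank
# deficient by construction), add delta = 1e-6 * mean(diag) to all
# eigenvalues, i.e. to the diagonal of G.
grm_eigen <- function(grm) {
  G <- grm$matrix
  ev <- eigen(G, symmetric = TRUE)
  d <- ev$values
  if (min(d) < 1e-8 * max(d)) {
    d <- d + 1e-6 * mean(diag(G))
  }
  if (min(d) <= 0) stop2("GRM not positive definite even after jitter")
  list(U = ev$vectors, d = d)
}

#' Fit multi-trait GBLUP by Gibbs sampling
#'
#' Model: `y = Xb + Zg + e` with intercept-only fixed effects,
#' `g ~ N(0, Sigma_g (x) G)` and `e ~ N(0, Sigma_e (x) I)`. Flat prior on the
#' intercepts, independent inverse-Wishart priors on `Sigma_g` and `Sigma_e`.
#' Sampling exploits the eigendecomposition of `G`, so one iteration costs
#' `O(n t^3)`.
#'
#' @param pheno data.frame with `accession_id` plus one numeric column per
#'   trait (one record per accession).
#' @param grm a `grm` object from [compute_grm()], covering the phenotyped
#'   accessions (inner join on ids).
#' @param cfg an [mcmc_config()].
#' @param traits optional character vector selecting/ordering trait columns.
#' @return Object of class `mt_gblup_fit`: posterior means `genetic_values`
#'   (n x t), `intercepts`, `components` (list `sigma_g`, `sigma_e`), retained
#'   draws `samples$sigma_g` / `samples$sigma_e` (t x t x n_kept arrays),
#'   posterior SDs, the split-chain potential scale reduction diagnostic
#'   `psrf`, and the aligned inputs.
#' @export
fit_mt_gblup <- function(pheno, grm, cfg = mcmc_config(), traits = NULL) {
  traits <- traits %||% setdiff(names(pheno), "accession_id")
  assert_that(length(traits) >= 1, "need at least one trait column")
  ids <- align_ids(grm$accession_ids, pheno$accession_id)
  Y <- as.matrix(pheno[match(ids, pheno$accession_id), traits, drop = FALSE])
  storage.mode(Y) <- "double"
  assert_that(!anyNA(Y), "phenotypes contain missing values after alignment")
  G <- grm$matrix[match(ids, grm$accession_ids),
                  match(ids, grm$accession_ids), drop = FALSE]
  n <- nrow(Y); t <- ncol(Y)
  assert_that(n > t + 1, "too few accessions for the number of traits")

  df_g <- cfg$iw_df_g %||% (t + 2)
  df_e <- cfg$iw_df_e %||% (t + 2)
  assert_that(df_g > t - 1 && df_e > t - 1, "prior df must exceed t - 1")
  vy <- apply(Y, 2, var)
  S_g <- cfg$iw_scale_g %||% diag(0.5 * vy, t)
  S_e <- cfg$iw_scale_e %||% diag(0.5 * vy, t)
  assert_that(all(dim(S_g) == c(t, t)) && all(dim(S_e) == c(t, t)),
              "prior scale matrices must be t x t")

  eg <- grm_eigen(list(matrix = G))
  ystar <- crossprod(eg$U, Y)
  u1 <- as.vector(crossprod(eg$U, rep(1, n)))

  set.seed(cfg$seed)
  res <- .gibbs_mtgblup(ystar, u1, eg$d, S_g, S_e, df_g, df_e,
                        cfg$n_burnin, cfg$n_iter, cfg$thin)

  gv <- eg$U %*% res$gstar_mean
  dimnames(gv) <- list(ids, traits)
  sg_draws <- res$sigma_g_draws
  se_draws <- res$sigma_e_draws
  dimnames(sg_draws) <- dimnames(se_draws) <- list(traits, traits, NULL)
  sigma_g <- apply(sg_draws, c(1, 2), mean)
  sigma_e <- apply(se_draws, c(1, 2), mean)

  fit <- list(
    genetic_values = gv,
    intercepts = setNames(as.vector(res$b_mean), traits),
    components = structure(list(sigma_g = sigma_g, sigma_e = sigma_e,
                                trait_names = traits),
                           class = "cov_components"),
    samples = list(sigma_g = sg_draws, sigma_e = se_draws),
    posterior_sd = list(sigma_g = apply(sg_draws, c(1, 2), sd),
                        sigma_e = apply(se_draws, c(1, 2), sd)),
    accession_ids = ids, trait_names = traits,
    n_kept = res$n_kept, config = cfg,
    psrf = NULL)
  fit$psrf <- psrf_variances(fit)
  class(fit) <- "mt_gblup_fit"
  if (any(fit$psrf > 1.1, na.rm = TRUE)) {
    warning("split-chain PSRF > 1.1 for some variance components; ",
            "consider a longer chain", call. = FALSE)
  }
  fit
}

#' @export
print.mt_gblup_fit <- function(x, ...) {
  cat(sprintf("mt_gblup_fit: %d accessions, %d trait(s), %d retained draws\n",
              length(x$accession_ids), length(x$trait_names), x$n_kept))
  cat("posterior mean heritabilities:\n")
  print(round(genomic_heritabilities(x)$mean, 3))
  invisible(x)
}

# Split-chain potential scale reduction factor on the variance draws
# (each diagonal element of Sigma_g and Sigma_e), first vs second half.
psrf_variances <- function(fit) {
  one <- function(x) {
    m <- length(x) %/% 2
    if (m < 10) return(NA_real_)
    halves <- list(x[1:m], x[(m + 1):(2 * m)])
    W <- mean(vapply(halves, var, 0))
    B <- m * var(vapply(halves, mean, 0))
    if (W <= 0) return(1)
    sqrt(((m - 1) / m * W + B / m) / W)
  }
  t <- length(fit$trait_names)
  vals <- c(
    vapply(seq_len(t), function(i) one(fit$samples$sigma_g[i, i, ]), 0),
    vapply(seq_len(t), function(i) one(fit$samples$sigma_e[i, i, ]), 0))
  setNames(vals, c(paste0("sigma_g.", fit$trait_names),
                   paste0("sigma_e.", fit$trait_names)))
}

#' Covariance components object
#'
#' @param sigma_g,sigma_e t x t symmetric positive-definite genetic and
#'   residual covariance matrices.
#' @param trait_names optional trait names.
#' @return Object of class `cov_components`.
#' @export
cov_components <- function(sigma_g, sigma_e, trait_names = NULL) {
  sigma_g <- as.matrix(sigma_g); sigma_e <- as.matrix(sigma_e)
  trait_names <- trait_names %||% rownames(sigma_g) %||%
    paste0("trait", seq_len(nrow(sigma_g)))
  dimnames(sigma_g) <- dimnames(sigma_e) <- list(trait_names, trait_names)
  structure(list(sigma_g = sigma_g, sigma_e = sigma_e,
                 trait_names = trait_names), class = "cov_components")
}

corr_from_cov <- function(S) {
  v <- diag(S)
  if (any(v <= 0)) stop2("zero or negative variance on the diagonal")
  S / sqrt(outer(v, v))
}

#' Genomic and residual correlations
#'
#' For a fitted model the correlation of each draw is computed and averaged
#' (posterior mean of correlations, with posterior SDs); for a bare
#' [cov_components()] the single-draw correlations are returned.
#'
#' @param x an `mt_gblup_fit` or `cov_components` object.
#' @return list with `genomic` and `residual` correlation matrices; for fits,
#'   also `genomic_sd` and `residual_sd`.
#' @export
genomic_correlations <- function(x) UseMethod("genomic_correlations")

#' @export
genomic_correlations.cov_components <- function(x) {
  list(genomic = corr_from_cov(x$sigma_g), residual = corr_from_cov(x$sigma_e))
}

#' @export
genomic_correlations.mt_gblup_fit <- function(x) {
  t_ <- length(x$trait_names)
  dn <- list(x$trait_names, x$trait_names)
  per_draw <- function(a) {
    arr <- vapply(seq_len(dim(a)[3]),
                  function(k) corr_from_cov(matrix(a[, , k], t_, t_)),
                  matrix(0, t_, t_))
    arr <- array(arr, c(t_, t_, dim(a)[3]))
    list(mean = structure(apply(arr, c(1, 2), mean), dimnames = dn),
         sd = structure(apply(arr, c(1, 2), sd), dimnames = dn))
  }
  g <- per_draw(x$samples$sigma_g)
  e <- per_draw(x$samples$sigma_e)
  list(genomic = g$mean, residual = e$mean,
       genomic_sd = g$sd, residual_sd = e$sd)
}

#' Genomic heritabilities
#'
#' `h2_i = sigma_g[i, i] / (sigma_g[i, i] + sigma_e[i, i])`, computed per
#' retained draw and averaged for fitted models.
#'
#' @param x an `mt_gblup_fit` or `cov_components` object.
#' @return list with `mean` (named vector) and, for fits, `sd`.
#' @export
genomic_heritabilities <- function(x) UseMethod("genomic_heritabilities")

#' @export
genomic_heritabilities.cov_components <- function(x) {
  vg <- diag(x$sigma_g); ve <- diag(x$sigma_e)
  if (any(vg + ve <= 0)) stop2("zero total variance")
  list(mean = setNames(vg / (vg + ve), x$trait_names))
}

#' @export
genomic_heritabilities.mt_gblup_fit <- function(x) {
  t <- length(x$trait_names)
  draws <- vapply(seq_len(dim(x$samples$sigma_g)[3]), function(k) {
    vg <- diag(matrix(x$samples$sigma_g[, , k], t, t))
    ve <- diag(matrix(x$samples$sigma_e[, , k], t, t))
    vg / (vg + ve)
  }, numeric(t))
  draws <- matrix(draws, nrow = t)
  list(mean = setNames(rowMeans(draws), x$trait_names),
       sd = setNames(apply(draws, 1, sd), x$trait_names))
}

#' Write MT-GBLUP outputs as TSV/JSON artifacts
#'
#' @param fit an `mt_gblup_fit`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly. Writes `genetic_values.tsv`, `components.tsv`
#'   and `gblup_manifest.json`.
#' @export
write_gblup_outputs <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gv <- data.frame(accession_id = fit$accession_ids, fit$genetic_values,
                   check.names = FALSE)
  data.table::fwrite(gv, file.path(dir, "genetic_values.tsv"), sep = "\t")
  comp <- rbind(
    data.frame(component = "sigma_g", trait_row = rep(fit$trait_names,
               times = length(fit$trait_names)),
               trait_col = rep(fit$trait_names, each = length(fit$trait_names)),
               mean = as.vector(fit$components$sigma_g),
               sd = as.vector(fit$posterior_sd$sigma_g)),
    data.frame(component = "sigma_e", trait_row = rep(fit$trait_names,
               times = length(fit$trait_names)),
               trait_col = rep(fit$trait_names, each = length(fit$trait_names)),
               mean = as.vector(fit$components$sigma_e),
               sd = as.vector(fit$posterior_sd$sigma_e)))
  data.table::fwrite(comp, file.path(dir, "components.tsv"), sep = "\t")
  manifest <- list(n_burnin = fit$config$n_burnin, n_iter = fit$config$n_iter,
                   thin = fit$config$thin, seed = fit$config$seed,
                   n_kept = fit$n_kept, psrf = as.list(fit$psrf),
                   heritabilities = as.list(genomic_heritabilities(fit)$mean))
  jsonlite::write_json(manifest, file.path(dir, "gblup_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
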