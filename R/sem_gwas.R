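# SEM-GWAS.  Given a learned trait DAG the phenotypes follow the recursive
# structural system  y = Lambda y + w s + Z g + e  with strictly
# lower-triangular Lambda under a topological trait ordering.  Each equation
# is fitted separately by GLS with its own single-trait mixed-model
# covariance V_i = sigma2_g[i] G + sigma2_e[i] I (plug-in components from
# MT-GBLUP); the diagonal structural-residual assumption that makes the
# recursive system identifiable also makes per-equation GLS the full
# information estimator.  SNP effects from a trait's own equation are the
# *direct* effects; products of structural coefficients along directed paths
# carry *indirect* effects, and the two sum to the total, which equals the
# corresponding row of (I - Lambda)^{-1} applied to the direct-effect vector.

# Per-trait GLS weights in the eigenbasis of G (one-off setup).
sem_context <- function(pheno, grm, comp, traits) {
  ids <- align_ids(grm$accession_ids, pheno$accession_id)
  Y <- as.matrix(pheno[match(ids, pheno$accession_id), traits, drop = FALSE])
  Y <- scale(Y, center = TRUE, scale = FALSE)
  G <- grm$matrix[match(ids, grm$accession_ids),
                  match(ids, grm$accession_ids), drop = FALSE]
  eg <- grm_eigen(list(matrix = G))
  ystar <- crossprod(eg$U, Y)
  wts <- sapply(traits, function(tr) {
    1 / (comp$sigma_g[tr, tr] * eg$d + comp$sigma_e[tr, tr])
  })
  list(ids = ids, traits = traits, U = eg$U, d = eg$d, ystar = ystar,
       wts = wts, n = nrow(Y))
}

# Weighted least squares of y on X with per-row weights w (GLS with known,
# diagonal covariance in the eigenbasis): coef and covariance (X'WX)^{-1}.
wls_fit <- function(X, y, w) {
  XtW <- t(X * w)
  A <- XtW %*% X
  Ainv <- solve(A)
  coef <- as.vector(Ainv %*% (XtW %*% y))
  list(coef = coef, cov = Ainv)
}

#' Estimate structural coefficients from a trait network
#'
#' For each trait with parents in the DAG, fits the mixed-model equation
#' `y_i = sum_k lambda_ik y_k + Z g_i + e_i` by GLS with plug-in single-trait
#' variance components, yielding the structural coefficient matrix `Lambda`
#' (strictly lower triangular under the topological trait ordering) and its
#' standard errors.
#'
#' @param pheno data.frame with `accession_id` and trait columns.
#' @param net a [trait_network()] over (a subset of) the trait columns.
#' @param grm a `grm` object.
#' @param comp [cov_components()] from [fit_mt_gblup()].
#' @return Object of class `structural_coefficients`: `lambda` (t x t, entry
#'   `[child, parent]`), `std_errors`, `ordering` (topological trait order),
#'   `traits`.
#' @export
estimate_lambda <- function(pheno, net, grm, comp) {
  traits <- net$nodes
  missing_traits <- setdiff(traits, names(pheno))
  if (length(missing_traits)) {
    stop2("trait(s) in network but not in phenotypes: ",
          paste(missing_traits, collapse = ", "))
  }
  adj <- arcs_to_adj(net$arcs, traits)
  ord <- topological_order(adj)
  ctx <- sem_context(pheno, grm, comp, traits)
  t_ <- length(traits)
  lambda <- se <- matrix(0, t_, t_, dimnames = list(traits, traits))
  for (tr in traits) {
    pa <- parents_of(adj, tr)
    if (!length(pa)) next
    X <- ctx$ystar[, pa, drop = FALSE]
    fit <- wls_fit(X, ctx$ystar[, tr], ctx$wts[, tr])
    lambda[tr, pa] <- fit$coef
    se[tr, pa] <- sqrt(diag(fit$cov))
  }
  structure(list(lambda = lambda, std_errors = se, ordering = ord,
                 traits = traits, network = net),
            class = "structural_coefficients")
}

#' @export
print.structural_coefficients <- function(x, ...) {
  cat("structural coefficients (lambda[child, parent]):\n")
  nz <- which(x$lambda != 0, arr.ind = TRUE)
  if (!nrow(nz)) {
    cat("  (empty network: all zero)\n")
  } else {
    for (i in seq_len(nrow(nz))) {
      cat(sprintf("  %s -> %s: %.4f (SE %.4f)\n",
                  x$traits[nz[i, 2]], x$traits[nz[i, 1]],
                  x$lambda[nz[i, 1], nz[i, 2]],
                  x$std_errors[nz[i, 1], nz[i, 2]]))
    }
  }
  invisible(x)
}

#' Direct SNP effects under the structural model
#'
#' For each trait, the SNP coefficient from that trait's structural equation,
#' with its parent traits included as covariates (SNP and parents fitted
#' jointly by GLS). For a parentless trait this is the single-trait
#' mixed-model association effect.
#'
#' @param w length-n marker vector aligned to the phenotyped accessions
#'   (centered internally).
#' @inheritParams estimate_lambda
#' @param lambda optional [estimate_lambda()] result (used only for its
#'   trait ordering; coefficients are re-estimated jointly with the SNP).
#' @return list with `effects`, `std_errors`, `p_values` (named by trait).
#' @export
sem_snp_direct_effects <- function(w, pheno, net, grm, comp, lambda = NULL) {
  traits <- net$nodes
  adj <- arcs_to_adj(net$arcs, traits)
  ctx <- sem_context(pheno, grm, comp, traits)
  assert_that(length(w) == ctx$n, "marker vector length must match accessions")
  wc <- w - mean(w)
  if (all(abs(wc) < .Machine$double.eps^0.5)) {
    warning("monomorphic marker: effects undefined, returning NA",
            call. = FALSE)
    na <- setNames(rep(NA_real_, length(traits)), traits)
    return(list(effects = na, std_errors = na, p_values = na))
  }
  wstar <- as.vector(crossprod(ctx$U, wc))
  eff <- sev <- setNames(numeric(length(traits)), traits)
  for (tr in traits) {
    pa <- parents_of(adj, tr)
    X <- cbind(wstar, ctx$ystar[, pa, drop = FALSE])
    fit <- wls_fit(X, ctx$ystar[, tr], ctx$wts[, tr])
    eff[tr] <- fit$coef[1]
    sev[tr] <- sqrt(fit$cov[1, 1])
  }
  list(effects = eff, std_errors = sev,
       p_values = 2 * pnorm(-abs(eff / sev)))
}

#' Enumerate directed paths between two traits
#'
#' All simple directed paths from `source` to `target` in the DAG, in
#' lexicographic order.
#'
#' @param net a [trait_network()].
#' @param source,target trait names.
#' @return list of character vectors (each a trait sequence, source first);
#'   empty list when no path exists.
#' @export
enumerate_paths <- function(net, source, target) {
  assert_that(all(c(source, target) %in% net$nodes),
              paste0("unknown trait: ",
                     paste(setdiff(c(source, target), net$nodes),
                           collapse = ", ")))
  adj <- arcs_to_adj(net$arcs, net$nodes)
  paths_between(adj, source, target)
}

# Path enumeration on a prebuilt adjacency matrix (sorted node names give
# lexicographic order).
paths_between <- function(adj, source, target) {
  paths <- list()
  nodes <- rownames(adj)
  walk <- function(v, trail) {
    if (v == target) {
      paths[[length(paths) + 1]] <<- trail
      return()
    }
    for (w in sort.int(nodes[adj[v, ]])) walk(w, c(trail, w))
  }
  walk(source, source)
  paths
}

#' Decompose SNP effects into direct, per-path indirect, and total
#'
#' The indirect effect along a directed path `(k, ..., i)` is the product of
#' the structural coefficients over consecutive arcs of the path times the
#' direct effect on the path's origin trait `k`; the total effect on trait
#' `i` is its direct effect plus the sum over all incoming paths. The totals
#' equal `(I - Lambda)^{-1} %*% direct` exactly.
#'
#' @param direct named length-t vector of direct effects (one per trait).
#' @param lambda a `structural_coefficients` object (or a bare t x t matrix
#'   with `lambda[child, parent]` entries matching the network arcs).
#' @param net the [trait_network()] the coefficients were estimated on.
#' @return Object of class `effect_decomposition`: per trait, `direct`,
#'   a named list of per-path `indirect` contributions, and `total`.
#' @export
decompose_effects <- function(direct, lambda, net) {
  L <- if (inherits(lambda, "structural_coefficients")) lambda$lambda else
    as.matrix(lambda)
  traits <- net$nodes
  assert_that(all(traits %in% names(direct) | is.null(names(direct))),
              "direct effects must be named by trait (or unnamed, in order)")
  if (is.null(names(direct))) names(direct) <- traits
  direct <- direct[traits]
  assert_that(all(dim(L) == length(traits)), "lambda/network size mismatch")
  if (is.null(rownames(L))) dimnames(L) <- list(traits, traits)
  adj <- arcs_to_adj(net$arcs, traits)
  offarc <- L
  if (nrow(net$arcs)) offarc[cbind(net$arcs$to, net$arcs$from)] <- 0
  assert_that(all(offarc == 0),
              "lambda has nonzero entries off the network arcs")
  out <- lapply(traits, function(tr) {
    paths <- list()
    for (src in setdiff(traits, tr)) {
      paths <- c(paths, paths_between(adj, src, tr))
    }
    ind <- vapply(paths, function(p) {
      coefs <- L[cbind(p[-1], p[-length(p)])]
      prod(coefs) * direct[[p[1]]]
    }, 0)
    names(ind) <- vapply(paths, paste, "", collapse = "->")
    list(direct = direct[[tr]], indirect = as.list(ind),
         total = direct[[tr]] + sum(ind))
  })
  names(out) <- traits
  structure(list(traits = traits, effects = out, lambda = L),
            class = "effect_decomposition")
}

#' @export
print.effect_decomposition <- function(x, ...) {
  for (tr in x$traits) {
    e <- x$effects[[tr]]
    cat(sprintf("%s: direct %.4f, total %.4f\n", tr, e$direct, e$total))
    for (p in names(e$indirect)) {
      cat(sprintf("  indirect via %s: %.4f\n", p, e$indirect[[p]]))
    }
  }
  invisible(x)
}

#' @export
as.data.frame.effect_decomposition <- function(x, ...) {
  rows <- lapply(x$traits, function(tr) {
    e <- x$effects[[tr]]
    ind <- unlist(e$indirect)
    data.frame(trait = tr, direct = e$direct,
               indirect = sum(ind %||% 0), total = e$total,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' SEM-GWAS scan: per-SNP effect decomposition
#'
#' Estimates `Lambda` once (without any SNP), then, for every SNP in
#' `snp_subset`, obtains per-equation direct effects (SNP jointly with parent
#' traits) and decomposes them into per-path indirect and total effects. The
#' scan is vectorised: parent-trait covariates are projected out per equation
#' once and all SNP columns are processed with matrix algebra.
#'
#' @param g a [geno_matrix()] (no missing dosages).
#' @inheritParams estimate_lambda
#' @param snp_subset optional character vector of `snp_id`s (default: all).
#' @param mtm optional `mtm_assoc` table; when supplied, the matching
#'   `effect_<trait>` columns are carried along as `mtm_total_<trait>` for
#'   side-by-side comparison.
#' @return data.frame of class `sem_assoc`: one row per SNP with, per trait,
#'   `direct_<trait>`, `se_direct_<trait>`, one `indirect_<path>` column per
#'   directed path, and `total_<trait>`.
#' @export
run_sem_gwas <- function(g, pheno, net, grm, comp, snp_subset = NULL,
                         mtm = NULL) {
  assert_that(!anyNA(g$dosages), "missing dosages: run impute_mean() first")
  traits <- net$nodes
  adj <- arcs_to_adj(net$arcs, traits)
  lam <- estimate_lambda(pheno, net, grm, comp)
  ctx <- sem_context(pheno, grm, comp, traits)

  keep <- if (is.null(snp_subset)) seq_len(ncol(g$dosages)) else {
    idx <- match(snp_subset, g$snps$snp_id)
    assert_that(!anyNA(idx), "snp_subset contains unknown snp_id(s)")
    idx
  }
  D <- g$dosages[match(ctx$ids, g$accession_ids), keep, drop = FALSE]
  Wc <- scale(D, center = TRUE, scale = FALSE)
  WS <- crossprod(ctx$U, Wc)                 # n x m'
  m <- ncol(WS)

  # per-equation weighted Frisch-Waugh: project parents out of SNP and child
  direct <- se_direct <- matrix(NA_real_, m, length(traits),
                                dimnames = list(NULL, traits))
  for (tr in traits) {
    wts <- ctx$wts[, tr]
    pa <- parents_of(adj, tr)
    y <- ctx$ystar[, tr]
    Wmat <- WS
    if (length(pa)) {
      X <- ctx$ystar[, pa, drop = FALSE]
      XtW <- t(X * wts)
      Ainv <- solve(XtW %*% X)
      y <- y - X %*% (Ainv %*% (XtW %*% y))
      Wmat <- WS - X %*% (Ainv %*% (XtW %*% WS))
    }
    denom <- colSums(Wmat^2 * wts)
    mono <- denom < .Machine$double.eps
    direct[, tr] <- ifelse(mono, NA_real_,
                           colSums(Wmat * wts * as.vector(y)) / denom)
    se_direct[, tr] <- ifelse(mono, NA_real_, sqrt(1 / denom))
  }

  out <- data.frame(snp_id = g$snps$snp_id[keep],
                    chromosome = g$snps$chromosome[keep],
                    position_bp = g$snps$position_bp[keep],
                    stringsAsFactors = FALSE)
  # path bookkeeping (shared across SNPs)
  path_list <- list()
  for (tr in traits) {
    for (src in setdiff(traits, tr)) {
      for (p in enumerate_paths(net, src, tr)) {
        path_list[[paste(p, collapse = "->")]] <- p
      }
    }
  }
  for (tr in traits) {
    out[[paste0("direct_", tr)]] <- direct[, tr]
    out[[paste0("se_direct_", tr)]] <- se_direct[, tr]
  }
  totals <- direct
  for (key in names(path_list)) {
    p <- path_list[[key]]
    coefs <- lam$lambda[cbind(p[-1], p[-length(p)])]
    contrib <- prod(coefs) * direct[, p[1]]
    out[[paste0("indirect_", key)]] <- contrib
    totals[, p[length(p)]] <- totals[, p[length(p)]] + contrib
  }
  for (tr in traits) out[[paste0("total_", tr)]] <- totals[, tr]
  if (!is.null(mtm)) {
    idx <- match(out$snp_id, mtm$snp_id)
    for (tr in intersect(traits, attr(mtm, "traits") %||% traits)) {
      out[[paste0("mtm_total_", tr)]] <- mtm[[paste0("effect_", tr)]][idx]
    }
  }
  attr(out, "lambda") <- lam
  attr(out, "traits") <- traits
  class(out) <- c("sem_assoc", "data.frame")
  out
}
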