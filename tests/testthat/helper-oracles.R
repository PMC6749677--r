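# Independent oracles used across the suite.  These deliberately avoid the
# package's computational shortcuts: dense matrix algebra, brute-force
# enumeration, and a plain-R transcription of the Gibbs full conditionals.

# --- restricted-likelihood grid search for single-trait h2 -------------------
reml_h2_grid <- function(y, G, grid = seq(0.01, 0.99, by = 0.01)) {
  n <- length(y)
  ev <- eigen(G, symmetric = TRUE)
  d <- ev$values
  if (min(d) < 1e-8 * max(d)) d <- d + 1e-6 * mean(diag(G))
  U <- ev$vectors
  ys <- crossprod(U, y)
  u1 <- crossprod(U, rep(1, n))
  ll <- function(h2) {
    gam <- h2 / (1 - h2)
    v <- gam * d + 1
    xtvx <- sum(u1^2 / v)
    bhat <- sum(u1 * ys / v) / xtvx
    r <- ys - u1 * bhat
    s2 <- sum(r^2 / v) / (n - 1)
    -0.5 * ((n - 1) * log(s2) + sum(log(v)) + log(xtvx))
  }
  grid[which.max(vapply(grid, ll, 0))]
}

# --- dense Kronecker-covariance GLS for one SNP ------------------------------
dense_gls_snp <- function(w, Y, G, Sg, Se) {
  n <- nrow(Y); t <- ncol(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  wc <- w - mean(w)
  ev <- eigen(G, symmetric = TRUE)
  d <- ev$values
  if (min(d) < 1e-8 * max(d)) G <- G + 1e-6 * mean(diag(G)) * diag(n)
  V <- kronecker(Sg, G) + kronecker(Se, diag(n))
  X <- kronecker(diag(t), matrix(wc, ncol = 1))
  Vi <- solve(V)
  A <- t(X) %*% Vi %*% X
  Ainv <- solve(A)
  eff <- as.vector(Ainv %*% (t(X) %*% Vi %*% as.vector(Yc)))
  se <- sqrt(diag(Ainv))
  list(effect = eff, se = se, p = 2 * pnorm(-abs(eff / se)))
}

# --- per-equation dense GLS (SEM direct effect) ------------------------------
dense_sem_direct <- function(w, Y, G, sg2, se2, parent_cols) {
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  wc <- w - mean(w)
  V <- sg2 * (G + 1e-6 * mean(diag(G)) * diag(n)) + se2 * diag(n)
  Vi <- solve(V)
  X <- cbind(wc, Yc[, parent_cols, drop = FALSE])
  A <- solve(t(X) %*% Vi %*% X)
  beta <- A %*% (t(X) %*% Vi %*% Yc[, ncol(Yc)])
  list(effect = beta[1], se = sqrt(A[1, 1]))
}

# --- exhaustive DAG enumeration ----------------------------------------------
all_dags <- function(nodes) {
  t <- length(nodes)
  pairs <- t(combn(t, 2))
  # each unordered pair: absent / forward / backward
  states <- expand.grid(rep(list(0:2), nrow(pairs)))
  out <- list()
  for (r in seq_len(nrow(states))) {
    adj <- matrix(FALSE, t, t, dimnames = list(nodes, nodes))
    for (k in seq_len(nrow(pairs))) {
      s <- states[r, k]
      if (s == 1) adj[pairs[k, 1], pairs[k, 2]] <- TRUE
      if (s == 2) adj[pairs[k, 2], pairs[k, 1]] <- TRUE
    }
    # acyclicity by Kahn's algorithm
    indeg <- colSums(adj)
    active <- rep(TRUE, t)
    repeat {
      src <- which(active & indeg == 0)
      if (!length(src)) break
      for (s in src) { indeg <- indeg - adj[s, ]; active[s] <- FALSE }
    }
    if (!any(active)) out[[length(out) + 1]] <- adj
  }
  out
}

exhaustive_best_bic <- function(data) {
  nodes <- colnames(data)
  dags <- all_dags(nodes)
  best <- -Inf
  for (adj in dags) {
    arcs <- which(adj, arr.ind = TRUE)
    dag <- data.frame(from = nodes[arcs[, 1]], to = nodes[arcs[, 2]])
    s <- bic_score(data, dag)
    if (s > best) best <- s
  }
  best
}

# --- naive dense-G multi-trait Gibbs sampler ---------------------------------
dense_gibbs_mtgblup <- function(Y, G, S_g, S_e, df_g, df_e,
                                burnin, iter, thin, seed) {
  set.seed(seed)
  n <- nrow(Y); t <- ncol(Y)
  G <- G + 1e-6 * mean(diag(G)) * diag(n)
  Ginv <- solve(G)
  riw <- function(df, S) {
    L <- chol(solve(S))   # upper
    A <- matrix(0, t, t)
    for (i in 1:t) {
      A[i, i] <- sqrt(rchisq(1, df - i + 1))
      if (i > 1) A[i, 1:(i - 1)] <- rnorm(i - 1)
    }
    W <- t(L) %*% A %*% t(A) %*% L
    solve(W)
  }
  Sg <- S_g / max(df_g - t - 1, 1) + 1e-8 * diag(t)
  Se <- S_e / max(df_e - t - 1, 1) + 1e-8 * diag(t)
  b <- rep(0, t); gmat <- matrix(0, n, t)
  gsum <- matrix(0, n, t); Sgsum <- Sesum <- matrix(0, t, t); kept <- 0
  for (it in 1:(burnin + iter)) {
    Seinv <- solve(Se); Sginv <- solve(Sg)
    b <- colMeans(Y - gmat) + drop(rnorm(t) %*% chol(Se / n))
    P <- kronecker(Sginv, Ginv) + kronecker(Seinv, diag(n))
    rhs <- as.vector((Y - rep(1, n) %o% b) %*% Seinv)
    Pc <- chol(P)
    mu <- backsolve(Pc, forwardsolve(t(Pc), rhs))
    gmat <- matrix(mu + backsolve(Pc, rnorm(n * t)), n, t)
    Sg <- riw(df_g + n, S_g + t(gmat) %*% Ginv %*% gmat)
    E <- Y - rep(1, n) %o% b - gmat
    Se <- riw(df_e + n, S_e + t(E) %*% E)
    if (it > burnin && (it - burnin) %% thin == 0) {
      kept <- kept + 1
      gsum <- gsum + gmat; Sgsum <- Sgsum + Sg; Sesum <- Sesum + Se
    }
  }
  list(g = gsum / kept, sigma_g = Sgsum / kept, sigma_e = Sesum / kept)
}

# --- small structured GRM (families of sibs) for informative fixtures --------
family_grm <- function(n, fam_size = 5, rel = 0.5) {
  fam <- rep(seq_len(ceiling(n / fam_size)), each = fam_size)[seq_len(n)]
  K <- outer(fam, fam, function(a, b) ifelse(a == b, rel, 0))
  diag(K) <- 1
  K
}

# random DAG + random lambda for decomposition checks
random_dag_lambda <- function(t, seed) {
  set.seed(seed)
  nodes <- paste0("t", seq_len(t))
  ord <- sample(nodes)
  adj <- matrix(FALSE, t, t, dimnames = list(nodes, nodes))
  L <- matrix(0, t, t, dimnames = list(nodes, nodes))
  for (i in seq_len(t - 1)) for (j in (i + 1):t) {
    if (runif(1) < 0.5) {
      adj[ord[i], ord[j]] <- TRUE
      L[ord[j], ord[i]] <- runif(1, -1, 1)
    }
  }
  list(net = trait_network(nodes, adj_to_arcs_helper(adj)), lambda = L)
}

adj_to_arcs_helper <- function(adj) {
  idx <- which(adj, arr.ind = TRUE)
  nodes <- rownames(adj)
  data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
             stringsAsFactors = FALSE)
}
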