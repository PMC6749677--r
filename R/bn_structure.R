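# Score-based structure learning for the trait network.  Nodes are traits,
# the data matrix holds posterior-mean genetic values (one row per accession),
# and each node is modelled as a linear-Gaussian regression on its parents.
# Higher BIC is better here: node score = max log-likelihood minus
# (k / 2) log n with k = |parents| + 2 (intercept + residual variance + one
# slope per parent).

node_score <- function(data, node, parents) {
  y <- data[, node]
  n <- length(y)
  if (length(parents)) {
    X <- cbind(1, data[, parents, drop = FALSE])
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
  } else {
    rss <- sum((y - mean(y))^2)
  }
  s2 <- max(rss / n, 1e-300)  # ML variance; floor guards exact-copy parents
  ll <- -(n / 2) * (log(2 * pi * s2) + 1)
  ll - ((length(parents) + 2) / 2) * log(n)
}

#' Gaussian BIC score of a trait DAG
#'
#' Sum over nodes of the maximized linear-Gaussian log-likelihood of each node
#' given its parents (intercept included, maximum-likelihood residual
#' variance) minus the per-node penalty `((|parents| + 2) / 2) * log(n)`.
#' Higher scores indicate better fit.
#'
#' @param data numeric n x t matrix (or data.frame) with one column per trait.
#' @param dag arc list: data.frame with `from` and `to` columns (may have zero
#'   rows), or a `trait_network`.
#' @return Scalar score.
#' @export
bic_score <- function(data, dag) {
  data <- as.matrix(data)
  assert_that(!anyNA(data), "data must be complete")
  nodes <- colnames(data) %||% paste0("trait", seq_len(ncol(data)))
  colnames(data) <- nodes
  arcs <- if (inherits(dag, "trait_network")) dag$arcs else as.data.frame(dag)
  adj <- arcs_to_adj(arcs, nodes)
  if (!is_acyclic(adj)) {
    stop2("dag contains a cycle: ", paste(find_cycle(adj), collapse = " -> "))
  }
  sum(vapply(nodes, function(v) node_score(data, v, parents_of(adj, v)), 0))
}

#' Construct a trait network object
#'
#' @param nodes character vector of trait names.
#' @param arcs data.frame with columns `from`, `to` and optionally `strength`,
#'   `direction`, `delta_bic`.
#' @param score_bic optional network BIC score.
#' @return Object of class `trait_network`.
#' @export
trait_network <- function(nodes, arcs = NULL, score_bic = NA_real_) {
  if (is.null(arcs) || !NROW(arcs)) {
    arcs <- data.frame(from = character(0), to = character(0),
                       strength = numeric(0), direction = numeric(0),
                       delta_bic = numeric(0), stringsAsFactors = FALSE)
  } else {
    arcs <- as.data.frame(arcs, stringsAsFactors = FALSE)
    for (col in c("strength", "direction", "delta_bic")) {
      if (is.null(arcs[[col]])) arcs[[col]] <- NA_real_
    }
    arcs <- arcs[order(arcs$from, arcs$to),
                 c("from", "to", "strength", "direction", "delta_bic")]
    rownames(arcs) <- NULL
  }
  adj <- arcs_to_adj(arcs, nodes)
  if (!is_acyclic(adj)) {
    stop2("arc set contains a cycle: ",
          paste(find_cycle(adj), collapse = " -> "))
  }
  structure(list(nodes = nodes, arcs = arcs, score_bic = score_bic),
            class = "trait_network")
}

#' @export
print.trait_network <- function(x, ...) {
  cat(sprintf("trait_network: %d nodes, %d arcs (BIC %s)\n",
              length(x$nodes), nrow(x$arcs),
              ifelse(is.na(x$score_bic), "not scored",
                     format(x$score_bic, digits = 6))))
  if (nrow(x$arcs)) {
    for (i in seq_len(nrow(x$arcs))) {
      a <- x$arcs[i, ]
      lab <- sprintf("  %s -> %s", a$from, a$to)
      if (!is.na(a$strength)) {
        lab <- sprintf("%s  [strength %.2f (direction %.2f)]",
                       lab, a$strength, a$direction)
      }
      if (!is.na(a$delta_bic)) lab <- sprintf("%s  dBIC %.3f", lab, a$delta_bic)
      cat(lab, "\n")
    }
  }
  invisible(x)
}

# Candidate moves, in the deterministic evaluation order used for
# tie-breaking: move type (add < delete < reverse), then (from, to).
legal_moves <- function(adj) {
  nodes <- rownames(adj)
  out <- list()
  for (from in nodes) for (to in nodes) {
    if (from == to) next
    if (!adj[from, to]) {
      if (!adj[to, from] && !creates_cycle(adj, from, to)) {
        out[[length(out) + 1]] <- list(type = "add", from = from, to = to)
      }
    } else {
      out[[length(out) + 1]] <- list(type = "delete", from = from, to = to)
      adj2 <- adj; adj2[from, to] <- FALSE
      if (!creates_cycle(adj2, to, from)) {
        out[[length(out) + 1]] <- list(type = "reverse", from = from, to = to)
      }
    }
  }
  ord <- order(vapply(out, function(m) match(m$type, c("add", "delete",
                                                       "reverse")), 0),
               vapply(out, `[[`, "", "from"), vapply(out, `[[`, "", "to"))
  out[ord]
}

#' Learn a trait DAG by greedy hill climbing
#'
#' Starts from the empty graph and repeatedly applies the single-arc
#' addition, deletion or reversal with the largest positive BIC gain until no
#' move improves the score. Deterministic: ties are broken by move type and
#' lexicographic (from, to). An optional Gaussian mutual-information
#' independence filter (`alpha`) can veto additions between marginally
#' independent pairs.
#'
#' @param data numeric n x t matrix of trait values (genetic values in the
#'   standard workflow).
#' @param seed unused unless `restarts > 0` (kept for interface stability).
#' @param max_iter maximum number of accepted moves.
#' @param restarts number of random-restart repetitions (0 = plain
#'   deterministic search); the best-scoring network is returned.
#' @param mi_alpha when non-`NULL`, significance level for the marginal
#'   Gaussian mutual-information test; arc additions between pairs that do
#'   not reject independence at `mi_alpha` are skipped.
#' @return A [trait_network()] with `score_bic` set.
#' @export
hill_climb <- function(data, seed = NULL, max_iter = 100, restarts = 0,
                       mi_alpha = NULL) {
  data <- as.matrix(data)
  nodes <- colnames(data) %||% paste0("trait", seq_len(ncol(data)))
  colnames(data) <- nodes
  n <- nrow(data); t <- ncol(data)
  assert_that(n > t + 2, "need n > t + 2 rows to score networks")

  mi_ok <- NULL
  if (!is.null(mi_alpha)) {
    r2 <- cor(data)^2
    stat <- -n * log(pmax(1 - r2, 1e-300))   # 2n * Gaussian MI ~ chisq(1)
    mi_ok <- stat > stats::qchisq(1 - mi_alpha, df = 1)
  }

  run_once <- function(adj) {
    scores <- vapply(nodes, function(v) node_score(data, v, parents_of(adj, v)), 0)
    for (iter in seq_len(max_iter)) {
      best_gain <- 1e-10  # strictly positive improvement required
      best <- NULL
      for (mv in legal_moves(adj)) {
        if (mv$type == "add" && !is.null(mi_ok) &&
            !mi_ok[mv$from, mv$to]) next
        gain <- move_gain(data, adj, scores, mv)
        if (gain > best_gain + 1e-12) {
          best_gain <- gain
          best <- mv
        }
      }
      if (is.null(best)) break
      upd <- apply_move(adj, best)
      adj <- upd
      for (v in affected_nodes(best)) {
        scores[v] <- node_score(data, v, parents_of(adj, v))
      }
    }
    list(adj = adj, score = sum(scores))
  }

  empty <- matrix(FALSE, t, t, dimnames = list(nodes, nodes))
  best <- run_once(empty)
  if (restarts > 0) {
    if (!is.null(seed)) set.seed(seed)
    for (r in seq_len(restarts)) {
      adj0 <- empty
      # random starting DAG: random order + random arcs
      ord <- sample(nodes)
      for (i in seq_len(t - 1)) for (j in (i + 1):t) {
        if (runif(1) < 0.3) adj0[ord[i], ord[j]] <- TRUE
      }
      cand <- run_once(adj0)
      if (cand$score > best$score) best <- cand
    }
  }
  net <- trait_network(nodes, adj_to_arcs(best$adj), score_bic = best$score)
  net
}

affected_nodes <- function(mv) {
  if (mv$type == "reverse") c(mv$from, mv$to) else mv$to
}

move_gain <- function(data, adj, scores, mv) {
  adj2 <- apply_move(adj, mv)
  sum(vapply(affected_nodes(mv),
             function(v) node_score(data, v, parents_of(adj2, v)) - scores[v],
             0))
}

apply_move <- function(adj, mv) {
  switch(mv$type,
         add = { adj[mv$from, mv$to] <- TRUE; adj },
         delete = { adj[mv$from, mv$to] <- FALSE; adj },
         reverse = { adj[mv$from, mv$to] <- FALSE
                     adj[mv$to, mv$from] <- TRUE; adj })
}

#' Bootstrap arc strength and direction
#'
#' Resamples rows with replacement, learns a network per replicate with
#' [hill_climb()], and summarises, for every ordered trait pair, the fraction
#' of replicates in which the pair is connected in either direction
#' (`strength`) and, conditional on presence, the fraction oriented
#' `from -> to` (`direction`).
#'
#' @inheritParams hill_climb
#' @param n_boot number of bootstrap replicates (default 2500).
#' @param seed RNG seed; resampling is deterministic given the seed.
#' @param ... passed on to [hill_climb()].
#' @return data.frame `from`, `to`, `strength`, `direction`, of class
#'   `arc_strengths`.
#' @export
bootstrap_strength <- function(data, n_boot = 2500, seed = 1, ...) {
  data <- as.matrix(data)
  nodes <- colnames(data) %||% paste0("trait", seq_len(ncol(data)))
  colnames(data) <- nodes
  assert_that(n_boot >= 1, "n_boot must be >= 1")
  t <- length(nodes)
  present <- matrix(0, t, t, dimnames = list(nodes, nodes))  # oriented counts
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(data), replace = TRUE)
    net <- hill_climb(data[idx, , drop = FALSE], ...)
    if (nrow(net$arcs)) {
      present[cbind(net$arcs$from, net$arcs$to)] <-
        present[cbind(net$arcs$from, net$arcs$to)] + 1
    }
  }
  either <- present + t(present)
  pairs <- which(upper.tri(either) | lower.tri(either), arr.ind = TRUE)
  out <- data.frame(
    from = nodes[pairs[, 1]], to = nodes[pairs[, 2]],
    strength = either[pairs] / n_boot,
    direction = ifelse(either[pairs] > 0, present[pairs] / either[pairs], 0),
    stringsAsFactors = FALSE)
  out <- out[order(out$from, out$to), ]
  rownames(out) <- NULL
  class(out) <- c("arc_strengths", "data.frame")
  out
}

#' Model-averaged network from bootstrap strengths
#'
#' Keeps trait pairs whose bootstrap strength meets `threshold` and orients
#' each retained arc by its majority direction (> 0.5; exact ties resolved
#' lexicographically). Errors if the resulting orientation is cyclic.
#'
#' @param strengths output of [bootstrap_strength()].
#' @param threshold minimum strength for an arc to be retained (default 0.85).
#' @return A [trait_network()] carrying the strengths/directions of retained
#'   arcs.
#' @export
averaged_network <- function(strengths, threshold = 0.85) {
  nodes <- sort(unique(c(strengths$from, strengths$to)))
  keep <- strengths[strengths$strength >= threshold &
                      strengths$from < strengths$to, , drop = FALSE]
  if (nrow(keep)) {
    flip <- keep$direction < 0.5
    tmp <- keep$from[flip]
    keep$from[flip] <- keep$to[flip]
    keep$to[flip] <- tmp
    keep$direction[flip] <- 1 - keep$direction[flip]
  }
  trait_network(nodes, keep)
}

#' Per-arc BIC change on removal
#'
#' For each arc of the network, the change in the network BIC score when that
#' arc alone is removed: `delta = score(without arc) - score(with arc)`.
#' Negative values mean the arc improves the fit (its removal costs score);
#' the most negative delta marks the most important arc.
#'
#' @param data the trait-value matrix the network was learned from.
#' @param net a [trait_network()].
#' @return The network with `arcs$delta_bic` filled in.
#' @export
arc_strength_delta_bic <- function(data, net) {
  data <- as.matrix(data)
  assert_that(inherits(net, "trait_network"), "net must be a trait_network")
  full <- bic_score(data, net$arcs[, c("from", "to")])
  deltas <- vapply(seq_len(nrow(net$arcs)), function(i) {
    bic_score(data, net$arcs[-i, c("from", "to")]) - full
  }, 0)
  net$arcs$delta_bic <- deltas
  net$score_bic <- full
  net
}

#' Export a trait network
#'
#' @param net a [trait_network()].
#' @param tsv_path optional path for an arcs TSV
#'   (from, to, strength, direction, delta_bic).
#' @param dot_path optional path for Graphviz DOT text.
#' @return `net`, invisibly.
#' @export
write_network <- function(net, tsv_path = NULL, dot_path = NULL) {
  if (!is.null(tsv_path)) {
    data.table::fwrite(net$arcs, tsv_path, sep = "\t")
  }
  if (!is.null(dot_path)) {
    lines <- c("digraph trait_network {",
               paste0("  \"", net$nodes, "\";"),
               if (nrow(net$arcs)) {
                 sprintf("  \"%s\" -> \"%s\"%s;", net$arcs$from, net$arcs$to,
                         ifelse(is.na(net$arcs$strength), "",
                                sprintf(" [label=\"%.2f (%.2f)\"]",
                                        net$arcs$strength, net$arcs$direction)))
               },
               "}")
    writeLines(lines, dot_path)
  }
  invisible(net)
}
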