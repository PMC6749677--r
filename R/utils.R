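# Internal helpers: small DAG utilities shared by the structure-learning and
# SEM modules, plus argument checking.  Trait networks here are tiny (a handful
# of nodes), so adjacency is kept as a logical matrix indexed by trait name.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop2(msg)
  invisible(TRUE)
}

#' @keywords internal
#' @noRd
arcs_to_adj <- function(arcs, nodes) {
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  if (NROW(arcs)) {
    bad <- !(arcs$from %in% nodes) | !(arcs$to %in% nodes)
    if (any(bad)) {
      stop2("arc references unknown trait: ",
            paste(unique(c(arcs$from[bad], arcs$to[bad])), collapse = ", "))
    }
    adj[cbind(arcs$from, arcs$to)] <- TRUE
  }
  adj
}

adj_to_arcs <- function(adj) {
  idx <- which(adj, arr.ind = TRUE)
  nodes <- rownames(adj)
  df <- data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                   stringsAsFactors = FALSE)
  df[order(df$from, df$to), , drop = FALSE]
}

# TRUE when adding from -> to to `adj` would close a directed cycle, i.e. a
# directed path to -> ... -> from already exists.
creates_cycle <- function(adj, from, to) {
  if (from == to) return(TRUE)
  seen <- to
  frontier <- to
  while (length(frontier)) {
    nxt <- rownames(adj)[colSums(adj[frontier, , drop = FALSE]) > 0]
    nxt <- setdiff(nxt, seen)
    if (from %in% nxt) return(TRUE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  FALSE
}

is_acyclic <- function(adj) {
  # Kahn's algorithm; returns TRUE for a DAG.
  indeg <- colSums(adj)
  active <- rep(TRUE, ncol(adj))
  repeat {
    src <- which(active & indeg == 0)
    if (!length(src)) break
    for (s in src) {
      indeg <- indeg - adj[s, ]
      active[s] <- FALSE
    }
  }
  !any(active)
}

find_cycle <- function(adj) {
  # Returns one directed cycle (vector of node names) for error messages.
  nodes <- rownames(adj)
  state <- setNames(integer(length(nodes)), nodes)  # 0 new, 1 open, 2 done
  path <- character(0)
  cyc <- NULL
  visit <- function(v) {
    if (!is.null(cyc)) return()
    if (state[v] == 1L) {
      i <- match(v, path)
      cyc <<- c(path[i:length(path)], v)
      return()
    }
    if (state[v] == 2L) return()
    state[v] <<- 1L
    path <<- c(path, v)
    for (w in nodes[adj[v, ]]) visit(w)
    path <<- path[-length(path)]
    state[v] <<- 2L
  }
  for (v in nodes) visit(v)
  cyc
}

# Topological order with lexicographic tie-breaking, so the Lambda matrix
# layout is reproducible across platforms.
topological_order <- function(adj) {
  nodes <- sort(rownames(adj))
  adj <- adj[nodes, nodes, drop = FALSE]
  if (!is_acyclic(adj)) {
    stop2("trait network contains a cycle: ",
          paste(find_cycle(adj), collapse = " -> "))
  }
  ord <- character(0)
  indeg <- colSums(adj)
  active <- setNames(rep(TRUE, length(nodes)), nodes)
  while (any(active)) {
    v <- names(which(active & indeg == 0))[1L]  # nodes sorted => lexicographic
    ord <- c(ord, v)
    indeg <- indeg - adj[v, ]
    active[v] <- FALSE
  }
  ord
}

parents_of <- function(adj, node) sort(rownames(adj)[adj[, node]])

children_of <- function(adj, node) sort(rownames(adj)[adj[node, ]])
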