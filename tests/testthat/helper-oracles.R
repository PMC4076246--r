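# Independent oracles used to cross-check the package implementations.
# These are deliberately naive (path enumeration, stratified hand
# arithmetic) and share no code with the package internals.

# Brute-force d-separation: enumerate every simple undirected path between
# x and y and apply the blocking rules edge by edge.
bf_d_separated <- function(dag, x, y, z = character(0)) {
  edges <- dag$edges
  nbrs <- function(v) unique(c(edges[edges[, 1] == v, 2],
                               edges[edges[, 2] == v, 1]))
  desc <- function(v) {
    seen <- character(0); frontier <- v
    while (length(frontier)) {
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(edges[edges[, 1] %in% frontier, 2]), seen)
    }
    seen
  }
  paths <- list()
  extend <- function(path) {
    tip <- path[length(path)]
    if (tip == y) {
      paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (v in setdiff(nbrs(tip), path)) extend(c(path, v))
  }
  extend(x)
  is_collider <- function(a, v, b) {
    any(edges[, 1] == a & edges[, 2] == v) &&
      any(edges[, 1] == b & edges[, 2] == v)
  }
  blocked <- function(path) {
    if (length(path) < 3) return(FALSE)  # direct edge: never blocked
    for (i in 2:(length(path) - 1)) {
      v <- path[i]
      if (is_collider(path[i - 1], v, path[i + 1])) {
        if (!any(desc(v) %in% z)) return(TRUE)
      } else {
        if (v %in% z) return(TRUE)
      }
    }
    FALSE
  }
  all(vapply(paths, blocked, logical(1))) || length(paths) == 0
}

# All DAG structures on k labelled nodes with a fixed topological order
# (upper-triangular adjacency). d-separation is invariant to node
# relabelling, so sweeping these covers every DAG structure on k nodes.
all_topo_dags <- function(k) {
  pairs <- t(utils::combn(k, 2))
  n_pairs <- nrow(pairs)
  lapply(seq_len(2^n_pairs) - 1L, function(code) {
    present <- bitwAnd(bitwShiftR(code, seq_len(n_pairs) - 1L), 1L) == 1L
    m <- pairs[present, , drop = FALSE]
    em <- matrix(paste0("n", as.vector(m)), nrow = nrow(m), ncol = 2)
    causal_dag(em, nodes = paste0("n", seq_len(k)))
  })
}

# Nonparametric standardization over the strata of a single discrete
# confounder column: sum_w P(W = w) * (P(Y|A=1,w) - P(Y|A=0,w)).
np_standardization <- function(table, wcol) {
  vals <- sort(unique(table[[wcol]]))
  psi <- 0
  for (w in vals) {
    rows <- table[[wcol]] == w
    p1 <- mean(table$Y[rows & table$A == 1])
    p0 <- mean(table$Y[rows & table$A == 0])
    psi <- psi + mean(rows) * (p1 - p0)
  }
  psi
}
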