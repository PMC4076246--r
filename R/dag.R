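#' Causal directed acyclic graphs
#'
#' A lightweight DAG representation for causal identification: nodes are
#' character names and edges are ordered (cause, effect) pairs. Used for
#' d-separation queries, backdoor-criterion checks, and enumeration of
#' minimal sufficient adjustment sets.
#'
#' @param edges Either a character vector of `"cause -> effect"` strings,
#'   a two-column matrix/data frame of (cause, effect), or `NULL` for an
#'   edgeless graph.
#' @param nodes Optional character vector of node names; nodes appearing
#'   in `edges` are added automatically, so this is only needed for
#'   isolated nodes.
#' @return An object of class `causal_dag` with elements `nodes`
#'   (character) and `edges` (two-column character matrix). Self-loops and
#'   edges with unknown endpoints are rejected; cyclic edge sets are
#'   representable (so they can be interrogated with [is_acyclic()]) but
#'   are rejected by every separation and adjustment operation.
#' @examples
#' g <- causal_dag(c("W -> X", "W -> Y", "X -> Y"))
#' is_acyclic(g)
#' d_separated(g, "X", "Y", "W")  # FALSE: the direct edge remains
#' @export
causal_dag <- function(edges = NULL, nodes = NULL) {
  if (is.character(edges) && !is.matrix(edges)) {
    edges <- parse_edge_strings(edges)
    nodes <- c(nodes, attr(edges, "isolated"))
  } else if (is.data.frame(edges)) {
    edges <- as.matrix(edges)
  } else if (is.null(edges)) {
    edges <- matrix(character(0), ncol = 2)
  }
  storage.mode(edges) <- "character"
  if (ncol(edges) != 2) stop("`edges` must have two columns", call. = FALSE)
  colnames(edges) <- c("from", "to")
  nodes <- sort(unique(c(nodes, as.vector(edges))))
  if (any(edges[, 1] == edges[, 2])) {
    stop("self-loops are not allowed in a causal DAG", call. = FALSE)
  }
  if (anyDuplicated(paste(edges[, 1], edges[, 2]))) {
    edges <- unique(edges)
  }
  structure(list(nodes = nodes, edges = edges), class = "causal_dag")
}

parse_edge_strings <- function(x) {
  x <- trimws(sub("#.*$", "", x))
  x <- x[nzchar(x)]
  has_edge <- grepl("->", x, fixed = TRUE)
  parts <- strsplit(x[has_edge], "->", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) {
    stop("malformed edge line(s): ", paste(x[has_edge][bad], collapse = "; "),
         call. = FALSE)
  }
  m <- matrix(trimws(unlist(parts)), ncol = 2, byrow = TRUE)
  attr(m, "isolated") <- trimws(x[!has_edge])
  m
}

#' @export
print.causal_dag <- function(x, ...) {
  cat("Causal DAG:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$edges)) {
    cat(paste(" ", x$edges[, 1], "->", x$edges[, 2]), sep = "\n")
  }
  iso <- setdiff(x$nodes, as.vector(x$edges))
  if (length(iso)) cat("  isolated:", paste(iso, collapse = ", "), "\n")
  invisible(x)
}

check_nodes <- function(dag, ...) {
  asked <- unlist(list(...), use.names = FALSE)
  unknown <- setdiff(asked, dag$nodes)
  if (length(unknown)) {
    stop("unknown node(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

parents_of <- function(dag, v) dag$edges[dag$edges[, 2] == v, 1]
children_of <- function(dag, v) dag$edges[dag$edges[, 1] == v, 2]

# Reflexive-transitive closure along edge direction.
reachable_from <- function(dag, start, direction = c("down", "up")) {
  direction <- match.arg(direction)
  step <- if (direction == "down") children_of else parents_of
  seen <- character(0)
  frontier <- start
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(lapply(frontier, step, dag = dag))),
                        seen)
  }
  seen
}

#' Test whether a directed graph is acyclic
#'
#' Kahn-style topological elimination; every [causal_dag()] operation that
#' performs separation or adjustment requires acyclicity.
#'
#' @param dag A `causal_dag`.
#' @return `TRUE` iff the graph has no directed cycle.
#' @export
is_acyclic <- function(dag) {
  stopifnot(inherits(dag, "causal_dag"))
  edges <- dag$edges
  nodes <- dag$nodes
  repeat {
    sinks <- setdiff(nodes, edges[, 1])
    if (!length(sinks)) break
    nodes <- setdiff(nodes, sinks)
    edges <- edges[!(edges[, 2] %in% sinks), , drop = FALSE]
  }
  length(nodes) == 0
}

require_acyclic <- function(dag) {
  if (!is_acyclic(dag)) {
    stop("graph contains a directed cycle; not a DAG", call. = FALSE)
  }
  invisible(TRUE)
}

#' d-separation
#'
#' Decides whether `x` and `y` are d-separated given the conditioning set
#' `z`: every path between them is blocked, where a chain or fork node
#' blocks when conditioned on, and a collider (a node where two arrows
#' collide) blocks unless it or one of its descendants is conditioned on.
#' Implemented by reachability over (node, travel-direction) states, which
#' is linear in the graph size.
#'
#' @param dag An acyclic `causal_dag`.
#' @param x,y Node names; must not lie in `z`.
#' @param z Character vector of conditioning nodes (possibly empty).
#' @return `TRUE` iff `x` and `y` are d-separated given `z`.
#' @export
d_separated <- function(dag, x, y, z = character(0)) {
  stopifnot(inherits(dag, "causal_dag"))
  require_acyclic(dag)
  z <- as.character(z)
  check_nodes(dag, x, y, z)
  if (x %in% z || y %in% z) {
    stop("`x` and `y` must not be members of the conditioning set",
         call. = FALSE)
  }
  if (x == y) return(FALSE)
  anc_z <- reachable_from(dag, z, "up")  # z and its ancestors
  # States: (node, how it was entered). "up" = entered from one of its
  # children (travelling against an edge), "down" = entered from a parent.
  seen <- new.env(parent = emptyenv())
  frontier <- list(c(x, "up"))
  while (length(frontier)) {
    st <- frontier[[1]]
    frontier <- frontier[-1]
    key <- paste(st[1], st[2])
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    v <- st[1]; dir <- st[2]
    if (v == y) return(FALSE)
    if (dir == "up" && !(v %in% z)) {
      for (p in parents_of(dag, v)) frontier <- c(frontier, list(c(p, "up")))
      for (ch in children_of(dag, v)) {
        frontier <- c(frontier, list(c(ch, "down")))
      }
    } else if (dir == "down") {
      if (!(v %in% z)) {
        for (ch in children_of(dag, v)) {
          frontier <- c(frontier, list(c(ch, "down")))
        }
      }
      if (v %in% anc_z) {
        # v is a conditioned collider, or has a conditioned descendant:
        # the path may bounce back towards its parents.
        for (p in parents_of(dag, v)) frontier <- c(frontier, list(c(p, "up")))
      }
    }
  }
  TRUE
}

#' Backdoor admissibility of an adjustment set
#'
#' A candidate set satisfies the backdoor criterion for the effect of
#' `exposure` on `outcome` when it contains no descendant of the exposure
#' and, conditioning on it, every backdoor path (a path whose first edge
#' points into the exposure) is blocked. Checked by removing the edges
#' out of the exposure and testing d-separation in the reduced graph.
#'
#' @param dag An acyclic `causal_dag`.
#' @param exposure,outcome Node names (distinct).
#' @param adjust_set Character vector of candidate adjustment nodes; must
#'   exclude exposure and outcome.
#' @return `TRUE` iff the set is backdoor-admissible.
#' @export
backdoor_admissible <- function(dag, exposure, outcome,
                                adjust_set = character(0)) {
  stopifnot(inherits(dag, "causal_dag"))
  require_acyclic(dag)
  adjust_set <- as.character(adjust_set)
  check_nodes(dag, exposure, outcome, adjust_set)
  if (exposure == outcome) stop("exposure and outcome must differ",
                                call. = FALSE)
  if (exposure %in% adjust_set || outcome %in% adjust_set) {
    stop("the adjustment set must exclude exposure and outcome",
         call. = FALSE)
  }
  desc <- setdiff(reachable_from(dag, exposure, "down"), exposure)
  if (length(intersect(adjust_set, desc))) return(FALSE)
  keep <- dag$edges[, 1] != exposure
  reduced <- causal_dag(dag$edges[keep, , drop = FALSE], nodes = dag$nodes)
  d_separated(reduced, exposure, outcome, adjust_set)
}

#' Minimal sufficient adjustment sets
#'
#' Enumerates all inclusion-minimal backdoor-admissible sets for the
#' effect of `exposure` on `outcome`, by exhaustive search over subsets of
#' the non-descendants of the exposure (smallest sets first, ties broken
#' lexicographically).
#'
#' @inheritParams backdoor_admissible
#' @return A list of character vectors (possibly containing the empty
#'   set), ordered by size then lexicographically. Empty when no
#'   admissible set exists.
#' @export
minimal_adjustment_sets <- function(dag, exposure, outcome) {
  stopifnot(inherits(dag, "causal_dag"))
  require_acyclic(dag)
  check_nodes(dag, exposure, outcome)
  candidates <- setdiff(dag$nodes,
                        c(outcome, reachable_from(dag, exposure, "down")))
  candidates <- sort(candidates)
  found <- list()
  for (size in 0:length(candidates)) {
    subsets <- if (size == 0) list(character(0)) else
      utils::combn(candidates, size, simplify = FALSE)
    for (s in subsets) {
      if (any(vapply(found, function(f) all(f %in% s), logical(1)))) next
      if (backdoor_admissible(dag, exposure, outcome, s)) {
        found <- c(found, list(s))
      }
    }
  }
  found
}

#' Read or write a DAG as edge-list text
#'
#' One `cause -> effect` pair per line; `#` starts a comment; a line with
#' a bare name declares an isolated node.
#'
#' @param path File path.
#' @param dag A `causal_dag`.
#' @return `read_dag` returns a `causal_dag`; `write_dag` returns `path`
#'   invisibly.
#' @export
read_dag <- function(path) {
  lines <- readLines(path, warn = FALSE)
  m <- parse_edge_strings(lines)
  causal_dag(m, nodes = attr(m, "isolated"))
}

#' @rdname read_dag
#' @export
write_dag <- function(dag, path) {
  stopifnot(inherits(dag, "causal_dag"))
  lines <- paste(dag$edges[, 1], "->", dag$edges[, 2])
  iso <- setdiff(dag$nodes, as.vector(dag$edges))
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Worked-example DAG fixtures
#'
#' Three small graphs used throughout the documentation and tests to
#' exercise the backdoor criterion. Panel A is classic confounding
#' (`W -> X`, `W -> Y`, `X -> Y`, plus independent exogenous causes
#' `U_X`, `U_Y`, `U_W`): the sufficient adjustment set is `{W}`. Panel B
#' is a collider (`X -> W <- Y` plus `X -> Y`): the empty set suffices,
#' and conditioning on `W` opens the path. Panel C combines an open
#' backdoor through `W3` with a collider at `W3` on a `W1`/`W2` path, so
#' adjusting for `W3` alone introduces a new bias; the minimal sufficient
#' sets are `{W1, W3}` and `{W2, W3}`.
#'
#' @param panel `"A"`, `"B"`, or `"C"`.
#' @return A `causal_dag`.
#' @export
dag_panel <- function(panel = c("A", "B", "C")) {
  panel <- match.arg(panel)
  switch(panel,
    A = causal_dag(c("W -> X", "W -> Y", "X -> Y",
                     "U_X -> X", "U_Y -> Y", "U_W -> W")),
    B = causal_dag(c("X -> W", "Y -> W", "X -> Y",
                     "U_X -> X", "U_Y -> Y", "U_W -> W")),
    C = causal_dag(c("W1 -> X", "W3 -> X", "X -> Y", "W3 -> Y", "W2 -> Y",
                     "W1 -> W3", "W2 -> W3"))
  )
}
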