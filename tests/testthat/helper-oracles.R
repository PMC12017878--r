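# Independent oracles used by the unit and property tests.

# Path-based d-separation: enumerate every simple path between x and y in the
# DAG and check blocking node-by-node (non-collider in z blocks; collider
# blocks unless it or a descendant is in z). Independent of the package's
# moralized-ancestral-graph implementation.
oracle_d_separated <- function(dag, x, y, z = character(0)) {
  nodes <- dag$nodes
  adj <- dag$adj
  desc_or_self <- function(v) c(v, descendants(dag, v))
  blocked <- function(path) {
    if (length(path) <= 2) return(FALSE)
    for (i in 2:(length(path) - 1)) {
      a <- path[i - 1]; b <- path[i]; c <- path[i + 1]
      is_collider <- adj[a, b] && adj[c, b]
      if (is_collider) {
        if (!any(desc_or_self(b) %in% z)) return(TRUE)
      } else {
        if (b %in% z) return(TRUE)
      }
    }
    FALSE
  }
  found_open <- FALSE
  walk <- function(path) {
    if (found_open) return()
    last <- path[length(path)]
    if (last == y) {
      if (!blocked(path)) found_open <<- TRUE
      return()
    }
    nbrs <- nodes[adj[last, ] | adj[, last]]
    for (nb in setdiff(nbrs, path)) walk(c(path, nb))
  }
  walk(x)
  !found_open
}

# Exhaustive backdoor-set oracle built on the path oracle.
oracle_backdoor_sets <- function(dag, exposure, outcome) {
  g2 <- dag
  g2$adj[exposure, ] <- FALSE
  candidates <- setdiff(dag$nodes,
                        c(exposure, outcome, descendants(dag, exposure)))
  valid <- list()
  for (k in 0:length(candidates)) {
    subsets <- if (k == 0) list(character(0)) else
      utils::combn(candidates, k, simplify = FALSE)
    for (z in subsets) {
      if (oracle_d_separated(g2, exposure, outcome, z)) {
        valid[[length(valid) + 1]] <- sort(z)
      }
    }
  }
  minimal <- Filter(function(s) {
    !any(vapply(valid, function(t) length(t) < length(s) && all(t %in% s),
                logical(1)))
  }, valid)
  minimal[order(vapply(minimal, paste, character(1), collapse = "\r"))]
}

# Random DAG over n nodes: edges only from lower to higher topological index.
random_dag <- function(n_nodes, p_edge = 0.35) {
  labels <- sprintf("n%02d", seq_len(n_nodes))
  edges <- NULL
  for (i in seq_len(n_nodes - 1)) {
    for (j in (i + 1):n_nodes) {
      if (stats::runif(1) < p_edge) edges <- rbind(edges, c(labels[i], labels[j]))
    }
  }
  build_dag(edges, nodes = labels)
}

expect_within_3se <- function(est, truth, se, label = "estimate") {
  expect_true(abs(est - truth) <= 3 * se,
              label = sprintf("%s = %.4f within 3 SE (%.4f) of %.4f",
                              label, est, 3 * se, truth))
}
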