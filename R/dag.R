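# Directed acyclic graphs, d-separation and backdoor adjustment sets.
#
# Graphs are small (the study diagram has 10 nodes) so everything works on a
# dense adjacency matrix. d-separation uses the moralized-ancestral-graph
# criterion; backdoor sets are found by exhaustive search over subsets of
# non-descendants of the exposure, reduced to the inclusion-minimal ones.

#' Build a directed acyclic graph
#'
#' @param edges a 2-column matrix/data frame of (parent, child) pairs, or a
#'   character vector of `"parent child"` lines (the edge-list text format).
#' @param nodes optional character vector of node labels; defaults to the
#'   nodes appearing in `edges`. Isolated nodes must be listed here.
#' @return An object of class `dag` (list with `nodes` and logical adjacency
#'   matrix `adj`, `adj[i, j]` meaning an edge i -> j).
#' @export
#' @examples
#' g <- build_dag(rbind(c("C", "X"), c("C", "Y"), c("X", "Y")))
#' backdoor_sets(g, "X", "Y")
build_dag <- function(edges, nodes = NULL) {
  if (is.character(edges) && is.null(dim(edges))) {
    parts <- strsplit(trimws(edges[nzchar(trimws(edges))]), "[[:space:]]+")
    if (length(parts) && any(lengths(parts) != 2)) {
      stop("edge lines must contain exactly two node labels")
    }
    edges <- do.call(rbind, parts)
  }
  if (is.null(edges) || length(edges) == 0) {
    edges <- matrix(character(0), ncol = 2)
  }
  edges <- as.matrix(edges)
  if (ncol(edges) != 2) stop("edges must have two columns (parent, child)")
  nodes <- sort(unique(c(nodes, as.vector(edges))))
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    adj[edges] <- TRUE
  }
  g <- structure(list(nodes = nodes, adj = adj), class = "dag")
  cyc <- find_cycle(adj)
  if (!is.null(cyc)) {
    stop("graph is cyclic: ", paste(cyc, collapse = " -> "))
  }
  g
}

#' @export
print.dag <- function(x, ...) {
  cat("DAG with", length(x$nodes), "nodes and", sum(x$adj), "edges\n")
  invisible(x)
}

# internal: return one directed cycle (as a node sequence) or NULL
find_cycle <- function(adj) {
  n <- nrow(adj)
  color <- integer(n)  # 0 white, 1 grey, 2 black
  stack <- character(0)
  found <- NULL
  visit <- function(i) {
    if (!is.null(found)) return()
    color[i] <<- 1L
    stack <<- c(stack, rownames(adj)[i])
    for (j in which(adj[i, ])) {
      if (color[j] == 1L) {
        lab <- rownames(adj)[j]
        found <<- c(stack[which(stack == lab)[1]:length(stack)], lab)
        return()
      }
      if (color[j] == 0L) visit(j)
      if (!is.null(found)) return()
    }
    color[i] <<- 2L
    stack <<- stack[-length(stack)]
  }
  for (i in seq_len(n)) if (color[i] == 0L) visit(i)
  found
}

#' Descendants of a node
#'
#' @param dag a [build_dag()] object.
#' @param node node label.
#' @return character vector of strict descendants (excluding `node`).
#' @export
descendants <- function(dag, node) {
  i <- match(node, dag$nodes)
  if (is.na(i)) stop("unknown node: ", node)
  seen <- logical(length(dag$nodes))
  frontier <- which(dag$adj[i, ])
  while (length(frontier)) {
    seen[frontier] <- TRUE
    frontier <- setdiff(which(colSums(dag$adj[frontier, , drop = FALSE]) > 0),
                        which(seen))
  }
  dag$nodes[seen]
}

#' Test d-separation
#'
#' Checks whether `x` and `y` are d-separated given conditioning set `z`,
#' using the moralized ancestral graph criterion: restrict to the ancestral
#' closure of `{x, y} U z`, moralize (marry co-parents, drop directions),
#' delete `z`, and test undirected connectivity.
#'
#' @param dag a [build_dag()] object.
#' @param x,y node labels.
#' @param z character vector of conditioning nodes (may be empty).
#' @return logical.
#' @export
d_separated <- function(dag, x, y, z = character(0)) {
  stopifnot(inherits(dag, "dag"))
  all_nodes <- dag$nodes
  if (!all(c(x, y, z) %in% all_nodes)) stop("unknown node label")
  if (x == y) stop("x and y must differ")
  # ancestral closure
  keep <- unique(c(x, y, z))
  repeat {
    parents <- all_nodes[rowSums(dag$adj[, keep, drop = FALSE]) > 0]
    new_keep <- unique(c(keep, parents))
    if (length(new_keep) == length(keep)) break
    keep <- new_keep
  }
  sub <- dag$adj[keep, keep, drop = FALSE]
  # moralize: undirected skeleton + edges between co-parents of a child
  und <- sub | t(sub)
  for (child in seq_along(keep)) {
    ps <- which(sub[, child])
    if (length(ps) > 1) und[ps, ps] <- TRUE
  }
  diag(und) <- FALSE
  # delete conditioning nodes, test reachability x -> y
  alive <- setdiff(keep, z)
  if (!(x %in% alive) || !(y %in% alive)) return(TRUE)
  und <- und[alive, alive, drop = FALSE]
  reach <- x
  repeat {
    nbrs <- alive[colSums(und[match(reach, alive), , drop = FALSE]) > 0]
    new_reach <- unique(c(reach, nbrs))
    if (length(new_reach) == length(reach)) break
    reach <- new_reach
  }
  !(y %in% reach)
}

#' Minimal sufficient backdoor adjustment sets
#'
#' Enumerates every inclusion-minimal node set Z such that Z contains no
#' descendant of the exposure and Z d-separates exposure from outcome in the
#' graph with the exposure's outgoing edges removed (the backdoor
#' criterion). Verified by exhaustive subset search; sets are returned in
#' lexicographic order, each sorted.
#'
#' @param dag a [build_dag()] object.
#' @param exposure,outcome node labels (must differ).
#' @return list of character vectors (possibly containing the empty set).
#' @export
backdoor_sets <- function(dag, exposure, outcome) {
  stopifnot(inherits(dag, "dag"))
  if (!all(c(exposure, outcome) %in% dag$nodes)) stop("unknown node label")
  if (exposure == outcome) stop("exposure and outcome must differ")
  g2 <- dag
  g2$adj[exposure, ] <- FALSE  # cut causal paths out of the exposure
  candidates <- setdiff(dag$nodes, c(exposure, outcome, descendants(dag, exposure)))
  if (length(candidates) > 16) {
    stop("exhaustive backdoor search limited to 16 candidate nodes")
  }
  valid <- list()
  for (k in 0:length(candidates)) {
    subsets <- if (k == 0) list(character(0)) else
      utils::combn(candidates, k, simplify = FALSE)
    for (z in subsets) {
      if (d_separated(g2, exposure, outcome, z)) valid[[length(valid) + 1]] <- sort(z)
    }
  }
  is_minimal <- vapply(seq_along(valid), function(i) {
    !any(vapply(seq_along(valid), function(j) {
      j != i && length(valid[[j]]) < length(valid[[i]]) &&
        all(valid[[j]] %in% valid[[i]])
    }, logical(1)))
  }, logical(1))
  minimal <- valid[is_minimal]
  keys <- vapply(minimal, paste, character(1), collapse = "\r")
  minimal[order(keys)]
}

#' The study causal diagram
#'
#' The hypothesized diagram for the delay-outcome analysis: diagnostic delay
#' affects survival directly and through three mediators (stage migration,
#' treatment intensity, surgical complications); age, BMI, comorbidity,
#' family history and molecular subtype confound both delay and survival.
#'
#' @return A 10-node [build_dag()] object.
#' @export
study_dag <- function() {
  confounders <- c("age", "bmi", "comorbidity", "family_history", "subtype")
  edges <- rbind(
    c("delay", "stage_migration"), c("stage_migration", "survival"),
    c("delay", "treatment_intensity"), c("treatment_intensity", "survival"),
    c("delay", "complications"), c("complications", "survival"),
    c("delay", "survival"),
    cbind(confounders, "delay"),
    cbind(confounders, "survival")
  )
  build_dag(edges)
}

#' Write / read a DAG as edge-list text
#'
#' One `"parent child"` pair per line.
#'
#' @param dag a [build_dag()] object.
#' @param path file path.
#' @export
write_dag <- function(dag, path) {
  idx <- which(dag$adj, arr.ind = TRUE)
  lines <- paste(dag$nodes[idx[, 1]], dag$nodes[idx[, 2]])
  writeLines(sort(lines), path)
  invisible(path)
}

#' @rdname write_dag
#' @export
read_dag <- function(path) {
  build_dag(readLines(path))
}
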