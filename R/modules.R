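#' Convert a sponge network (or edge table) to an igraph graph
#'
#' @param x a \code{sponge_network}, a data.frame with columns \code{rna_a},
#'   \code{rna_b}, or an igraph graph (returned as is, simplified).
#' @return a simple undirected igraph graph.
#' @export
as_sponge_graph <- function(x) {
  if (inherits(x, "igraph")) {
    return(igraph::simplify(x, remove.multiple = TRUE, remove.loops = TRUE))
  }
  stopifnot(is.data.frame(x), all(c("rna_a", "rna_b") %in% names(x)))
  g <- igraph::graph_from_data_frame(x[, c("rna_a", "rna_b")],
                                     directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

membership_to_modules <- function(membership, names, method) {
  mods <- split(names, membership)
  ord <- order(-vapply(mods, length, integer(1)),
               vapply(mods, function(m) min(m), character(1)))
  module_set(mods[ord], method)
}

#' Fast greedy modularity modules (FN)
#'
#' Community detection by greedy agglomerative modularity optimization:
#' starting from singleton communities, the merge with the largest
#' modularity gain is applied until no gain remains. Implemented with the
#' fast greedy algorithm in igraph. Isolated nodes become singletons.
#'
#' @param g graph (igraph, sponge network or edge data.frame).
#' @return a \code{module_set} partitioning the nodes.
#' @export
fn_modules <- function(g) {
  g <- as_sponge_graph(g)
  if (igraph::vcount(g) == 0) return(module_set(list(), "FN"))
  cl <- igraph::cluster_fast_greedy(g, weights = NULL)
  # cut the merge dendrogram at the modularity maximum ourselves: the
  # membership reported by igraph can stop one merge short on ties
  n_at_max <- igraph::vcount(g) - (which.max(cl$modularity) - 1)
  memb <- igraph::cut_at(cl, no = n_at_max)
  membership_to_modules(memb, igraph::V(g)$name, "FN")
}

#' Markov clustering modules (MCL)
#'
#' Simulates flow on the graph by alternating expansion (matrix squaring)
#' and inflation (elementwise power with column renormalization) on the
#' column-stochastic adjacency matrix with unit self-loops, until the matrix
#' change drops below \code{tol}. Entries below 1e-12 are pruned each
#' iteration. Clusters are read off the limit matrix as weakly connected
#' components of its support; the output is a partition (a node attracted by
#' several clusters goes to the largest, then lexicographically smallest,
#' one).
#'
#' @param g graph.
#' @param inflation inflation exponent, > 1 (default 2; larger values give
#'   finer clusterings).
#' @param tol convergence tolerance on the max absolute change.
#' @param max_iter iteration cap; non-convergence returns the current
#'   clustering with a warning.
#' @return a \code{module_set} partitioning the nodes.
#' @export
mcl_modules <- function(g, inflation = 2, tol = 1e-6, max_iter = 200) {
  if (inflation <= 1) stop("inflation must be > 1")
  g <- as_sponge_graph(g)
  nodes <- igraph::V(g)$name
  nn <- length(nodes)
  if (nn == 0) return(module_set(list(), "MCL"))
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  diag(A) <- 1
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                     # expansion
    M2 <- M2^inflation                # inflation
    M2[M2 < 1e-12] <- 0
    M2 <- sweep(M2, 2, colSums(M2), "/")
    if (max(abs(M2 - M)) < tol) {
      M <- M2
      converged <- TRUE
      break
    }
    M <- M2
  }
  if (!converged) warning("MCL did not converge within max_iter")
  support <- M > 1e-6
  # components of the attractor-support structure: attractor row i links the
  # nodes it covers
  supp_idx <- which(support, arr.ind = TRUE)
  g_supp <- igraph::make_empty_graph(n = nn, directed = FALSE)
  if (nrow(supp_idx) > 0) {
    g_supp <- igraph::add_edges(g_supp, t(supp_idx))
  }
  comp_id <- igraph::components(g_supp)$membership
  mods <- split(nodes, comp_id)
  ord <- order(-vapply(mods, length, integer(1)),
               vapply(mods, min, character(1)))
  module_set(mods[ord], "MCL")
}

edge_similarity_matrix <- function(el, adj_list) {
  ne <- nrow(el)
  D <- matrix(1, ne, ne)
  diag(D) <- 0
  nbr_inc <- lapply(names(adj_list), function(v) sort(c(v, adj_list[[v]])))
  names(nbr_inc) <- names(adj_list)
  for (i in seq_len(ne - 1)) {
    for (j in (i + 1):ne) {
      sharedv <- intersect(el[i, ], el[j, ])
      if (length(sharedv) != 1) next
      a <- setdiff(el[i, ], sharedv)
      b <- setdiff(el[j, ], sharedv)
      na <- nbr_inc[[a]]; nb <- nbr_inc[[b]]
      sim <- length(intersect(na, nb)) / length(union(na, nb))
      D[i, j] <- D[j, i] <- 1 - sim
    }
  }
  D
}

partition_density <- function(el, cluster_id) {
  ne <- nrow(el)
  d <- 0
  for (cl in unique(cluster_id)) {
    idx <- cluster_id == cl
    mc <- sum(idx)
    nc <- length(unique(c(el[idx, 1], el[idx, 2])))
    if (nc > 2) d <- d + mc * (mc - nc + 1) / ((nc - 2) * (nc - 1))
  }
  2 * d / ne
}

#' Link community modules (LINKCOMM)
#'
#' Clusters the edges of the graph rather than its nodes: edges sharing a
#' node are scored by the Jaccard similarity of the inclusive neighborhoods
#' (node plus neighbors) of their non-shared endpoints, edges are merged by
#' single-linkage hierarchical clustering, and the dendrogram is cut where
#' the partition density D = (2/|E|) sum_c m_c (m_c - n_c + 1) /
#' ((n_c - 2)(n_c - 1)) is maximal (ties resolved toward the finer cut).
#' Modules are the node sets induced by the edge clusters, so modules may
#' overlap (a node can carry edges of several communities).
#'
#' @param g graph with at least one edge.
#' @param min_size minimum number of nodes for a module to be reported
#'   (default 2).
#' @return a \code{module_set}; overlapping modules allowed.
#' @export
linkcomm_modules <- function(g, min_size = 2) {
  g <- as_sponge_graph(g)
  if (igraph::ecount(g) == 0) stop("graph has no edges")
  el <- igraph::as_edgelist(g)
  storage.mode(el) <- "character"
  ne <- nrow(el)
  if (ne == 1) {
    mods <- list(sort(el[1, ]))
    mods <- mods[vapply(mods, length, integer(1)) >= min_size]
    return(module_set(mods, "LINKCOMM"))
  }
  adj_list <- lapply(igraph::adjacent_vertices(g, igraph::V(g)), names)
  names(adj_list) <- igraph::V(g)$name
  D <- edge_similarity_matrix(el, adj_list)
  hc <- stats::hclust(stats::as.dist(D), method = "single")
  heights <- sort(unique(c(0, hc$height)))
  best_d <- -Inf
  best_cut <- NULL
  for (h in heights) {
    cl <- stats::cutree(hc, h = h)
    d <- partition_density(el, cl)
    if (d > best_d + 1e-12) {
      best_d <- d
      best_cut <- cl
    }
  }
  mods <- lapply(split(seq_len(ne), best_cut), function(idx) {
    sort(unique(c(el[idx, 1], el[idx, 2])))
  })
  mods <- mods[vapply(mods, length, integer(1)) >= min_size]
  ord <- order(-vapply(mods, length, integer(1)),
               vapply(mods, function(m) min(m), character(1)))
  module_set(mods[ord], "LINKCOMM")
}

#' MCODE modules
#'
#' Vertex-weighting plus outward traversal: each node is weighted by the
#' core number of the highest k-core of its closed neighborhood times that
#' core's edge density; seeds are processed in decreasing weight and a
#' complex grows outward over not-yet-assigned neighbors whose weight is at
#' least (1 - vwp) times the seed weight. The optional haircut reduces each
#' complex to its 2-core (removing loosely attached degree-1 members).
#' Modules are reported in decreasing seed-weight order.
#'
#' @param g graph.
#' @param vwp vertex weight percentage in [0, 1) (default 0.2).
#' @param haircut apply the 2-core haircut (default TRUE).
#' @param fluff reserved; setting TRUE is an error (not implemented).
#' @return a \code{module_set} of connected dense subgraphs.
#' @export
mcode_modules <- function(g, vwp = 0.2, haircut = TRUE, fluff = FALSE) {
  if (isTRUE(fluff)) stop("fluff is not implemented")
  if (vwp < 0 || vwp >= 1) stop("vwp must lie in [0, 1)")
  g <- as_sponge_graph(g)
  nodes <- igraph::V(g)$name
  if (length(nodes) == 0 || igraph::ecount(g) == 0) {
    return(module_set(list(), "MCODE"))
  }
  w <- vapply(nodes, function(v) {
    nb <- c(v, names(igraph::neighbors(g, v)))
    sub <- igraph::induced_subgraph(g, nb)
    cores <- igraph::coreness(sub)
    kmax <- max(cores)
    core_nodes <- names(cores)[cores == kmax]
    core_sub <- igraph::induced_subgraph(sub, core_nodes)
    nc <- igraph::vcount(core_sub)
    dens <- if (nc < 2) 0 else
      2 * igraph::ecount(core_sub) / (nc * (nc - 1))
    kmax * dens
  }, numeric(1))
  names(w) <- nodes
  seeds <- nodes[order(-w, nodes)]
  assigned <- character(0)
  modules <- list()
  seed_w <- numeric(0)
  for (s in seeds) {
    if (s %in% assigned) next
    thr <- (1 - vwp) * w[[s]]
    members <- s
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- unique(unlist(lapply(frontier, function(v) {
        names(igraph::neighbors(g, v))
      })))
      nxt <- setdiff(nxt, c(members, assigned))
      nxt <- nxt[w[nxt] >= thr]
      members <- c(members, nxt)
      frontier <- nxt
    }
    if (haircut && length(members) > 1) {
      sub <- igraph::induced_subgraph(g, members)
      cores <- igraph::coreness(sub)
      members <- names(cores)[cores >= 2]
    }
    if (length(members) >= 2) {
      modules <- c(modules, list(sort(members)))
      seed_w <- c(seed_w, w[[s]])
      assigned <- union(assigned, members)
    }
    assigned <- union(assigned, s)
  }
  ord <- order(-seed_w)
  module_set(modules[ord], "MCODE")
}

#' Filter modules by size
#'
#' Keeps modules with at least \code{min_size} members, renumbered from 1 in
#' the original order.
#'
#' @param ms a \code{module_set}.
#' @param min_size minimum module size (default 3, the usual module-size
#'   cutoff for the FN/MCL/LINKCOMM/MCODE methods).
#' @return a filtered \code{module_set}.
#' @export
filter_modules <- function(ms, min_size = 3) {
  keep <- vapply(ms$modules, length, integer(1)) >= min_size
  module_set(ms$modules[keep], ms$method)
}
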