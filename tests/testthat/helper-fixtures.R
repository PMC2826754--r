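# Fixtures and independent oracles used across the suite. The oracles are
# deliberately naive (enumeration over edge subsets, igraph::components for
# connectivity) and independent of the package's flow/enumeration code
# paths.

make_net <- function(from, to, r, isolated = character()) {
  prob_network(data.frame(from = from, to = to, reliability = r,
                          stringsAsFactors = FALSE), isolated = isolated)
}

# the worked 3-node series chain: s - m - t, both edges 0.6
chain_net <- function() make_net(c("s", "m"), c("m", "t"), c(0.6, 0.6))

# diamond: two node-disjoint 2-edge routes s-a-t and s-b-t, all r = 0.5
diamond_net <- function() {
  make_net(c("s", "a", "s", "b"), c("a", "t", "b", "t"), rep(0.5, 4))
}

# degree-independence fixture: sinks u and v each sit behind a single
# 2-edge path of identical reliabilities from the query q, but v's
# intermediate node y is a hub with 8 extra edges.
hub_contrast_net <- function() {
  make_net(c("q", "x", "q", "y", sprintf("h%d", 1:8)),
           c("x", "u", "y", "v", rep("y", 8)),
           c(0.6, 0.6, 0.6, 0.6, rep(0.5, 8)))
}

# random simple graph on <= 8 nodes with bounded edge count
random_net <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  nodes <- letters[seq_len(n_nodes)]
  allp <- t(utils::combn(nodes, 2L))
  pick <- sample.int(nrow(allp), min(n_edges, nrow(allp)))
  prob_network(data.frame(from = allp[pick, 1L], to = allp[pick, 2L],
                          reliability = round(stats::runif(length(pick),
                                                           0.05, 0.95), 3),
                          stringsAsFactors = FALSE),
               isolated = nodes)
}

# independent exact reliability: enumerate edge subsets, test connectivity
# with igraph::components (never touches the package's C++ path)
oracle_exact <- function(net, q, sink) {
  ed <- network_edges(net)
  E <- nrow(ed)
  nodes <- network_nodes(net)
  tot <- 0
  for (mask in 0:(2 ^ E - 1)) {
    bits <- bitwAnd(mask, as.integer(2 ^ (seq_len(E) - 1))) > 0L
    p <- prod(ifelse(bits, ed$reliability, 1 - ed$reliability))
    sub <- igraph::graph_from_data_frame(ed[bits, 1:2, drop = FALSE],
                                         directed = FALSE, vertices = nodes)
    comp <- igraph::components(sub)$membership
    if (any(comp[q] == comp[[sink]])) tot <- tot + p
  }
  tot
}

# brute-force minimum edge cut separating q from sink: smallest k such
# that removing some k edges disconnects them
oracle_min_cut <- function(net, q, sink) {
  ed <- network_edges(net)
  E <- nrow(ed)
  nodes <- network_nodes(net)
  connected_without <- function(rm) {
    keep <- setdiff(seq_len(E), rm)
    sub <- igraph::graph_from_data_frame(ed[keep, 1:2, drop = FALSE],
                                         directed = FALSE, vertices = nodes)
    comp <- igraph::components(sub)$membership
    any(comp[q] == comp[[sink]])
  }
  if (!connected_without(integer())) return(0L)
  for (k in seq_len(E)) {
    combs <- utils::combn(E, k)
    for (j in seq_len(ncol(combs)))
      if (!connected_without(combs[, j])) return(k)
  }
  E
}

# do all simple source->sink paths share no edge pairwise?
all_simple_paths_disjoint <- function(net, q, sink) {
  g <- net$graph
  esets <- list()
  for (s in q) {
    ps <- igraph::all_simple_paths(g, from = s, to = sink)
    for (p in ps) {
      nm <- igraph::V(g)$name[as.integer(p)]
      a <- nm[-length(nm)]; b <- nm[-1L]
      esets[[length(esets) + 1L]] <- paste(pmin(a, b), pmax(a, b))
    }
  }
  if (length(esets) <= 1L) return(TRUE)
  all_edges <- unlist(esets)
  !anyDuplicated(all_edges)
}
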