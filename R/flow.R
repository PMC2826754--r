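# Net-Flow core: maximum edge-disjoint paths via unit-capacity max flow,
# the product-form reliability lower bound, whole-network candidate
# ranking, and the brute-force exact-reliability oracle.
#
# The bound: with d pairwise edge-disjoint source->sink paths whose
# failure probabilities are P_i = 1 - prod_j r_j, the events "path i
# operational" are independent, so
#     R >= 1 - prod_{i=1..d} P_i .
# The bound is sound for *any* edge-disjoint path set and tightens as d
# grows; by Menger's theorem the maximum d equals the minimum-cardinality
# s-t edge cut, attained by max flow with unit edge capacities.

.SUPER <- ".__SUPERSOURCE__"

# Super-source flow graph: one artificial vertex joined to each query
# member by a certain (r = 1) edge whose capacity equals that member's
# degree, so a member can head several disjoint paths. Network edges have
# unit capacity; artificial edges never appear in reported paths.
.flow_graph <- function(net, sources) {
  g <- net$graph
  igraph::E(g)$capacity <- 1
  g <- igraph::add_vertices(g, 1L, name = .SUPER)
  deg <- igraph::degree(g, v = sources)
  super_edges <- as.vector(rbind(.SUPER, sources))
  g <- igraph::add_edges(g, super_edges,
                         attr = list(reliability = 1,
                                     capacity = pmax(as.numeric(deg), 1)))
  g
}

# Flatten a flow graph into the arrays the min-cost max-flow solver wants.
# Cost -log r makes the solver pick, among all maximum flows, the one
# whose edges carry the largest reliability product.
.mcmf_arrays <- function(sg) {
  el <- igraph::as_edgelist(sg, names = FALSE)
  list(n = igraph::vcount(sg),
       from = el[, 1L] - 1L, to = el[, 2L] - 1L,
       cap = as.numeric(igraph::E(sg)$capacity),
       cost = -log(igraph::E(sg)$reliability),
       names = igraph::V(sg)$name)
}

.mcmf <- function(arr, source_name, sink_name) {
  cpp_mincost_maxflow(arr$n, arr$from, arr$to, arr$cap, arr$cost,
                      match(source_name, arr$names) - 1L,
                      match(sink_name, arr$names) - 1L)
}

# Peel unit paths off a max-flow solution, most reliable first (shortest
# path on -log r over flow-carrying edges). Maximises the resulting bound
# among decompositions of the given flow; residual ties fall to the
# deterministic tie-break of the shortest-path routine.
.decompose_flow <- function(sg, mf, sink, carry_mult = FALSE) {
  d <- as.integer(round(mf$value))
  if (d == 0L) return(list())
  el <- igraph::as_edgelist(sg)
  fl <- mf$flow
  use <- abs(fl) > 1e-9
  tail_ <- ifelse(fl[use] > 0, el[use, 1L], el[use, 2L])
  head_ <- ifelse(fl[use] > 0, el[use, 2L], el[use, 1L])
  rel <- igraph::E(sg)$reliability[use]
  df <- data.frame(from = tail_, to = head_,
                   w = -log(rel), cap = round(abs(fl[use])), rel = rel,
                   stringsAsFactors = FALSE)
  if (carry_mult) df$mult <- igraph::E(sg)$multiplicity[use]
  gg <- igraph::graph_from_data_frame(
    df, directed = TRUE,
    vertices = sort(unique(c(df$from, df$to, sink, .SUPER))))
  paths <- vector("list", d)
  for (i in seq_len(d)) {
    sp <- suppressWarnings(
      igraph::shortest_paths(gg, from = .SUPER, to = sink,
                             weights = igraph::E(gg)$w, mode = "out",
                             output = "both"))
    ep <- sp$epath[[1L]]
    if (length(ep) == 0L) break  # flow exhausted early (cycle remainder)
    nodes <- igraph::V(gg)$name[as.integer(sp$vpath[[1L]])]
    real <- nodes[-1L]                       # drop super-source
    erel <- igraph::E(gg)$rel[as.integer(ep)][-1L]  # drop artificial edge
    p <- list(nodes = real, rel = erel)
    if (carry_mult)
      p$mult <- igraph::E(gg)$mult[as.integer(ep)][-1L]
    paths[[i]] <- p
    newcap <- igraph::E(gg)$cap[as.integer(ep)] - 1L
    igraph::E(gg)$cap[as.integer(ep)] <- newcap
    gg <- igraph::delete_edges(gg, igraph::E(gg)[igraph::E(gg)$cap <= 0])
  }
  paths[!vapply(paths, is.null, TRUE)]
}

.as_disjoint_paths <- function(paths, sources, sink) {
  structure(list(
    paths    = lapply(paths, `[[`, "nodes"),
    failure  = vapply(paths, function(p) 1 - prod(p$rel), 0),
    lengths  = vapply(paths, function(p) length(p$rel), 0L),
    d        = length(paths),
    sources  = sources, sink = sink),
    class = "disjoint_paths")
}

#' Maximum set of edge-disjoint paths from a query to a sink
#'
#' Computes a maximum cardinality set of pairwise edge-disjoint paths from
#' any query member to `sink` via unit-capacity maximum flow. Multiple
#' sources are handled with a virtual super-source joined to each member
#' by an artificial certain edge that never appears in the reported paths
#' and does not count toward path lengths. By Menger's theorem the number
#' of paths equals the minimum-cardinality edge cut separating the query
#' from the sink.
#'
#' @param net a [prob_network()].
#' @param sources character vector of query node ids (sink excluded).
#' @param sink sink node id.
#' @return A `disjoint_paths` object: `paths` (list of node sequences),
#'   per-path `failure` probabilities and `lengths`, and the path count `d`
#'   (0 when the sink is disconnected from every source).
#' @export
max_edge_disjoint_paths <- function(net, sources, sink) {
  sources <- validate_query(net, sources)
  if (!sink %in% igraph::V(net$graph)$name)
    stop("sink not in network: ", sink)
  if (sink %in% sources) stop("sink must not be a query member: ", sink)
  sg <- .flow_graph(net, sources)
  mf <- .mcmf(.mcmf_arrays(sg), .SUPER, sink)
  .as_disjoint_paths(.decompose_flow(sg, mf, sink), sources, sink)
}

#' @export
print.disjoint_paths <- function(x, ...) {
  cat(sprintf("%d edge-disjoint path(s) {%s} -> %s\n", x$d,
              paste(x$sources, collapse = ","), x$sink))
  for (i in seq_len(x$d))
    cat(sprintf("  [%d] %s  (failure %.4g)\n", i,
                paste(x$paths[[i]], collapse = "-"), x$failure[i]))
  invisible(x)
}

#' Failure probability of a single path
#'
#' A path operates only if every link on it is functional, so its failure
#' probability is `1 - prod(r_j)` over the reliabilities of its edges.
#'
#' @param path character vector of consecutive node ids.
#' @param net a [prob_network()] containing every consecutive pair as an
#'   edge.
#' @return Failure probability in \[0, 1).
#' @export
path_failure_probability <- function(path, net) {
  stopifnot(inherits(net, "prob_network"), length(path) >= 2L)
  g <- net$graph
  vp <- as.vector(rbind(path[-length(path)], path[-1L]))
  ids <- igraph::get_edge_ids(g, vp, error = FALSE)
  if (any(ids == 0)) {
    i <- which(ids == 0)[1L]
    stop("no such edge: ", path[i], "-", path[i + 1L])
  }
  1 - prod(igraph::E(g)$reliability[ids])
}

#' Reliability lower bound from a disjoint path set
#'
#' `1 - prod(P_i)` over the failure probabilities of the edge-disjoint
#' paths; 0 for an empty set (no evidence of connection).
#'
#' @param pset a `disjoint_paths` object.
#' @return Lower bound on two-terminal reliability, in \[0, 1).
#' @export
reliability_lower_bound <- function(pset) {
  stopifnot(inherits(pset, "disjoint_paths"))
  if (pset$d == 0L) return(0)
  1 - prod(pset$failure)
}

#' Net-Flow reliability score of one candidate
#'
#' Composes [max_edge_disjoint_paths()], per-path failure probabilities and
#' [reliability_lower_bound()] into the query answer for one sink: a
#' provable lower bound on the probability that the sink is connected to
#' the partially known complex.
#'
#' @inheritParams max_edge_disjoint_paths
#' @param q character vector of query node ids.
#' @return A `reliability_result`: `sink`, `bound`, `d`, `path_set`.
#' @examples
#' net <- prob_network(data.frame(from = c("s", "m"), to = c("m", "t"),
#'                                reliability = c(0.6, 0.6)))
#' netflow_score(net, "s", "t")$bound  # 0.36: single path, bound is tight
#' @export
netflow_score <- function(net, q, sink) {
  pset <- max_edge_disjoint_paths(net, q, sink)
  structure(list(sink = sink, bound = reliability_lower_bound(pset),
                 d = pset$d, path_set = pset),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("Net-Flow reliability of %s: bound %.6g via %d disjoint path(s)\n",
              x$sink, x$bound, x$d))
  invisible(x)
}

# Shared engine: one flow graph, one max flow per sink.
.netflow_all <- function(net, q, sinks) {
  sg <- .flow_graph(net, q)
  arr <- .mcmf_arrays(sg)
  lapply(sinks, function(s) {
    mf <- .mcmf(arr, .SUPER, s)
    pset <- .as_disjoint_paths(.decompose_flow(sg, mf, s), q, s)
    structure(list(sink = s, bound = reliability_lower_bound(pset),
                   d = pset$d, path_set = pset),
              class = "reliability_result")
  })
}

#' Rank every candidate protein against a query
#'
#' Scores each non-query node with [netflow_score()] (each node becomes the
#' sink in turn, the query members are the sources) and orders candidates
#' by bound, descending; ties break by lexicographic node id so the output
#' is deterministic.
#'
#' @inheritParams netflow_score
#' @return A `netflow_ranking`: a data frame with columns `sink`, `bound`,
#'   `d` (one row per candidate, best first), with the full
#'   `reliability_result` list in attribute `"results"`.
#' @export
rank_candidates <- function(net, q) {
  q <- validate_query(net, q)
  sinks <- setdiff(network_nodes(net), q)
  res <- .netflow_all(net, q, sinks)
  df <- data.frame(sink = vapply(res, `[[`, "", "sink"),
                   bound = vapply(res, `[[`, 0, "bound"),
                   d = vapply(res, `[[`, 0L, "d"),
                   stringsAsFactors = FALSE)
  o <- order(-df$bound, df$sink)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "results") <- res[o]
  attr(df, "query") <- q
  class(df) <- c("netflow_ranking", "data.frame")
  df
}

#' @export
print.netflow_ranking <- function(x, n = 10L, ...) {
  cat(sprintf("Net-Flow ranking of %d candidates (query: %s)\n", nrow(x),
              paste(attr(x, "query"), collapse = ",")))
  print.data.frame(utils::head(as.data.frame(x), n))
  if (nrow(x) > n) cat("...", nrow(x) - n, "more\n")
  invisible(x)
}

#' @export
plot.netflow_ranking <- function(x, n = 20L, ...) {
  top <- utils::head(x, n)
  graphics::barplot(rev(top$bound), names.arg = rev(top$sink), horiz = TRUE,
                    las = 1, xlab = "reliability lower bound", ...)
  invisible(x)
}

#' Exact two-terminal reliability by brute-force enumeration
#'
#' Sums, over all `2^|E|` edge operational states, the probability of every
#' state in which at least one query member is connected to the sink. Exact
#' network reliability is NP-hard, so the oracle refuses networks beyond
#' `max_edges` edges; use [mcs_reliability()] there instead.
#'
#' @inheritParams netflow_score
#' @param max_edges enumeration cap (default 20).
#' @return The exact connection probability.
#' @export
exact_reliability <- function(net, q, sink, max_edges = 20L) {
  q <- validate_query(net, q)
  if (!sink %in% igraph::V(net$graph)$name) stop("sink not in network: ", sink)
  if (sink %in% q) stop("sink must not be a query member: ", sink)
  ed <- network_edges(net)
  if (nrow(ed) > max_edges)
    stop("network has ", nrow(ed), " edges; exact enumeration is capped at ",
         max_edges, " -- use mcs_reliability() for an estimate")
  nodes <- network_nodes(net)
  cpp_exact_reliability(match(ed$from, nodes) - 1L, match(ed$to, nodes) - 1L,
                        ed$reliability, match(q, nodes) - 1L,
                        match(sink, nodes) - 1L, length(nodes))
}
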