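# Cluster-graph construction, bandwidth-modified reliability bounds, and
# the best-first hierarchical search that answers threshold and budgeted
# queries with bound-based pruning.
#
# The cluster graph replaces each active cluster by one vertex; an edge
# joins two vertices iff at least one network edge crosses their member
# sets, weighted by the *maximum* crossing-edge probability and annotated
# with the crossing-edge count (multiplicity). One edge-disjoint path in
# the cluster graph can stand for several real disjoint paths, but never
# more than the multiplicity of its first edge out of the query vertex --
# the path's bandwidth b -- so the cluster-level bound is
#     R_max >= 1 - prod_i P_i^{b_i} .
# Clusters whose R_max falls below the query threshold are pruned without
# ever running a real flow instance for their members.

#' Build the cluster graph for an active cluster set
#'
#' Query proteins are first removed from their home clusters and then
#' added back as individual vertices, so a query member is never its own
#' candidate. The remaining active clusters must be disjoint and cover all
#' non-query nodes.
#'
#' @param net a [prob_network()].
#' @param clusters list of cluster records (`id`, `members`), e.g. a
#'   subset of a `cluster_hierarchy`'s clusters.
#' @param q character vector of query node ids.
#' @return A `cluster_graph`: `edges` (`from`, `to`, `weight`,
#'   `multiplicity`), `vertices`, `query`, `cluster_ids`, and the
#'   member map `members`.
#' @export
build_cluster_graph <- function(net, clusters, q) {
  q <- validate_query(net, q)
  mem <- lapply(clusters, function(cl) setdiff(cl$members, q))
  ids <- vapply(clusters, `[[`, "", "id")
  keep <- lengths(mem) > 0L
  mem <- stats::setNames(mem[keep], ids[keep])
  allm <- unlist(mem, use.names = FALSE)
  if (anyDuplicated(allm))
    stop("overlapping active clusters: node(s) ",
         paste(utils::head(allm[duplicated(allm)], 5L), collapse = ", "))
  uncovered <- setdiff(setdiff(network_nodes(net), q), allm)
  if (length(uncovered))
    stop("active clusters do not cover node(s): ",
         paste(utils::head(uncovered, 5L), collapse = ", "))
  map <- c(unlist(lapply(names(mem), function(id)
             stats::setNames(rep(id, length(mem[[id]])), mem[[id]]))),
           stats::setNames(q, q))
  edges <- .aggregate_cross_edges(network_edges(net), map)
  structure(list(edges = edges,
                 vertices = sort(c(names(mem), q)),
                 query = q, cluster_ids = sort(names(mem)), members = mem),
            class = "cluster_graph")
}

#' @export
print.cluster_graph <- function(x, ...) {
  cat("Cluster graph:", length(x$cluster_ids), "cluster(s) +",
      length(x$query), "query vertex(es),", nrow(x$edges), "edge(s)\n")
  invisible(x)
}

#' Bandwidth-modified maximum reliability bound of a cluster
#'
#' Upper estimate of any member's Net-Flow bound, from two flow
#' computations on the cluster graph (query vertices as sources, the
#' target cluster as sink):
#'
#' 1. *Bandwidth form*: unit-capacity max flow gives edge-disjoint cluster
#'    paths; each path's failure `P_i` is exponentiated by its
#'    `bandwidth_i`, the multiplicity of the path's first edge out of the
#'    query vertex (for a length-1 path, of that single edge), since one
#'    cluster path can stand for up to that many real disjoint paths.
#'    Because `bandwidth_i >= 1` this never falls below the plain
#'    product-form bound on the same paths.
#' 2. *Multiplicity form*: the same flow problem with each cluster edge
#'    allowed to carry as many units as the network edges it represents;
#'    every routed unit contributes its route's failure probability once.
#'    This covers real disjoint paths that funnel through a shared cluster
#'    edge, which the first-edge-only bandwidth rule can miss.
#'
#' The reported bound is the larger of the two estimates, so pruning in
#' [threshold_query()] errs on the safe side. With all multiplicities 1
#' both forms reduce to the plain bound, making the singleton clustering
#' exactly equivalent to [netflow_score()].
#'
#' @param cg a [build_cluster_graph()] result.
#' @param q query node ids (vertices of `cg`).
#' @param target a cluster id (vertex of `cg`).
#' @return A `cluster_bound`: `cluster`, `max_bound`, and the bandwidth
#'   form's per-path `failure` and `bandwidth`.
#' @export
cluster_max_bound <- function(cg, q, target) {
  stopifnot(inherits(cg, "cluster_graph"))
  if (!target %in% cg$vertices) stop("target not in cluster graph: ", target)
  missing_q <- setdiff(q, cg$vertices)
  if (length(missing_q))
    stop("query vertices not in cluster graph: ",
         paste(missing_q, collapse = ", "))
  ed <- cg$edges
  base <- function(caps, super_caps) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = ed$from, to = ed$to, reliability = ed$weight,
                 capacity = caps, multiplicity = ed$multiplicity,
                 stringsAsFactors = FALSE),
      directed = FALSE, vertices = cg$vertices)
    g <- igraph::add_vertices(g, 1L, name = .SUPER)
    igraph::add_edges(g, as.vector(rbind(.SUPER, q)),
                      attr = list(reliability = 1, capacity = super_caps,
                                  multiplicity = NA_integer_))
  }
  if (nrow(ed)) {
    q_mult <- vapply(q, function(v)
      sum(ed$multiplicity[ed$from == v | ed$to == v]), 0)
  } else q_mult <- rep(0, length(q))
  # bandwidth form: unit capacities, first-edge multiplicity as exponent
  g1 <- base(rep(1, nrow(ed)), pmax(q_mult, 1))
  mf1 <- .mcmf(.mcmf_arrays(g1), .SUPER, target)
  paths <- .decompose_flow(g1, mf1, target, carry_mult = TRUE)
  if (length(paths) == 0L)
    return(structure(list(cluster = target, max_bound = 0,
                          failure = numeric(), bandwidth = integer(),
                          paths = list()),
                     class = "cluster_bound"))
  failure <- vapply(paths, function(p) 1 - prod(p$rel), 0)
  band <- vapply(paths, function(p) as.integer(p$mult[1L]), 0L)
  bound_band <- 1 - prod(failure ^ band)
  # multiplicity form: capacities equal to represented edge counts
  g2 <- base(as.numeric(ed$multiplicity), pmax(q_mult, 1))
  mf2 <- .mcmf(.mcmf_arrays(g2), .SUPER, target)
  units <- .decompose_flow(g2, mf2, target)
  bound_multi <- if (length(units))
    1 - prod(vapply(units, function(p) 1 - prod(p$rel), 0)) else 0
  structure(list(cluster = target,
                 max_bound = max(bound_band, bound_multi),
                 failure = failure, bandwidth = band,
                 paths = lapply(paths, `[[`, "nodes")),
            class = "cluster_bound")
}

#' @export
print.cluster_bound <- function(x, ...) {
  cat(sprintf("Cluster %s: max bound %.6g over %d path(s), bandwidths %s\n",
              x$cluster, x$max_bound, length(x$failure),
              paste(x$bandwidth, collapse = ",")))
  invisible(x)
}

.strip_rec <- function(rec, q) {
  rec$members <- setdiff(rec$members, q)
  rec
}

# Internal best-first engine shared by threshold_query and budgeted_query.
# Expands the open cluster with the highest max bound; leaves deliver
# their members as candidates. With threshold = 0 everything expands and
# the delivered order is the budgeted candidate ranking.
.best_first <- function(net, h, q, threshold, strict, adapt, k, floor_thr,
                        budget_mode = FALSE) {
  q <- validate_query(net, q)
  recs <- h$clusters
  active <- list()
  for (id in h$roots) {
    r <- .strip_rec(recs[[id]], q)
    if (length(r$members)) active[[id]] <- r
  }
  open <- names(active)
  bounds <- numeric(0)
  expanded <- 0L
  candidates <- character(0)
  flow_cache <- list()
  initial_threshold <- threshold
  repeat {
    need <- if (strict) open else setdiff(open, names(bounds))
    if (length(need) && length(active)) {
      cg <- build_cluster_graph(net, active, q)
      for (id in need)
        bounds[id] <- cluster_max_bound(cg, q, id)$max_bound
    }
    elig <- open[bounds[open] >= threshold]
    if (length(elig) == 0L) {
      if (budget_mode) break
      newc <- setdiff(candidates, names(flow_cache))
      for (s in newc) flow_cache[[s]] <- netflow_score(net, q, s)
      ans_b <- vapply(flow_cache[candidates], `[[`, 0, "bound")
      n_ans <- sum(ans_b >= threshold)
      want_more <- (adapt == "halve" && n_ans == 0L) ||
        (adapt == "target_k" && n_ans < k)
      useful <- length(open) > 0L || any(ans_b < threshold)
      if (want_more && useful && threshold / 2 >= floor_thr) {
        threshold <- threshold / 2
        next
      }
      break
    }
    best <- elig[order(-bounds[elig], elig)][1L]
    rec <- active[[best]]
    if (length(rec$children) == 0L) {
      candidates <- c(candidates, sort(rec$members))
      open <- setdiff(open, best)
    } else {
      kids <- lapply(recs[rec$children], .strip_rec, q = q)
      kids <- kids[vapply(kids, function(r) length(r$members) > 0L, TRUE)]
      active[[best]] <- NULL
      for (kr in kids) active[[kr$id]] <- kr
      open <- c(setdiff(open, best), vapply(kids, `[[`, "", "id"))
      bounds <- bounds[setdiff(names(bounds), best)]
      if (strict) bounds <- numeric(0)
      expanded <- expanded + 1L
    }
  }
  list(threshold = threshold, initial_threshold = initial_threshold,
       candidates = candidates, flow_cache = flow_cache,
       expanded = expanded, pruned = length(open), q = q,
       bounds = bounds)
}

.report <- function(state, answers, fraction = NULL) {
  ab <- vapply(answers, `[[`, 0, "bound")
  an <- vapply(answers, `[[`, "", "sink")
  o <- order(-ab, an)
  answers <- answers[o]
  df <- data.frame(sink = an[o], bound = ab[o],
                   d = vapply(answers, `[[`, 0L, "d"),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(list(answers = answers, answers_df = df,
                 threshold = state$threshold,
                 initial_threshold = state$initial_threshold,
                 fraction = fraction,
                 flow_instances_executed = length(state$flow_cache),
                 clusters_expanded = state$expanded,
                 clusters_pruned = state$pruned,
                 candidates = state$candidates, query = state$q),
            class = "query_report")
}

#' Threshold query with hierarchical bound-based pruning
#'
#' Best-first search over the cluster hierarchy: starting from the roots,
#' the open cluster with the highest bandwidth-modified bound that still
#' exceeds the threshold is expanded into its children (leaves deliver
#' their members as candidates) until no open cluster exceeds the
#' threshold; the remaining clusters are pruned without running any flow
#' instance for their members. Every candidate is then verified with a
#' true [netflow_score()] on the whole network, and candidates whose bound
#' meets the threshold are returned.
#'
#' After each expansion the cluster graph is rebuilt for the new active
#' set, but bounds of untouched clusters are reused; `strict = TRUE`
#' recomputes all open bounds on the updated graph at every step.
#'
#' If the threshold turns out too high it can be decreased adaptively
#' without losing work: cached cluster bounds and verified scores are
#' reused when the search resumes. Policies: `"none"` keeps the threshold;
#' `"halve"` halves it while the answer set is empty; `"target_k"` halves
#' until at least `k` answers are found or the threshold floor `1e-6` is
#' reached.
#'
#' @param net a [prob_network()].
#' @param h a `cluster_hierarchy`.
#' @param q character vector of query node ids.
#' @param threshold probability threshold in (0, 1).
#' @param adapt threshold adaptation policy.
#' @param k answer count target for `adapt = "target_k"`.
#' @param strict recompute all open cluster bounds after every expansion.
#' @return A `query_report`: `answers` (list of `reliability_result`,
#'   best first), `answers_df`, the final `threshold`, and the work
#'   counters `flow_instances_executed`, `clusters_expanded`,
#'   `clusters_pruned`.
#' @export
threshold_query <- function(net, h, q, threshold,
                            adapt = c("none", "halve", "target_k"),
                            k = 5L, strict = FALSE) {
  adapt <- match.arg(adapt)
  stopifnot(inherits(h, "cluster_hierarchy"),
            threshold > 0, threshold < 1)
  st <- .best_first(net, h, q, threshold, strict, adapt, k,
                    floor_thr = 1e-6)
  keep <- Filter(function(r) r$bound >= st$threshold,
                 st$flow_cache[st$candidates])
  .report(st, unname(keep))
}

#' Budgeted approximate query
#'
#' Best-first expansion with no threshold ranks all candidates by the max
#' bound of the leaf cluster that delivers them (most promising first);
#' real flow instances are then spent only on the top
#' `ceiling(fraction * n_candidates)` of that list. `fraction = 1`
#' reproduces [rank_candidates()]; `fraction = 0.01` spends 1% of the flow
#' instances, a 100x speedup.
#'
#' @inheritParams threshold_query
#' @param fraction fraction of candidates to verify, in (0, 1].
#' @return A `query_report`; `answers` are the verified candidates sorted
#'   by bound.
#' @export
budgeted_query <- function(net, h, q, fraction) {
  stopifnot(inherits(h, "cluster_hierarchy"),
            fraction > 0, fraction <= 1)
  st <- .best_first(net, h, q, threshold = 0, strict = FALSE,
                    adapt = "none", k = 0L, floor_thr = 0,
                    budget_mode = TRUE)
  n_cand <- length(setdiff(network_nodes(net), st$q))
  budget <- ceiling(fraction * n_cand)
  top <- utils::head(st$candidates, budget)
  st$flow_cache <- stats::setNames(
    lapply(top, function(s) netflow_score(net, st$q, s)), top)
  st$threshold <- 0
  .report(st, unname(st$flow_cache), fraction = fraction)
}

#' @export
print.query_report <- function(x, n = 10L, ...) {
  mode <- if (is.null(x$fraction))
    sprintf("threshold %.4g (initial %.4g)", x$threshold, x$initial_threshold)
  else sprintf("budget fraction %.4g", x$fraction)
  cat("Query report (", mode, "): ", length(x$answers), " answer(s)\n",
      sep = "")
  cat(sprintf("  flow instances: %d | clusters expanded: %d | pruned: %d\n",
              x$flow_instances_executed, x$clusters_expanded,
              x$clusters_pruned))
  print.data.frame(utils::head(x$answers_df, n))
  if (nrow(x$answers_df) > n) cat("...", nrow(x$answers_df) - n, "more\n")
  invisible(x)
}
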