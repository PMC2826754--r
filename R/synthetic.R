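# Synthetic probabilistic scale-free networks with planted complexes, and
# the leave-one-out membership-query evaluation protocol. The generator
# emulates the summary statistics of the yeast interaction network the
# method was designed for: ~3100 proteins with ~4 edges per node on a
# preferential-attachment (scale-free) backbone, a background weight law
# with many weak and few strong interactions, and 27 vertex-disjoint
# complexes of 3-15 members wired densely with high-reliability edges.

#' Generate a probabilistic scale-free network with planted complexes
#'
#' A preferential-attachment backbone provides the scale-free topology;
#' background edge weights are drawn from `weight_law` (default Beta(1,3):
#' many weak edges, few strong). Each planted complex occupies
#' vertex-disjoint nodes and is realized as a connected subgraph -- a
#' random spanning tree plus extra edges up to at least half of all pairs
#' -- whose edges have reliability at least `intra_reliability`. Where a
#' planted edge coincides with a background edge the maximum weight is
#' kept. Deterministic given `seed`.
#'
#' @param n_nodes number of proteins.
#' @param attach_edges preferential-attachment edges per new node; 4
#'   matches the ~12600 edges / ~3100 nodes density of the yeast network.
#' @param weight_law background edge-weight law:
#'   `list(dist = "beta", shape1, shape2)` or `list(dist = "fixed", r)`.
#' @param n_complexes number of planted complexes.
#' @param complex_size_range inclusive size range of planted complexes.
#' @param intra_reliability minimum reliability of intra-complex edges.
#' @param seed integer seed.
#' @return `list(network = prob_network, complexes = list of
#'   list(id, members))`.
#' @export
generate_network <- function(n_nodes = 3112L, attach_edges = 4L,
                             weight_law = list(dist = "beta",
                                               shape1 = 1, shape2 = 3),
                             n_complexes = 27L,
                             complex_size_range = c(3L, 15L),
                             intra_reliability = 0.9, seed = 1L) {
  stopifnot(n_nodes >= 2, attach_edges >= 1, n_complexes >= 0,
            intra_reliability > 0, intra_reliability <= 1)
  set.seed(seed)
  size_pool <- seq(complex_size_range[1L], complex_size_range[2L])
  sizes <- if (n_complexes > 0)
    size_pool[sample.int(length(size_pool), n_complexes, replace = TRUE)]
  else integer()
  if (sum(sizes) > n_nodes)
    stop("infeasible: ", sum(sizes), " complex members exceed ",
         n_nodes, " nodes")
  nodes <- sprintf(paste0("p%0", nchar(n_nodes), "d"), seq_len(n_nodes))
  g <- igraph::sample_pa(n_nodes, m = attach_edges, directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  nE <- nrow(el)
  w <- switch(weight_law$dist,
              beta = stats::rbeta(nE, weight_law$shape1, weight_law$shape2),
              fixed = rep(weight_law$r, nE),
              stop("unknown weight law: ", weight_law$dist))
  w <- pmin(pmax(w, 1e-4), 1)
  edges <- data.frame(from = nodes[el[, 1L]], to = nodes[el[, 2L]],
                      reliability = w, stringsAsFactors = FALSE)
  complexes <- list()
  if (n_complexes > 0) {
    pool <- sample(nodes)
    off <- 0L
    for (ci in seq_len(n_complexes)) {
      mem <- sort(pool[off + seq_len(sizes[ci])])
      off <- off + sizes[ci]
      s <- length(mem)
      ord <- sample(mem)
      tree <- data.frame(
        from = ord[-1L],
        to = vapply(seq_len(s - 1L),
                    function(i) ord[sample.int(i, 1L)], ""),
        stringsAsFactors = FALSE)
      allp <- t(utils::combn(mem, 2L))
      target <- ceiling(0.5 * nrow(allp))
      pk <- paste(pmin(allp[, 1L], allp[, 2L]),
                  pmax(allp[, 1L], allp[, 2L]))
      tk <- paste(pmin(tree$from, tree$to), pmax(tree$from, tree$to))
      extra_pool <- which(!pk %in% tk)
      n_extra <- max(0L, target - nrow(tree))
      extra <- if (n_extra > 0)
        extra_pool[sample.int(length(extra_pool),
                              min(n_extra, length(extra_pool)))]
      else integer()
      ce <- rbind(tree,
                  data.frame(from = allp[extra, 1L], to = allp[extra, 2L],
                             stringsAsFactors = FALSE))
      ce$reliability <- stats::runif(nrow(ce), intra_reliability, 1)
      edges <- rbind(edges, ce)
      complexes[[ci]] <- list(id = sprintf("cplx%02d", ci), members = mem)
    }
  }
  list(network = prob_network(edges, isolated = nodes),
       complexes = complexes)
}

#' Leave-one-out complex membership evaluation
#'
#' For every complex and every member, the member is left out, the rest of
#' the complex becomes the query, and all non-query nodes are scored with
#' the chosen method. The left-out member's rank (1-based; ties share the
#' best rank, with the max tie rank also recorded) and score are collected
#' into per-query records, a top-k recovery curve, and the material for
#' per-threshold recall.
#'
#' @param net a [prob_network()].
#' @param complexes list of `list(id, members)`, each with >= 3 members.
#' @param method scoring method: `"netflow"` (exhaustive
#'   [rank_candidates()]), `"netflow_clustered"` ([budgeted_query()] over a
#'   hierarchy), `"mcs"`, or `"rwr"`.
#' @param hierarchy `cluster_hierarchy` for `"netflow_clustered"` (built
#'   with defaults when omitted).
#' @param fraction verification budget for `"netflow_clustered"`.
#' @param n_samples,seed MCS sampling parameters.
#' @param restart_prob RWR restart probability.
#' @param max_k largest k of the recovery curve.
#' @return A `loo_eval`: `records` data frame (complex, left_out, rank,
#'   rank_max, score), `topk` recovery curve, `method`.
#' @export
leave_one_out <- function(net, complexes,
                          method = c("netflow", "netflow_clustered",
                                     "mcs", "rwr"),
                          hierarchy = NULL, fraction = 1.0,
                          n_samples = 1000L, seed = 1L,
                          restart_prob = 0.5, max_k = 25L) {
  method <- match.arg(method)
  stopifnot(length(complexes) > 0)
  if (any(vapply(complexes, function(cp) length(cp$members), 0L) < 3L))
    stop("every complex needs at least 3 members")
  if (method == "netflow_clustered" && is.null(hierarchy))
    hierarchy <- build_hierarchy(net)
  nodes <- network_nodes(net)
  rows <- list()
  qi <- 0L
  for (cp in complexes) {
    for (m in cp$members) {
      qi <- qi + 1L
      q <- setdiff(cp$members, m)
      scores <- switch(method,
        netflow = {
          rk <- rank_candidates(net, q)
          stats::setNames(rk$bound, rk$sink)
        },
        netflow_clustered = {
          rep_ <- budgeted_query(net, hierarchy, q, fraction)
          s <- stats::setNames(rep(0, length(nodes) - length(q)),
                               setdiff(nodes, q))
          s[rep_$answers_df$sink] <- rep_$answers_df$bound
          s
        },
        mcs = {
          sinks <- setdiff(nodes, q)
          stats::setNames(vapply(seq_along(sinks), function(i)
            mcs_reliability(net, q, sinks[i], n_samples = n_samples,
                            seed = seed + 7L * qi + i)$estimate, 0),
            sinks)
        },
        rwr = {
          aff <- random_walk_with_restart(net, q, restart_prob)$affinities
          aff[setdiff(nodes, q)]
        })
      sm <- scores[[m]]
      rows[[qi]] <- data.frame(
        complex = cp$id, left_out = m,
        rank = 1L + sum(scores > sm),
        rank_max = sum(scores >= sm),
        score = sm, stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  ks <- seq_len(max_k)
  topk <- data.frame(k = ks,
                     recovery = vapply(ks, function(k)
                       mean(records$rank <= k), 0))
  structure(list(records = records, topk = topk, method = method),
            class = "loo_eval")
}

#' Per-threshold recall of left-out members
#'
#' For each threshold, the fraction of leave-one-out queries whose
#' left-out member scored at least that threshold; non-increasing in the
#' threshold.
#'
#' @param eval a `loo_eval`.
#' @param thresholds numeric vector of thresholds.
#' @return Named numeric vector of recalls.
#' @export
threshold_recall <- function(eval, thresholds) {
  stopifnot(inherits(eval, "loo_eval"), nrow(eval$records) > 0)
  stats::setNames(vapply(thresholds, function(t)
    mean(eval$records$score >= t), 0), format(thresholds))
}

#' @export
print.loo_eval <- function(x, ...) {
  cat(sprintf("Leave-one-out evaluation (%s): %d queries over %d complexes\n",
              x$method, nrow(x$records), length(unique(x$records$complex))))
  cat(sprintf("  median rank %g | top-1 %.1f%% | top-10 %.1f%%\n",
              stats::median(x$records$rank),
              100 * mean(x$records$rank <= 1),
              100 * mean(x$records$rank <= 10)))
  invisible(x)
}

#' @export
plot.loo_eval <- function(x, ...) {
  graphics::plot(x$topk$k, 100 * x$topk$recovery, type = "b",
                 xlab = "k", ylab = "% queries with left-out member in top-k",
                 ylim = c(0, 100), ...)
  invisible(x)
}
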