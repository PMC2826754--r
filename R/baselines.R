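# Comparison methods: Monte Carlo simulation (MCS) of two-terminal
# reliability, and random walk with restart (RWR). MCS, like Net-Flow,
# does not penalize high-degree nodes but offers no proven bound; RWR
# normalizes the edge weights incident on each node and therefore down-
# weights evidence that routes through hubs.

#' Monte Carlo estimate of two-terminal reliability
#'
#' Each sample keeps every edge independently with its reliability; the
#' sample scores 1 when a kept path of length at most `max_path_len` edges
#' (any length when `NULL`) connects some query member to the sink. The
#' estimate is the sample mean with binomial standard error
#' `sqrt(p(1-p)/n)`. A path-length cutoff of 4 is the literature default
#' for complex membership screens, but it misses genuinely connected pairs
#' whose evidence is still indirect, so no cutoff is applied unless asked.
#'
#' @inheritParams netflow_score
#' @param n_samples number of Monte Carlo samples.
#' @param max_path_len maximum kept-path length in edges, or `NULL` for
#'   unbounded.
#' @param seed integer seed; the estimate is deterministic given the seed.
#' @return An `mcs_estimate`: `sink`, `estimate`, `n_samples`, `stderr`,
#'   `max_path_len`, `seed`.
#' @export
mcs_reliability <- function(net, q, sink, n_samples = 10000L,
                            max_path_len = NULL, seed = 1L) {
  q <- validate_query(net, q)
  stopifnot(n_samples >= 1)
  nodes <- network_nodes(net)
  if (!sink %in% nodes) stop("sink not in network: ", sink)
  if (sink %in% q) stop("sink must not be a query member: ", sink)
  ed <- network_edges(net)
  E <- nrow(ed)
  n <- length(nodes)
  ei <- match(ed$from, nodes); ej <- match(ed$to, nodes)
  src <- match(q, nodes); snk <- match(sink, nodes)
  cutoff <- if (is.null(max_path_len)) Inf else max_path_len
  # adjacency as flat vectors: neighbor + edge index per node
  nb <- vector("list", n)
  for (e in seq_len(E)) {
    nb[[ei[e]]] <- rbind(nb[[ei[e]]], c(ej[e], e))
    nb[[ej[e]]] <- rbind(nb[[ej[e]]], c(ei[e], e))
  }
  connected <- function(kept) {
    dist <- rep(Inf, n)
    dist[src] <- 0
    queue <- src
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (dist[v] >= cutoff) next
      for (rix in seq_len(NROW(nb[[v]]))) {
        w <- nb[[v]][rix, 1L]
        if (kept[nb[[v]][rix, 2L]] && !is.finite(dist[w])) {
          if (w == snk) return(TRUE)
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
      }
    }
    snk %in% src  # unreachable (src == snk excluded above)
  }
  set.seed(seed)
  if (E == 0L) {
    est <- 0
  } else if (E <= 25L && n_samples > 64L) {
    # evaluate connectivity once per distinct edge-state pattern
    kept <- matrix(stats::runif(n_samples * E), n_samples, E) <
      matrix(ed$reliability, n_samples, E, byrow = TRUE)
    keys <- as.vector(kept %*% 2 ^ (seq_len(E) - 1))
    uk <- unique(keys)
    conn <- vapply(uk, function(key) {
      bits <- floor(key / 2 ^ (seq_len(E) - 1)) %% 2 == 1
      connected(bits)
    }, TRUE)
    est <- mean(conn[match(keys, uk)])
  } else {
    hits <- 0L
    for (i in seq_len(n_samples))
      hits <- hits + connected(stats::runif(E) < ed$reliability)
    est <- hits / n_samples
  }
  structure(list(sink = sink, estimate = est, n_samples = n_samples,
                 stderr = sqrt(est * (1 - est) / n_samples),
                 max_path_len = max_path_len, seed = seed),
            class = "mcs_estimate")
}

#' @export
print.mcs_estimate <- function(x, ...) {
  cat(sprintf("MCS reliability of %s: %.6g (se %.3g, n = %d%s)\n",
              x$sink, x$estimate, x$stderr, x$n_samples,
              if (is.null(x$max_path_len)) ""
              else paste0(", cutoff ", x$max_path_len)))
  invisible(x)
}

#' Random walk with restart affinities
#'
#' Simulates a walker that follows column-normalized edge weights (each
#' node's incident weights divided by their sum) and teleports back to the
#' query with probability `restart_prob` at every step; the restart
#' distribution is uniform over query members. The stationary solution of
#' `x = (1 - c) W x + c e` is found by power iteration to an L1 change
#' below 1e-10. Because of the per-node normalization, affinity routed
#' through a high-degree node is diluted -- the behaviour Net-Flow avoids.
#'
#' @inheritParams netflow_score
#' @param restart_prob restart probability in (0, 1); 0.5 is the
#'   conventional choice.
#' @param max_iter iteration cap for the power method.
#' @return An `rwr_affinity`: named `affinities` vector summing to 1 and
#'   `restart_prob`.
#' @export
random_walk_with_restart <- function(net, q, restart_prob = 0.5,
                                     max_iter = 100000L) {
  q <- validate_query(net, q)
  stopifnot(restart_prob > 0, restart_prob < 1)
  nodes <- network_nodes(net)
  A <- igraph::as_adjacency_matrix(net$graph, attr = "reliability",
                                   sparse = FALSE)
  A <- A[nodes, nodes]
  cs <- colSums(A)
  if (any(cs[q] == 0))
    stop("query node(s) with zero-weight degree: ",
         paste(q[cs[q] == 0], collapse = ", "))
  W <- sweep(A, 2L, ifelse(cs > 0, cs, 1), "/")
  e <- stats::setNames(rep(0, length(nodes)), nodes)
  e[q] <- 1 / length(q)
  x <- e
  for (it in seq_len(max_iter)) {
    xn <- (1 - restart_prob) * as.vector(W %*% x) + restart_prob * e
    if (sum(abs(xn - x)) < 1e-10) { x <- xn; break }
    x <- xn
  }
  structure(list(affinities = stats::setNames(as.vector(x), nodes),
                 restart_prob = restart_prob, iterations = it),
            class = "rwr_affinity")
}

#' @export
print.rwr_affinity <- function(x, n = 10L, ...) {
  cat(sprintf("RWR affinities (restart %.3g, %d iterations)\n",
              x$restart_prob, x$iterations))
  print(utils::head(sort(x$affinities, decreasing = TRUE), n))
  invisible(x)
}
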