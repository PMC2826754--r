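# Flat and hierarchical clusterings of the network. Two flat schemes:
# spectral clustering on the interaction-probability similarity matrix,
# and Nearest Neighbor Clustering (NNC), a greedy size-constrained
# agglomeration over edges in decreasing weight order. NNC is designed so
# that the maximum-weight edge *between* clusters stays low (that edge is
# what the cluster graph keeps) and cluster sizes stay near-uniform.
# Hierarchies come from applying NNC recursively to the cluster graph of
# the level below.

# Greedy NNC engine, shared by the flat network clustering and the
# level-above-level hierarchy construction. `node_sizes` counts protein
# members per item, so the size constraint is always in proteins.
# Edges in decreasing weight, ties by lexicographic (from, to); any action
# whose result would exceed max_size is skipped, never split.
.nnc_core <- function(edges, node_ids, node_sizes, max_size) {
  assign <- stats::setNames(rep(NA_integer_, length(node_ids)), node_ids)
  sizes <- stats::setNames(as.numeric(node_sizes), node_ids)
  csize <- numeric(0)
  members <- list()
  nxt <- 0L
  if (nrow(edges)) {
    o <- order(-edges$weight, edges$from, edges$to)
    for (i in o) {
      u <- edges$from[i]; v <- edges$to[i]
      au <- assign[[u]]; av <- assign[[v]]
      if (is.na(au) && is.na(av)) {
        if (sizes[[u]] + sizes[[v]] <= max_size) {
          nxt <- nxt + 1L
          assign[[u]] <- nxt; assign[[v]] <- nxt
          csize[nxt] <- sizes[[u]] + sizes[[v]]
          members[[nxt]] <- c(u, v)
        }
      } else if (is.na(av)) {
        if (csize[au] + sizes[[v]] <= max_size) {
          assign[[v]] <- au
          csize[au] <- csize[au] + sizes[[v]]
          members[[au]] <- c(members[[au]], v)
        }
      } else if (is.na(au)) {
        if (csize[av] + sizes[[u]] <= max_size) {
          assign[[u]] <- av
          csize[av] <- csize[av] + sizes[[u]]
          members[[av]] <- c(members[[av]], u)
        }
      } else if (au != av) {
        if (csize[au] + csize[av] <= max_size) {
          assign[members[[av]]] <- au
          csize[au] <- csize[au] + csize[av]
          members[[au]] <- c(members[[au]], members[[av]])
          members[[av]] <- character()
          csize[av] <- 0
        }
      }
    }
  }
  groups <- members[vapply(members, length, 0L) > 0L]
  groups <- c(groups, as.list(node_ids[is.na(assign)]))  # singletons last
  groups <- lapply(groups, sort)
  groups[order(vapply(groups, `[`, "", 1L))]
}

# Aggregate network edges that cross between vertex groups: `map` sends a
# node id to its group's vertex id (NA = dropped). Returns the max-weight
# rule of the cluster graph plus the crossing-edge count (multiplicity).
.aggregate_cross_edges <- function(ed, map) {
  va <- unname(map[ed$from]); vb <- unname(map[ed$to])
  keep <- !is.na(va) & !is.na(vb) & va != vb
  if (!any(keep))
    return(data.frame(from = character(), to = character(),
                      weight = numeric(), multiplicity = integer(),
                      stringsAsFactors = FALSE))
  a <- pmin(va[keep], vb[keep]); b <- pmax(va[keep], vb[keep])
  key <- paste(a, b, sep = "\r")
  w <- tapply(ed$reliability[keep], key, max)
  m <- tapply(rep(1L, sum(keep)), key, sum)
  parts <- strsplit(names(w), "\r", fixed = TRUE)
  df <- data.frame(from = vapply(parts, `[`, "", 1L),
                   to   = vapply(parts, `[`, "", 2L),
                   weight = as.numeric(w), multiplicity = as.integer(m),
                   stringsAsFactors = FALSE)
  df[order(df$from, df$to), , drop = FALSE]
}

.make_cluster <- function(id, members, level = 0L, children = character()) {
  list(id = id, members = sort(members), level = as.integer(level),
       children = children)
}

#' Nearest Neighbor Clustering with a size constraint
#'
#' Greedy agglomeration over edges in decreasing weight order: both
#' endpoints unassigned starts a new cluster, one assigned absorbs the
#' other, two different clusters merge — except that any action whose
#' resulting cluster would exceed `max_size` members is skipped. Weight
#' ties break by lexicographic edge order, so output is deterministic.
#' Nodes left unassigned become singleton clusters.
#'
#' @param net a [prob_network()].
#' @param max_size maximum cluster size in nodes (>= 2). The default 100
#'   matches the size constraint that yields ~65 clusters on a
#'   3112-protein yeast-scale network.
#' @return List of flat clusters, each `list(id, members, level = 0,
#'   children = character())`, ordered by smallest member id.
#' @export
nnc_cluster <- function(net, max_size = 100L) {
  stopifnot(inherits(net, "prob_network"), max_size >= 2)
  nodes <- network_nodes(net)
  groups <- .nnc_core(
    stats::setNames(network_edges(net)[c("from", "to", "reliability")],
                    c("from", "to", "weight")),
    nodes, rep(1, length(nodes)), max_size)
  fmt <- paste0("C%0", nchar(length(groups)), "d")
  lapply(seq_along(groups),
         function(i) .make_cluster(sprintf(fmt, i), groups[[i]]))
}

#' Spectral clustering of the interaction network
#'
#' The interaction network provides a similarity matrix directly: entry
#' M(i, j) is the probability that proteins i and j interact. The rows of
#' the eigenvector matrix for the k largest eigenvalues of M are clustered
#' by k-means (10 random restarts, best within-cluster sum of squares
#' kept; deterministic given `seed`). When fewer than k distinct embedded
#' rows exist, the cluster count drops to the number of distinct rows.
#'
#' @inheritParams nnc_cluster
#' @param k number of clusters, `2 <= k <= |nodes|`.
#' @param seed integer seed for the k-means restarts.
#' @param normalized use the symmetric normalized Laplacian embedding
#'   instead of the raw similarity matrix (off by default).
#' @return List of flat clusters as in [nnc_cluster()].
#' @export
spectral_cluster <- function(net, k, seed = 1L, normalized = FALSE) {
  stopifnot(inherits(net, "prob_network"))
  nodes <- network_nodes(net)
  n <- length(nodes)
  if (k < 2 || k > n) stop("k must be in [2, ", n, "]")
  M <- igraph::as_adjacency_matrix(net$graph, attr = "reliability",
                                   sparse = FALSE)
  M <- M[nodes, nodes]
  if (normalized) {
    dg <- pmax(rowSums(M), .Machine$double.eps)
    Di <- 1 / sqrt(dg)
    M <- diag(n) - (Di * M) %*% diag(Di)
    M <- -M  # largest eigenvalues of -L_sym ~ smallest of L_sym
  }
  ev <- eigen(M, symmetric = TRUE)
  U <- ev$vectors[, seq_len(k), drop = FALSE]
  keyU <- apply(round(U, 10L), 1L, paste, collapse = ",")
  uniq <- unique(round(U, 10L))
  k_eff <- min(k, nrow(uniq))
  set.seed(seed)
  if (k_eff == nrow(uniq)) {
    # every distinct embedded row is its own centre; k-means is a no-op
    assignment <- match(keyU, unique(keyU))
  } else {
    best <- NULL
    for (rep in seq_len(10L)) {
      ctr <- uniq[sample.int(nrow(uniq), k_eff), , drop = FALSE]
      km <- suppressWarnings(stats::kmeans(U, centers = ctr,
                                           iter.max = 100L))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    assignment <- best$cluster
  }
  groups <- split(nodes, assignment)
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[`, "", 1L))]
  fmt <- paste0("S%0", nchar(length(groups)), "d")
  lapply(seq_along(groups),
         function(i) .make_cluster(sprintf(fmt, i), groups[[i]]))
}

#' Build a cluster hierarchy by recursive NNC
#'
#' Leaves come from [nnc_cluster()] at `leaf_size`; each higher level runs
#' NNC on the cluster graph of the level below (max-weight inter-cluster
#' edges) with the next size bound, counted in protein members. Clusters
#' that do not merge at a level are carried upward unchanged and may merge
#' later; whatever remains after the last level forms the roots.
#'
#' @inheritParams nnc_cluster
#' @param leaf_size size bound for leaf clusters.
#' @param level_sizes strictly increasing member-count bounds, starting at
#'   `leaf_size`; one NNC pass runs per additional entry. The defaults give
#'   3-4 levels on a yeast-scale (~3000 node) network.
#' @return A `cluster_hierarchy`: `clusters` (named list of cluster
#'   records) and `roots` (top-level cluster ids).
#' @export
build_hierarchy <- function(net, leaf_size = 100L,
                            level_sizes = c(100, 400, 1600, Inf)) {
  stopifnot(inherits(net, "prob_network"))
  if (level_sizes[1L] != leaf_size)
    stop("level_sizes must start at leaf_size")
  if (any(diff(level_sizes) <= 0))
    stop("level_sizes must be strictly increasing")
  leaves <- nnc_cluster(net, max_size = leaf_size)
  all <- stats::setNames(leaves, vapply(leaves, `[[`, "", "id"))
  current <- all
  ed <- network_edges(net)
  for (li in seq_along(level_sizes)[-1L]) {
    if (length(current) <= 1L) break
    ids <- names(current)
    map <- unlist(lapply(ids, function(id)
      stats::setNames(rep(id, length(current[[id]]$members)),
                      current[[id]]$members)))
    ce <- .aggregate_cross_edges(ed, map)
    groups <- .nnc_core(ce, ids,
                        vapply(current, function(cl) length(cl$members), 0),
                        level_sizes[li])
    nxt <- list(); counter <- 0L
    for (grp in groups) {
      if (length(grp) == 1L) {
        nxt[[grp]] <- current[[grp]]  # carried forward unchanged
      } else {
        counter <- counter + 1L
        id <- sprintf("L%d_%03d", li - 1L, counter)
        rec <- .make_cluster(id,
                             unlist(lapply(current[grp], `[[`, "members")),
                             level = li - 1L, children = sort(grp))
        all[[id]] <- rec
        nxt[[id]] <- rec
      }
    }
    current <- nxt
  }
  structure(list(clusters = all, roots = sort(names(current))),
            class = "cluster_hierarchy")
}

#' Trivial hierarchy with one singleton leaf per node
#'
#' Every node becomes its own leaf cluster and a root. With this
#' degenerate hierarchy the cluster graph is isomorphic to the network and
#' cluster bounds equal the plain Net-Flow bounds, which makes it the
#' exactness reference for the pruned search.
#'
#' @inheritParams nnc_cluster
#' @return A `cluster_hierarchy`.
#' @export
singleton_hierarchy <- function(net) {
  nodes <- network_nodes(net)
  recs <- lapply(nodes, function(v) .make_cluster(v, v))
  ids <- vapply(recs, `[[`, "", "id")
  structure(list(clusters = stats::setNames(recs, ids), roots = sort(ids)),
            class = "cluster_hierarchy")
}

#' @export
print.cluster_hierarchy <- function(x, ...) {
  lv <- vapply(x$clusters, `[[`, 0L, "level")
  cat("Cluster hierarchy:", length(x$clusters), "clusters,",
      length(x$roots), "root(s)\n")
  for (l in sort(unique(lv)))
    cat(sprintf("  level %d: %d cluster(s)\n", l, sum(lv == l)))
  invisible(x)
}

#' Hierarchy JSON serialization
#'
#' `write_hierarchy()` stores `{"clusters": [{id, level, members,
#' children}], "roots": [...]}`; `read_hierarchy()` restores it.
#'
#' @param h a `cluster_hierarchy`.
#' @param path JSON file path.
#' @return `path` invisibly, or the restored `cluster_hierarchy`.
#' @export
write_hierarchy <- function(h, path) {
  stopifnot(inherits(h, "cluster_hierarchy"))
  obj <- list(clusters = unname(lapply(h$clusters, function(cl)
    list(id = cl$id, level = cl$level, members = as.list(cl$members),
         children = as.list(cl$children)))),
    roots = as.list(h$roots))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_hierarchy
#' @export
read_hierarchy <- function(path) {
  obj <- jsonlite::read_json(path)
  recs <- lapply(obj$clusters, function(cl)
    .make_cluster(cl$id, unlist(cl$members), cl$level,
                  children = sort(as.character(unlist(cl$children)))))
  ids <- vapply(recs, `[[`, "", "id")
  structure(list(clusters = stats::setNames(recs, ids),
                 roots = sort(as.character(unlist(obj$roots)))),
            class = "cluster_hierarchy")
}
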