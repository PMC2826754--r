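# Data model and file I/O for probabilistic interaction networks.
#
# A prob_network is a simple undirected graph whose edges carry the
# probability (0, 1] that the interaction is functional. Internally the
# object wraps an igraph graph with a "reliability" edge attribute; node
# identifiers are opaque, case-sensitive strings.

#' Construct a probabilistic interaction network
#'
#' Builds a validated `prob_network` from an edge table. The graph is
#' undirected and simple: self-loops are rejected, duplicate rows for the
#' same unordered pair are collapsed keeping the maximum probability (the
#' same max rule used for cluster-graph edges), and every reliability must
#' lie in (0, 1]. A reliability of exactly 0 is rejected rather than kept:
#' a never-functional edge cannot contribute to any bound.
#'
#' @param edges data frame (or coercible) with columns `from`, `to`,
#'   `reliability` (the first three columns are used positionally if the
#'   names differ).
#' @param isolated optional character vector of additional node ids with no
#'   incident edges.
#' @return An object of class `prob_network`.
#' @examples
#' net <- prob_network(data.frame(from = c("a", "b"), to = c("b", "c"),
#'                                reliability = c(0.6, 0.6)))
#' network_nodes(net)
#' @export
prob_network <- function(edges, isolated = character()) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 3L)
    stop("`edges` needs three columns: from, to, reliability")
  df <- data.frame(from = as.character(edges[[1L]]),
                   to   = as.character(edges[[2L]]),
                   reliability = as.numeric(edges[[3L]]),
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L && length(isolated) == 0L)
    stop("empty network: no edges and no nodes")
  if (anyNA(df$reliability))
    stop("non-numeric reliability value")
  if (any(df$from == df$to))
    stop("self-loops are not allowed: ",
         paste(unique(df$from[df$from == df$to]), collapse = ", "))
  bad <- df$reliability <= 0 | df$reliability > 1
  if (any(bad))
    stop("edge reliability outside (0, 1] for pair(s): ",
         paste(paste0(df$from[bad], "-", df$to[bad]), collapse = ", "))
  # canonical unordered pair; keep-max collapse of duplicates
  a <- pmin(df$from, df$to)
  b <- pmax(df$from, df$to)
  key <- paste(a, b, sep = "\r")
  r <- tapply(df$reliability, key, max)
  keys <- names(r)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  cdf <- data.frame(from = vapply(parts, `[`, "", 1L),
                    to   = vapply(parts, `[`, "", 2L),
                    reliability = as.numeric(r),
                    stringsAsFactors = FALSE)
  cdf <- cdf[order(cdf$from, cdf$to), , drop = FALSE]
  rownames(cdf) <- NULL
  verts <- sort(unique(c(cdf$from, cdf$to, as.character(isolated))))
  g <- igraph::graph_from_data_frame(cdf, directed = FALSE, vertices = verts)
  structure(list(graph = g), class = "prob_network")
}

#' @export
print.prob_network <- function(x, ...) {
  cat("Probabilistic interaction network:",
      igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "edges\n")
  if (igraph::ecount(x$graph) > 0L) {
    r <- igraph::E(x$graph)$reliability
    cat(sprintf("  edge reliability: min %.4g, median %.4g, max %.4g\n",
                min(r), stats::median(r), max(r)))
  }
  invisible(x)
}

#' @export
summary.prob_network <- function(object, ...) {
  g <- object$graph
  out <- list(n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
              degree = summary(igraph::degree(g)),
              reliability = if (igraph::ecount(g)) summary(igraph::E(g)$reliability))
  class(out) <- "summary.prob_network"
  out
}

#' @export
print.summary.prob_network <- function(x, ...) {
  cat("Nodes:", x$n_nodes, " Edges:", x$n_edges, "\n")
  cat("Degree distribution:\n"); print(x$degree)
  if (!is.null(x$reliability)) {
    cat("Edge reliabilities:\n"); print(x$reliability)
  }
  invisible(x)
}

#' Network accessors
#'
#' `network_nodes()` returns the sorted node ids; `network_edges()` returns
#' the canonical edge table (`from < to` lexicographically, rows sorted).
#'
#' @param net a `prob_network`.
#' @return Character vector of node ids, or a data frame with columns
#'   `from`, `to`, `reliability`.
#' @export
network_nodes <- function(net) {
  stopifnot(inherits(net, "prob_network"))
  sort(igraph::V(net$graph)$name)
}

#' @rdname network_nodes
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "prob_network"))
  g <- net$graph
  if (igraph::ecount(g) == 0L)
    return(data.frame(from = character(), to = character(),
                      reliability = numeric(), stringsAsFactors = FALSE))
  el <- igraph::as_edgelist(g)
  df <- data.frame(from = pmin(el[, 1L], el[, 2L]),
                   to   = pmax(el[, 1L], el[, 2L]),
                   reliability = igraph::E(g)$reliability,
                   stringsAsFactors = FALSE)
  df <- df[order(df$from, df$to), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a probabilistic network from a text file
#'
#' Two dialects are supported. `tsv`: whitespace- or tab-separated rows
#' `node_a node_b probability`. `sif`: rows `node_a pp node_b probability`.
#' Lines starting with `#` and blank lines are ignored. Duplicate rows for
#' one unordered pair collapse to the maximum probability; malformed rows
#' and probabilities outside (0, 1] raise an error naming the line.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"sif"`.
#' @return A `prob_network`.
#' @export
read_network <- function(path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("empty network file: ", path)
  ntok <- if (format == "tsv") 3L else 4L
  from <- to <- character(length(idx)); r <- numeric(length(idx))
  for (i in seq_along(idx)) {
    tok <- strsplit(trimws(lines[idx[i]]), "[ \t]+")[[1L]]
    if (length(tok) != ntok)
      stop(sprintf("malformed row at line %d of %s: expected %d fields, got %d",
                   idx[i], path, ntok, length(tok)))
    if (format == "sif" && tok[2L] != "pp")
      stop(sprintf("malformed row at line %d of %s: expected interaction type 'pp'",
                   idx[i], path))
    from[i] <- tok[1L]
    to[i] <- tok[if (format == "tsv") 2L else 3L]
    p <- suppressWarnings(as.numeric(tok[ntok]))
    if (is.na(p))
      stop(sprintf("malformed row at line %d of %s: probability '%s' is not numeric",
                   idx[i], path, tok[ntok]))
    if (p <= 0 || p > 1)
      stop(sprintf("line %d of %s: probability %g outside (0, 1]", idx[i], path, p))
    r[i] <- p
  }
  if (any(from == to)) {
    bad <- idx[from == to][1L]
    stop(sprintf("line %d of %s: self-loop rejected", bad, path))
  }
  prob_network(data.frame(from = from, to = to, reliability = r,
                          stringsAsFactors = FALSE))
}

#' Write a probabilistic network to a text file
#'
#' Round-trips with [read_network()]: probabilities are printed with 8
#' significant digits.
#'
#' @param net a `prob_network`.
#' @param path output file path.
#' @param format `"tsv"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "prob_network"))
  df <- network_edges(net)
  if (nrow(df) == 0L) stop("refusing to write a network with no edges")
  lines <- if (format == "tsv") {
    sprintf("%s\t%s\t%.8g", df$from, df$to, df$reliability)
  } else {
    sprintf("%s\tpp\t%s\t%.8g", df$from, df$to, df$reliability)
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) stop("cannot write to ", path, ": ",
                                          conditionMessage(e)))
  invisible(path)
}

#' Validate a query set against a network
#'
#' A query is the set of proteins of a partially known complex or pathway.
#' Every member must be a node of the network; duplicates are collapsed
#' with a warning.
#'
#' @param net a `prob_network`.
#' @param q character vector of node ids.
#' @return The validated query (character vector).
#' @export
validate_query <- function(net, q) {
  stopifnot(inherits(net, "prob_network"))
  q <- as.character(q)
  if (length(q) == 0L) stop("empty query")
  if (anyDuplicated(q)) {
    warning("duplicate query members collapsed")
    q <- unique(q)
  }
  missing <- setdiff(q, igraph::V(net$graph)$name)
  if (length(missing))
    stop("query members not in network: ", paste(missing, collapse = ", "))
  q
}

#' Read a query file (one node id per line)
#'
#' @param path file path; `#` comments and blank lines ignored.
#' @return Character vector of node ids.
#' @export
read_query <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  q <- lines[!grepl("^(#|$)", lines)]
  if (length(q) == 0L) stop("empty query file: ", path)
  q
}
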