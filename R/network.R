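#' Build a network object from an edge table
#'
#' Canonical network container used throughout crankr: an undirected simple
#' graph with optional edge weights in (0, 1]. Edges are canonicalized so each
#' unordered pair appears once; duplicate rows collapse to the maximum weight;
#' self-loops are dropped (with a message). Directed input is symmetrized by
#' default (edge present if either direction is, weight = max), or refused
#' when `strict = TRUE`.
#'
#' @param edges A data frame whose first two columns are node IDs and whose
#'   optional third column is an edge weight in (0, 1].
#' @param directed Is the input edge table directed? Directed edges are
#'   symmetrized unless `strict = TRUE`.
#' @param strict Refuse directed input instead of symmetrizing.
#' @return An object of class `crank_network`.
#' @examples
#' net <- as_crank_network(data.frame(from = c("a", "b"), to = c("b", "c")))
#' net
#' @export
as_crank_network <- function(edges, directed = FALSE, strict = FALSE) {
  if (inherits(edges, "crank_network")) {
    return(edges)
  }
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2) {
    abort("`edges` must have at least two columns (endpoints).")
  }
  if (directed && strict) {
    abort("directed input refused in strict mode; symmetrize explicitly or set strict = FALSE.")
  }
  from <- as.character(edges[[1]])
  to <- as.character(edges[[2]])
  w <- if (ncol(edges) >= 3) as.numeric(edges[[3]]) else rep(1, length(from))
  if (anyNA(from) || anyNA(to) || anyNA(w)) {
    abort("edge table contains missing endpoints or weights.")
  }
  if (any(w <= 0 | w > 1)) {
    abort("edge weights must lie in (0, 1].")
  }
  loops <- from == to
  if (any(loops)) {
    inform(sprintf("dropping %d self-loop(s)", sum(loops)))
    from <- from[!loops]
    to <- to[!loops]
    w <- w[!loops]
  }
  nodes <- unique(c(from, to))
  i <- match(from, nodes)
  j <- match(to, nodes)
  # canonical unordered form, duplicates keep the maximum weight
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  key <- paste(lo, hi)
  keep <- !duplicated(key)
  w_max <- tapply(w, factor(key, levels = key[keep]), max)
  new_crank_network(nodes, lo[keep], hi[keep], as.numeric(w_max))
}

new_crank_network <- function(nodes, i, j, w) {
  n <- length(nodes)
  ord <- order(i, j)
  i <- i[ord]; j <- j[ord]; w <- w[ord]
  deg <- numeric(n)
  for (k in seq_along(i)) {
    deg[i[k]] <- deg[i[k]] + w[k]
    deg[j[k]] <- deg[j[k]] + w[k]
  }
  adj <- vector("list", n)
  adjw <- vector("list", n)
  if (length(i)) {
    ends <- c(i, j)
    other <- c(j, i)
    ww <- c(w, w)
    o <- order(ends)
    split_idx <- split(seq_along(ends)[o], ends[o])
    for (u in names(split_idx)) {
      idx <- split_idx[[u]]
      adj[[as.integer(u)]] <- other[idx]
      adjw[[as.integer(u)]] <- ww[idx]
    }
  }
  for (u in seq_len(n)) {
    if (is.null(adj[[u]])) {
      adj[[u]] <- integer(0)
      adjw[[u]] <- numeric(0)
    }
  }
  structure(
    list(
      nodes = nodes,
      n = n,
      i = i, j = j, w = w,
      deg = deg,
      m = sum(w),
      m_count = length(i),
      adj = adj,
      adjw = adjw
    ),
    class = "crank_network"
  )
}

#' @export
print.crank_network <- function(x, ...) {
  cat(sprintf(
    "<crank_network> %d nodes, %d edges%s (total edge weight %.6g)\n",
    x$n, x$m_count,
    if (all(x$w == 1)) "" else " (weighted)",
    x$m
  ))
  invisible(x)
}

#' @rdname as_crank_network
#' @param x A `crank_network`.
#' @export
is_crank_network <- function(x) inherits(x, "crank_network")

#' Edge table of a network
#'
#' @param net A `crank_network`.
#' @return A tibble with columns `from`, `to`, `weight`.
#' @export
network_edges <- function(net) {
  stopifnot(is_crank_network(net))
  tibble(
    from = net$nodes[net$i],
    to = net$nodes[net$j],
    weight = net$w
  )
}

#' Node IDs of a network
#'
#' @param net A `crank_network`.
#' @export
network_nodes <- function(net) {
  stopifnot(is_crank_network(net))
  net$nodes
}

#' Convert to an igraph graph
#'
#' @param net A `crank_network`.
#' @return An undirected [igraph::graph] with a `weight` edge attribute.
#' @export
as_igraph <- function(net) {
  stopifnot(is_crank_network(net))
  g <- igraph::graph_from_edgelist(
    cbind(net$nodes[net$i], net$nodes[net$j]),
    directed = FALSE
  )
  igraph::E(g)$weight <- net$w
  g
}

#' Read a whitespace-separated edge list
#'
#' Each non-comment line holds two node IDs and an optional weight in (0, 1].
#' Lines starting with `#` are skipped; duplicate edges collapse to the
#' maximum weight.
#'
#' @param path Path to the edge list file.
#' @inheritParams as_crank_network
#' @return A `crank_network`.
#' @export
read_edge_list <- function(path, directed = FALSE, strict = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("edge list file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  nf <- lengths(fields)
  if (any(bad <- !(nf %in% c(2L, 3L)))) {
    abort(sprintf(
      "malformed edge list line %d: expected 2 or 3 fields, got %d",
      which(keep)[which(bad)[1]], nf[which(bad)[1]]
    ))
  }
  from <- vapply(fields, `[[`, character(1), 1L)
  to <- vapply(fields, `[[`, character(1), 2L)
  w <- vapply(fields, function(f) {
    if (length(f) == 3L) suppressWarnings(as.numeric(f[[3]])) else 1
  }, numeric(1))
  if (anyNA(w)) {
    abort(sprintf(
      "malformed edge list line %d: weight is not a number",
      which(keep)[which(is.na(w))[1]]
    ))
  }
  as_crank_network(data.frame(from, to, w), directed = directed, strict = strict)
}

node_index <- function(net, ids, context = "node") {
  idx <- match(as.character(ids), net$nodes)
  if (anyNA(idx)) {
    abort(sprintf(
      "%s ID(s) not in network: %s", context,
      paste(utils::head(as.character(ids)[is.na(idx)], 5), collapse = ", ")
    ))
  }
  idx
}
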