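#' The probabilistic community-model contract
#'
#' The prioritization metrics can run downstream of any community detection
#' method that exposes three quantities: the probability `p_C(u)` that node
#' `u` belongs to community `C`, the probability `p(u, v)` of an edge, and
#' the contribution `p_C(u, v)` of community `C` towards that edge. A
#' `crank_model` bundles vectorized accessors for the three quantities
#' together with the network and the detected communities.
#'
#' Two providers ship with the package: [crisp_model()] adapts a hard
#' (crisp) community assignment, and [fit_affiliation_model()] fits a
#' noisy-OR affiliation model whose fit satisfies the contract.
#'
#' @param net A `crank_network`.
#' @param communities Tibble with columns `community`, `node`.
#' @param p_member `function(u_idx, community_id)` vectorized over node
#'   indices.
#' @param p_edge `function(u_idx, v_idx)` vectorized over pairs.
#' @param p_comm_edge `function(u_idx, v_idx, community_id)` vectorized over
#'   pairs.
#' @param provider Character label used in contract-violation errors.
#' @return An object of class `crank_model`.
#' @export
new_crank_model <- function(net, communities, p_member, p_edge, p_comm_edge,
                            provider = "custom") {
  stopifnot(is_crank_network(net), is.function(p_member),
            is.function(p_edge), is.function(p_comm_edge))
  structure(
    list(
      net = net,
      communities = validate_communities(communities, net),
      p_member = p_member,
      p_edge = p_edge,
      p_comm_edge = p_comm_edge,
      provider = provider
    ),
    class = "crank_model"
  )
}

#' @export
print.crank_model <- function(x, ...) {
  cat(sprintf(
    "<crank_model> provider '%s': %d communities on %d nodes\n",
    x$provider, length(unique(x$communities$community)), x$net$n
  ))
  invisible(x)
}

check_prob <- function(p, what, provider) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort(sprintf(
      "contract violation by provider '%s': %s outside [0, 1]",
      provider, what
    ))
  }
  p
}

# internal accessors on node indices, with contract validation
model_member <- function(model, u_idx, cid) {
  unname(check_prob(model$p_member(u_idx, cid),
                    sprintf("p_C(u) for community %s", cid), model$provider))
}

model_edge <- function(model, u_idx, v_idx) {
  unname(check_prob(model$p_edge(u_idx, v_idx), "p(u,v)", model$provider))
}

model_comm_edge <- function(model, u_idx, v_idx, cid) {
  unname(check_prob(model$p_comm_edge(u_idx, v_idx, cid),
                    sprintf("p_C(u,v) for community %s", cid), model$provider))
}

#' Query the three contract quantities by node ID
#'
#' @param model A `crank_model`.
#' @param u,v Node IDs.
#' @param community A community ID.
#' @return Numeric vector of probabilities.
#' @export
membership_prob <- function(model, u, community) {
  model_member(model, node_index(model$net, u), as.character(community))
}

#' @rdname membership_prob
#' @export
edge_prob <- function(model, u, v) {
  model_edge(model, node_index(model$net, u), node_index(model$net, v))
}

#' @rdname membership_prob
#' @export
comm_edge_prob <- function(model, u, v, community) {
  model_comm_edge(model, node_index(model$net, u), node_index(model$net, v),
                  as.character(community))
}

#' Crisp-partition adapter
#'
#' Wraps a hard community assignment as a `crank_model`: membership is 0/1,
#' the edge probability is the observed edge weight (0 for non-edges), and
#' the community contribution `p_C(u,v)` equals the edge weight when both
#' endpoints belong to `C` and the edge is observed, else 0. This lets the
#' prioritization run downstream of any detection method, probabilistic or
#' not.
#'
#' @param net A `crank_network`.
#' @param comms Tibble with columns `community`, `node` (overlap allowed).
#' @return A `crank_model`.
#' @examples
#' net <- as_crank_network(data.frame(from = c("a", "b"), to = c("b", "c")))
#' m <- crisp_model(net, data.frame(community = "0", node = c("a", "b")))
#' edge_prob(m, "a", "b")
#' @export
crisp_model <- function(net, comms) {
  stopifnot(is_crank_network(net))
  comms <- validate_communities(comms, net)
  member <- lapply(community_index_list(comms, net), function(idx) {
    z <- logical(net$n); z[idx] <- TRUE; z
  })
  # edge weight lookup: hashed environment keyed "lo hi"
  wtab <- new.env(parent = emptyenv(), size = 2L * max(1L, net$m_count))
  for (k in seq_len(net$m_count)) {
    assign(paste(net$i[k], net$j[k]), net$w[k], envir = wtab)
  }
  edge_w <- function(ui, vi) {
    keys <- paste(pmin(ui, vi), pmax(ui, vi))
    vapply(keys, function(k) {
      w <- wtab[[k]]
      if (is.null(w)) 0 else w
    }, numeric(1), USE.NAMES = FALSE)
  }
  get_member <- function(cid) {
    mb <- member[[as.character(cid)]]
    if (is.null(mb)) abort(sprintf("unknown community ID: %s", cid))
    mb
  }
  new_crank_model(
    net, comms,
    p_member = function(u_idx, cid) as.numeric(get_member(cid)[u_idx]),
    p_edge = edge_w,
    p_comm_edge = function(u_idx, v_idx, cid) {
      mb <- get_member(cid)
      edge_w(u_idx, v_idx) * as.numeric(mb[u_idx] & mb[v_idx])
    },
    provider = "crisp"
  )
}
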