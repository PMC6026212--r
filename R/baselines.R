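internal_weight <- function(net, idx) {
  ie <- internal_edges(net, idx)
  if (length(ie)) sum(net$w[ie]) else 0
}

#' Baseline community rankings
#'
#' Three reference orderings against which the robustness-based
#' prioritization is compared. `modularity_rank` scores every community by
#' its contribution to Newman modularity, \eqn{e_C/m - (vol_C/2m)^2}, where
#' `e_C` is the internal edge weight and `vol_C` the summed (weighted)
#' degree of the members, and ranks by decreasing score. `conductance_rank`
#' scores by \eqn{\phi(C) = cut(C) / \min(vol(C), vol(V \setminus C))} and
#' ranks ascending (well-separated communities first); a community with zero
#' volume gets \eqn{\phi = 1} (worst). `random_rank` is a seeded uniform
#' random permutation. Communities may overlap; each is scored
#' independently.
#'
#' @param net A `crank_network` with at least one edge.
#' @param comms Tibble with columns `community`, `node`.
#' @return A tibble with columns `community`, `score`, `rank`, `method`.
#' @examples
#' net <- as_crank_network(data.frame(from = c("a", "b", "c"),
#'                                    to = c("b", "c", "a")))
#' modularity_rank(net, data.frame(community = "0", node = c("a", "b", "c")))
#' @export
modularity_rank <- function(net, comms) {
  stopifnot(is_crank_network(net))
  comms <- validate_communities(comms, net)
  if (net$m <= 0) abort("modularity undefined on an edgeless network.")
  idx_list <- community_index_list(comms, net)
  score <- vapply(idx_list, function(idx) {
    internal_weight(net, idx) / net$m - (sum(net$deg[idx]) / (2 * net$m))^2
  }, numeric(1))
  out <- ranks_from_scores(tibble(community = names(idx_list), score = score))
  out$method <- "modularity"
  out
}

#' @rdname modularity_rank
#' @export
conductance_rank <- function(net, comms) {
  stopifnot(is_crank_network(net))
  comms <- validate_communities(comms, net)
  if (net$m <= 0) abort("conductance undefined on an edgeless network.")
  idx_list <- community_index_list(comms, net)
  phi <- vapply(idx_list, function(idx) community_conductance(net, idx),
                numeric(1))
  # low conductance = high priority: rank ascending phi
  out <- ranks_from_scores(tibble(community = names(idx_list), score = -phi))
  out$score <- -out$score
  out$method <- "conductance"
  out
}

community_conductance <- function(net, idx) {
  vol <- sum(net$deg[idx])
  if (vol <= 0) return(1)
  cut <- vol - 2 * internal_weight(net, idx)
  denom <- min(vol, 2 * net$m - vol)
  if (denom <= 0) {
    return(if (cut <= 0) 0 else 1) # whole-network community has no boundary
  }
  min(1, cut / denom)
}

#' @rdname modularity_rank
#' @param seed Integer seed for the random permutation.
#' @export
random_rank <- function(comms, seed) {
  comms <- validate_communities(comms)
  ids <- community_ids(comms)
  withr::local_seed(as.integer(seed))
  ord <- sample(ids)
  tibble(
    community = ord,
    score = NA_real_,
    rank = seq_along(ord),
    method = "random"
  )
}
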