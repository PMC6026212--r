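# Independent brute-force evaluation of the four metrics: literal loops over
# the public model accessors, kept deliberately naive and separate from the
# vectorized implementations they check.

oracle_clip <- function(p) pmin(pmax(p, 1e-9), 1 - 1e-9)

oracle_q <- function(net, u, v) min(1, net$deg[u] * net$deg[v] / (2 * net$m))

oracle_members <- function(model, cid) {
  sort(match(unique(model$communities$node[model$communities$community == cid]),
             model$net$nodes))
}

oracle_is_edge <- function(net, u, v) {
  any(net$i == min(u, v) & net$j == max(u, v))
}

oracle_pep <- function(net, p, u, v, alpha) {
  (1 - alpha) * p + alpha * oracle_q(net, u, v)
}

oracle_pep_comm <- function(net, pc, pe, u, v, alpha) {
  share <- min(1, pc / max(pe, 1e-9))
  (1 - alpha) * pc + alpha * oracle_q(net, u, v) * share
}

oracle_likelihood <- function(model, cid, alpha) {
  net <- model$net
  mem <- oracle_members(model, cid)
  ids <- net$nodes
  logs <- numeric(0)
  for (u in mem) {
    logs <- c(logs, log(oracle_clip(membership_prob(model, ids[u], cid))))
  }
  for (u in mem) {
    for (v in mem) {
      if (u == v) next
      pc <- comm_edge_prob(model, ids[u], ids[v], cid)
      pe <- edge_prob(model, ids[u], ids[v])
      pca <- oracle_clip(oracle_pep_comm(net, pc, pe, u, v, alpha))
      edge_part <- if (oracle_is_edge(net, u, v)) pca else 1 - pca
      logs <- c(logs,
                log(oracle_clip(membership_prob(model, ids[v], cid))) +
                  log(oracle_clip(edge_part)))
    }
  }
  exp(mean(logs))
}

oracle_density <- function(model, cid, alpha) {
  net <- model$net
  mem <- oracle_members(model, cid)
  logs <- numeric(0)
  for (k in seq_len(net$m_count)) {
    if (net$i[k] %in% mem && net$j[k] %in% mem) {
      pe <- edge_prob(model, net$nodes[net$i[k]], net$nodes[net$j[k]])
      logs <- c(logs, log(oracle_clip(oracle_pep(net, pe, net$i[k], net$j[k], alpha))))
    }
  }
  if (!length(logs)) return(0)
  exp(mean(logs))
}

oracle_boundary <- function(model, cid, alpha) {
  net <- model$net
  mem <- oracle_members(model, cid)
  outside <- setdiff(seq_len(net$n), mem)
  if (!length(outside)) return(1)
  logs <- numeric(0)
  for (u in mem) {
    for (v in outside) {
      pe <- edge_prob(model, net$nodes[u], net$nodes[v])
      pa <- oracle_clip(oracle_pep(net, pe, u, v, alpha))
      logs <- c(logs, log(1 - pa))
    }
  }
  exp(mean(logs))
}

oracle_allegiance <- function(model, cid, alpha) {
  net <- model$net
  mem <- oracle_members(model, cid)
  hits <- 0
  for (u in mem) {
    inside <- 0
    outside <- 0
    for (k in seq_len(net$m_count)) {
      other <- if (net$i[k] == u) net$j[k] else if (net$j[k] == u) net$i[k] else NA
      if (is.na(other)) next
      pe <- edge_prob(model, net$nodes[u], net$nodes[other])
      pa <- oracle_pep(net, pe, u, other, alpha)
      if (other %in% mem) inside <- inside + pa else outside <- outside + pa
    }
    if (inside >= outside) hits <- hits + 1
  }
  hits / length(mem)
}

expect_metric_matches_oracle <- function(model, cid, alpha, tol = 1e-9) {
  pairs <- list(
    c(metric_likelihood(model, cid, alpha), oracle_likelihood(model, cid, alpha)),
    c(metric_density(model, cid, alpha), oracle_density(model, cid, alpha)),
    c(metric_boundary(model, cid, alpha, exact = TRUE),
      oracle_boundary(model, cid, alpha)),
    c(metric_allegiance(model, cid, alpha), oracle_allegiance(model, cid, alpha))
  )
  for (p in pairs) {
    if (p[1] == 0 || p[2] == 0) {
      expect_equal(p[1], p[2], tolerance = tol)
    } else {
      expect_lt(abs(log(p[1]) - log(p[2])), tol)
    }
  }
}
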