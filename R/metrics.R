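#' Robustness score of a structural feature
#'
#' Combines a feature value on the observed network, `f0`, with its value
#' under the perturbed network, `f_alpha`, into the prioritization score
#' \deqn{r_f = \frac{f_0}{1 + |f_0 - f_\alpha|}.}
#' The score equals `f0` when the feature is unchanged by the perturbation
#' (maximally robust), is damped as the feature drifts, and is 0 whenever
#' `f0` is 0. Values stay in \[0, 1\] whenever the inputs do.
#'
#' @param f0 Feature value(s) at `alpha = 0`, in \[0, 1\].
#' @param f_alpha Feature value(s) under perturbation, in \[0, 1\].
#' @return Numeric vector of scores in \[0, 1\].
#' @examples
#' robustness_score(0.8, 0.3)
#' @export
robustness_score <- function(f0, f_alpha) {
  if (any(f0 < 0 | f0 > 1 | f_alpha < 0 | f_alpha > 1, na.rm = FALSE) ||
      anyNA(f0) || anyNA(f_alpha)) {
    abort("`f0` and `f_alpha` must lie in [0, 1].")
  }
  f0 / (1 + abs(f0 - f_alpha))
}

P_MIN <- 1e-9

clip_prob <- function(p) pmin(pmax(p, P_MIN), 1 - P_MIN)

# perturbed community edge contribution: the configuration-model term is
# scaled by the community's share of the total edge probability
pep_comm <- function(p_comm, p_edge, du, dv, m, alpha) {
  share <- pmin(1, p_comm / pmax(p_edge, P_MIN))
  (1 - alpha) * p_comm + alpha * pmin(1, du * dv / (2 * m)) * share
}

resolve_community <- function(model, community) {
  cid <- as.character(community)
  idx <- node_index(model$net, unique(model$communities$node[
    model$communities$community == cid
  ]), context = "community node")
  if (!length(idx)) abort(sprintf("community '%s' is empty or unknown.", cid))
  list(cid = cid, idx = sort(idx))
}

# observed internal edges of a community: rows of the edge table with both
# endpoints inside
internal_edges <- function(net, idx) {
  inside <- logical(net$n)
  inside[idx] <- TRUE
  which(inside[net$i] & inside[net$j])
}

#' Community likelihood metric
#'
#' Measures how well the observed edges among community members are explained
#' by the community: the product over members `u` of the membership
#' probability `p_C(u)` and, over ordered member pairs `(u, v)`, of
#' `p_C(v) * p_C(u,v|alpha)` for observed edges and
#' `p_C(v) * (1 - p_C(u,v|alpha))` for non-edges, where `p_C(u,v|alpha)`
#' routes the model's community edge contribution through the analytic
#' perturbation. Running the pair product over ordered pairs (each unordered
#' pair enters twice, once per orientation) makes the metric symmetric in
#' the pair and therefore invariant under node relabeling. The product is
#' reported as its per-term geometric mean so that values are comparable
#' across community sizes; all queried probabilities are clipped to
#' `[1e-9, 1 - 1e-9]` before logs.
#'
#' @param model A `crank_model`.
#' @param community A community ID present in `model$communities`.
#' @param alpha Perturbation intensity in \[0, 1\].
#' @return A value in \[0, 1\].
#' @export
metric_likelihood <- function(model, community, alpha = 0) {
  check_alpha(alpha)
  net <- model$net
  cc <- resolve_community(model, community)
  idx <- cc$idx
  cn <- length(idx)
  log_memb <- log(clip_prob(model_member(model, idx, cc$cid)))
  total <- sum(log_memb)
  count <- cn
  if (cn >= 2) {
    pr <- t(utils::combn(cn, 2)) # local positions, col1 < col2
    ui <- idx[pr[, 1]]
    vi <- idx[pr[, 2]]
    is_edge <- logical(nrow(pr))
    ie <- internal_edges(net, idx)
    if (length(ie)) {
      pos <- integer(net$n)
      pos[idx] <- seq_len(cn)
      a <- pmin(pos[net$i[ie]], pos[net$j[ie]])
      b <- pmax(pos[net$i[ie]], pos[net$j[ie]])
      is_edge <- ((pr[, 1] - 1) * cn + pr[, 2]) %in% ((a - 1) * cn + b)
    }
    p_comm <- model_comm_edge(model, ui, vi, cc$cid)
    p_edge <- model_edge(model, ui, vi)
    p_ca <- clip_prob(pep_comm(p_comm, p_edge, net$deg[ui], net$deg[vi],
                               net$m, alpha))
    edge_part <- log(clip_prob(ifelse(is_edge, p_ca, 1 - p_ca)))
    # ordered pairs: s(u,v) * s(v,u) = p_C(u) p_C(v) (edge part)^2
    total <- total + sum(log_memb[pr[, 1]] + log_memb[pr[, 2]] + 2 * edge_part)
    count <- count + cn * (cn - 1)
  }
  exp(total / count)
}

#' Community density metric
#'
#' The joint probability of the observed edges between community members,
#' using unconditioned edge probabilities `p(u,v|alpha)`, reported as the
#' per-edge geometric mean. A community with no internal edges scores 0.
#'
#' @inheritParams metric_likelihood
#' @return A value in \[0, 1\].
#' @export
metric_density <- function(model, community, alpha = 0) {
  check_alpha(alpha)
  net <- model$net
  cc <- resolve_community(model, community)
  ie <- internal_edges(net, cc$idx)
  if (!length(ie)) return(0)
  ui <- net$i[ie]
  vi <- net$j[ie]
  p <- model_edge(model, ui, vi)
  pa <- clip_prob(pep(p, net$deg[ui], net$deg[vi], net$m, alpha))
  exp(mean(log(pa)))
}

#' Community boundary metric
#'
#' Accumulates the likelihood against edges that cross the community
#' boundary: the product over pairs `(u in C, v outside C)` of
#' `1 - p(u,v|alpha)`, reported as the per-pair geometric mean. For networks
#' up to `exact_max` nodes all cross pairs are enumerated; larger networks
#' use negative sampling: for every member all observed boundary edges are
#' evaluated exactly, and `n_samples` uniformly drawn (without replacement)
#' non-neighbor outside nodes stand in for the remaining pairs, with the
#' sampled contribution scaled up accordingly. With a full sampling budget
#' the estimate coincides with exact enumeration. A community covering the
#' whole vertex set has an empty boundary and scores 1.
#'
#' @inheritParams metric_likelihood
#' @param n_samples Negative samples per community member.
#' @param seed Integer seed for the sampling mode.
#' @param exact Force exact enumeration (`TRUE`/`FALSE`); default chooses
#'   exact when the network has at most `exact_max` nodes.
#' @param exact_max Node-count cutoff for automatic exact enumeration.
#' @return A value in \[0, 1\].
#' @export
metric_boundary <- function(model, community, alpha = 0, n_samples = 50,
                            seed = 1, exact = NULL, exact_max = 2000) {
  check_alpha(alpha)
  net <- model$net
  cc <- resolve_community(model, community)
  idx <- cc$idx
  outside <- setdiff(seq_len(net$n), idx)
  if (!length(outside)) return(1)
  if (is.null(exact)) exact <- net$n <= exact_max
  if (exact) {
    ui <- rep(idx, each = length(outside))
    vi <- rep(outside, times = length(idx))
    p <- model_edge(model, ui, vi)
    pa <- clip_prob(pep(p, net$deg[ui], net$deg[vi], net$m, alpha))
    return(exp(mean(log1p(-pa))))
  }
  withr::local_seed(as.integer(seed))
  inside <- logical(net$n)
  inside[idx] <- TRUE
  total <- 0
  for (u in idx) {
    partners <- net$adj[[u]][!inside[net$adj[[u]]]]
    if (length(partners)) {
      p <- model_edge(model, rep(u, length(partners)), partners)
      pa <- clip_prob(pep(p, net$deg[u], net$deg[partners], net$m, alpha))
      total <- total + sum(log1p(-pa))
    }
    rest <- setdiff(outside, partners)
    n_rest <- length(rest)
    if (n_rest > 0) {
      take <- min(n_samples, n_rest)
      smp <- if (take == n_rest) rest else rest[sample.int(n_rest, take)]
      p <- model_edge(model, rep(u, take), smp)
      pa <- clip_prob(pep(p, net$deg[u], net$deg[smp], net$m, alpha))
      total <- total + mean(log1p(-pa)) * n_rest
    }
  }
  exp(total / (length(idx) * length(outside)))
}

#' Community allegiance metric
#'
#' The fraction of community members whose total (perturbed) edge probability
#' towards neighbors inside the community is at least as large as towards
#' neighbors outside:
#' \deqn{f_a(C|\alpha) = \frac{1}{|C|}\sum_{u \in C}
#'   \delta\Big(\textstyle\sum_{v \in N_u \cap C} p(u,v|\alpha) \ge
#'   \sum_{v \in N_u \setminus C} p(u,v|\alpha)\Big),}
#' where sums run over network neighbors only.
#'
#' @inheritParams metric_likelihood
#' @return A value in \[0, 1\].
#' @export
metric_allegiance <- function(model, community, alpha = 0) {
  check_alpha(alpha)
  net <- model$net
  cc <- resolve_community(model, community)
  inside <- logical(net$n)
  inside[cc$idx] <- TRUE
  hits <- vapply(cc$idx, function(u) {
    nb <- net$adj[[u]]
    if (!length(nb)) return(TRUE)
    p <- model_edge(model, rep(u, length(nb)), nb)
    pa <- pep(p, net$deg[u], net$deg[nb], net$m, alpha)
    sum(pa[inside[nb]]) >= sum(pa[!inside[nb]])
  }, logical(1))
  mean(hits)
}

#' Score all communities with the four prioritization metrics
#'
#' Evaluates likelihood, density, boundary and allegiance for every
#' community at `alpha = 0` and at the supplied perturbation intensity, and
#' combines each pair with [robustness_score()].
#'
#' @param model A `crank_model` (e.g. from [fit_affiliation_model()] or
#'   [crisp_model()]).
#' @param comms Optional tibble with columns `community`, `node`; defaults
#'   to the model's own communities.
#' @param alpha Perturbation intensity of the perturbed evaluation
#'   (default 0.15).
#' @param n_samples,exact,exact_max Passed to [metric_boundary()].
#' @param seed Integer seed (only consumed by the boundary sampling mode).
#' @return A `crank_metrics` tibble with one row per community: the four
#'   feature values at `alpha = 0` (`f_l0` .. `f_a0`), at the perturbed
#'   level (`f_l_alpha` .. `f_a_alpha`), and the four robustness scores
#'   `r_l`, `r_d`, `r_b`, `r_a`.
#' @export
score_communities <- function(model, comms = NULL, alpha = 0.15,
                              n_samples = 50, seed = 1, exact = NULL,
                              exact_max = 2000) {
  stopifnot(inherits(model, "crank_model"))
  check_alpha(alpha)
  if (!is.null(comms)) {
    model$communities <- validate_communities(comms, model$net)
  }
  ids <- community_ids(model$communities)
  if (!length(ids)) abort("no communities to score.")
  one_level <- function(a) {
    purrr::map_dfr(seq_along(ids), function(ci) {
      cid <- ids[[ci]]
      tibble(
        community = cid,
        f_l = metric_likelihood(model, cid, a),
        f_d = metric_density(model, cid, a),
        f_b = metric_boundary(model, cid, a, n_samples = n_samples,
                              seed = seed + ci, exact = exact,
                              exact_max = exact_max),
        f_a = metric_allegiance(model, cid, a)
      )
    })
  }
  at0 <- one_level(0)
  ata <- one_level(alpha)
  out <- tibble(
    community = ids,
    f_l0 = at0$f_l, f_d0 = at0$f_d, f_b0 = at0$f_b, f_a0 = at0$f_a,
    f_l_alpha = ata$f_l, f_d_alpha = ata$f_d,
    f_b_alpha = ata$f_b, f_a_alpha = ata$f_a,
    r_l = robustness_score(at0$f_l, ata$f_l),
    r_d = robustness_score(at0$f_d, ata$f_d),
    r_b = robustness_score(at0$f_b, ata$f_b),
    r_a = robustness_score(at0$f_a, ata$f_a)
  )
  attr(out, "alpha") <- alpha
  class(out) <- c("crank_metrics", class(out))
  out
}

#' Write a metric table as TSV
#'
#' Column order: `community`, the four `alpha = 0` feature values, the four
#' perturbed feature values, the four robustness scores. The perturbation
#' intensity is recorded in a `# alpha=` comment line.
#'
#' @param metrics A `crank_metrics` tibble from [score_communities()].
#' @param path Output path.
#' @export
write_metric_table <- function(metrics, path) {
  write_tsv_file(as.data.frame(metrics), path,
                 header_lines = sprintf("# alpha=%g",
                                        attr(metrics, "alpha") %||% NA))
}
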