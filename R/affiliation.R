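#' Fit a noisy-OR affiliation model
#'
#' Fits nonnegative node-community affiliation strengths `F` under the
#' noisy-OR edge model \eqn{p(u,v) = 1 - \exp(-\epsilon - F_u \cdot F_v)}:
#' observed edges contribute \eqn{\log(1 - e^{-\epsilon - F_u\cdot F_v})} to
#' the log-likelihood and non-edges contribute \eqn{-F_u \cdot F_v -
#' \epsilon}. Optimization is seeded-random initialization followed by block
#' coordinate ascent over node rows (projected gradient with backtracking
#' line search), using the cached column-sum trick so a sweep costs
#' `O(m * k)`. The fitted object satisfies the community-model contract
#' (see [new_crank_model()]): membership probability
#' \eqn{1 - e^{-F_{uC}}}, edge probability as above, and community edge
#' contribution \eqn{1 - e^{-F_{uC} F_{vC}}}.
#'
#' Detected communities are derived either by thresholding (`assign =
#' "threshold"`, the default): node `u` belongs to community `C` when
#' `F[u, C] >= threshold` (default `log(2)`, i.e. membership probability at
#' least 0.5) -- or as a full partition (`assign = "argmax"`): every node
#' joins the community of its largest affiliation strength. The partition
#' mode is what the planted-partition benchmark uses, since thresholding
#' yields small pure node subsets whose gold-standard accuracies are
#' degenerately tied. Empty communities are dropped in both modes.
#'
#' @param net A `crank_network`.
#' @param k Number of communities to fit (`1 <= k <=` number of nodes).
#' @param iters Maximum number of coordinate-ascent sweeps.
#' @param seed Integer seed for the random initialization; the fit is
#'   deterministic given the seed.
#' @param epsilon Background edge intensity; default `2m / (n (n - 1))`
#'   (the background density).
#' @param tol Relative log-likelihood change below which the fit stops.
#' @param threshold Affiliation strength above which a node is assigned to a
#'   community (threshold mode).
#' @param assign Community derivation: `"threshold"` (overlapping, may leave
#'   nodes unassigned) or `"argmax"` (a partition over all nodes).
#' @return An object of classes `crank_affiliation` and `crank_model` with
#'   fields `F` (n x k matrix), `epsilon`, `loglik` (per-sweep trace),
#'   `converged`, and `communities` (tibble of thresholded assignments).
#' @examples
#' net <- as_crank_network(expand.grid(from = letters[1:4], to = letters[1:4]))
#' fit <- fit_affiliation_model(net, k = 1, seed = 1)
#' glance(fit)
#' @export
fit_affiliation_model <- function(net, k, iters = 50, seed = 1,
                                  epsilon = NULL, tol = 1e-6,
                                  threshold = log(2),
                                  assign = c("threshold", "argmax")) {
  assign <- match.arg(assign)
  stopifnot(is_crank_network(net))
  n <- net$n
  if (n == 0 || net$m_count == 0) abort("cannot fit a model on an empty network.")
  if (k < 1 || k > n) abort("`k` must satisfy 1 <= k <= number of nodes.")
  k <- as.integer(k)
  if (is.null(epsilon)) epsilon <- max(2 * net$m / (n * (n - 1)), 1e-8)

  withr::local_seed(as.integer(seed))
  F <- matrix(runif(n * k, 0, 0.1), nrow = n, ncol = k)
  # seed each community on a locally-minimal-conductance neighborhood:
  # closed neighborhoods whose conductance is no worse than any neighbor's,
  # taken in ascending conductance order (remaining slots filled at random)
  nb_cond <- vapply(seq_len(n), function(u) {
    community_conductance(net, unique(c(u, net$adj[[u]])))
  }, numeric(1))
  loc_min <- which(vapply(seq_len(n), function(u) {
    !length(net$adj[[u]]) || nb_cond[u] <= min(nb_cond[net$adj[[u]]])
  }, logical(1)))
  candidates <- loc_min[order(nb_cond[loc_min])]
  # greedy diversity: skip candidates already covered by an earlier seed's
  # neighborhood so the k communities start in different regions
  seeds <- integer(0)
  covered <- logical(n)
  for (u in candidates) {
    if (length(seeds) == k) break
    if (covered[u]) next
    seeds <- c(seeds, u)
    covered[unique(c(u, net$adj[[u]]))] <- TRUE
  }
  if (length(seeds) < k) {
    pool <- setdiff(which(!covered), seeds)
    if (length(pool) < k - length(seeds)) {
      pool <- setdiff(seq_len(n), seeds)
    }
    seeds <- c(seeds, sample(pool)[seq_len(k - length(seeds))])
  }
  for (c_ in seq_len(k)) {
    F[unique(c(seeds[c_], net$adj[[seeds[c_]]])), c_] <- 1
  }
  S <- colSums(F)
  adj <- net$adj

  row_obj <- function(fu, FN, lin) {
    x <- epsilon + drop(FN %*% fu)
    sum(log(-expm1(-x))) - sum(fu * lin)
  }

  loglik <- function() {
    fe <- rowSums(F[net$i, , drop = FALSE] * F[net$j, , drop = FALSE])
    pair_sum <- (sum(S^2) - sum(F * F)) / 2
    n_nonedge <- n * (n - 1) / 2 - net$m_count
    sum(log(-expm1(-epsilon - fe))) - (pair_sum - sum(fe)) - epsilon * n_nonedge
  }

  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  n_sweeps <- 0L
  for (sweep in seq_len(iters)) {
    for (u in seq_len(n)) {
      nb <- adj[[u]]
      fu <- F[u, ]
      FN <- F[nb, , drop = FALSE]
      lin <- (S - fu) - colSums(FN) # gradient of the non-edge penalty
      g0 <- row_obj(fu, FN, lin)
      x <- epsilon + drop(FN %*% fu)
      grad <- drop(crossprod(FN, exp(-x) / (-expm1(-x)))) - lin
      step <- 1
      for (half in 1:12) {
        fnew <- pmax(0, fu + step * grad)
        if (row_obj(fnew, FN, lin) > g0) {
          F[u, ] <- fnew
          S <- S - fu + fnew
          break
        }
        step <- step / 2
      }
    }
    ll <- loglik()
    if (!is.finite(ll)) {
      abort(sprintf(
        "non-finite log-likelihood at sweep %d (epsilon = %g); inspect input weights.",
        sweep, epsilon
      ))
    }
    ll_trace <- c(ll_trace, ll)
    n_sweeps <- sweep
    if (is.finite(ll_prev) && abs(ll - ll_prev) <= tol * (1 + abs(ll_prev))) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }

  ids <- as.character(seq_len(k) - 1L)
  colnames(F) <- ids
  rownames(F) <- net$nodes
  if (assign == "argmax") {
    amax <- max.col(F, ties.method = "first")
    comms <- tibble(community = ids[amax], node = net$nodes)
  } else {
    assigned <- which(F >= threshold, arr.ind = TRUE)
    comms <- tibble(
      community = ids[assigned[, 2]],
      node = net$nodes[assigned[, 1]]
    )
  }
  comms <- comms[order(match(comms$community, ids), match(comms$node, net$nodes)), ]

  model <- affiliation_as_model(net, F, epsilon, comms)
  model$loglik <- ll_trace
  model$converged <- converged
  model$iterations <- n_sweeps
  model$k <- k
  model$threshold <- threshold
  model
}

affiliation_as_model <- function(net, F, epsilon, comms) {
  model <- new_crank_model(
    net, comms,
    p_member = function(u_idx, cid) -expm1(-F[u_idx, cid]),
    p_edge = function(u_idx, v_idx) {
      -expm1(-epsilon - rowSums(F[u_idx, , drop = FALSE] * F[v_idx, , drop = FALSE]))
    },
    p_comm_edge = function(u_idx, v_idx, cid) {
      -expm1(-F[u_idx, cid] * F[v_idx, cid])
    },
    provider = "affiliation"
  )
  model$F <- F
  model$epsilon <- epsilon
  class(model) <- c("crank_affiliation", class(model))
  model
}

#' @export
print.crank_affiliation <- function(x, ...) {
  cat(sprintf(
    "<crank_affiliation> k = %d on %d nodes; %d non-empty communities; logLik %.4f (%s after %d sweep(s))\n",
    x$k, x$net$n, length(unique(x$communities$community)),
    utils::tail(x$loglik, 1),
    if (x$converged) "converged" else "not converged", x$iterations
  ))
  invisible(x)
}

#' @describeIn fit_affiliation_model One row per (node, community) pair with
#'   the affiliation strength and implied membership probability.
#' @param x A `crank_affiliation`.
#' @param ... Unused.
#' @export
tidy.crank_affiliation <- function(x, ...) {
  tibble(
    node = rep(rownames(x$F), times = ncol(x$F)),
    community = rep(colnames(x$F), each = nrow(x$F)),
    strength = as.vector(x$F),
    membership_prob = -expm1(-as.vector(x$F))
  )
}

#' @describeIn fit_affiliation_model One-row model summary.
#' @export
glance.crank_affiliation <- function(x, ...) {
  tibble(
    k = x$k,
    epsilon = x$epsilon,
    log_lik = utils::tail(x$loglik, 1),
    n_iter = x$iterations,
    converged = x$converged,
    n_communities = length(unique(x$communities$community))
  )
}

#' Serialize / restore a fitted affiliation model
#'
#' Writes a TSV of (node, community, strength) triples preceded by a one-line
#' header carrying the background intensity epsilon; `read_affiliation_model`
#' restores a model that round-trips exactly.
#'
#' @param model A `crank_affiliation`.
#' @param path File path.
#' @export
write_affiliation_model <- function(model, path) {
  stopifnot(inherits(model, "crank_affiliation"))
  df <- tidy(model)
  write_tsv_file(
    df[c("node", "community", "strength")], path,
    header_lines = sprintf("# epsilon=%.17g threshold=%.17g", model$epsilon,
                           model$threshold %||% log(2))
  )
}

#' @rdname write_affiliation_model
#' @param net The `crank_network` the model was fitted on.
#' @export
read_affiliation_model <- function(path, net) {
  stopifnot(is_crank_network(net))
  header <- readLines(path, n = 1)
  if (!grepl("^# epsilon=", header)) {
    abort("not an affiliation model file (missing epsilon header).")
  }
  epsilon <- as.numeric(sub(".*epsilon=(\\S+).*", "\\1", header))
  threshold <- if (grepl("threshold=", header)) {
    as.numeric(sub(".*threshold=(\\S+).*", "\\1", header))
  } else {
    log(2)
  }
  if (is.na(epsilon)) abort("could not parse epsilon from the model header.")
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                          colClasses = c("character", "character", "numeric"))
  ids <- sort_ids(unique(df$community))
  F <- matrix(0, nrow = net$n, ncol = length(ids),
              dimnames = list(net$nodes, ids))
  F[cbind(node_index(net, df$node), match(df$community, ids))] <- df$strength
  assigned <- which(F >= threshold, arr.ind = TRUE)
  comms <- tibble(community = ids[assigned[, 2]], node = net$nodes[assigned[, 1]])
  model <- affiliation_as_model(net, F, epsilon, comms)
  model$k <- length(ids)
  model$threshold <- threshold
  model$loglik <- NA_real_
  model$converged <- NA
  model$iterations <- NA_integer_
  model
}
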