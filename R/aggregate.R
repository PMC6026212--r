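#' Ranked list from metric scores
#'
#' Orders communities by decreasing score; ties are broken by ascending
#' community ID (numeric order when all IDs are numeric).
#'
#' @param scores A tibble with columns `community` and `score`, or a named
#'   numeric vector.
#' @return A tibble with columns `community`, `score`, `rank` (1 = best).
#' @examples
#' ranks_from_scores(c(a = 0.9, b = 0.5, c = 0.1))
#' @export
ranks_from_scores <- function(scores) {
  if (is.numeric(scores) && !is.null(names(scores))) {
    scores <- tibble(community = names(scores), score = unname(scores))
  }
  scores <- as_tibble(as.data.frame(scores))
  if (!all(c("community", "score") %in% names(scores))) {
    abort("`scores` needs columns `community` and `score` (or a named vector).")
  }
  if (anyNA(scores$score) || any(!is.finite(scores$score))) {
    abort("scores must be finite and non-missing.")
  }
  scores$community <- as.character(scores$community)
  if (anyDuplicated(scores$community)) abort("duplicate community IDs in scores.")
  ord <- order(-scores$score, match(scores$community, sort_ids(scores$community)))
  out <- scores[ord, c("community", "score")]
  out$rank <- seq_len(nrow(out))
  out
}

check_lists <- function(lists) {
  if (!length(lists)) abort("at least one ranked list is required.")
  base <- sort(lists[[1]]$community)
  for (l in lists) {
    if (!all(c("community", "rank") %in% names(l))) {
      abort("each ranked list needs columns `community` and `rank`.")
    }
    if (!identical(sort(l$community), base)) {
      abort("ranked lists must cover the identical community set.")
    }
    if (!identical(sort(as.integer(l$rank)), seq_along(base))) {
      abort("ranks must be a permutation of 1..n in every list.")
    }
  }
  invisible(lists)
}

# bag index of each rank: contiguous, equally sized groups (last may be short)
bag_of_rank <- function(rank, n, n_bags) {
  bag_size <- ceiling(n / n_bags)
  pmin(n_bags, ceiling(rank / bag_size))
}

default_n_bags <- function(n) min(50L, max(5L, ceiling(n / 10)))

# final ordering from raw aggregate scores: ascending score (low = good),
# ties by community ID
order_aggregate <- function(communities, score) {
  ord <- order(score, match(communities, sort_ids(communities)))
  tibble(
    community = communities[ord],
    score = score[ord],
    rank = seq_along(ord)
  )
}

#' Initialize the aggregate prioritization
#'
#' With all importance weights equal, the initial aggregate score of a
#' community is the mean of its ranks across the input lists; communities
#' are ordered by ascending score (ties by ID).
#'
#' @param lists A list of ranked lists (tibbles with `community`, `rank`),
#'   one per metric, all over the same community set.
#' @return A tibble with `community`, `score`, `rank`.
#' @export
initialize_aggregate <- function(lists) {
  check_lists(lists)
  comm <- lists[[1]]$community
  rank_mat <- vapply(lists, function(l) l$rank[match(comm, l$community)],
                     numeric(length(comm)))
  order_aggregate(comm, rowMeans(rank_mat))
}

#' Update importance weights from a temporary gold standard
#'
#' The top `gold_size` communities of the current aggregate act as a
#' temporary gold standard. For each metric `r` and bag `i` the importance
#' weight is the Bayes-factor-style ratio of the observed to the expected
#' number of gold communities whose rank in list `r` falls into bag `i`:
#' `K = (g + s) / (e + s)` with pseudo-count `s`, where `e = gold_size *
#' bag_size / n` is the count expected under uniform placement. Weights are
#' capped to `k_cap`.
#'
#' @param aggregate Current aggregate (tibble with `community`, `rank`).
#' @param lists List of ranked lists as in [initialize_aggregate()].
#' @param n_bags Number of bags each list is partitioned into.
#' @param gold_size Size of the temporary gold standard (`>= 1`).
#' @param smoothing Pseudo-count `s`.
#' @param k_cap Length-2 numeric: lower and upper cap on the weights.
#' @return A matrix of weights, one row per list, one column per bag.
#' @export
update_importance_weights <- function(aggregate, lists, n_bags,
                                      gold_size, smoothing = 1,
                                      k_cap = c(1 / 20, 20)) {
  check_lists(lists)
  if (gold_size < 1) abort("`gold_size` must be >= 1.")
  n <- nrow(aggregate)
  gold <- aggregate$community[order(aggregate$rank)][seq_len(min(gold_size, n))]
  bag_size <- ceiling(n / n_bags)
  K <- matrix(NA_real_, nrow = length(lists), ncol = n_bags,
              dimnames = list(names(lists), NULL))
  for (r in seq_along(lists)) {
    l <- lists[[r]]
    gold_ranks <- l$rank[match(gold, l$community)]
    g <- tabulate(bag_of_rank(gold_ranks, n, n_bags), nbins = n_bags)
    # actual bag sizes (last bag may be short)
    sizes <- tabulate(bag_of_rank(seq_len(n), n, n_bags), nbins = n_bags)
    e <- length(gold) * sizes / n
    K[r, ] <- pmin(k_cap[2], pmax(k_cap[1], (g + smoothing) / (e + smoothing)))
  }
  K
}

#' Aggregate ranked metric lists into one prioritization
#'
#' Unsupervised iterative rank aggregation: initialize the aggregate as the
#' mean rank across lists, then alternate between (1) recomputing the
#' Bayes-factor importance weights of every (list, bag) from the current
#' top-ranked communities ([update_importance_weights()]) and (2) rescoring
#' every community as the importance-weighted average of its ranks,
#' \deqn{R(C) = \frac{\sum_r w_r^{i_r(C)}\, R_r(C)}{\sum_r w_r^{i_r(C)}},
#'   \qquad w = \log(K + 1),}
#' ranking by ascending `R(C)`, until the aggregate order no longer changes
#' (or `max_iter` is reached). The `log(K + 1)` form keeps every list's
#' contribution positive so that informative lists (large `K`) gain
#' influence and uninformative ones (`K` near its floor) lose it, while the
#' normalization makes the score a genuine weighted mean rank: identical
#' input lists are reproduced unchanged and a single list is a fixed point
#' for any number of bags. The rescoring applies a damped update with a
#' shrinking (1/t) step — a running average of the weighted mean ranks —
#' which leaves every fixed point unchanged, keeps the first step exact,
#' and prevents the order from cycling across bag boundaries. The procedure
#' is fully deterministic.
#'
#' @inheritParams update_importance_weights
#' @param lists A named list of ranked lists (tibbles with `community`,
#'   `rank`), e.g. one per prioritization metric.
#' @param n_bags Number of bags; default `min(50, max(5, ceiling(n / 10)))`.
#' @param gold_size Temporary gold-standard size; default one bag.
#' @param max_iter Iteration cap.
#' @return A `crank_prioritization` tibble (`community`, `score`, `rank`)
#'   with attributes `converged`, `iterations` and `weights`.
#' @examples
#' l <- ranks_from_scores(c(a = .9, b = .5, c = .1))
#' aggregate_ranks(list(l, l, l, l))
#' @export
aggregate_ranks <- function(lists, n_bags = NULL, gold_size = NULL,
                            max_iter = 100, smoothing = 1,
                            k_cap = c(1 / 20, 20)) {
  check_lists(lists)
  comm <- lists[[1]]$community
  n <- length(comm)
  n_bags <- as.integer(n_bags %||% default_n_bags(n))
  n_bags <- max(1L, min(n_bags, n))
  gold_size <- as.integer(gold_size %||% ceiling(n / n_bags))
  rank_mat <- vapply(lists, function(l) l$rank[match(comm, l$community)],
                     numeric(n))
  bag_mat <- bag_of_rank(rank_mat, n, n_bags)

  aggregate <- initialize_aggregate(lists)
  score_vec <- aggregate$score[match(comm, aggregate$community)]
  converged <- FALSE
  cycle_resolved <- FALSE
  iterations <- 0L
  K <- NULL
  prev_order <- NULL
  prev_proposed <- NULL
  for (it in seq_len(max_iter)) {
    iterations <- it
    K <- update_importance_weights(aggregate, lists, n_bags, gold_size,
                                   smoothing, k_cap)
    w <- matrix(log1p(K[cbind(rep(seq_along(lists), each = n),
                              as.vector(bag_mat))]),
                nrow = n)
    proposed <- rowSums(w * rank_mat) / rowSums(w)
    # damped update with shrinking step (running average): the pure map can
    # cycle between orders when a community sits on a bag boundary of its
    # own aggregate; averaging keeps every fixed point (score = proposed
    # there), the first step is undamped, and the 1/t step makes the score
    # sequence settle
    score_vec <- score_vec + (proposed - score_vec) / it
    new_aggregate <- order_aggregate(comm, score_vec)
    if (identical(new_aggregate$community, aggregate$community)) {
      aggregate <- new_aggregate
      converged <- TRUE
      break
    }
    if (!is.null(prev_order) && identical(new_aggregate$community, prev_order)) {
      # period-2 cycle: the damped scores converge to an exact tie between
      # the alternating communities, so rank at the limit — the mean of the
      # two alternating proposals — and let the ID tie-break settle any
      # residual equality; this is the Cesaro limit of the dynamics
      score_vec <- (proposed + prev_proposed) / 2
      aggregate <- order_aggregate(comm, score_vec)
      converged <- TRUE
      cycle_resolved <- TRUE
      break
    }
    prev_order <- aggregate$community
    prev_proposed <- proposed
    aggregate <- new_aggregate
  }
  structure(
    aggregate,
    converged = converged,
    cycle_resolved = cycle_resolved,
    iterations = iterations,
    weights = K,
    n_bags = n_bags,
    gold_size = gold_size,
    class = c("crank_prioritization", class(aggregate))
  )
}

#' @export
print.crank_prioritization <- function(x, ...) {
  cat(sprintf(
    "<crank_prioritization> %d communities (%s after %d iteration(s))\n",
    nrow(x),
    if (isTRUE(attr(x, "converged"))) "converged" else "NOT converged",
    attr(x, "iterations") %||% NA_integer_
  ))
  NextMethod()
}

#' @describeIn aggregate_ranks Tidy view: one row per community with rank
#'   and aggregate score.
#' @param x A `crank_prioritization`.
#' @param ... Unused.
#' @export
tidy.crank_prioritization <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' @describeIn aggregate_ranks One-row convergence summary.
#' @export
glance.crank_prioritization <- function(x, ...) {
  tibble(
    n_communities = nrow(x),
    converged = isTRUE(attr(x, "converged")),
    cycle_resolved = isTRUE(attr(x, "cycle_resolved")),
    iterations = attr(x, "iterations") %||% NA_integer_,
    n_bags = attr(x, "n_bags") %||% NA_integer_,
    gold_size = attr(x, "gold_size") %||% NA_integer_
  )
}
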