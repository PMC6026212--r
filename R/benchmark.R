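#' Generate a planted stochastic block model benchmark network
#'
#' Samples an undirected simple graph in which the node set is partitioned
#' into blocks; each within-block pair is an edge independently with its
#' block's `p_in` and each cross-block pair with `p_out`. The default
#' configuration plants 10 communities of 30 nodes (N = 300), five with
#' `p_in = 0.6` and five with `p_in = 0.2`, so that half the planted
#' communities are markedly harder to detect.
#'
#' @param n_blocks Number of planted blocks.
#' @param block_size Nodes per block.
#' @param p_in Within-block edge probability; scalar or one value per block.
#' @param p_out Cross-block edge probability.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param max_nodes Safety cap on `n_blocks * block_size`.
#' @return A `crank_sbm` list with fields `net` (a `crank_network` over all
#'   planted nodes, including any isolated ones), `planted` (tibble
#'   `community`, `node`), `block_p_in` (tibble `community`, `p_in`),
#'   `p_out`, and `seed`.
#' @examples
#' bm <- generate_sbm(n_blocks = 2, block_size = 5, p_in = 1, p_out = 0, seed = 1)
#' bm$net
#' @export
generate_sbm <- function(n_blocks = 10, block_size = 30,
                         p_in = rep(c(0.6, 0.2), each = 5),
                         p_out = 0.05, seed = 1, max_nodes = 100000) {
  if (length(p_in) == 1) p_in <- rep(p_in, n_blocks)
  if (length(p_in) != n_blocks) {
    abort("`p_in` must be a scalar or give one value per block.")
  }
  if (any(c(p_in, p_out) < 0 | c(p_in, p_out) > 1)) {
    abort("edge probabilities must lie in [0, 1].")
  }
  n <- n_blocks * block_size
  if (n > max_nodes) abort(sprintf("requested %d nodes exceeds max_nodes = %d", n, max_nodes))
  pref <- matrix(p_out, n_blocks, n_blocks)
  diag(pref) <- p_in
  withr::local_seed(as.integer(seed))
  g <- igraph::sample_sbm(n, pref.matrix = pref,
                          block.sizes = rep(block_size, n_blocks))
  nodes <- sprintf("v%03d", seq_len(n))
  el <- igraph::as_edgelist(g, names = FALSE)
  net <- if (nrow(el)) {
    new_crank_network(nodes, pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]),
                      rep(1, nrow(el)))
  } else {
    new_crank_network(nodes, integer(0), integer(0), numeric(0))
  }
  block_ids <- as.character(seq_len(n_blocks) - 1L)
  structure(
    list(
      net = net,
      planted = tibble(
        community = rep(block_ids, each = block_size),
        node = nodes
      ),
      block_p_in = tibble(community = block_ids, p_in = p_in),
      p_out = p_out,
      seed = as.integer(seed)
    ),
    class = "crank_sbm"
  )
}

#' @export
print.crank_sbm <- function(x, ...) {
  cat(sprintf(
    "<crank_sbm> %d planted blocks (p_in %s, p_out %g), seed %d\n",
    nrow(x$block_p_in),
    paste(unique(x$block_p_in$p_in), collapse = "/"), x$p_out, x$seed
  ))
  print(x$net)
  invisible(x)
}

#' Gold-standard ranking of detected communities
#'
#' Matches every detected community to the planted block maximizing the
#' overlap and scores it by the fraction of its nodes falling in that block
#' (its accuracy). Communities are ordered by decreasing accuracy, ties by
#' decreasing size, then by ID.
#'
#' @param detected Tibble (`community`, `node`) of detected communities; all
#'   must be non-empty.
#' @param planted Tibble (`community`, `node`) of planted blocks over the
#'   same node universe.
#' @return A `crank_gold` tibble: `community`, `accuracy`, `matched_block`,
#'   `size`, `rank`.
#' @export
gold_standard_ranking <- function(detected, planted) {
  detected <- validate_communities(detected)
  planted <- validate_communities(planted)
  ids <- community_ids(detected)
  if (!length(ids)) abort("no detected communities to rank.")
  block_ids <- community_ids(planted)
  block_of <- setNames(planted$community, planted$node)
  rows <- purrr::map_dfr(ids, function(cid) {
    members <- detected$node[detected$community == cid]
    hits <- table(factor(block_of[members], levels = block_ids))
    best <- block_ids[which.max(hits)] # ties: first block in ID order
    tibble(
      community = cid,
      accuracy = as.numeric(max(hits)) / length(members),
      matched_block = best,
      size = length(members)
    )
  })
  ord <- order(-rows$accuracy, -rows$size, match(rows$community, ids))
  out <- rows[ord, ]
  out$rank <- seq_len(nrow(out))
  class(out) <- c("crank_gold", class(out))
  out
}

#' Spearman correlation between a candidate ranking and the gold standard
#'
#' Gold ranks are derived from accuracy with average ranks for ties, so a
#' candidate is not rewarded for an arbitrary ordering of equally accurate
#' communities.
#'
#' @param candidate A ranked tibble with columns `community`, `rank`.
#' @param gold A `crank_gold` from [gold_standard_ranking()].
#' @return Spearman's rho in \[-1, 1\].
#' @export
spearman_evaluation <- function(candidate, gold) {
  if (!all(c("community", "rank") %in% names(candidate))) {
    abort("`candidate` needs columns `community` and `rank`.")
  }
  if (nrow(candidate) < 2) abort("Spearman correlation undefined for n < 2.")
  if (!setequal(candidate$community, gold$community)) {
    abort("candidate and gold standard must cover the same communities.")
  }
  acc <- gold$accuracy[match(candidate$community, gold$community)]
  gold_rank <- rank(-acc, ties.method = "average")
  stats::cor(candidate$rank, gold_rank, method = "spearman")
}

#' Run the planted-partition benchmark
#'
#' For each seeded replicate: generate an SBM network, detect communities
#' with the affiliation-model fitter, rank the detected communities four
#' ways (robustness-based prioritization, per-community modularity,
#' conductance, random) and score each ranking by Spearman's rho against
#' the gold standard. Replicates on which the detector returns fewer than
#' two non-empty communities are skipped and counted.
#'
#' @param n_networks Number of replicate networks.
#' @param base_seed Integer base seed; every source of randomness in a
#'   replicate derives from it and the replicate index.
#' @param n_blocks,block_size,p_in,p_out Passed to [generate_sbm()].
#' @param k Number of communities the detector fits (default: the planted
#'   count).
#' @param alpha Perturbation intensity for the metric evaluation.
#' @param detector_iters Sweeps allowed to the affiliation fitter.
#' @param progress Emit a message every 10 replicates.
#' @return A `crank_benchmark` tibble with one row per method
#'   (`method`, `mean_rho`, `sd`, `ci_low`, `ci_high`, `n_replicates`);
#'   attributes `replicates` (per-replicate rho values) and `difficulty`
#'   (per-replicate mean gold accuracy of detected communities matched to
#'   each planted `p_in` level).
#' @export
run_benchmark <- function(n_networks = 100, base_seed = 1,
                          n_blocks = 10, block_size = 30,
                          p_in = rep(c(0.6, 0.2), each = 5),
                          p_out = 0.05, k = n_blocks, alpha = 0.15,
                          detector_iters = 50, progress = FALSE) {
  if (n_networks < 1) abort("`n_networks` must be >= 1.")
  per_rep <- list()
  diff_rep <- list()
  n_skipped <- 0L
  for (r in seq_len(n_networks)) {
    seeds <- replicate_seeds(base_seed, r)
    bm <- generate_sbm(n_blocks, block_size, p_in, p_out, seed = seeds["sbm"])
    res <- tryCatch(
      benchmark_replicate(bm, k, alpha, detector_iters, seeds),
      error = function(e) {
        warn(sprintf("replicate %d skipped: %s", r, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(res)) {
      n_skipped <- n_skipped + 1L
      next
    }
    per_rep[[length(per_rep) + 1L]] <- mutate(res$rho, replicate = r)
    diff_rep[[length(diff_rep) + 1L]] <- mutate(res$difficulty, replicate = r)
    if (progress && r %% 10 == 0) inform(sprintf("replicate %d/%d", r, n_networks))
  }
  if (!length(per_rep)) abort("all replicates failed.")
  reps <- bind_rows(per_rep)
  summary <- reps |>
    group_by(.data$method) |>
    summarise(
      mean_rho = mean(.data$rho),
      sd = sd(.data$rho),
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(
      ci_low = .data$mean_rho - qnorm(0.975) * .data$sd / sqrt(.data$n_replicates),
      ci_high = .data$mean_rho + qnorm(0.975) * .data$sd / sqrt(.data$n_replicates)
    ) |>
    select("method", "mean_rho", "sd", "ci_low", "ci_high", "n_replicates") |>
    arrange(desc(.data$mean_rho))
  structure(
    summary,
    replicates = reps,
    difficulty = bind_rows(diff_rep),
    n_skipped = n_skipped,
    config = list(
      n_networks = n_networks, base_seed = base_seed, n_blocks = n_blocks,
      block_size = block_size, p_in = p_in, p_out = p_out, k = k,
      alpha = alpha, detector_iters = detector_iters
    ),
    class = c("crank_benchmark", class(summary))
  )
}

# deterministic sub-seed derivation: one global seed splits into per-use
# streams by replicate index and a per-purpose offset
replicate_seeds <- function(base_seed, r) {
  base <- (as.numeric(base_seed) * 10007 + r * 101) %% 2147480000
  c(sbm = base + 1, fit = base + 2, metrics = base + 3, random = base + 4)
}

benchmark_replicate <- function(bm, k, alpha, detector_iters, seeds) {
  net <- bm$net
  fit <- fit_affiliation_model(net, k = k, iters = detector_iters,
                               seed = seeds["fit"], assign = "argmax")
  detected <- fit$communities
  if (length(unique(detected$community)) < 2) {
    abort("detector returned fewer than two non-empty communities")
  }
  gold <- gold_standard_ranking(detected, bm$planted)
  metrics <- score_communities(fit, alpha = alpha, seed = seeds["metrics"])
  pri <- aggregate_ranks(metric_rank_lists(metrics))
  rho <- tibble(
    method = c("crank", "modularity", "conductance", "random"),
    rho = c(
      spearman_evaluation(pri, gold),
      spearman_evaluation(modularity_rank(net, detected), gold),
      spearman_evaluation(conductance_rank(net, detected), gold),
      spearman_evaluation(random_rank(detected, seed = seeds["random"]), gold)
    ),
    aggregation_converged = isTRUE(attr(pri, "converged")),
    aggregation_iterations = attr(pri, "iterations")
  )
  difficulty <- gold |>
    as_tibble() |>
    left_join(bm$block_p_in, by = c(matched_block = "community")) |>
    group_by(.data$p_in) |>
    summarise(mean_accuracy = mean(.data$accuracy), n = dplyr::n(),
              .groups = "drop")
  list(rho = rho, difficulty = difficulty)
}

#' Ranked lists from a metric table
#'
#' One ranked list per robustness score column (`r_l`, `r_d`, `r_b`, `r_a`),
#' ready for [aggregate_ranks()].
#'
#' @param metrics A `crank_metrics` tibble from [score_communities()].
#' @return A named list of ranked tibbles.
#' @export
metric_rank_lists <- function(metrics) {
  cols <- c(likelihood = "r_l", density = "r_d",
            boundary = "r_b", allegiance = "r_a")
  lapply(cols, function(cl) {
    ranks_from_scores(tibble(community = metrics$community,
                             score = metrics[[cl]]))
  })
}

#' @export
print.crank_benchmark <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "<crank_benchmark> %d replicate(s), %d skipped; N = %d nodes, p_out = %g\n",
    cfg$n_networks, attr(x, "n_skipped"),
    cfg$n_blocks * cfg$block_size, cfg$p_out
  ))
  NextMethod()
}

#' @describeIn run_benchmark Per-replicate Spearman rho values in long form.
#' @param x A `crank_benchmark`.
#' @param ... Unused.
#' @export
tidy.crank_benchmark <- function(x, ...) {
  as_tibble(attr(x, "replicates"))
}

#' @describeIn run_benchmark One-row summary of the benchmark run.
#' @export
glance.crank_benchmark <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble(
    n_networks = cfg$n_networks,
    n_skipped = attr(x, "n_skipped"),
    p_out = cfg$p_out,
    alpha = cfg$alpha,
    best_method = x$method[which.max(x$mean_rho)]
  )
}
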