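#' Prioritize the communities of a network
#'
#' One-call pipeline: build (or accept) a community model, score every
#' community with the four robustness metrics ([score_communities()]) and
#' aggregate the four rankings into a single prioritization
#' ([aggregate_ranks()]). Rank 1 is the most promising community for
#' follow-up.
#'
#' @param net A `crank_network` (or an edge table coercible with
#'   [as_crank_network()]).
#' @param comms Optional tibble (`community`, `node`) of detected
#'   communities; wrapped with [crisp_model()] unless `model` is given.
#' @param model Optional `crank_model`; overrides `comms`-based adaption.
#' @param k If neither `comms` nor `model` is given, fit an affiliation
#'   model with `k` communities first.
#' @param alpha Perturbation intensity (default 0.15).
#' @param n_samples,seed Passed to the metric evaluation.
#' @param n_bags,gold_size,max_iter Passed to [aggregate_ranks()].
#' @return A `crank_prioritization` tibble with columns `community`,
#'   `score`, `rank` and the four robustness scores `r_l`, `r_d`, `r_b`,
#'   `r_a`; the full metric table is attached as attribute `metrics`.
#' @examples
#' net <- as_crank_network(data.frame(
#'   from = c("a", "a", "b", "d", "d", "e", "c"),
#'   to   = c("b", "c", "c", "e", "f", "f", "d")
#' ))
#' comms <- data.frame(community = rep(c("0", "1"), each = 3),
#'                     node = c("a", "b", "c", "d", "e", "f"))
#' prioritize_communities(net, comms, seed = 7)
#' @export
prioritize_communities <- function(net, comms = NULL, model = NULL, k = NULL,
                                   alpha = 0.15, n_samples = 50, seed = 1,
                                   n_bags = NULL, gold_size = NULL,
                                   max_iter = 100) {
  net <- as_crank_network(net)
  if (is.null(model)) {
    model <- if (!is.null(comms)) {
      crisp_model(net, comms)
    } else if (!is.null(k)) {
      fit_affiliation_model(net, k = k, seed = seed)
    } else {
      abort("supply `comms`, a fitted `model`, or `k` to fit one.")
    }
  } else if (!is.null(comms)) {
    model$communities <- validate_communities(comms, net)
  }
  metrics <- score_communities(model, alpha = alpha, n_samples = n_samples,
                               seed = seed)
  pri <- aggregate_ranks(metric_rank_lists(metrics), n_bags = n_bags,
                         gold_size = gold_size, max_iter = max_iter)
  scores <- as.data.frame(metrics)[match(pri$community, metrics$community),
                                   c("r_l", "r_d", "r_b", "r_a")]
  out <- dplyr::bind_cols(as_tibble(as.data.frame(pri)), as_tibble(scores))
  attr(out, "metrics") <- metrics
  attr(out, "converged") <- attr(pri, "converged")
  attr(out, "iterations") <- attr(pri, "iterations")
  attr(out, "weights") <- attr(pri, "weights")
  attr(out, "n_bags") <- attr(pri, "n_bags")
  attr(out, "gold_size") <- attr(pri, "gold_size")
  attr(out, "alpha") <- alpha
  class(out) <- c("crank_prioritization", class(out))
  out
}

#' Write a prioritization as TSV (plus a JSON convergence sidecar)
#'
#' Columns: `community_id`, `rank`, `aggregate_score`, `r_l`, `r_d`, `r_b`,
#' `r_a` (robustness columns only when present). Convergence metadata goes
#' to `<path>.json`.
#'
#' @param pri A `crank_prioritization`.
#' @param path Output TSV path.
#' @param header Optional character vector of `# `-prefixed header lines.
#' @export
write_ranking <- function(pri, path, header = character(0)) {
  df <- as.data.frame(pri)
  names(df)[names(df) == "community"] <- "community_id"
  names(df)[names(df) == "score"] <- "aggregate_score"
  keep <- intersect(c("community_id", "rank", "aggregate_score",
                      "r_l", "r_d", "r_b", "r_a", "method"), names(df))
  write_tsv_file(df[keep], path,
                 header_lines = if (length(header)) paste0("# ", header))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(
        converged = isTRUE(attr(pri, "converged")),
        iterations = attr(pri, "iterations"),
        n_bags = attr(pri, "n_bags"),
        gold_size = attr(pri, "gold_size")
      ),
      paste0(path, ".json"), auto_unbox = TRUE, null = "null"
    )
  }
  invisible(path)
}

#' Write an edge list
#'
#' @param net A `crank_network`.
#' @param path Output path.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(is_crank_network(net))
  df <- network_edges(net)
  if (all(df$weight == 1)) df$weight <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
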