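#' Analytic edge probability under degree-preserving perturbation
#'
#' The perturbation model rewires a fraction `alpha` of the edges while
#' preserving every node's degree. Rather than rewiring physically, crankr
#' evaluates edge probabilities in closed form as a mixture between the
#' observed probability and the configuration-model expectation:
#' \deqn{p(u,v \mid \alpha) = (1-\alpha)\,p(u,v) + \alpha \min\!\big(1,\,
#'   k_u k_v / 2m\big),}
#' which equals the observed `p_uv` at `alpha = 0` and the configuration-model
#' edge probability at `alpha = 1` (a random graph with the original degree
#' sequence), and is linear in `alpha` in between.
#'
#' @param net A `crank_network`.
#' @param p_uv Observed edge probability(ies) in \[0, 1\]; recycled against
#'   `u`/`v`.
#' @param u,v Node IDs (vectors of equal length); `u != v` elementwise.
#' @param alpha Perturbation intensity in \[0, 1\].
#' @return Numeric vector of perturbed edge probabilities in \[0, 1\].
#' @examples
#' net <- as_crank_network(data.frame(a = c("a", "b"), b = c("b", "c")))
#' perturbed_edge_prob(net, 1, "a", "b", alpha = 0.15)
#' @export
perturbed_edge_prob <- function(net, p_uv, u, v, alpha) {
  stopifnot(is_crank_network(net))
  check_alpha(alpha)
  if (net$m <= 0) abort("empty network: no edges, configuration model undefined.")
  ui <- node_index(net, u)
  vi <- node_index(net, v)
  if (any(ui == vi)) abort("perturbed_edge_prob requires u != v.")
  if (any(p_uv < 0 | p_uv > 1)) abort("`p_uv` must lie in [0, 1].")
  pep(p_uv, net$deg[ui], net$deg[vi], net$m, alpha)
}

# internal fast path: mixture of observed probability and configuration model
pep <- function(p, du, dv, m, alpha) {
  (1 - alpha) * p + alpha * pmin(1, du * dv / (2 * m))
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    abort("`alpha` must be a single number in [0, 1].")
  }
  invisible(alpha)
}

#' Degree-preserving Monte-Carlo rewiring
#'
#' Physically rewires `ceiling(alpha * m)` randomly selected edges in a
#' degree-preserving manner: the selected edges are broken into stubs and the
#' stubs re-matched uniformly at random, rejecting self-loops and duplicate
#' edges (with bounded re-shuffling of the rejected stubs, then swap-repair
#' against already-placed edges). This function is the Monte-Carlo oracle
#' against which the analytic [perturbed_edge_prob()] is validated; the
#' prioritization metrics never call it.
#'
#' @param net A `crank_network`.
#' @param alpha Fraction of edges to rewire, in \[0, 1\].
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return A `crank_network` with the identical degree sequence.
#' @export
rewire_network <- function(net, alpha, seed) {
  stopifnot(is_crank_network(net))
  check_alpha(alpha)
  m <- net$m_count
  n_sel <- ceiling(alpha * m)
  if (n_sel < 2) {
    return(net)
  }
  withr::local_seed(as.integer(seed))
  sel <- sample.int(m, n_sel)
  kept <- setdiff(seq_len(m), sel)

  # current edge set: kept edges, then re-matched pairs appended
  cur_i <- net$i[kept]
  cur_j <- net$j[kept]
  cur_w <- net$w[kept]
  occupied <- new.env(parent = emptyenv(), size = 2L * m)
  for (k in seq_along(cur_i)) {
    assign(paste(cur_i[k], cur_j[k]), TRUE, envir = occupied)
  }
  is_free <- function(a, b) {
    a != b && is.null(occupied[[paste(min(a, b), max(a, b))]])
  }
  place <- function(a, b, wa) {
    if (!is_free(a, b)) return(FALSE)
    assign(paste(min(a, b), max(a, b)), TRUE, envir = occupied)
    cur_i <<- c(cur_i, min(a, b))
    cur_j <<- c(cur_j, max(a, b))
    cur_w <<- c(cur_w, wa)
    TRUE
  }

  stubs <- c(rbind(net$i[sel], net$j[sel]))
  wts <- c(rbind(net$w[sel], net$w[sel]))
  ord <- sample.int(length(stubs))
  pend_s <- stubs[ord]
  pend_w <- wts[ord]
  for (round in seq_len(100L)) {
    # vectorized matching round: pair consecutive stubs, accept pairs that
    # are loop-free and not duplicates (of kept edges, earlier new edges,
    # or of another pair accepted in this round)
    a <- pend_s[c(TRUE, FALSE)]; b <- pend_s[c(FALSE, TRUE)]
    wa <- pend_w[c(TRUE, FALSE)]; wb <- pend_w[c(FALSE, TRUE)]
    keys <- paste(pmin(a, b), pmax(a, b))
    taken <- vapply(keys, function(k) !is.null(occupied[[k]]), logical(1),
                    USE.NAMES = FALSE)
    ok <- a != b & !taken & !duplicated(keys)
    if (any(ok)) {
      for (k in keys[ok]) assign(k, TRUE, envir = occupied)
      cur_i <- c(cur_i, pmin(a, b)[ok])
      cur_j <- c(cur_j, pmax(a, b)[ok])
      cur_w <- c(cur_w, wa[ok])
    }
    fail_s <- c(rbind(a[!ok], b[!ok]))
    fail_w <- c(rbind(wa[!ok], wb[!ok]))
    if (!length(fail_s)) break
    ord <- sample.int(length(fail_s))
    pend_s <- fail_s[ord]
    pend_w <- fail_w[ord]
    if (round == 100L) {
      # swap-repair: resolve each stuck pair (a, b) by removing a placed
      # edge (c, d) and adding (a, d) and (c, b); degrees are unchanged
      for (p in seq_len(length(pend_s) %/% 2L)) {
        a <- pend_s[2L * p - 1L]; b <- pend_s[2L * p]
        wa <- pend_w[2L * p - 1L]
        done <- FALSE
        for (e in sample.int(length(cur_i))) {
          c_ <- cur_i[e]; d_ <- cur_j[e]
          for (pair in list(c(c_, d_), c(d_, c_))) {
            cc <- pair[1]; dd <- pair[2]
            if (a %in% c(cc, dd) || b %in% c(cc, dd)) next
            # tentatively remove (cc, dd) so freeness checks see it gone
            key <- paste(min(cc, dd), max(cc, dd))
            rm(list = key, envir = occupied)
            if (is_free(a, dd) && is_free(cc, b) &&
                !(min(a, dd) == min(cc, b) && max(a, dd) == max(cc, b))) {
              we <- cur_w[e]
              cur_i <- cur_i[-e]; cur_j <- cur_j[-e]; cur_w <- cur_w[-e]
              place(a, dd, wa)
              place(cc, b, we)
              done <- TRUE
              break
            }
            assign(key, TRUE, envir = occupied)
          }
          if (done) break
        }
        if (!done) {
          abort("rewire_network: unable to re-match stubs without multi-edges; graph too constrained.")
        }
      }
    }
  }
  new_crank_network(net$nodes, cur_i, cur_j, cur_w)
}
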