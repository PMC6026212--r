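# Small networks built in code, shared across test files.

# two 5-cliques joined by a single bridge edge
two_cliques_bridge <- function() {
  k5 <- t(utils::combn(5, 2))
  edges <- rbind(
    cbind(paste0("a", k5[, 1]), paste0("a", k5[, 2])),
    cbind(paste0("b", k5[, 1]), paste0("b", k5[, 2])),
    c("a1", "b1")
  )
  as_crank_network(data.frame(from = edges[, 1], to = edges[, 2]))
}

two_cliques_comms <- function() {
  tibble::tibble(
    community = rep(c("0", "1"), each = 5),
    node = c(paste0("a", 1:5), paste0("b", 1:5))
  )
}

# two triangles joined by one bridge edge
two_triangles_bridge <- function() {
  as_crank_network(data.frame(
    from = c("t1", "t1", "t2", "u1", "u1", "u2", "t1"),
    to   = c("t2", "t3", "t3", "u2", "u3", "u3", "u1")
  ))
}

# a weighted toy network with two loose groups
weighted_toy <- function() {
  as_crank_network(data.frame(
    from   = c("a", "a", "b", "c", "d", "d", "e", "c"),
    to     = c("b", "c", "c", "e", "e", "f", "f", "d"),
    weight = c(0.9, 0.8, 0.7, 0.3, 0.6, 0.9, 0.5, 0.4)
  ))
}

weighted_toy_comms <- function() {
  tibble::tibble(
    community = rep(c("0", "1"), each = 3),
    node = c("a", "b", "c", "d", "e", "f")
  )
}

# an Erdos-Renyi-ish seeded random network for property tests
random_net <- function(n = 20, p = 0.25, seed = 99) {
  withr::with_seed(seed, {
    pairs <- t(utils::combn(n, 2))
    keep <- stats::runif(nrow(pairs)) < p
    as_crank_network(data.frame(
      from = paste0("n", pairs[keep, 1]),
      to = paste0("n", pairs[keep, 2])
    ))
  })
}
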