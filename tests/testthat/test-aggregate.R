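test_that("scores become descending ranks with ID tie-breaks", {
  r <- ranks_from_scores(c(a = 0.9, b = 0.5, c = 0.1))
  expect_equal(r$community, c("a", "b", "c"))
  expect_equal(r$rank, 1:3)
  # all-equal scores fall back to ID order
  r2 <- ranks_from_scores(c(c = 0.5, a = 0.5, b = 0.5))
  expect_equal(r2$community, c("a", "b", "c"))
  r3 <- ranks_from_scores(c(a = 0.2, b = 0.9))
  expect_equal(r3$community[r3$rank == 1], "b")
  # numeric-looking IDs sort numerically on ties
  r4 <- ranks_from_scores(c(`10` = 0.5, `2` = 0.5))
  expect_equal(r4$community, c("2", "10"))
  expect_error(ranks_from_scores(c(a = NaN)), "finite")
})

test_that("equal-weight initialization averages ranks", {
  l <- ranks_from_scores(c(a = 3, b = 2, c = 1))
  agg <- initialize_aggregate(list(l, l, l, l))
  expect_equal(agg$community, c("a", "b", "c"))
  expect_equal(agg$score, 1:3)

  # hand-computed mean ranks 1, 2.25, 2.75 put a first
  mk <- function(ranks) {
    tibble::tibble(community = c("a", "b", "c"), rank = ranks)
  }
  agg2 <- initialize_aggregate(list(mk(c(1, 2, 3)), mk(c(1, 3, 2)),
                                    mk(c(1, 2, 3)), mk(c(1, 2, 3))))
  expect_equal(agg2$community, c("a", "b", "c"))
  expect_equal(agg2$score, c(1, 2.25, 2.75))

  # two reversed lists of two tie at 1.5; ID order decides
  l1 <- tibble::tibble(community = c("x", "y"), rank = 1:2)
  l2 <- tibble::tibble(community = c("y", "x"), rank = 1:2)
  agg3 <- initialize_aggregate(list(l1, l2))
  expect_equal(agg3$community, c("x", "y"))
  expect_equal(agg3$score, c(1.5, 1.5))

  bad <- tibble::tibble(community = c("x", "z"), rank = 1:2)
  expect_error(initialize_aggregate(list(l1, bad)), "identical community set")
})

test_that("importance weights track gold concentration per bag", {
  n <- 12
  ids <- sprintf("c%02d", 1:n)
  base <- tibble::tibble(community = ids, rank = 1:n)
  agg <- base # gold = top ranks of the aggregate

  # list ranks of the 4 gold communities: 1, 2, 3, 5 over 3 bags of 4
  perm <- c(1, 2, 3, 5)
  lr <- integer(n); lr[perm] <- 1:4; lr[-perm] <- 5:12
  list_r <- tibble::tibble(community = ids, rank = lr)
  K <- update_importance_weights(agg, list(list_r), n_bags = 3, gold_size = 4)
  # g = (3, 1, 0), e = 4/3 each: K^1 > K^2 > K^3
  expect_equal(as.vector(K), (c(3, 1, 0) + 1) / (4 / 3 + 1))
  expect_true(K[1] > K[2] && K[2] > K[3])

  # all gold in bag 1 maximizes the weight
  conc <- tibble::tibble(community = ids, rank = 1:n)
  K2 <- update_importance_weights(agg, list(conc), n_bags = 3, gold_size = 4)
  expect_equal(which.max(K2), 1L)

  # uniformly spread gold stays near 1 (within smoothing)
  spread <- tibble::tibble(community = ids,
                           rank = c(1, 5, 9, 2, 6, 10, 3, 7, 11, 4, 8, 12))
  K3 <- update_importance_weights(agg, list(spread), n_bags = 3,
                                  gold_size = 3)
  expect_true(all(abs(K3 - 1) < 0.5))
})

test_that("identical lists and single lists are fixed points", {
  scores <- setNames(seq(1, 0.1, length.out = 10), paste0("c", 0:9))
  l <- ranks_from_scores(scores)
  agg <- aggregate_ranks(list(l, l, l, l))
  expect_equal(agg$community, l$community)
  expect_true(attr(agg, "converged"))
  expect_equal(attr(agg, "iterations"), 1L)
  for (nb in c(1, 2, 3, 5, 10)) {
    single <- aggregate_ranks(list(l), n_bags = nb)
    expect_equal(single$community, l$community)
    expect_true(attr(single, "converged"))
  }
})

test_that("majority signal wins over one inverted list", {
  n <- 40
  ids <- sprintf("c%02d", 1:n)
  fwd <- tibble::tibble(community = ids, rank = 1:n)
  rev <- tibble::tibble(community = ids, rank = n:1)
  agg <- aggregate_ranks(list(fwd, fwd, fwd, rev))
  rho_fwd <- stats::cor(agg$rank[match(ids, agg$community)], 1:n,
                        method = "spearman")
  rho_rev <- stats::cor(agg$rank[match(ids, agg$community)], n:1,
                        method = "spearman")
  expect_gt(rho_fwd, rho_rev)
  expect_gt(rho_fwd, 0.9)
})

test_that("aggregation is deterministic and label-invariant", {
  withr::with_seed(5, {
    n <- 30
    ids <- sprintf("c%02d", 1:n)
    lists <- lapply(1:4, function(i) {
      ranks_from_scores(setNames(runif(n), ids))
    })
  })
  a1 <- aggregate_ranks(lists)
  a2 <- aggregate_ranks(lists)
  expect_identical(a1, a2)

  # relabel communities with a score-preserving bijection
  relab <- setNames(sprintf("z%02d", sample(seq_along(ids))), ids)
  lists2 <- lapply(lists, function(l) {
    tibble::tibble(community = unname(relab[l$community]), score = l$score,
                   rank = l$rank)
  })
  a3 <- aggregate_ranks(lists2)
  expect_equal(unname(relab[a1$community]), a3$community)
  expect_equal(a1$rank, a3$rank)
})

test_that("converged aggregates are true fixed points", {
  # four noisy views of one underlying quality signal (the benchmark regime)
  withr::with_seed(11, {
    n <- 25
    ids <- sprintf("c%02d", 1:n)
    signal <- sort(runif(n), decreasing = TRUE)
    lists <- lapply(1:4, function(i) {
      ranks_from_scores(setNames(signal + rnorm(n, sd = 0.15), ids))
    })
  })
  agg <- aggregate_ranks(lists, max_iter = 100)
  expect_true(attr(agg, "converged"))
  expect_false(attr(agg, "cycle_resolved")) # a genuine fixed point
  # one more two-stage pass must leave the order unchanged
  K <- update_importance_weights(agg, lists,
                                 n_bags = attr(agg, "n_bags"),
                                 gold_size = attr(agg, "gold_size"))
  comm <- lists[[1]]$community
  rank_mat <- vapply(lists, function(l) l$rank[match(comm, l$community)],
                     numeric(n))
  bag_mat <- crankr:::bag_of_rank(rank_mat, n, attr(agg, "n_bags"))
  w <- matrix(log1p(K[cbind(rep(1:4, each = n), as.vector(bag_mat))]),
              nrow = n)
  proposed <- rowSums(w * rank_mat) / rowSums(w)
  score_final <- agg$score[match(comm, agg$community)]
  it_next <- attr(agg, "iterations") + 1
  redo <- crankr:::order_aggregate(
    comm, score_final + (proposed - score_final) / it_next
  )
  expect_identical(redo$community, agg$community)
})

test_that("one shuffled list barely moves the consensus top decile", {
  n <- 100
  ids <- sprintf("c%03d", 1:n)
  fwd <- tibble::tibble(community = ids, rank = 1:n)
  shuf <- withr::with_seed(77, {
    tibble::tibble(community = sample(ids), rank = 1:n)
  })
  base <- aggregate_ranks(list(fwd, fwd, fwd, fwd))
  noisy <- aggregate_ranks(list(fwd, fwd, fwd, fwd, shuf))
  top <- function(a) a$community[a$rank <= n / 10]
  overlap <- length(intersect(top(base), top(noisy))) / (n / 10)
  expect_gte(overlap, 0.8)
})
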