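test_that("robustness score follows the defining formula and edge cases", {
  expect_equal(robustness_score(0, 0.7), 0)
  expect_equal(robustness_score(0.8, 0.8), 0.8)
  expect_equal(robustness_score(0.8, 0.3), 0.8 / 1.5)
  expect_error(robustness_score(1.2, 0.5), "\\[0, 1\\]")
  expect_error(robustness_score(0.5, -0.1), "\\[0, 1\\]")
  # vectorized
  expect_equal(robustness_score(c(0.4, 0.9), c(0.4, 0.1)),
               c(0.4, 0.9 / 1.8))
})

test_that("robustness score is non-increasing in the perturbation drift", {
  f0 <- 0.7
  drifts <- seq(0, 0.7, by = 0.05)
  vals <- robustness_score(rep(f0, length(drifts)), f0 - drifts)
  expect_true(all(diff(vals) <= 0))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("likelihood metric hits its closed-form corners", {
  net <- two_cliques_bridge()
  m <- crisp_model(net, two_cliques_comms())
  # a clique of full members: every factor is 1 (up to clipping)
  expect_equal(metric_likelihood(m, "0", 0), 1, tolerance = 1e-6)
  # a zero-membership member annihilates the product (up to clipping)
  m2 <- new_crank_model(
    net, tibble::tibble(community = "2", node = c("a1", "a2")),
    p_member = function(u, cid) as.numeric(net$nodes[u] != "a1"),
    p_edge = m$p_edge,
    p_comm_edge = function(u, v, cid) rep(1, length(u)),
    provider = "zero-member"
  )
  expect_lt(metric_likelihood(m2, "2", 0), 1e-3)
})

test_that("density metric: observed crisp edges give 1, no edges give 0", {
  net <- two_cliques_bridge()
  m <- crisp_model(net, two_cliques_comms())
  expect_equal(metric_density(m, "0", 0), 1, tolerance = 1e-6)
  # community with no internal edges
  comms <- rbind(two_cliques_comms(),
                 tibble::tibble(community = "2", node = c("a2", "b2")))
  m2 <- crisp_model(net, comms)
  expect_equal(metric_density(m2, "2", 0), 0)
  expect_equal(metric_density(m2, "2", 0.15), 0)
})

test_that("boundary metric: empty boundary gives 1, crisp cut crushes it", {
  net <- two_cliques_bridge()
  whole <- tibble::tibble(community = "0", node = net$nodes)
  m <- crisp_model(net, whole)
  expect_equal(metric_boundary(m, "0", 0), 1)
  # a community with an observed weight-1 boundary edge at alpha = 0
  m2 <- crisp_model(net, two_cliques_comms())
  b <- metric_boundary(m2, "0", 0)
  expect_lt(b, exp(log(1e-9) / 25)) # one annihilated factor out of 25 pairs
})

test_that("allegiance metric matches per-node accounting", {
  net <- two_triangles_bridge()
  comms <- tibble::tibble(community = rep(c("0", "1"), each = 3),
                          node = c("t1", "t2", "t3", "u1", "u2", "u3"))
  m <- crisp_model(net, comms)
  # each triangle node: 2 internal neighbors vs at most 1 external
  expect_equal(metric_allegiance(m, "0", 0), 1)
  # whole vertex set: no external neighbors
  whole <- tibble::tibble(community = "0", node = net$nodes)
  expect_equal(metric_allegiance(crisp_model(net, whole), "0", 0), 1)
  # singleton with neighbors loses
  single <- rbind(comms, tibble::tibble(community = "2", node = "t1"))
  expect_equal(metric_allegiance(crisp_model(net, single), "2", 0), 0)
})

test_that("all four metrics equal brute-force enumeration on toy fixtures", {
  fixtures <- list(
    list(model = crisp_model(two_cliques_bridge(), two_cliques_comms()),
         cids = c("0", "1")),
    list(model = crisp_model(weighted_toy(), weighted_toy_comms()),
         cids = c("0", "1"))
  )
  net3 <- random_net(n = 20, p = 0.25, seed = 99)
  fit3 <- fit_affiliation_model(net3, k = 3, seed = 13, assign = "argmax")
  fixtures <- c(fixtures, list(list(model = fit3,
                                    cids = unique(fit3$communities$community))))
  for (fx in fixtures) {
    for (cid in fx$cids) {
      for (a in c(0, 0.15)) {
        expect_metric_matches_oracle(fx$model, cid, a)
      }
    }
  }
})

test_that("boundary sampling with a full budget equals exact enumeration", {
  bm <- generate_sbm(n_blocks = 3, block_size = 10, p_in = 0.6, p_out = 0.1,
                     seed = 23)
  fit <- fit_affiliation_model(bm$net, k = 3, seed = 2, assign = "argmax")
  for (cid in unique(fit$communities$community)) {
    exact <- metric_boundary(fit, cid, 0.15, exact = TRUE)
    full <- metric_boundary(fit, cid, 0.15, n_samples = bm$net$n,
                            seed = 5, exact = FALSE)
    expect_equal(log(full), log(exact), tolerance = 1e-12)
  }
})

test_that("boundary sampling is unbiased in log space", {
  bm <- generate_sbm(n_blocks = 5, block_size = 10, p_in = 0.5, p_out = 0.08,
                     seed = 29)
  fit <- fit_affiliation_model(bm$net, k = 5, seed = 3, assign = "argmax")
  cid <- fit$communities$community[1]
  exact <- log(metric_boundary(fit, cid, 0.15, exact = TRUE))
  ests <- vapply(1:200, function(s) {
    log(metric_boundary(fit, cid, 0.15, n_samples = 5, seed = s,
                        exact = FALSE))
  }, numeric(1))
  se <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - exact), 3 * se)
})

test_that("metrics are invariant under node relabeling", {
  net <- weighted_toy()
  comms <- weighted_toy_comms()
  m <- crisp_model(net, comms)
  # relabel nodes by a fixed permutation and rebuild
  perm <- setNames(paste0("z", 7:2), c("a", "b", "c", "d", "e", "f"))
  ed <- network_edges(net)
  net2 <- as_crank_network(data.frame(from = perm[ed$from], to = perm[ed$to],
                                      w = ed$weight))
  comms2 <- tibble::tibble(community = comms$community, node = perm[comms$node])
  m2 <- crisp_model(net2, comms2)
  for (cid in c("0", "1")) {
    for (a in c(0, 0.15)) {
      expect_equal(metric_likelihood(m2, cid, a), metric_likelihood(m, cid, a))
      expect_equal(metric_density(m2, cid, a), metric_density(m, cid, a))
      expect_equal(metric_boundary(m2, cid, a, exact = TRUE),
                   metric_boundary(m, cid, a, exact = TRUE))
      expect_equal(metric_allegiance(m2, cid, a), metric_allegiance(m, cid, a))
    }
  }
})

test_that("score_communities composes the per-metric operations", {
  net <- two_cliques_bridge()
  m <- crisp_model(net, two_cliques_comms())
  tab <- score_communities(m, alpha = 0.15, seed = 11)
  expect_s3_class(tab, "crank_metrics")
  for (i in seq_len(nrow(tab))) {
    cid <- tab$community[i]
    expect_equal(tab$f_l0[i], metric_likelihood(m, cid, 0))
    expect_equal(tab$f_d_alpha[i], metric_density(m, cid, 0.15))
    expect_equal(tab$f_a0[i], metric_allegiance(m, cid, 0))
    expect_equal(tab$r_d[i], robustness_score(tab$f_d0[i], tab$f_d_alpha[i]))
  }
  expect_true(all(as.matrix(tab[-1]) >= 0 & as.matrix(tab[-1]) <= 1))
})

test_that("alpha = 0 as the perturbed level collapses scores onto features", {
  net <- weighted_toy()
  m <- crisp_model(net, weighted_toy_comms())
  tab <- score_communities(m, alpha = 0, seed = 2)
  expect_equal(tab$r_l, tab$f_l0)
  expect_equal(tab$r_d, tab$f_d0)
  expect_equal(tab$r_b, tab$f_b0)
  expect_equal(tab$r_a, tab$f_a0)
})

test_that("whole-network community keeps a perfect boundary score", {
  net <- two_triangles_bridge()
  m <- crisp_model(net, tibble::tibble(community = "0", node = net$nodes))
  tab <- score_communities(m, alpha = 0.15, seed = 1)
  expect_equal(tab$r_b, 1)
})

test_that("denser planted modules earn higher density robustness", {
  bm <- generate_sbm(seed = 31)
  m <- crisp_model(bm$net, bm$planted)
  tab <- score_communities(m, alpha = 0.15, seed = 7)
  tab <- dplyr::left_join(tab, bm$block_p_in, by = "community")
  med <- tapply(tab$r_d, tab$p_in, stats::median)
  expect_gt(med[["0.6"]], med[["0.2"]])
})
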