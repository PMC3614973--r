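# the worked 3-node network used throughout: w12 = .5, w13 = .2, w23 = .1
W3 <- matrix(c(0, .5, .2,
               .5, 0, .1,
               .2, .1, 0), 3, 3, byrow = TRUE)

test_that("strength matches hand computation on the 3-node network", {
  s <- strength(W3)
  expect_equal(unname(s$values), c(0.7, 0.6, 0.3))
  expect_equal(s$min, 0.3)
  expect_equal(s$mean, 1.6 / 3)
  expect_equal(s$max, 0.7)
  # uniform graph: every strength (N-1)c
  Wu <- matrix(0.4, 4, 4); diag(Wu) <- 0
  expect_equal(unname(strength(Wu)$values), rep(3 * 0.4, 4))
  W0 <- matrix(0, 3, 3)
  expect_equal(unname(strength(W0)$values), rep(0, 3))
})

test_that("shortest paths use 1/w lengths and prefer the direct edge", {
  p <- weighted_shortest_paths(W3)
  expect_equal(p$distances[1, 2], 2.0)       # direct 1/.5 beats 1/.2 + 1/.1
  expect_equal(p$distances[1, 3], 5.0)
  expect_equal(p$distances[2, 3], 1 / .5 + 1 / .2)  # detour via node 1 beats 1/.1
  Wu <- matrix(0.25, 5, 5); diag(Wu) <- 0
  pu <- weighted_shortest_paths(Wu)
  expect_true(all(pu$distances[upper.tri(pu$distances)] == 4))
  expect_equal(unname(pu$values), rep(4, 5))
})

test_that("raising a weight never lengthens any distance", {
  set.seed(3)
  W <- random_sl_graph(6)
  d0 <- weighted_shortest_paths(W)$distances
  W2 <- W
  W2[2, 5] <- W2[5, 2] <- min(0.99, W[2, 5] * 2)
  d1 <- weighted_shortest_paths(W2)$distances
  expect_true(all(d1 <= d0 + 1e-12))
})

test_that("zero off-diagonal weights are rejected by path metrics", {
  W <- W3
  W[1, 3] <- W[3, 1] <- 0
  expect_error(weighted_shortest_paths(W), "zero weight")
  expect_error(betweenness(W), "zero weight")
})

test_that("closeness is the reciprocal mean distance", {
  p <- weighted_shortest_paths(W3)
  cc <- closeness(p$distances)
  expect_equal(unname(cc$values), 1 / unname(p$values))
  expect_equal(order(cc$values), rev(order(p$values)))
  Wu <- matrix(0.3, 4, 4); diag(Wu) <- 0
  expect_equal(unname(closeness(weighted_shortest_paths(Wu)$distances)$values),
               rep(0.3, 4))
})

test_that("betweenness counts shortest-path transits over ordered pairs", {
  Wu <- matrix(0.5, 5, 5); diag(Wu) <- 0
  expect_equal(unname(betweenness(Wu)$values), rep(0, 5))
  # star-heavy weights: node 2 carries the 1-3 traffic in both directions
  Ws <- matrix(c(0, .9, .1,
                 .9, 0, .9,
                 .1, .9, 0), 3, 3, byrow = TRUE)
  bc <- betweenness(Ws)
  expect_equal(unname(bc$values), c(0, 2, 0))
})

test_that("eigenvector centrality solves the eigen equation", {
  ec <- eigenvector_centrality(W3)
  expect_equal(sqrt(sum(ec$values^2)), 1, tolerance = 1e-12)
  expect_true(all(ec$values >= 0))
  resid <- sqrt(sum((W3 %*% ec$values - ec$lambda * ec$values)^2))
  expect_lt(resid, 1e-10)
  # against the dense symmetric eigensolver
  ev <- eigen(W3, symmetric = TRUE)
  v <- abs(ev$vectors[, which.max(ev$values)])
  expect_equal(unname(ec$values), v, tolerance = 1e-9)
  Wu <- matrix(0.2, 4, 4); diag(Wu) <- 0
  expect_equal(unname(eigenvector_centrality(Wu)$values), rep(1 / 2, 4))
})

test_that("weighted clustering matches the single-triangle closed form", {
  cl <- weighted_clustering(W3)
  expect_equal(unname(cl$values),
               rep((1 * 0.4 * 0.2)^(1 / 3), 3), tolerance = 1e-12)
  Wu <- matrix(0.7, 5, 5); diag(Wu) <- 0
  expect_equal(unname(weighted_clustering(Wu)$values), rep(1, 5))
  expect_error(weighted_clustering(matrix(0, 2, 2)), "at least 3")
})

test_that("all metrics agree with brute-force enumeration on random graphs", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(3:7, 1)
    W <- random_sl_graph(n)
    o <- oracle_graph_metrics(W)
    expect_equal(unname(strength(W)$values), o$strength, tolerance = 1e-9)
    p <- weighted_shortest_paths(W)
    expect_equal(unname(p$distances), o$distances, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(unname(closeness(p$distances)$values), o$closeness,
                 tolerance = 1e-9)
    expect_equal(unname(betweenness(W)$values), o$betweenness,
                 tolerance = 1e-9)
    expect_equal(unname(eigenvector_centrality(W)$values), o$eigenvector,
                 tolerance = 1e-9)
    expect_equal(unname(weighted_clustering(W)$values), o$clustering,
                 tolerance = 1e-9)
  }
})

test_that("power-law MLE has its closed form and recovers a known exponent", {
  fit <- powerlaw_fit(c(1, exp(1), exp(2)), d_min = 1)
  expect_equal(fit$alpha, 2, tolerance = 1e-12)
  expect_equal(fit$n_tail, 3L)
  # scale invariance
  fit2 <- powerlaw_fit(10 * c(1, exp(1), exp(2)))
  expect_equal(fit2$alpha, fit$alpha, tolerance = 1e-12)
  # Monte-Carlo recovery: inverse-CDF draws from alpha = 2.5
  set.seed(123)
  d <- (1 - runif(10000))^(-1 / 1.5)
  expect_lt(abs(powerlaw_fit(d)$alpha - 2.5), 0.1)
  expect_error(powerlaw_fit(c(0, 1, 2)), "positive")
  expect_error(powerlaw_fit(rep(2, 5)), "undefined")
})

test_that("the ks cutoff scan also recovers the exponent", {
  set.seed(5)
  d <- (1 - runif(5000))^(-1 / 1.5)
  fit <- powerlaw_fit(d, method = "ks")
  expect_lt(abs(fit$alpha - 2.5), 0.15)
})

test_that("feature vectors have 18 named, ordered, finite entries", {
  set.seed(31)
  W <- random_sl_graph(7)
  fv <- feature_vector(W)
  expect_identical(names(fv), feature_names())
  expect_true(all(is.finite(unlist(fv))))
  # min <= mean <= max inside every family
  for (fam in c("strength", "path", "closeness", "eigenvector", "clustering")) {
    expect_lte(fv[[paste0(fam, "_min")]], fv[[paste0(fam, "_mean")]])
    expect_lte(fv[[paste0(fam, "_mean")]], fv[[paste0(fam, "_max")]])
  }
  expect_lte(fv[["betweenness_mean"]], fv[["betweenness_max"]])
})

test_that("features are invariant under channel relabelling", {
  set.seed(13)
  W <- random_sl_graph(6)
  perm <- sample(6)
  expect_equal(feature_vector(W), feature_vector(W[perm, perm]),
               tolerance = 1e-9)
})

test_that("a uniform network collapses every family to a single value", {
  # (assembled metric by metric: equal strengths leave the power-law index
  # undefined, so feature_vector() correctly refuses this degenerate graph)
  Wu <- matrix(0.5, 6, 6); diag(Wu) <- 0
  p <- weighted_shortest_paths(Wu)
  for (m in list(strength(Wu), p, closeness(p$distances),
                 eigenvector_centrality(Wu), weighted_clustering(Wu))) {
    expect_equal(m$min, m$max, tolerance = 1e-12)
  }
  expect_error(feature_vector(Wu), "undefined")
})

test_that("path-based metrics agree with an established graph library", {
  skip_if_not_installed("igraph")
  set.seed(55)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    W <- random_sl_graph(n)
    g <- igraph::graph_from_adjacency_matrix(1 / W, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    expect_equal(unname(weighted_shortest_paths(W)$distances),
                 unname(igraph::distances(g)), tolerance = 1e-9)
    # igraph counts unordered pairs; ours counts ordered pairs
    expect_equal(unname(betweenness(W)$values),
                 2 * unname(igraph::betweenness(g, directed = FALSE)),
                 tolerance = 1e-9)
  }
})
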