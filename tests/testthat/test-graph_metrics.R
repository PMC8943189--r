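# Weighted topology measures against brute-force oracles and closed forms.

test_that("weight-to-distance and shortest paths follow the reciprocal rule", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 2
  d <- weight_to_distance(w)
  expect_equal(d[1, 2], 0.5)
  expect_identical(d[1, 3], Inf)
  expect_identical(diag(d), rep(0, 3))

  # chain A-B-C with unit weights: d(A,C) = 2
  ch <- matrix(0, 3, 3)
  ch[1, 2] <- ch[2, 1] <- 1
  ch[2, 3] <- ch[3, 2] <- 1
  expect_equal(shortest_path_matrix(ch)[1, 3], 2)

  # heavy direct shortcut wins: AB=1, BC=1, AC=10 -> d(A,C) = 0.1
  tri <- ch
  tri[1, 3] <- tri[3, 1] <- 10
  sp <- shortest_path_matrix(tri)
  expect_equal(sp[1, 3], 0.1)
  expect_equal(sp, oracle_floyd_warshall(tri), ignore_attr = TRUE)

  # isolated node: infinite everywhere off-diagonal
  iso <- matrix(0, 3, 3)
  iso[1, 2] <- iso[2, 1] <- 1
  spi <- shortest_path_matrix(iso)
  expect_identical(spi[3, 1:2], c(Inf, Inf))
  expect_identical(spi[3, 3], 0)
})

test_that("efficiencies match closed forms and the brute-force oracle", {
  # two nodes with weight w: single pair at distance 1/w
  w2 <- matrix(c(0, 3.7, 3.7, 0), 2, 2)
  expect_equal(global_efficiency(w2), 3.7)
  # fully disconnected graph has zero efficiency
  expect_equal(global_efficiency(matrix(0, 4, 4)), 0)
  # star graph: no neighbor-neighbor edges -> local efficiency 0
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(local_efficiency(star)$mean, 0)
  # complete triangle, uniform weight: each neighbor subgraph is one pair
  tri <- matrix(2.5, 3, 3); diag(tri) <- 0
  expect_equal(unname(local_efficiency(tri)$nodal), rep(2.5, 3))

  for (s in 1:8) {
    w <- random_weighted_graph(10, 0.4, seed = s)
    expect_equal(global_efficiency(w), oracle_global_efficiency(w),
                 tolerance = 1e-10)
    expect_equal(unname(nodal_efficiency(w)), oracle_nodal_efficiency(w),
                 tolerance = 1e-10)
    expect_equal(unname(local_efficiency(w)$nodal),
                 oracle_local_efficiency(w), tolerance = 1e-10)
    expect_equal(global_efficiency(w), mean(nodal_efficiency(w)),
                 tolerance = 1e-12)
  }
})

test_that("degree, strength and assortativity", {
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  ds <- degree_strength(k4)
  expect_identical(ds$degree, rep(3L, 4))
  expect_equal(ds$strength, rep(3, 4))
  empty <- matrix(0, 3, 3)
  expect_identical(degree_strength(empty)$degree, rep(0L, 3))

  # star: perfectly disassortative
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(assortativity_degree_weighted(star), -1)
  # regular ring: zero degree variance -> undefined
  ring <- matrix(0, 6, 6)
  for (i in 1:6) { j <- i %% 6 + 1; ring[i, j] <- ring[j, i] <- 1 }
  expect_true(is.na(assortativity_degree_weighted(ring)))
  # random graph vs direct correlation over the doubled edge list
  w <- random_weighted_graph(12, 0.4, seed = 31)
  deg <- rowSums(w > 0)
  e <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  oracle <- cor(c(deg[e[, 1]], deg[e[, 2]]), c(deg[e[, 2]], deg[e[, 1]]))
  expect_equal(assortativity_degree_weighted(w), oracle, tolerance = 1e-12)
})

test_that("Onnela clustering and hierarchy against loop oracles", {
  w <- random_weighted_graph(10, 0.5, seed = 17)
  expect_equal(unname(clustering_onnela(w)), oracle_onnela_clustering(w),
               tolerance = 1e-10)
  # hierarchy beta equals an independent log-log regression
  k <- rowSums(w > 0)
  cc <- oracle_onnela_clustering(w)
  ok <- k >= 2 & cc > 0
  beta <- -unname(coef(lm(log(cc[ok]) ~ log(k[ok])))[2])
  expect_equal(hierarchy(w), beta, tolerance = 1e-10)
  # constant degree and clustering: flat decay, beta 0
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  expect_equal(hierarchy(k4), 0)
  # fewer than 3 eligible nodes: undefined
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  expect_true(is.na(hierarchy(star)))
})

test_that("rich club matches enumeration and its closed forms", {
  # complete uniform graph: numerator equals denominator at every level
  k4 <- matrix(2, 4, 4); diag(k4) <- 0
  rc <- rich_club(k4)
  expect_true(all(abs(rc - 1) < 1e-12))
  # levels at or above the maximum degree are omitted
  expect_false("3" %in% names(rc))
  # toy graphs vs brute-force enumeration
  for (s in 1:5) {
    w <- random_weighted_graph(6, 0.5, seed = 40 + s)
    expect_equal(rich_club(w), oracle_rich_club(w), tolerance = 1e-10)
  }
})

test_that("betweenness matches exhaustive path enumeration", {
  # path A-B-C: B lies on the single shortest path of one pair
  ch <- matrix(0, 3, 3)
  ch[1, 2] <- ch[2, 1] <- 1
  ch[2, 3] <- ch[3, 2] <- 1
  expect_equal(unname(betweenness_weighted(ch)), c(0, 1, 0))
  # complete uniform graph: all direct paths, zero betweenness
  k5 <- matrix(1, 5, 5); diag(k5) <- 0
  expect_equal(unname(betweenness_weighted(k5)), rep(0, 5))
  for (s in 1:5) {
    w <- random_weighted_graph(7, 0.5, seed = 50 + s)
    expect_equal(unname(betweenness_weighted(w)), oracle_betweenness(w),
                 tolerance = 1e-10)
  }
})

test_that("small-world indices: identity, lattice regime, determinism", {
  # Watts-Strogatz-style lattice with shortcuts: high clustering relative
  # to degree-matched randomizations
  n <- 20
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (o in 1:2) {
      j <- (i + o - 1) %% n + 1
      w[i, j] <- w[j, i] <- 1
    }
  }
  w[1, 10] <- w[10, 1] <- 1
  w[5, 15] <- w[15, 5] <- 1
  sw <- small_worldness(w, n_rand = 30, seed = 2)
  expect_equal(sw$sigma, sw$gamma / sw$lambda, tolerance = 1e-12)
  expect_gt(sw$sigma, 1)
  # determinism under a fixed seed
  sw2 <- small_worldness(w, n_rand = 30, seed = 2)
  expect_identical(sw, sw2)
})

test_that("weight scaling: efficiency scales, topology metrics do not", {
  w <- random_weighted_graph(12, 0.45, seed = 77)
  c_ <- 3.2
  expect_equal(global_efficiency(c_ * w), c_ * global_efficiency(w),
               tolerance = 1e-10)
  expect_equal(local_efficiency(c_ * w)$mean,
               c_ * local_efficiency(w)$mean, tolerance = 1e-10)
  expect_identical(degree_strength(c_ * w)$degree, degree_strength(w)$degree)
  expect_equal(assortativity_degree_weighted(c_ * w),
               assortativity_degree_weighted(w), tolerance = 1e-12)
  sw1 <- small_worldness(w, n_rand = 10, seed = 5)
  sw2 <- small_worldness(c_ * w, n_rand = 10, seed = 5)
  expect_equal(sw1$gamma, sw2$gamma, tolerance = 1e-10)
  expect_equal(sw1$lambda, sw2$lambda, tolerance = 1e-10)
})

test_that("relabeling nodes leaves metrics unchanged", {
  w <- random_weighted_graph(11, 0.4, seed = 91)
  set.seed(1)
  p <- sample(11)
  wp <- w[p, p]
  expect_equal(global_efficiency(wp), global_efficiency(w),
               tolerance = 1e-10)
  expect_equal(local_efficiency(wp)$mean, local_efficiency(w)$mean,
               tolerance = 1e-10)
  expect_equal(hierarchy(wp), hierarchy(w), tolerance = 1e-10)
  expect_equal(assortativity_degree_weighted(wp),
               assortativity_degree_weighted(w), tolerance = 1e-12)
  expect_equal(rich_club(wp), rich_club(w), tolerance = 1e-10)
  expect_equal(sort(unname(betweenness_weighted(wp))),
               sort(unname(betweenness_weighted(w))), tolerance = 1e-10)
})

test_that("metric_set assembles consistently and deterministically", {
  w <- random_weighted_graph(15, 0.4, seed = 8)
  ms1 <- metric_set(w, n_rand = 10, seed = 3)
  ms2 <- metric_set(w, n_rand = 10, seed = 3)
  expect_identical(ms1, ms2)
  expect_equal(ms1$global_efficiency, mean(ms1$nodal_efficiency),
               tolerance = 1e-12)
  expect_length(ms1$degree, 15L)
  expect_true(all(ms1$degree <= 14L))
  # mirror-symmetric hemisphere pair gives identical metric sets
  co <- simulate_cohort(generator_config(seed = 12, n_subjects = 1))
  sp <- split_hemispheres(co$template, "left")
  m_i <- metric_set(sp$ipsi, n_rand = 5, seed = 9)
  m_c <- metric_set(sp$contra, n_rand = 5, seed = 9)
  expect_equal(metric_scalars(m_i), metric_scalars(m_c), tolerance = 1e-10)
})
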