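# Edge-wise paired statistic, threshold-free score transform, permutation
# FWE inference.

# pairs with a single varying edge (1,2) carrying per-subject differences d
single_edge_pairs <- function(d, nn = 3) {
  lapply(d, function(di) {
    wi <- matrix(0, nn, nn)
    wc <- matrix(0, nn, nn)
    wi[1, 2] <- wi[2, 1] <- 10
    wc[1, 2] <- wc[2, 1] <- 10 + di
    make_pair(wi, wc)
  })
}

test_that("identical hemispheres give all-zero statistics", {
  pairs <- single_edge_pairs(rep(0, 5))
  st <- paired_edge_statistic(pairs, c("left", "left", "right", "right",
                                       "right"))
  expect_true(all(st$t_values == 0))
})

test_that("intercept t matches the closed-form normal-equations solution", {
  d <- c(1, 2, 3, 2, 1)
  side <- c(-1, -1, 1, 1, 1)
  pairs <- single_edge_pairs(d)
  covariate <- ifelse(side > 0, "right", "left")
  st <- paired_edge_statistic(pairs, covariate)

  # oracle: explicit least squares on X = [1, centered side]
  X <- cbind(1, side - mean(side))
  beta <- solve(t(X) %*% X, t(X) %*% d)
  rss <- sum((d - X %*% beta)^2)
  se0 <- sqrt(rss / (length(d) - 2) * solve(t(X) %*% X)[1, 1])
  expect_equal(st$t_values[1, 2], beta[1] / se0, tolerance = 1e-12)
  expect_identical(st$df, 3L)
  expect_true(isSymmetric(st$t_values))
})

test_that("direction swap negates differences before truncation", {
  pairs <- single_edge_pairs(c(2, 3, 2.5, 3.5, 3))  # strong contra > ipsi
  cov <- c("left", "left", "right", "right", "right")
  fwd <- paired_edge_statistic(pairs, cov, "contra_gt_ipsi")
  rev <- paired_edge_statistic(pairs, cov, "ipsi_gt_contra")
  expect_gt(fwd$t_values[1, 2], 0)
  expect_identical(rev$t_values[1, 2], 0)
})

test_that("constant covariate falls back to a one-sample t with warning", {
  d <- c(1, 2, 3, 2, 1)
  pairs <- single_edge_pairs(d)
  expect_warning(st <- paired_edge_statistic(pairs, rep("left", 5)),
                 "constant")
  expect_equal(st$t_values[1, 2], mean(d) / (sd(d) / sqrt(5)),
               tolerance = 1e-12)
  expect_identical(st$df, 4L)
})

test_that("score of an isolated edge approaches the analytic integral", {
  # single suprathreshold edge: extent = 1 at every threshold, so the score
  # tends to the integral of h^3 dh from 0 to t, i.e. t^4/4
  tm <- matrix(0, 6, 6)
  tm[1, 2] <- tm[2, 1] <- 2
  for (mode in c("component", "incident")) {
    sc <- tfnbs_transform(tm, tfnbs_params(n_steps = 1000,
                                           extent_mode = mode))
    expect_equal(sc[1, 2], 4, tolerance = 0.005)
    expect_true(all(sc[tm == 0] == 0))
  }
  # rescaling the statistic by c rescales the score by c^(H+1)
  sc1 <- tfnbs_transform(tm, tfnbs_params(n_steps = 400))
  sc2 <- tfnbs_transform(2.5 * tm, tfnbs_params(n_steps = 400))
  expect_equal(sc2[1, 2] / sc1[1, 2], 2.5^4, tolerance = 1e-10)
})

test_that("all-zero statistic maps score zero and negatives are rejected", {
  tm <- matrix(0, 5, 5)
  expect_true(all(tfnbs_transform(tm) == 0))
  tm[1, 2] <- tm[2, 1] <- -1
  expect_error(tfnbs_transform(tm), "negative")
})

test_that("adjacent suprathreshold edges outscore disjoint ones", {
  # two edges of equal height: sharing a node (or component) raises extent
  disjoint <- matrix(0, 4, 4)
  disjoint[1, 2] <- disjoint[2, 1] <- 1
  disjoint[3, 4] <- disjoint[4, 3] <- 1
  adjacent <- matrix(0, 4, 4)
  adjacent[1, 2] <- adjacent[2, 1] <- 1
  adjacent[2, 3] <- adjacent[3, 2] <- 1
  for (mode in c("component", "incident")) {
    par <- tfnbs_params(n_steps = 500, extent_mode = mode)
    sd_ <- tfnbs_transform(disjoint, par)
    sa <- tfnbs_transform(adjacent, par)
    expect_gt(sa[1, 2], sd_[1, 2])
  }
  # fine-grid brute-force check of the component-mode value: two edges in one
  # component, extent 2 at all thresholds -> score = 2^0.4 * t^4/4
  par <- tfnbs_params(n_steps = 2000)
  sa <- tfnbs_transform(adjacent, par)
  expect_equal(sa[1, 2], 2^0.4 * 1 / 4, tolerance = 0.005)
})

test_that("raising one edge's statistic never lowers its score", {
  set.seed(9)
  for (rep in 1:5) {
    tm <- random_weighted_graph(8, 0.4, seed = 100 + rep)
    tm <- tm / max(tm) * 3
    par <- tfnbs_params(n_steps = 50)
    s0 <- tfnbs_transform(tm, par)
    e <- which(tm > 0, arr.ind = TRUE)[1, ]
    tm2 <- tm
    tm2[e[1], e[2]] <- tm2[e[2], e[1]] <- tm[e[1], e[2]] * 1.5
    s1 <- tfnbs_transform(tm2, par)
    expect_gte(s1[e[1], e[2]], s0[e[1], e[2]] - 1e-12)
  }
})

test_that("permutation p-values respect the +1/+1 floor and monotonicity", {
  pairs <- single_edge_pairs(c(2, 3, 2.5, 3.5, 3, 2.2, 2.8, 3.1), nn = 5)
  cov <- rep(c("left", "right"), 4)
  res <- permutation_fwe(pairs, cov, tfnbs_params(n_perm = 200, seed = 4))
  ut <- upper.tri(res$p_fwe)
  expect_true(all(res$p_fwe[ut] >= 1 / 201))
  expect_true(all(res$p_fwe[ut] <= 1))
  expect_length(res$null_max, 200L)
  # monotone: larger score implies smaller-or-equal p within one result
  o <- order(res$scores[ut])
  expect_true(all(diff(res$p_fwe[ut][o]) <= 1e-15))
  # warning when n_perm exceeds the number of distinct sign patterns
  expect_warning(
    permutation_fwe(single_edge_pairs(c(1, 2, 1.5)), c("left", "right",
                                                       "right"),
                    tfnbs_params(n_perm = 20, seed = 1)),
    "sign patterns")
})

test_that("Freedman-Lane with constant covariate equals pure sign-flipping", {
  d <- c(1.5, -0.5, 2, 0.3, -1, 0.8, 1.2)
  n <- length(d)
  pairs <- single_edge_pairs(d)
  par <- tfnbs_params(n_perm = 64, seed = 21, n_steps = 100)
  res <- suppressWarnings(permutation_fwe(pairs, rep("left", n), par))

  # reference: pure subject-level sign flips of d, same RNG stream
  set.seed(par$seed)
  S <- matrix(sample(c(-1, 1), par$n_perm * n, replace = TRUE), par$n_perm, n)
  ref <- vapply(seq_len(par$n_perm), function(b) {
    ds <- S[b, ] * d
    tv <- mean(ds) / (sd(ds) / sqrt(n))
    tm <- matrix(0, 3, 3)
    tm[1, 2] <- tm[2, 1] <- max(tv, 0)
    max(tfnbs_transform(tm, par))
  }, numeric(1))
  expect_equal(res$null_max, ref, tolerance = 1e-12)
})

test_that("significant_edges filters, sorts and handles edge cases", {
  pairs <- single_edge_pairs(c(2, 3, 2.5, 3.5, 3, 2.2, 2.8, 3.1), nn = 4)
  cov <- rep(c("left", "right"), 4)
  res <- permutation_fwe(pairs, cov, tfnbs_params(n_perm = 250, seed = 8))
  sig <- significant_edges(res, alpha = 0.05)
  expect_true(all(sig$p_fwe < 0.05))
  expect_true(!is.unsorted(sig$p_fwe))
  expect_identical(nrow(significant_edges(res, alpha = 0)), 0L)
  res1 <- res
  res1$p_fwe[] <- 1
  expect_identical(nrow(significant_edges(res1, alpha = 0.05)), 0L)
})
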