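# Synthetic cohort generator: atlas structure, template symmetry, lesion
# model, clinical marginals, replicates, determinism.

test_that("default atlas has the expected composition", {
  atlas <- make_default_atlas()
  expect_identical(nrow(atlas), 79L)
  expect_identical(sum(atlas$tissue_class %in% c("cortical", "subcortical")),
                   76L)
  expect_identical(sum(atlas$hemisphere == "left"), 39L)
  expect_identical(sum(atlas$hemisphere == "right"), 39L)
  expect_identical(sum(atlas$hemisphere == "midline"), 1L)
  hom <- attr(atlas, "homolog")
  expect_length(hom, 39L)
  expect_false(anyDuplicated(hom) > 0)
  expect_true(all(sub("lh.", "", names(hom), fixed = TRUE) ==
                    sub("rh.", "", unname(hom), fixed = TRUE)))
})

test_that("template is mirror-symmetric and modular", {
  cfg <- generator_config(seed = 5)
  set.seed(cfg$seed)
  tpl <- simulate_template(cfg)
  sp <- split_hemispheres(tpl, "left")
  expect_equal(unname(sp$ipsi$weights), unname(sp$contra$weights))
  expect_true(isSymmetric(tpl$weights))
  expect_true(all(diag(tpl$weights) == 0))
  expect_true(all(tpl$weights >= 0))
  # edge density within modules exceeds between-module density
  modules <- attr(tpl, "modules")
  atlas <- tpl$nodes
  left <- names(attr(atlas, "homolog"))
  base <- sub("lh.", "", left, fixed = TRUE)
  wl <- tpl$weights[left, left] > 0
  same <- outer(modules[base], modules[base], "==")
  ut <- upper.tri(wl)
  expect_gt(mean(wl[ut & same]), mean(wl[ut & !same]))
})

test_that("zero lesion effect leaves the truth ledger empty", {
  co <- simulate_cohort(generator_config(seed = 8, n_subjects = 5,
                                         lesion_effect_delta = 0))
  for (t in co$truth) {
    expect_identical(nrow(t$affected_edges), 0L)
    expect_identical(t$delta, 0)
  }
})

test_that("affected edges are confined to the ipsilesional hemisphere", {
  co <- simulate_cohort(generator_config(seed = 13, n_subjects = 6))
  atlas <- co$atlas
  for (t in co$truth) {
    hemi_labs <- c(atlas$label[atlas$hemisphere == t$lesion_side],
                   atlas$label[atlas$hemisphere == "midline"])
    expect_gt(nrow(t$affected_edges), 0)
    expect_true(all(t$affected_edges$node_i %in% hemi_labs))
    expect_true(all(t$affected_edges$node_j %in% hemi_labs))
    expect_length(t$lesion_nodes, 4L)
    # after the split, every affected edge lies inside the ipsi matrix
    i <- match(t$lesion_side, c("left", "right"))
    expect_true(all(t$affected_edges$node_i %in% hemi_labs))
  }
})

test_that("affected edges are weakened below their homologs on average", {
  co <- simulate_cohort(generator_config(seed = 21, n_subjects = 8))
  atlas <- co$atlas
  hom <- attr(atlas, "homolog")
  to_other <- c(stats::setNames(unname(hom), names(hom)),
                stats::setNames(names(hom), unname(hom)),
                stats::setNames("brainstem", "brainstem"))
  ratios <- unlist(lapply(seq_along(co$subjects), function(s) {
    t <- co$truth[[s]]
    w <- co$subjects[[s]]$connectome_a$weights
    apply(t$affected_edges, 1, function(e) {
      w[e[["node_i"]], e[["node_j"]]] /
        w[to_other[[e[["node_i"]]]], to_other[[e[["node_j"]]]]]
    })
  }))
  ratios <- ratios[is.finite(ratios)]
  expect_lt(mean(ratios), 1)
  expect_lt(median(ratios), 1)
})

test_that("clinical marginals match the configured targets", {
  co <- simulate_cohort(generator_config(seed = 4))
  cl <- co$clinical
  expect_identical(nrow(cl), 37L)
  # MRC marginal is exact by construction
  expect_identical(as.integer(table(factor(cl$mrc, levels = 2:5))),
                   c(1L, 1L, 12L, 23L))
  expect_identical(sum(is.na(cl$nihss)), 3L)
  # RMT ratio within 3 standard errors of 1.02
  expect_lt(abs(mean(cl$rmt_ratio) - 1.02), 3 * 0.166 / sqrt(37))
  # grade proportions over a large cohort approach 13:10:14
  big <- simulate_cohort(generator_config(seed = 19, n_subjects = 400,
                                          nihss_missing = 0))
  pg <- as.numeric(table(factor(big$clinical$who_grade, 2:4))) / 400
  expect_true(all(abs(pg - c(13, 10, 14) / 37) < 0.08))
  # lesion side proportion near 21/37 right
  pr <- mean(big$clinical$lesion_side == "right")
  expect_lt(abs(pr - 21 / 37), 0.08)
  # subgroup tags average slightly above one per subject (overlap)
  ntags <- mean(lengths(big$clinical$subgroups))
  expect_gt(ntags, 1)
  expect_lt(ntags, 1.35)
})

test_that("algorithm replicate preserves pattern and correlates strongly", {
  co <- simulate_cohort(generator_config(seed = 9, n_subjects = 2))
  s <- co$subjects[[1]]
  # noiseless identity configuration
  cfg0 <- generator_config(algorithm_scale = 1, algorithm_noise_sd = 0)
  rep0 <- algorithm_replicate(s$connectome_a, cfg0)
  expect_equal(rep0$weights, s$connectome_a$weights, tolerance = 1e-12)
  # pure rescaling scales global efficiency by the same factor
  cfg9 <- generator_config(algorithm_scale = 0.9, algorithm_noise_sd = 0)
  rep9 <- algorithm_replicate(s$connectome_a, cfg9)
  expect_equal(global_efficiency(rep9),
               0.9 * global_efficiency(s$connectome_a), tolerance = 1e-10)
  # default replicate: same zero pattern, strong edge-weight correlation
  b <- s$connectome_b$weights
  a <- s$connectome_a$weights
  expect_identical(b > 0, a > 0)
  ut <- upper.tri(a) & a > 0
  expect_gt(cor(a[ut], b[ut]), 0.8)
})

test_that("cohorts are deterministic given the seed, on disk too", {
  cfg <- generator_config(seed = 33, n_subjects = 3)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_equal(c1$clinical, c2$clinical)
  expect_equal(c1$subjects[[2]]$connectome_a$weights,
               c2$subjects[[2]]$connectome_a$weights)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(c1, d1)
  write_cohort(c2, d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  # round-trip through read_cohort
  back <- read_cohort(d1)
  expect_equal(back$subjects[[1]]$connectome_a$weights,
               c1$subjects[[1]]$connectome_a$weights, tolerance = 1e-10)
})

test_that("larger lesion effects monotonically depress ipsi efficiency", {
  geff <- sapply(c(0, 0.3, 0.6), function(delta) {
    co <- simulate_cohort(generator_config(
      seed = 55, n_subjects = 6, lesion_effect_delta = delta))
    mean(sapply(seq_along(co$subjects), function(i) {
      sp <- split_hemispheres(co$subjects[[i]]$connectome_a,
                              co$clinical$lesion_side[i])
      global_efficiency(sp$ipsi)
    }))
  })
  expect_true(all(diff(geff) < 0))
  # paired split symmetry under the null: differences centered near zero
  co0 <- simulate_cohort(generator_config(seed = 56, n_subjects = 12,
                                          lesion_effect_delta = 0))
  d <- sapply(seq_along(co0$subjects), function(i) {
    sp <- split_hemispheres(co0$subjects[[i]]$connectome_a,
                            co0$clinical$lesion_side[i])
    global_efficiency(sp$contra) - global_efficiency(sp$ipsi)
  })
  tt <- t.test(d)
  expect_gt(tt$p.value, 0.01)
})
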