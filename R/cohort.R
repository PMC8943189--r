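# Seeded synthetic glioma-cohort generator: mirror-symmetric whole-brain
# templates with modular intra-hemispheric topology, per-subject noise,
# lesion-localized ipsilesional weight reduction, two correlated tractography
# replicates per subject, and clinical covariates with realistic marginals.

.subgroup_seed_region <- c(precentral = "precentral",
                           postcentral = "postcentral",
                           insular = "insula",
                           frontal = "superiorfrontal")

#' Generator configuration
#'
#' Defaults reproduce the study conditions of a 37-patient unilateral glioma
#' cohort: lesion side 16 left : 21 right, subgroup weights 16:15:8:3
#' (precentral:postcentral:insular:frontal, multi-membership allowed), WHO
#' grade weights 13:10:14 (II:III:IV), tumor volume lognormal with mean
#' 24.97 and SD 23.84 cm^3, RMT ratio normal(1.02, 0.166), MRC marginal
#' \{2:1, 3:1, 4:12, 5:23\}/37, NIHSS missing in 3 subjects. Baseline weights
#' are lognormal on a scale placing hemispheric global efficiency near 5e3.
#'
#' @param n_subjects cohort size.
#' @param module_count intra-hemispheric modules per hemisphere.
#' @param within_module_p,between_module_p intra-hemispheric edge
#'   probabilities within/between modules.
#' @param weight_log_mean,weight_log_sd lognormal baseline weight parameters
#'   (log streamline counts).
#' @param homotopic_p probability of an interhemispheric homotopic edge.
#' @param brainstem_p probability of a brainstem edge per lateralized node.
#' @param subject_noise_sd log-scale SD of per-edge subject noise.
#' @param subject_scale_sd log-scale SD of the per-subject global weight
#'   factor (between-subject variation in total streamline count).
#' @param lesion_effect_delta mean fractional weight reduction on affected
#'   edges; 0 disables the lesion effect (global-null configuration).
#' @param lesion_concentration Beta concentration of the per-subject delta.
#' @param lesion_node_count nodes in the lesion neighborhood.
#' @param grade_delta_slope,volume_delta_slope modulation of the expected
#'   delta by WHO grade (per grade unit from III) and tumor volume (per cm^3
#'   from the cohort mean).
#' @param subgroup_weights,overlap_p subgroup sampling weights and the
#'   probability of a second subgroup tag.
#' @param lesion_side_p_right probability of a right-sided lesion.
#' @param grade_weights WHO grade sampling weights for grades 2, 3, 4.
#' @param volume_mean,volume_sd tumor volume moments (cm^3) matched by the
#'   lognormal.
#' @param rmt_ratio_mean,rmt_ratio_sd,rmt_healthy_mean,rmt_healthy_sd RMT
#'   marginals (V/m; ratio dimensionless), normal truncated to positive.
#' @param nihss_coupling,nihss_noise_sd linear coupling of NIHSS to realized
#'   fractional connectivity damage, and its additive noise; coupling 0
#'   decouples NIHSS from the lesion (null configuration).
#' @param nihss_missing number of subjects with missing NIHSS.
#' @param mrc_marginal MRC counts for grades 2..5, rescaled to the cohort.
#' @param algorithm_scale,algorithm_noise_sd global weight factor and
#'   log-scale edge noise of the deterministic-like tractography replicate.
#' @param seed integer root seed.
#' @return A \code{generator_config} list.
#' @export
generator_config <- function(
    n_subjects = 37,
    module_count = 5,
    within_module_p = 0.8,
    between_module_p = 0.3,
    weight_log_mean = log(4600),
    weight_log_sd = 0.6,
    homotopic_p = 0.8,
    brainstem_p = 0.5,
    subject_noise_sd = 0.15,
    subject_scale_sd = 0.08,
    lesion_effect_delta = 0.3,
    lesion_concentration = 50,
    lesion_node_count = 4,
    grade_delta_slope = 0.15,
    volume_delta_slope = 0.002,
    subgroup_weights = c(precentral = 16, postcentral = 15, insular = 8,
                         frontal = 3),
    overlap_p = 5 / 37,
    lesion_side_p_right = 21 / 37,
    grade_weights = c("2" = 13, "3" = 10, "4" = 14),
    volume_mean = 24.97,
    volume_sd = 23.84,
    rmt_ratio_mean = 1.02,
    rmt_ratio_sd = 0.166,
    rmt_healthy_mean = 34.59,
    rmt_healthy_sd = 6.81,
    nihss_coupling = 15,
    nihss_noise_sd = 1,
    nihss_missing = 3,
    mrc_marginal = c("2" = 1, "3" = 1, "4" = 12, "5" = 23),
    algorithm_scale = 0.8,
    algorithm_noise_sd = 0.2,
    seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_subjects >= 1,
            cfg$within_module_p >= 0, cfg$within_module_p <= 1,
            cfg$between_module_p >= 0, cfg$between_module_p <= 1,
            cfg$homotopic_p >= 0, cfg$homotopic_p <= 1,
            cfg$lesion_effect_delta >= 0, cfg$lesion_effect_delta < 1,
            cfg$weight_log_sd > 0, cfg$algorithm_scale > 0)
  class(cfg) <- "generator_config"
  cfg
}

# lognormal parameters matching a target mean and SD on the natural scale
lognormal_params <- function(mean, sd) {
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log(1 + cv2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mean, sd)
  x
}

#' Mirror-symmetric whole-brain template connectome
#'
#' Builds the cohort baseline: modular intra-hemispheric topology (module
#' assignments mirrored across hemispheres), lognormal streamline-count
#' weights, brainstem edges mirrored per side, and homotopic
#' interhemispheric edges. The left and right blocks are exactly equal under
#' the homolog map, so a hemispheric split of the template is entry-wise
#' identical between sides.
#'
#' @param config \code{\link{generator_config}}; note the caller controls
#'   the RNG state (use \code{set.seed} or \code{\link{simulate_cohort}}).
#' @param atlas node table, default \code{\link{make_default_atlas}()}.
#' @return A whole-brain \code{\link{connectome}} with a \code{"modules"}
#'   attribute (module id per lateralized base region).
#' @export
simulate_template <- function(config, atlas = make_default_atlas()) {
  hom <- homolog_map(atlas)
  left <- names(hom)
  nl <- length(left)
  base <- sub("^lh\\.", "", left)
  modules <- stats::setNames(
    rep(seq_len(config$module_count), length.out = nl), base)

  n <- nrow(atlas)
  w <- matrix(0, n, n, dimnames = list(atlas$label, atlas$label))
  li <- match(left, atlas$label)
  ri <- match(unname(hom), atlas$label)
  bi <- match(atlas$label[atlas$hemisphere == "midline"], atlas$label)

  # intra-hemispheric block, generated once and mirrored
  for (a in seq_len(nl - 1)) {
    for (b in (a + 1):nl) {
      p <- if (modules[a] == modules[b]) config$within_module_p else
        config$between_module_p
      if (stats::runif(1) < p) {
        wt <- stats::rlnorm(1, config$weight_log_mean, config$weight_log_sd)
        w[li[a], li[b]] <- w[li[b], li[a]] <- wt
        w[ri[a], ri[b]] <- w[ri[b], ri[a]] <- wt
      }
    }
  }
  # brainstem edges, mirrored per side
  for (a in seq_len(nl)) {
    if (stats::runif(1) < config$brainstem_p) {
      wt <- stats::rlnorm(1, config$weight_log_mean, config$weight_log_sd)
      w[li[a], bi] <- w[bi, li[a]] <- wt
      w[ri[a], bi] <- w[bi, ri[a]] <- wt
    }
  }
  # homotopic interhemispheric edges
  for (a in seq_len(nl)) {
    if (stats::runif(1) < config$homotopic_p) {
      wt <- stats::rlnorm(1, config$weight_log_mean, config$weight_log_sd)
      w[li[a], ri[a]] <- w[ri[a], li[a]] <- wt
    }
  }
  conn <- connectome(w, nodes = atlas)
  attr(conn, "modules") <- modules
  conn
}

# symmetric per-edge multiplicative lognormal noise on the upper triangle
symmetric_noise <- function(w, sd) {
  if (sd <= 0) return(w)
  n <- nrow(w)
  eps <- matrix(0, n, n)
  ut <- upper.tri(eps)
  eps[ut] <- stats::rnorm(sum(ut), 0, sd)
  eps <- eps + t(eps)
  w * exp(eps)
}

#' Simulate one subject
#'
#' Subject connectome = template with per-edge lognormal noise and a global
#' per-subject scale factor; a lesion neighborhood (the subgroup's seed
#' region plus its strongest same-module neighbors) has its ipsilesional
#' edges reduced by a Beta-distributed fraction whose mean scales with WHO
#' grade and tumor volume. Clinical covariates follow the configured
#' marginals; NIHSS couples linearly to the realized fractional damage. MRC
#' is assigned at cohort level (see \code{\link{simulate_cohort}}) and is
#' \code{NA} here.
#'
#' @param template output of \code{\link{simulate_template}}.
#' @param config \code{\link{generator_config}}.
#' @param subject_index integer id.
#' @return A \code{synthetic_subject}: \code{connectome_a}
#'   (probabilistic-like), \code{connectome_b} (deterministic-like
#'   replicate), \code{clinical} (one-row data frame), and \code{truth}
#'   (lesion nodes, affected edges, realized delta, damage fraction).
#' @export
simulate_subject <- function(template, config, subject_index = 1L) {
  atlas <- template$nodes
  modules <- attr(template, "modules")
  hom <- homolog_map(atlas)

  lesion_side <- if (stats::runif(1) < config$lesion_side_p_right) "right"
  else "left"
  sgn <- names(config$subgroup_weights)
  subgroup <- sample(sgn, 1, prob = config$subgroup_weights)
  if (length(sgn) > 1 && stats::runif(1) < config$overlap_p) {
    rest <- setdiff(sgn, subgroup)
    subgroup <- c(subgroup,
                  sample(rest, 1, prob = config$subgroup_weights[rest]))
  }

  who_grade <- as.integer(sample(names(config$grade_weights), 1,
                                 prob = config$grade_weights))
  vp <- lognormal_params(config$volume_mean, config$volume_sd)
  tumor_volume <- stats::rlnorm(1, vp$meanlog, vp$sdlog)

  # subject-level connectome noise
  scale_s <- exp(stats::rnorm(1, 0, config$subject_scale_sd))
  w <- symmetric_noise(template$weights, config$subject_noise_sd) * scale_s

  # lesion neighborhood: subgroup seed region + strongest same-module
  # neighbors in the template, lesion_node_count nodes in total
  seed_region <- .subgroup_seed_region[[subgroup[1]]]
  same_mod <- names(modules)[modules == modules[seed_region]]
  prefix <- if (lesion_side == "left") "lh." else "rh."
  seed_lab <- paste0(prefix, seed_region)
  cand <- setdiff(same_mod, seed_region)
  cand_lab <- paste0(prefix, cand)
  ord <- order(template$weights[seed_lab, cand_lab], decreasing = TRUE)
  lesion_nodes <- c(seed_lab,
                    cand_lab[ord][seq_len(min(config$lesion_node_count - 1,
                                              length(cand)))])

  ipsi_labs <- c(atlas$label[atlas$hemisphere == lesion_side],
                 atlas$label[atlas$hemisphere == "midline"])
  delta <- 0
  affected <- data.frame(node_i = character(0), node_j = character(0),
                         stringsAsFactors = FALSE)
  damage <- 0
  hemi_idx <- match(ipsi_labs, atlas$label)
  hemi_total <- sum(w[hemi_idx, hemi_idx]) / 2
  if (config$lesion_effect_delta > 0) {
    m <- config$lesion_effect_delta *
      (1 + config$grade_delta_slope * (who_grade - 3) +
         config$volume_delta_slope * (tumor_volume - config$volume_mean))
    m <- min(max(m, 0.01), 0.95)
    kappa <- config$lesion_concentration
    delta <- stats::rbeta(1, m * kappa, (1 - m) * kappa)
    sub <- w[hemi_idx, hemi_idx]
    in_les <- atlas$label[hemi_idx] %in% lesion_nodes
    hit <- (outer(in_les, in_les, "|")) & upper.tri(sub) & sub > 0
    idx <- which(hit, arr.ind = TRUE)
    affected <- data.frame(
      node_i = atlas$label[hemi_idx[idx[, 1]]],
      node_j = atlas$label[hemi_idx[idx[, 2]]],
      stringsAsFactors = FALSE)
    removed <- sum(sub[hit]) * delta
    sub[hit] <- sub[hit] * (1 - delta)
    sub[lower.tri(sub)] <- t(sub)[lower.tri(sub)]
    w[hemi_idx, hemi_idx] <- sub
    damage <- removed / hemi_total
  }

  rmt_healthy <- rnorm_pos(1, config$rmt_healthy_mean, config$rmt_healthy_sd)
  rmt_ratio <- rnorm_pos(1, config$rmt_ratio_mean, config$rmt_ratio_sd)
  nihss <- round(config$nihss_coupling * damage +
                   stats::rnorm(1, 0, config$nihss_noise_sd))
  nihss <- min(max(nihss, 0), 42)

  conn_a <- connectome(w, nodes = atlas)
  conn_b <- algorithm_replicate(conn_a, config)
  clinical <- data.frame(
    subject_id = sprintf("sub-%03d", subject_index),
    lesion_side = lesion_side,
    subgroup = paste(subgroup, collapse = ";"),
    mrc = NA_integer_,
    nihss = nihss,
    who_grade = who_grade,
    tumor_volume_cm3 = tumor_volume,
    rmt_pathological = rmt_ratio * rmt_healthy,
    rmt_healthy = rmt_healthy,
    stringsAsFactors = FALSE
  )
  structure(list(
    connectome_a = conn_a, connectome_b = conn_b, clinical = clinical,
    truth = list(lesion_side = lesion_side, lesion_nodes = lesion_nodes,
                 affected_edges = affected, delta = delta, damage = damage)
  ), class = "synthetic_subject")
}

#' Correlated tractography replicate of a connectome
#'
#' Rescales all weights by a global factor and applies symmetric per-edge
#' lognormal noise; the zero pattern is preserved. Emulates a second
#' (deterministic-like) tractography algorithm run on the same brain.
#'
#' @param conn source \code{\link{connectome}}.
#' @param config \code{\link{generator_config}} supplying
#'   \code{algorithm_scale} and \code{algorithm_noise_sd}.
#' @return A \code{\link{connectome}}.
#' @export
algorithm_replicate <- function(conn, config) {
  w <- symmetric_noise(conn$weights, config$algorithm_noise_sd) *
    config$algorithm_scale
  connectome(w, nodes = conn$nodes)
}

# cohort-level MRC assignment: worst damage -> lowest grade, following the
# configured marginal counts rescaled to the cohort size
assign_mrc <- function(damage, marginal, n) {
  counts <- round(marginal / sum(marginal) * n)
  while (sum(counts) > n) counts[which.max(counts)] <-
    counts[which.max(counts)] - 1
  while (sum(counts) < n) counts[which.max(counts)] <-
    counts[which.max(counts)] + 1
  grades <- rep(as.integer(names(marginal)), counts)  # ascending MRC
  mrc <- integer(n)
  mrc[order(damage, decreasing = TRUE)] <- grades
  mrc
}

#' Simulate a full cohort
#'
#' Deterministic given \code{config$seed}. Generates the template, all
#' subjects (two connectome replicates each), the cohort clinical table
#' (with the cohort-level MRC quantile assignment and NIHSS missingness),
#' and the ground-truth ledger for recovery tests. Optionally writes the
#' cohort to disk: two connectome TSVs per subject (suffixes
#' \code{_algA}/\code{_algB}), \code{clinical.csv}, \code{truth.json} and a
#' flat key=value \code{generator_config.txt}.
#'
#' @param config \code{\link{generator_config}}.
#' @param dir optional output directory.
#' @param atlas node table, default \code{\link{make_default_atlas}()}.
#' @return A \code{synthetic_cohort}: \code{subjects} (list of
#'   \code{synthetic_subject}), \code{clinical} (validated table),
#'   \code{truth}, \code{template}, \code{atlas}, \code{config}.
#' @export
simulate_cohort <- function(config = generator_config(), dir = NULL,
                            atlas = make_default_atlas()) {
  set.seed(config$seed)
  template <- simulate_template(config, atlas)
  subjects <- lapply(seq_len(config$n_subjects), function(i) {
    simulate_subject(template, config, i)
  })
  clinical <- do.call(rbind, lapply(subjects, function(s) s$clinical))
  damage <- vapply(subjects, function(s) s$truth$damage, numeric(1))
  clinical$mrc <- assign_mrc(damage, config$mrc_marginal, config$n_subjects)
  if (config$nihss_missing > 0 && config$nihss_missing < config$n_subjects) {
    clinical$nihss[sample(config$n_subjects, config$nihss_missing)] <- NA
  }
  clinical <- validate_clinical(clinical)
  truth <- lapply(subjects, function(s) s$truth)
  names(truth) <- clinical$subject_id
  cohort <- structure(list(subjects = subjects, clinical = clinical,
                           truth = truth, template = template, atlas = atlas,
                           config = config), class = "synthetic_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d subjects, seed %d, delta %.2f\n",
              length(x$subjects), x$config$seed,
              x$config$lesion_effect_delta))
  invisible(x)
}

#' Write a cohort to disk
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    id <- s$clinical$subject_id
    write_connectome(s$connectome_a, file.path(dir, paste0(id, "_algA.tsv")))
    write_connectome(s$connectome_b, file.path(dir, paste0(id, "_algB.tsv")))
  }
  cl <- cohort$clinical
  cl$subgroups <- NULL
  cl$rmt_ratio <- NULL
  utils::write.csv(cl, file.path(dir, "clinical.csv"), row.names = FALSE)
  jsonlite::write_json(
    lapply(cohort$truth, function(t) list(
      lesion_side = t$lesion_side, lesion_nodes = t$lesion_nodes,
      affected_edges = t$affected_edges, delta = t$delta,
      damage = t$damage)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  cfg <- cohort$config
  lines <- vapply(names(unclass(cfg)), function(k) {
    paste0(k, " = ", paste(cfg[[k]], collapse = ",")
    )
  }, character(1))
  writeLines(lines, file.path(dir, "generator_config.txt"))
  invisible(NULL)
}
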