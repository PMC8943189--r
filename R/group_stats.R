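# Cohort-level statistics: paired hemisphere comparisons, FDR-corrected
# Spearman clinical correlations, cross-algorithm agreement.

#' Paired comparison of a metric between hemispheres
#'
#' Two-sided paired t-test and Wilcoxon signed-rank test (zero differences
#' dropped, mid-rank ties; exact distribution for n <= 25 without ties or
#' zeros, otherwise normal approximation with continuity correction), plus
#' descriptive means and SDs of both sides.
#'
#' @param values_ipsi,values_contra aligned per-subject metric vectors.
#' @return A one-row data frame: \code{statistic_t}, \code{df}, \code{p_t},
#'   \code{statistic_wilcoxon}, \code{p_wilcoxon}, means/SDs and \code{n}.
#' @export
paired_compare <- function(values_ipsi, values_contra) {
  n <- length(values_ipsi)
  if (length(values_contra) != n) stop("hemisphere vectors must be aligned")
  if (n < 3) stop("need at least 3 subjects")
  d <- values_contra - values_ipsi
  out <- data.frame(
    statistic_t = NA_real_, df = n - 1L, p_t = NA_real_,
    statistic_wilcoxon = NA_real_, p_wilcoxon = NA_real_,
    mean_ipsi = mean(values_ipsi), sd_ipsi = stats::sd(values_ipsi),
    mean_contra = mean(values_contra), sd_contra = stats::sd(values_contra),
    n = n
  )
  if (all(d == 0)) {
    out$statistic_t <- 0
    out$p_t <- 1
    return(out)  # Wilcoxon undefined on all-zero differences
  }
  if (stats::sd(d) <= 1e-10 * mean(abs(d))) {
    # constant nonzero shift: t degenerates, flag as p -> 0
    out$statistic_t <- sign(mean(d)) * Inf
    out$p_t <- 0
  } else {
    tt <- stats::t.test(values_contra, values_ipsi, paired = TRUE)
    out$statistic_t <- unname(tt$statistic)
    out$p_t <- tt$p.value
  }
  dz <- d[d != 0]
  exact <- length(dz) <= 25 && !anyDuplicated(abs(dz))
  wt <- suppressWarnings(
    stats::wilcox.test(values_contra, values_ipsi, paired = TRUE,
                       exact = exact, correct = TRUE)
  )
  out$statistic_wilcoxon <- unname(wt$statistic)
  out$p_wilcoxon <- wt$p.value
  out
}

spearman_p <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tval), df = n - 2)
}

#' FDR-corrected Spearman correlations over a declared family
#'
#' Computes Spearman rank correlations (mid-rank ties, p from the
#' t-approximation with n-2 df) for each declared (feature, clinical
#' variable) pair, with pairwise deletion of missing values, and applies
#' Benjamini-Hochberg adjustment across exactly the declared family.
#' Constant vectors are excluded with a warning (the family shrinks).
#'
#' @param feature_table data frame or matrix, subjects x features.
#' @param clinical_table data frame, subjects x clinical variables, aligned
#'   by row.
#' @param family data frame with columns \code{feature} and \code{variable}
#'   naming the tested pairs; defaults to the full cross of columns.
#' @return Data frame of \code{CorrelationResult} rows (feature, variable,
#'   rho, n, p_raw, p_fdr, method), sorted by \code{p_fdr}.
#' @export
spearman_fdr <- function(feature_table, clinical_table, family = NULL) {
  feature_table <- as.data.frame(feature_table)
  clinical_table <- as.data.frame(clinical_table)
  if (nrow(feature_table) != nrow(clinical_table)) {
    stop("feature and clinical tables must be aligned by subject")
  }
  if (is.null(family)) {
    family <- expand.grid(feature = names(feature_table),
                          variable = names(clinical_table),
                          stringsAsFactors = FALSE)
  }
  rows <- list()
  for (i in seq_len(nrow(family))) {
    x <- feature_table[[family$feature[i]]]
    y <- clinical_table[[family$variable[i]]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 4) {
      warning(sprintf("%s ~ %s: fewer than 4 complete pairs, dropped",
                      family$feature[i], family$variable[i]))
      next
    }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      warning(sprintf("%s ~ %s: constant vector, dropped from family",
                      family$feature[i], family$variable[i]))
      next
    }
    rho <- stats::cor(x[ok], y[ok], method = "spearman")
    rows[[length(rows) + 1]] <- data.frame(
      feature = family$feature[i], variable = family$variable[i],
      rho = rho, n = sum(ok), p_raw = spearman_p(rho, sum(ok)),
      method = "spearman", stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(feature = character(0), variable = character(0),
                      rho = numeric(0), n = integer(0), p_raw = numeric(0),
                      p_fdr = numeric(0), method = character(0)))
  }
  res <- do.call(rbind, rows)
  res$p_fdr <- stats::p.adjust(res$p_raw, method = "BH")
  res[order(res$p_fdr, res$p_raw), ]
}

#' Cross-algorithm agreement of network metrics
#'
#' Pearson correlation per metric between two aligned metric tables (e.g.
#' probabilistic- vs deterministic-like tractography replicates), either per
#' hemisphere group or pooled across hemispheres.
#'
#' @param metrics_a,metrics_b aligned data frames (subjects or
#'   subject-hemisphere rows x metric columns) with an optional
#'   \code{hemisphere} grouping column.
#' @param pooled if \code{TRUE} (default), correlate over all rows together;
#'   otherwise per hemisphere group.
#' @return Data frame of Pearson \code{CorrelationResult} rows.
#' @export
cross_algorithm_agreement <- function(metrics_a, metrics_b, pooled = TRUE) {
  metrics_a <- as.data.frame(metrics_a)
  metrics_b <- as.data.frame(metrics_b)
  if (!identical(dim(metrics_a), dim(metrics_b))) {
    stop("metric tables must have identical shape")
  }
  grp <- if (!pooled && "hemisphere" %in% names(metrics_a)) {
    metrics_a$hemisphere
  } else {
    rep("pooled", nrow(metrics_a))
  }
  cols <- setdiff(names(metrics_a), c("subject_id", "hemisphere"))
  rows <- list()
  for (g in unique(grp)) {
    sel <- grp == g
    for (cl in cols) {
      x <- metrics_a[[cl]][sel]
      y <- metrics_b[[cl]][sel]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 4 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          feature = cl, variable = g, rho = NA_real_, n = sum(ok),
          p_raw = NA_real_, method = "pearson", stringsAsFactors = FALSE)
        next
      }
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      rows[[length(rows) + 1]] <- data.frame(
        feature = cl, variable = g, rho = unname(ct$estimate), n = sum(ok),
        p_raw = ct$p.value, method = "pearson", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Contra-minus-ipsi feature table
#'
#' Per-subject differences of homolog-aligned edge weights and scalar
#' metrics, the feature input for the clinical correlation analyses.
#'
#' @param pairs list of \code{hemispheric_pair} objects.
#' @param metrics_ipsi,metrics_contra optional aligned lists of
#'   \code{metric_set}s; their scalar metrics are appended as
#'   \code{diff_<metric>} columns.
#' @param edges optional data frame with columns \code{node_i}, \code{node_j}
#'   (region names) restricting the edge features; default all edges.
#' @return Data frame, subjects x features; edge columns are named
#'   \code{"<node_i>--<node_j>"}.
#' @export
hemispheric_difference_table <- function(pairs, metrics_ipsi = NULL,
                                         metrics_contra = NULL,
                                         edges = NULL) {
  pd <- pair_difference_matrix(pairs, "contra_gt_ipsi")
  cn <- paste0(pd$regions[pd$edge_i], "--", pd$regions[pd$edge_j])
  D <- pd$D
  colnames(D) <- cn
  if (!is.null(edges)) {
    keep <- match(paste0(edges$node_i, "--", edges$node_j), cn)
    alt <- match(paste0(edges$node_j, "--", edges$node_i), cn)
    keep[is.na(keep)] <- alt[is.na(keep)]
    if (anyNA(keep)) {
      stop("unknown edge: ",
           paste0(edges$node_i, "--", edges$node_j)[is.na(keep)][1])
    }
    D <- D[, keep, drop = FALSE]
  }
  out <- as.data.frame(D)
  if (!is.null(metrics_ipsi)) {
    if (length(metrics_ipsi) != length(pairs) ||
        length(metrics_contra) != length(pairs)) {
      stop("metric lists must be aligned with pairs")
    }
    mi <- do.call(rbind, lapply(metrics_ipsi, metric_scalars))
    mc <- do.call(rbind, lapply(metrics_contra, metric_scalars))
    dm <- mc - mi
    names(dm) <- paste0("diff_", names(dm))
    out <- cbind(out, dm)
  }
  out
}
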