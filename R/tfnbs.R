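# Threshold-free network-based statistics: edge-wise paired GLM statistic
# with a hemispheric-side nuisance covariate, threshold-free score transform,
# and Freedman-Lane sign-flip permutation inference with FWE control via the
# maximum-score null distribution.

#' TFNBS parameters
#'
#' @param exponent_e extent exponent E (default 0.4).
#' @param exponent_h height exponent H (default 3).
#' @param n_steps threshold-integration steps; the step is
#'   \code{dh = max(t)/n_steps} (default 100).
#' @param n_perm number of permutations (default 5000).
#' @param extent_mode \code{"component"} (edge count of the suprathreshold
#'   connected component, the TFNBS-literature definition, default) or
#'   \code{"incident"} (suprathreshold edges incident to either endpoint).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed for the permutation stream.
#' @return A \code{tfnbs_params} list.
#' @export
tfnbs_params <- function(exponent_e = 0.4, exponent_h = 3, n_steps = 100,
                         n_perm = 5000,
                         extent_mode = c("component", "incident"),
                         alpha = 0.05, seed = 1L) {
  extent_mode <- match.arg(extent_mode)
  stopifnot(exponent_e >= 0, exponent_h >= 0, n_steps >= 10, n_perm >= 1,
            alpha > 0, alpha < 1)
  structure(list(exponent_e = exponent_e, exponent_h = exponent_h,
                 n_steps = as.integer(n_steps), n_perm = as.integer(n_perm),
                 extent_mode = extent_mode, alpha = alpha,
                 seed = as.integer(seed)),
            class = "tfnbs_params")
}

# subjects x edges matrix of hemispheric weight differences, upper triangle
# of the homolog-aligned 40x40 matrices; sign set by the tested direction
pair_difference_matrix <- function(pairs,
                                   direction = c("contra_gt_ipsi",
                                                 "ipsi_gt_contra")) {
  direction <- match.arg(direction)
  regions <- pairs[[1]]$regions
  for (p in pairs) {
    if (!identical(p$regions, regions)) {
      stop("all hemispheric pairs must share one node table")
    }
  }
  nn <- length(regions)
  ut <- upper.tri(matrix(0, nn, nn))
  D <- t(vapply(pairs, function(p) {
    d <- p$contra$weights[ut] - p$ipsi$weights[ut]
    if (direction == "ipsi_gt_contra") -d else d
  }, numeric(sum(ut))))
  idx <- which(ut, arr.ind = TRUE)
  list(D = D, regions = regions, edge_i = idx[, 1], edge_j = idx[, 2],
       direction = direction)
}

# one-sided intercept t-statistics for d = b0 + b1 * side_c per edge;
# S is a matrix of +-1 sign-flip vectors (one row per permutation); the
# identity row reproduces the observed statistics. Freedman-Lane: residuals
# of the covariate-only reduced model are sign-flipped, the fitted covariate
# part is retained.
edge_t_matrix <- function(D, side_c, S) {
  n <- nrow(D)
  ssc <- sum(side_c^2)
  if (ssc > 0) {
    gamma <- drop(side_c %*% D) / ssc        # reduced-model slope per edge
    Fit <- outer(side_c, gamma)              # fitted covariate part
    R <- D - Fit
    df <- n - 2
  } else {
    gamma <- numeric(ncol(D))
    Fit <- matrix(0, n, ncol(D))
    R <- D
    df <- n - 1
  }
  mean_s <- (S %*% R) / n                    # colMeans(Fit) = 0 by centering
  sum2 <- rep(1, nrow(S)) %o% (colSums(Fit^2) + colSums(R^2)) +
    2 * (S %*% (Fit * R))
  if (ssc > 0) {
    b1 <- rep(1, nrow(S)) %o% gamma + (S %*% (R * side_c)) / ssc
    rss <- pmax(sum2 - n * mean_s^2 - ssc * b1^2, 0)
  } else {
    rss <- pmax(sum2 - n * mean_s^2, 0)
  }
  se <- sqrt(rss / df / n)
  t <- ifelse(se > 0, mean_s / se, 0)
  pmax(t, 0)                                 # one-sided truncation
}

center_side <- function(covariate, n) {
  side <- ifelse(covariate == "right", 1, -1)
  if (length(side) != n) stop("covariate length must equal number of pairs")
  if (length(unique(side)) < 2) {
    warning("constant lesion-side covariate; dropping it (one-sample t)")
    return(rep(0, n))
  }
  side - mean(side)
}

#' Edge-wise paired statistic between hemispheres
#'
#' For each edge, the subject-wise hemispheric weight difference
#' (contralesional minus ipsilesional; sign flipped for direction
#' \code{ipsi_gt_contra}) is regressed on the mean-centered lesion side
#' (coded -1/+1). The reported statistic is the one-sided t of the intercept
#' (negative values truncated to zero), with n-2 degrees of freedom.
#'
#' @param pairs list of \code{hemispheric_pair} objects sharing one atlas.
#' @param covariate per-subject lesion side (\code{"left"}/\code{"right"}).
#' @param direction tested direction.
#' @return A \code{stat_matrix}: symmetric matrix of truncated t values plus
#'   region names, direction and degrees of freedom.
#' @export
paired_edge_statistic <- function(pairs, covariate,
                                  direction = c("contra_gt_ipsi",
                                                "ipsi_gt_contra")) {
  direction <- match.arg(direction)
  if (length(pairs) < 3) stop("need at least 3 subjects")
  pd <- pair_difference_matrix(pairs, direction)
  n <- nrow(pd$D)
  side_c <- center_side(covariate, n)
  tvec <- drop(edge_t_matrix(pd$D, side_c, matrix(1, 1, n)))
  nn <- length(pd$regions)
  tm <- matrix(0, nn, nn, dimnames = list(pd$regions, pd$regions))
  tm[cbind(pd$edge_i, pd$edge_j)] <- tvec
  tm <- tm + t(tm)
  df <- if (sum(side_c^2) > 0) n - 2L else n - 1L
  structure(list(t_values = tm, regions = pd$regions, direction = direction,
                 df = df, n = n), class = "stat_matrix")
}

#' Threshold-free score transform
#'
#' Integrates \code{extent(h)^E * h^H * dh} over the threshold grid
#' \code{h_k = k * dh}, \code{dh = max(t)/n_steps}, for every edge over the
#' thresholds it survives. An all-zero statistic map yields all-zero scores.
#'
#' @param stats a \code{stat_matrix} (nonnegative), or a symmetric
#'   nonnegative numeric matrix.
#' @param params \code{\link{tfnbs_params}}.
#' @return Symmetric matrix of TFNBS scores.
#' @export
tfnbs_transform <- function(stats, params = tfnbs_params()) {
  tm <- if (inherits(stats, "stat_matrix")) stats$t_values else stats
  if (any(tm < 0)) stop("negative statistics; truncate before scoring")
  nn <- nrow(tm)
  ut <- which(upper.tri(tm), arr.ind = TRUE)
  sc <- .tfnbs_score_edges(tm[upper.tri(tm)], ut[, 1] - 1L, ut[, 2] - 1L,
                           nn, params$exponent_e, params$exponent_h,
                           params$n_steps,
                           params$extent_mode == "component")
  out <- matrix(0, nn, nn, dimnames = dimnames(tm))
  out[upper.tri(out)] <- sc
  out + t(out)
}

#' Permutation FWE inference for TFNBS
#'
#' Computes observed TFNBS scores and a max-score permutation null via
#' Freedman-Lane subject-level sign flipping of the hemispheric difference
#' residuals (the fitted lesion-side part is retained). FWE-corrected
#' p-values use the +1/+1 estimator
#' \code{p = (1 + #(null_max >= score)) / (n_perm + 1)}.
#'
#' @inheritParams paired_edge_statistic
#' @param params \code{\link{tfnbs_params}}.
#' @return A \code{tfnbs_result}: score and p-value matrices, the permutation
#'   maxima, the observed \code{stat_matrix} and the parameters.
#' @export
permutation_fwe <- function(pairs, covariate, params = tfnbs_params(),
                            direction = c("contra_gt_ipsi",
                                          "ipsi_gt_contra")) {
  direction <- match.arg(direction)
  if (length(pairs) < 3) stop("need at least 3 subjects")
  pd <- pair_difference_matrix(pairs, direction)
  n <- nrow(pd$D)
  side_c <- center_side(covariate, n)
  if (params$n_perm > 2^n) {
    warning("n_perm exceeds the number of distinct sign patterns (2^n); ",
            "sampling with replacement retained")
  }

  tvec <- drop(edge_t_matrix(pd$D, side_c, matrix(1, 1, n)))
  ei0 <- pd$edge_i - 1L
  ej0 <- pd$edge_j - 1L
  nn <- length(pd$regions)
  comp <- params$extent_mode == "component"
  obs_sc <- .tfnbs_score_edges(tvec, ei0, ej0, nn, params$exponent_e,
                               params$exponent_h, params$n_steps, comp)

  set.seed(params$seed)
  null_max <- numeric(params$n_perm)
  done <- 0L
  while (done < params$n_perm) {
    nb <- min(1000L, params$n_perm - done)
    S <- matrix(sample(c(-1, 1), nb * n, replace = TRUE), nb, n)
    Tb <- edge_t_matrix(pd$D, side_c, S)
    for (b in seq_len(nb)) {
      sc <- .tfnbs_score_edges(Tb[b, ], ei0, ej0, nn, params$exponent_e,
                               params$exponent_h, params$n_steps, comp)
      null_max[done + b] <- if (length(sc)) max(sc) else 0
    }
    done <- done + nb
  }

  pvec <- (1 + vapply(obs_sc, function(s) sum(null_max >= s), numeric(1))) /
    (params$n_perm + 1)
  mk <- function(v) {
    m <- matrix(0, nn, nn, dimnames = list(pd$regions, pd$regions))
    m[cbind(pd$edge_i, pd$edge_j)] <- v
    m + t(m)
  }
  tm <- mk(tvec)
  p_fwe <- mk(pvec)
  diag(p_fwe) <- 1
  stat <- structure(list(t_values = tm, regions = pd$regions,
                         direction = direction,
                         df = if (sum(side_c^2) > 0) n - 2L else n - 1L,
                         n = n), class = "stat_matrix")
  structure(list(scores = mk(obs_sc), p_fwe = p_fwe, null_max = null_max,
                 params = params, stat = stat, regions = pd$regions,
                 direction = direction),
            class = "tfnbs_result")
}

#' @export
print.tfnbs_result <- function(x, ...) {
  ns <- sum(x$p_fwe[upper.tri(x$p_fwe)] < x$params$alpha)
  cat(sprintf("tfnbs_result (%s): %d significant edges at alpha=%g, %d perms\n",
              x$direction, ns, x$params$alpha, x$params$n_perm))
  invisible(x)
}

#' Significant edges of a TFNBS result
#'
#' @param result a \code{tfnbs_result}.
#' @param alpha significance level; edges with \code{p_fwe < alpha} are kept.
#' @return Data frame with columns \code{node_i}, \code{node_j}, \code{t},
#'   \code{score}, \code{p_fwe}, \code{direction}, sorted by ascending p,
#'   then descending score, then label pair.
#' @export
significant_edges <- function(result, alpha = result$params$alpha) {
  ut <- which(upper.tri(result$p_fwe), arr.ind = TRUE)
  keep <- result$p_fwe[ut] < alpha
  ut <- ut[keep, , drop = FALSE]
  df <- data.frame(
    node_i = result$regions[ut[, 1]],
    node_j = result$regions[ut[, 2]],
    t = result$stat$t_values[ut],
    score = result$scores[ut],
    p_fwe = result$p_fwe[ut],
    direction = rep(result$direction, nrow(ut)),
    stringsAsFactors = FALSE
  )
  df[order(df$p_fwe, -df$score, df$node_i, df$node_j), , drop = FALSE]
}
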