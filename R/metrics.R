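# Weighted undirected graph topology measures. Distances are reciprocal
# weights (1/w on raw streamline counts, no normalization); disconnected
# pairs have infinite distance and contribute zero efficiency.

as_weight_matrix <- function(conn) {
  if (inherits(conn, "connectome")) conn$weights else as.matrix(conn)
}

conn_igraph <- function(w) {
  igraph::graph_from_adjacency_matrix(w, mode = "undirected", weighted = TRUE,
                                      diag = FALSE)
}

#' Convert connection weights to edge lengths
#'
#' Edge length is the reciprocal weight; a zero weight means no direct link
#' (length coded as \code{Inf}).
#'
#' @param conn connectome or weight matrix.
#' @return Matrix of edge lengths.
#' @export
weight_to_distance <- function(conn) {
  w <- as_weight_matrix(conn)
  d <- ifelse(w > 0, 1 / w, Inf)
  diag(d) <- 0
  d
}

#' All-pairs shortest path lengths
#'
#' Shortest paths over reciprocal-weight edge lengths; disconnected pairs
#' are \code{Inf}.
#'
#' @param conn connectome or weight matrix.
#' @return Symmetric matrix of path lengths with zero diagonal.
#' @export
shortest_path_matrix <- function(conn) {
  w <- as_weight_matrix(conn)
  g <- conn_igraph(w)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  dimnames(d) <- dimnames(w)
  d
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over all ordered node pairs
#' (\code{1/Inf = 0} for disconnected pairs). With raw streamline-count
#' weights this is on the scale of the weights themselves.
#'
#' @param conn connectome or weight matrix.
#' @return Scalar efficiency.
#' @export
global_efficiency <- function(conn) {
  d <- shortest_path_matrix(conn)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 nodes")
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

#' Nodal efficiency
#'
#' Per node, the mean inverse shortest-path length to all other nodes; the
#' global efficiency is the mean of the nodal values.
#'
#' @param conn connectome or weight matrix.
#' @return Numeric vector, one value per node.
#' @export
nodal_efficiency <- function(conn) {
  d <- shortest_path_matrix(conn)
  n <- nrow(d)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  rowSums(inv) / (n - 1)
}

#' Local efficiency
#'
#' Per node, the global efficiency of the subgraph induced by its neighbors
#' (original weights, the node itself removed); nodes with fewer than two
#' neighbors score zero. The network value is the mean over nodes.
#'
#' @param conn connectome or weight matrix.
#' @return List with \code{mean} and per-node \code{nodal} values.
#' @export
local_efficiency <- function(conn) {
  w <- as_weight_matrix(conn)
  n <- nrow(w)
  nodal <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    if (length(nb) >= 2) {
      nodal[i] <- global_efficiency(w[nb, nb, drop = FALSE])
    }
  }
  names(nodal) <- rownames(w)
  list(mean = mean(nodal), nodal = nodal)
}

#' Degree and strength
#'
#' @param conn connectome or weight matrix.
#' @return List with integer \code{degree} (count of nonzero incident
#'   weights) and \code{strength} (row sums).
#' @export
degree_strength <- function(conn) {
  w <- as_weight_matrix(conn)
  list(degree = as.integer(rowSums(w > 0)), strength = rowSums(w))
}

#' Degree assortativity
#'
#' Pearson correlation of endpoint degrees over the edge list, each
#' undirected edge contributing both orientations.
#'
#' @param conn connectome or weight matrix.
#' @return Scalar in [-1, 1], or \code{NA} if endpoint degrees have zero
#'   variance.
#' @export
assortativity_degree_weighted <- function(conn) {
  w <- as_weight_matrix(conn)
  deg <- rowSums(w > 0)
  e <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  if (nrow(e) == 0) return(NA_real_)
  x <- c(deg[e[, 1]], deg[e[, 2]])
  y <- c(deg[e[, 2]], deg[e[, 1]])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Onnela weighted clustering coefficient
#'
#' Weights are normalized by the graph-wide maximum; the nodal coefficient is
#' the mean over neighbor pairs of the geometric mean of the three triangle
#' weights (cube root). Nodes with degree < 2 score zero.
#'
#' @param conn connectome or weight matrix.
#' @return Numeric vector of nodal clustering values.
#' @export
clustering_onnela <- function(conn) {
  w <- as_weight_matrix(conn)
  mx <- max(w)
  if (mx == 0) return(numeric(nrow(w)))
  wh <- (w / mx)^(1 / 3)
  num <- diag(wh %*% wh %*% wh)
  k <- rowSums(w > 0)
  c_i <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  stats::setNames(c_i, rownames(w))
}

#' Hierarchy exponent
#'
#' The exponent beta of the power-law decay of clustering with degree
#' (C proportional to k^-beta): the negative slope of the least-squares fit
#' of log clustering on log degree over nodes with degree >= 2 and positive
#' clustering.
#'
#' @param conn connectome or weight matrix.
#' @return Scalar beta, or \code{NA} with fewer than 3 eligible nodes.
#' @export
hierarchy <- function(conn) {
  w <- as_weight_matrix(conn)
  k <- rowSums(w > 0)
  cc <- clustering_onnela(w)
  ok <- k >= 2 & cc > 0
  if (sum(ok) < 3) return(NA_real_)
  if (stats::sd(log(k[ok])) == 0) return(0)  # constant degree: flat decay
  fit <- stats::lm.fit(cbind(1, log(k[ok])), log(cc[ok]))
  -unname(fit$coefficients[2])
}

#' Weighted rich-club coefficients
#'
#' For each degree level k from 1 up to the maximum degree, nodes with
#' degree > k form the rich club; the coefficient is the total weight among
#' them divided by the sum of the equally many largest edge weights anywhere
#' in the graph. Levels with fewer than two rich nodes or no rich-club edges
#' are omitted (so k at or above the maximum degree never appears).
#'
#' @param conn connectome or weight matrix.
#' @return Named numeric vector indexed by k.
#' @export
rich_club <- function(conn) {
  w <- as_weight_matrix(conn)
  deg <- rowSums(w > 0)
  all_w <- sort(w[upper.tri(w) & w > 0], decreasing = TRUE)
  out <- numeric(0)
  if (max(deg) < 1) return(out)
  for (k in seq_len(max(deg))) {
    rich <- deg > k
    if (sum(rich) < 2) next
    sub <- w[rich, rich, drop = FALSE]
    ew <- sub[upper.tri(sub) & sub > 0]
    if (length(ew) == 0) next
    out[as.character(k)] <- sum(ew) / sum(all_w[seq_along(ew)])
  }
  out
}

#' Weighted betweenness centrality
#'
#' Brandes betweenness over reciprocal-weight edge lengths; path endpoints
#' are excluded. Each unordered pair contributes 1 split over its shortest
#' paths.
#'
#' @param conn connectome or weight matrix.
#' @return Numeric vector of nodal betweenness values.
#' @export
betweenness_weighted <- function(conn) {
  w <- as_weight_matrix(conn)
  g <- conn_igraph(w)
  b <- igraph::betweenness(g, weights = 1 / igraph::E(g)$weight,
                           directed = FALSE)
  stats::setNames(as.numeric(b), rownames(w))
}

# characteristic path length over connected pairs only (nulls may disconnect)
char_path_length <- function(w) {
  d <- shortest_path_matrix(w)
  v <- d[upper.tri(d)]
  v <- v[is.finite(v)]
  if (length(v) == 0) return(NA_real_)
  mean(v)
}

# Maslov-Sneppen degree-preserving rewire; weights reassigned at random to
# the rewired edge positions
rewire_null <- function(w) {
  g <- conn_igraph(w)
  ne <- igraph::ecount(g)
  if (ne < 2) return(w)
  g2 <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * ne))
  wnew <- matrix(0, nrow(w), ncol(w), dimnames = dimnames(w))
  el <- igraph::as_edgelist(g2, names = FALSE)
  wt <- sample(w[upper.tri(w) & w > 0])
  wnew[el] <- wt
  wnew + t(wnew)
}

#' Small-world indices
#'
#' Clustering (mean Onnela coefficient) and characteristic path length
#' (mean shortest path over connected pairs) of the observed graph relative
#' to degree-preserving randomized nulls with the weight multiset randomly
#' reassigned: gamma = C/C_null, lambda = L/L_null, sigma = gamma/lambda.
#'
#' @param conn connectome or weight matrix.
#' @param n_rand number of null networks (default 100).
#' @param seed optional integer seed for the null stream.
#' @return List with \code{gamma}, \code{lambda}, \code{sigma}.
#' @export
small_worldness <- function(conn, n_rand = 100, seed = NULL) {
  w <- as_weight_matrix(conn)
  if (!is.null(seed)) set.seed(seed)
  C <- mean(clustering_onnela(w))
  L <- char_path_length(w)
  Cn <- numeric(n_rand)
  Ln <- numeric(n_rand)
  for (r in seq_len(n_rand)) {
    wn <- rewire_null(w)
    Cn[r] <- mean(clustering_onnela(wn))
    Ln[r] <- char_path_length(wn)
  }
  gamma <- C / mean(Cn)
  lambda <- L / mean(Ln, na.rm = TRUE)
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}

#' Full metric set for one connectome
#'
#' Assembles the global and nodal topology measures; deterministic given
#' \code{seed} (used for the small-world nulls). Component failures are
#' propagated as \code{NA} with a warning.
#'
#' @param conn connectome or weight matrix.
#' @param n_rand number of small-world null networks.
#' @param seed integer seed.
#' @return A \code{metric_set} list: scalars \code{global_efficiency},
#'   \code{local_efficiency}, \code{assortativity}, \code{hierarchy_beta},
#'   \code{gamma}, \code{lambda}, \code{sigma}; vectors
#'   \code{nodal_efficiency}, \code{local_efficiency_nodal}, \code{degree},
#'   \code{strength}, \code{betweenness}, \code{clustering};
#'   mapping \code{rich_club}.
#' @export
metric_set <- function(conn, n_rand = 100, seed = 1L) {
  w <- as_weight_matrix(conn)
  le <- local_efficiency(w)
  ne <- nodal_efficiency(w)
  ds <- degree_strength(w)
  sw <- tryCatch(small_worldness(w, n_rand = n_rand, seed = seed),
                 error = function(e) {
                   warning("small-world computation failed: ",
                           conditionMessage(e))
                   list(gamma = NA_real_, lambda = NA_real_, sigma = NA_real_)
                 })
  structure(list(
    global_efficiency = mean(ne),
    local_efficiency = le$mean,
    assortativity = assortativity_degree_weighted(w),
    hierarchy_beta = hierarchy(w),
    gamma = sw$gamma, lambda = sw$lambda, sigma = sw$sigma,
    nodal_efficiency = ne,
    local_efficiency_nodal = le$nodal,
    degree = ds$degree, strength = ds$strength,
    betweenness = betweenness_weighted(w),
    clustering = clustering_onnela(w),
    rich_club = rich_club(w)
  ), class = "metric_set")
}

#' Scalar metrics of a metric set as a one-row data frame
#'
#' @param ms a \code{metric_set}.
#' @return One-row data frame of the scalar measures.
#' @export
metric_scalars <- function(ms) {
  data.frame(global_efficiency = ms$global_efficiency,
             local_efficiency = ms$local_efficiency,
             assortativity = ms$assortativity,
             hierarchy_beta = ms$hierarchy_beta,
             gamma = ms$gamma, lambda = ms$lambda, sigma = ms$sigma)
}
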