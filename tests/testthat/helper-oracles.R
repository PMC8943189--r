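# Brute-force oracles, independent of the package's implementation paths
# (igraph-free): Floyd-Warshall distances, loop-based efficiencies,
# exhaustive-path betweenness, direct rich-club enumeration.

oracle_floyd_warshall <- function(w) {
  n <- nrow(w)
  d <- ifelse(w > 0, 1 / w, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_global_efficiency <- function(w) {
  d <- oracle_floyd_warshall(w)
  n <- nrow(w)
  s <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && is.finite(d[i, j])) s <- s + 1 / d[i, j]
    }
  }
  s / (n * (n - 1))
}

oracle_nodal_efficiency <- function(w) {
  d <- oracle_floyd_warshall(w)
  n <- nrow(w)
  sapply(seq_len(n), function(i) {
    v <- 1 / d[i, -i]
    sum(v[is.finite(v)]) / (n - 1)
  })
}

oracle_local_efficiency <- function(w) {
  n <- nrow(w)
  sapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(w[nb, nb, drop = FALSE])
  })
}

# exhaustive simple-path enumeration betweenness (feasible for <= 8 nodes);
# each unordered pair contributes 1 split over its shortest paths, endpoints
# excluded
oracle_betweenness <- function(w, tol = 1e-12) {
  n <- nrow(w)
  btw <- numeric(n)
  all_paths <- function(s, t) {
    paths <- list()
    walk <- function(v, visited, len) {
      if (v == t) {
        paths[[length(paths) + 1]] <<- list(nodes = visited, len = len)
        return(invisible(NULL))
      }
      for (u in which(w[v, ] > 0)) {
        if (!(u %in% visited)) walk(u, c(visited, u), len + 1 / w[v, u])
      }
    }
    walk(s, s, 0)
    paths
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_paths(s, t)
      if (!length(paths)) next
      lens <- vapply(paths, function(p) p$len, numeric(1))
      short <- paths[lens <= min(lens) + tol]
      sigma <- length(short)
      inner <- table(unlist(lapply(short, function(p) {
        setdiff(p$nodes, c(s, t))
      })))
      for (v in names(inner)) {
        btw[as.integer(v)] <- btw[as.integer(v)] + inner[[v]] / sigma
      }
    }
  }
  btw
}

oracle_rich_club <- function(w) {
  deg <- rowSums(w > 0)
  all_w <- sort(w[upper.tri(w) & w > 0], decreasing = TRUE)
  out <- numeric(0)
  if (max(deg) < 1) return(out)
  for (k in seq_len(max(deg))) {
    rich <- which(deg > k)
    if (length(rich) < 2) next
    ew <- c()
    for (a in seq_along(rich)) {
      for (b in seq_along(rich)) {
        if (b > a && w[rich[a], rich[b]] > 0) {
          ew <- c(ew, w[rich[a], rich[b]])
        }
      }
    }
    if (!length(ew)) next
    out[as.character(k)] <- sum(ew) / sum(all_w[seq_along(ew)])
  }
  out
}

oracle_onnela_clustering <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  k <- rowSums(w > 0)
  cc <- numeric(n)
  if (mx == 0) return(cc)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    s <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && j != h &&
            w[i, j] > 0 && w[i, h] > 0 && w[j, h] > 0) {
          s <- s + ((w[i, j] / mx) * (w[i, h] / mx) * (w[j, h] / mx))^(1 / 3)
        }
      }
    }
    cc[i] <- s / (k[i] * (k[i] - 1))
  }
  cc
}

# random symmetric weighted test graph
random_weighted_graph <- function(n, p = 0.5, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  on <- ut & matrix(runif(n * n) < p, n, n)
  w[on] <- rlnorm(sum(on), 0, 1)
  w + t(w)
}

# minimal 5-node two-hemisphere toy atlas (2 lateralized regions per side
# plus brainstem) for split tests
make_toy_atlas <- function() {
  node_table(
    label = c("lh.a", "lh.b", "rh.a", "rh.b", "bs"),
    hemisphere = c("left", "left", "right", "right", "midline"),
    tissue_class = c("cortical", "cortical", "cortical", "cortical",
                     "brainstem"),
    homolog = c(lh.a = "rh.a", lh.b = "rh.b")
  )
}

# hand-built hemispheric pair from two aligned weight matrices
make_pair <- function(w_ipsi, w_contra, regions = NULL,
                      lesion_side = "left") {
  if (is.null(regions)) regions <- paste0("r", seq_len(nrow(w_ipsi)))
  dimnames(w_ipsi) <- list(regions, regions)
  dimnames(w_contra) <- list(regions, regions)
  structure(list(ipsi = connectome(w_ipsi), contra = connectome(w_contra),
                 lesion_side = lesion_side, regions = regions),
            class = "hemispheric_pair")
}

# independent Benjamini-Hochberg implementation (step-up from the largest p)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1))[ro])
}
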