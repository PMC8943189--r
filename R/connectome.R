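# Connectome container, TSV serialization and the hemispheric split.

#' Construct a connectome
#'
#' A connectome is a symmetric, zero-diagonal, nonnegative weighted adjacency
#' matrix (weights in streamline counts) bound to a \code{\link{node_table}}
#' whose order defines the matrix rows and columns.
#'
#' @param weights square numeric matrix.
#' @param nodes a \code{\link{node_table}} of matching length, or \code{NULL}
#'   to keep only the matrix dimnames.
#' @param sym_tol asymmetry tolerance; matrices asymmetric within the
#'   tolerance are symmetrized as \code{(W + t(W))/2}, beyond it rejected.
#' @return A \code{connectome} object.
#' @export
connectome <- function(weights, nodes = NULL, sym_tol = 1e-9) {
  if (!is.matrix(weights) || nrow(weights) != ncol(weights)) {
    stop("weights must be a square matrix")
  }
  if (!all(is.finite(weights))) stop("weights must be finite")
  if (any(weights < 0)) {
    bad <- which(weights < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative weight at [%d,%d]", bad[1], bad[2]))
  }
  asym <- abs(weights - t(weights))
  if (max(asym) > sym_tol) {
    bad <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf("asymmetric beyond tolerance at [%d,%d]: |%g - %g| = %g",
                 bad[1], bad[2], weights[bad[1], bad[2]],
                 weights[bad[2], bad[1]], max(asym)))
  }
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (!is.null(nodes)) {
    if (nrow(nodes) != nrow(weights)) {
      stop("node table length does not match matrix dimension")
    }
    if (!is.null(rownames(weights)) &&
        !identical(rownames(weights), nodes$label)) {
      diff <- setdiff(union(rownames(weights), nodes$label),
                      intersect(rownames(weights), nodes$label))
      stop("matrix labels do not match node table: ",
           paste(diff, collapse = ", "))
    }
    dimnames(weights) <- list(nodes$label, nodes$label)
  }
  structure(list(weights = weights, nodes = nodes), class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("connectome: %d nodes, %d edges, total weight %.4g\n",
              nrow(x$weights), sum(x$weights[upper.tri(x$weights)] > 0),
              sum(x$weights) / 2))
  invisible(x)
}

n_nodes <- function(conn) nrow(conn$weights)

#' Read a connectome from a labeled dense TSV
#'
#' The file carries node labels in its first row and first column and a
#' dense numeric body. Validation (symmetry to 1e-9, nonnegativity,
#' zero diagonal) is applied on read.
#'
#' @param path file path.
#' @param nodes optional \code{\link{node_table}}; if supplied, the file's
#'   labels must match it exactly (same order).
#' @return A \code{\link{connectome}}.
#' @export
read_connectome <- function(path, nodes = NULL) {
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  w <- as.matrix(df)
  if (!is.numeric(w)) stop("non-numeric entries in connectome body")
  if (!identical(rownames(w), colnames(w))) {
    stop("row and column labels differ")
  }
  connectome(w, nodes = nodes)
}

#' Write a connectome as a labeled dense TSV
#'
#' Zeros are written explicitly; \code{read_connectome()} of the written file
#' reproduces the weights to 1e-12.
#'
#' @param conn a \code{\link{connectome}}.
#' @param path output file path.
#' @export
write_connectome <- function(conn, path) {
  w <- conn$weights
  if (is.null(rownames(w))) {
    labs <- if (!is.null(conn$nodes)) conn$nodes$label else
      paste0("n", seq_len(nrow(w)))
    dimnames(w) <- list(labs, labs)
  }
  df <- data.frame(label = rownames(w), w, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Split a whole-brain connectome into hemispheric matrices
#'
#' Splits a 79-node whole-brain matrix into an ipsilesional and a
#' contralesional 40-node matrix (39 lateralized nodes plus the shared
#' brainstem). Interhemispheric edges are excluded; each brainstem edge goes
#' to the hemisphere of its lateralized endpoint. The contralesional matrix
#' rows are ordered by the homolog map so that row \code{k} of the two
#' matrices are homologous regions.
#'
#' @param conn whole-brain \code{\link{connectome}} with a node table.
#' @param lesion_side \code{"left"} or \code{"right"}; the ipsilesional side.
#' @return A \code{hemispheric_pair}: list with elements \code{ipsi} and
#'   \code{contra} (40-node connectomes), \code{lesion_side}, and
#'   \code{regions} (hemisphere-neutral region names aligned to the rows).
#' @export
split_hemispheres <- function(conn, lesion_side = c("left", "right")) {
  lesion_side <- match.arg(lesion_side)
  nodes <- conn$nodes
  if (is.null(nodes)) stop("split requires a connectome with a node table")
  hom <- homolog_map(nodes)
  if (is.null(hom)) stop("node table lacks a homolog bijection")
  bs <- nodes$label[nodes$hemisphere == "midline"]
  if (length(bs) != 1) stop("atlas must have exactly one midline node")

  left_labs  <- names(hom)          # atlas order of left labels
  right_labs <- unname(hom)         # homolog-aligned right labels

  take <- function(labs) {
    idx <- match(c(labs, bs), nodes$label)
    sub_nodes <- node_table(
      label = nodes$label[idx],
      hemisphere = nodes$hemisphere[idx],
      tissue_class = nodes$tissue_class[idx]
    )
    connectome(conn$weights[idx, idx, drop = FALSE], nodes = sub_nodes)
  }
  lw <- take(left_labs)
  rw <- take(right_labs)
  if (lesion_side == "left") {
    ipsi <- lw; contra <- rw
  } else {
    ipsi <- rw; contra <- lw
  }
  structure(list(
    ipsi = ipsi, contra = contra, lesion_side = lesion_side,
    regions = c(sub("^lh\\.", "", left_labs), bs)
  ), class = "hemispheric_pair")
}

#' @export
print.hemispheric_pair <- function(x, ...) {
  cat(sprintf("hemispheric_pair: lesion side %s, %d nodes per hemisphere\n",
              x$lesion_side, n_nodes(x$ipsi)))
  invisible(x)
}
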