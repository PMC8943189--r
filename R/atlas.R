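# Default whole-brain parcellation: DKT cortical labels plus subcortical gray,
# cerebellum and brainstem.

.dkt_cortical <- c(
  "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus", "entorhinal",
  "fusiform", "inferiorparietal", "inferiortemporal", "isthmuscingulate",
  "lateraloccipital", "lateralorbitofrontal", "lingual",
  "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
  "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
  "postcentral", "posteriorcingulate", "precentral", "precuneus",
  "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
  "superiorparietal", "superiortemporal", "supramarginal",
  "transversetemporal", "insula"
)

.subcortical <- c(
  "thalamus", "caudate", "putamen", "pallidum", "hippocampus", "amygdala",
  "accumbens"
)

#' Construct a node table
#'
#' A node table fixes the row/column semantics of every connectome matrix:
#' an ordered set of region labels, each tagged with a hemisphere
#' (\code{left}, \code{right} or \code{midline}) and a tissue class, plus a
#' bijective homolog map pairing each left-hemisphere label with its
#' right-hemisphere counterpart.
#'
#' @param label character vector of unique region labels, in matrix order.
#' @param hemisphere character vector, one of \code{"left"}, \code{"right"},
#'   \code{"midline"} per label.
#' @param tissue_class character vector, one of \code{"cortical"},
#'   \code{"subcortical"}, \code{"cerebellar"}, \code{"brainstem"}.
#' @param homolog named character vector mapping each left label to its right
#'   homolog, or \code{NULL} for tables without lateral pairs (e.g. a single
#'   hemisphere).
#' @return A \code{node_table} object (a data frame with a \code{homolog}
#'   attribute).
#' @export
node_table <- function(label, hemisphere, tissue_class, homolog = NULL) {
  stopifnot(length(label) == length(hemisphere),
            length(label) == length(tissue_class))
  if (anyDuplicated(label)) {
    stop("node labels must be unique")
  }
  if (!all(hemisphere %in% c("left", "right", "midline"))) {
    stop("hemisphere must be left, right or midline")
  }
  if (!all(tissue_class %in% c("cortical", "subcortical", "cerebellar",
                               "brainstem"))) {
    stop("unknown tissue_class")
  }
  if (!is.null(homolog)) {
    left  <- label[hemisphere == "left"]
    right <- label[hemisphere == "right"]
    if (!setequal(names(homolog), left) ||
        !setequal(unname(homolog), right) ||
        anyDuplicated(unname(homolog))) {
      stop("homolog map must be a bijection between left and right labels")
    }
    homolog <- homolog[left]  # fixed order: left labels' atlas order
  }
  nt <- data.frame(label = label, hemisphere = hemisphere,
                   tissue_class = tissue_class, stringsAsFactors = FALSE)
  attr(nt, "homolog") <- homolog
  class(nt) <- c("node_table", "data.frame")
  nt
}

#' Default 79-node whole-brain atlas
#'
#' 31 DKT cortical and 7 subcortical gray-matter labels per hemisphere
#' (76 gray-matter nodes in total), one cerebellar label per hemisphere, and
#' a single midline brainstem node: 79 nodes, of which 39 per hemisphere are
#' lateralized. Labels are prefixed \code{lh.}/\code{rh.}; the brainstem has
#' no prefix.
#'
#' @return A \code{\link{node_table}} with 79 rows.
#' @export
make_default_atlas <- function() {
  base <- c(.dkt_cortical, .subcortical, "cerebellum")
  cls  <- c(rep("cortical", length(.dkt_cortical)),
            rep("subcortical", length(.subcortical)),
            "cerebellar")
  label <- c(paste0("lh.", base), paste0("rh.", base), "brainstem")
  hemisphere <- c(rep("left", length(base)), rep("right", length(base)),
                  "midline")
  tissue <- c(cls, cls, "brainstem")
  homolog <- stats::setNames(paste0("rh.", base), paste0("lh.", base))
  node_table(label, hemisphere, tissue, homolog)
}

#' @export
print.node_table <- function(x, ...) {
  cat(sprintf("node_table: %d nodes (%d left, %d right, %d midline)\n",
              nrow(x), sum(x$hemisphere == "left"),
              sum(x$hemisphere == "right"), sum(x$hemisphere == "midline")))
  invisible(x)
}

homolog_map <- function(nodes) attr(nodes, "homolog")
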