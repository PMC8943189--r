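# Clinical records: lesion side, subgroup tags, MRC, NIHSS, WHO grade,
# tumor volume and nTMS resting motor thresholds.

.known_subgroups <- c("precentral", "postcentral", "insular", "frontal")

#' Read and validate a cohort clinical table
#'
#' Expects a CSV with columns \code{subject_id}, \code{lesion_side},
#' \code{subgroup} (semicolon-separated tags from precentral, postcentral,
#' insular, frontal), \code{mrc} (0-5), \code{nihss} (0-42, may be missing),
#' \code{who_grade} (2-4), \code{tumor_volume_cm3}, \code{rmt_pathological}
#' and \code{rmt_healthy} (V/m, positive). The pathological-to-healthy RMT
#' ratio is derived on read.
#'
#' @param path CSV file path.
#' @return A data frame of validated records with an added \code{rmt_ratio}
#'   column and \code{subgroup} parsed into a list column \code{subgroups}.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "lesion_side", "subgroup", "mrc", "nihss",
           "who_grade", "tumor_volume_cm3", "rmt_pathological", "rmt_healthy")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  validate_clinical(df)
}

validate_clinical <- function(df) {
  fail <- function(row, msg) stop(sprintf("clinical row %d: %s", row, msg))
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (!r$lesion_side %in% c("left", "right")) {
      fail(i, "lesion_side must be left or right")
    }
    if (is.na(r$mrc) || r$mrc < 0 || r$mrc > 5 || r$mrc != round(r$mrc)) {
      fail(i, sprintf("MRC %s out of range 0-5", r$mrc))
    }
    if (!is.na(r$nihss) && (r$nihss < 0 || r$nihss > 42)) {
      fail(i, sprintf("NIHSS %s out of range 0-42", r$nihss))
    }
    if (!r$who_grade %in% 2:4) {
      fail(i, sprintf("WHO grade %s not in {2,3,4}", r$who_grade))
    }
    if (is.na(r$tumor_volume_cm3) || r$tumor_volume_cm3 < 0) {
      fail(i, "tumor volume must be >= 0")
    }
    if (is.na(r$rmt_pathological) || r$rmt_pathological <= 0 ||
        is.na(r$rmt_healthy) || r$rmt_healthy <= 0) {
      fail(i, "RMT values must be positive")
    }
    tags <- strsplit(as.character(r$subgroup), ";")[[1]]
    if (!all(tags %in% .known_subgroups)) {
      fail(i, paste("unknown subgroup tag:",
                    paste(setdiff(tags, .known_subgroups), collapse = ", ")))
    }
  }
  if (anyDuplicated(df$subject_id)) stop("duplicate subject_id")
  df$rmt_ratio <- df$rmt_pathological / df$rmt_healthy
  df$subgroups <- strsplit(as.character(df$subgroup), ";")
  df
}

#' Subjects belonging to a subgroup
#'
#' @param clinical validated clinical table.
#' @param subgroup one of the known tags, or \code{"all"} for the entire
#'   cohort.
#' @return logical vector over rows of \code{clinical}.
#' @export
in_subgroup <- function(clinical, subgroup) {
  if (identical(subgroup, "all")) return(rep(TRUE, nrow(clinical)))
  if (!subgroup %in% .known_subgroups) stop("unknown subgroup: ", subgroup)
  vapply(clinical$subgroups, function(t) subgroup %in% t, logical(1))
}
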