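# End-to-end orchestration: cohort -> hemispheric split -> TFNBS ->
# topology metrics -> group statistics, with a reproducibility manifest.

seed_stream <- function(root, k) as.integer(root) * 1000L + as.integer(k)

#' Analysis configuration
#'
#' @param mode \code{"synthetic"} (generate a cohort) or \code{"files"}
#'   (read one written by \code{\link{write_cohort}} from \code{input_dir}).
#' @param generator \code{\link{generator_config}} for synthetic mode.
#' @param input_dir cohort directory for files mode.
#' @param tfnbs \code{\link{tfnbs_params}}.
#' @param subgroups subgroup blocks to analyze (\code{"all"} plus any of
#'   precentral, postcentral, insular, frontal).
#' @param directions TFNBS directions to test.
#' @param clinical_vars clinical variables entering the correlation
#'   families.
#' @param n_rand small-world null networks per metric set.
#' @param compute_metrics set \code{FALSE} to skip the topology-metric and
#'   downstream statistics blocks (TFNBS only).
#' @param out_dir optional report output directory.
#' @param seed root seed; all stage seeds are derived from it as
#'   \code{seed * 1000 + stage offset}.
#' @return An \code{analysis_config} list.
#' @export
analysis_config <- function(mode = c("synthetic", "files"),
                            generator = generator_config(),
                            input_dir = NULL,
                            tfnbs = tfnbs_params(),
                            subgroups = c("all", "precentral", "postcentral",
                                          "insular", "frontal"),
                            directions = c("contra_gt_ipsi",
                                           "ipsi_gt_contra"),
                            clinical_vars = c("mrc", "nihss", "rmt_ratio",
                                              "tumor_volume_cm3",
                                              "who_grade"),
                            n_rand = 100,
                            compute_metrics = TRUE,
                            out_dir = NULL,
                            seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(all(subgroups %in% c("all", .known_subgroups)))
  if (mode == "files" && is.null(input_dir)) {
    stop("files mode requires input_dir")
  }
  structure(list(mode = mode, generator = generator, input_dir = input_dir,
                 tfnbs = tfnbs, subgroups = subgroups,
                 directions = directions, clinical_vars = clinical_vars,
                 n_rand = n_rand, compute_metrics = compute_metrics,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read a cohort written by \code{write_cohort}
#'
#' @param dir cohort directory.
#' @param atlas node table the connectomes must match.
#' @return List with \code{subjects} (each holding \code{connectome_a},
#'   \code{connectome_b}, \code{clinical}) and the validated \code{clinical}
#'   table.
#' @export
read_cohort <- function(dir, atlas = make_default_atlas()) {
  clinical <- read_clinical_table(file.path(dir, "clinical.csv"))
  subjects <- lapply(seq_len(nrow(clinical)), function(i) {
    id <- clinical$subject_id[i]
    list(
      connectome_a = read_connectome(file.path(dir, paste0(id, "_algA.tsv")),
                                     nodes = atlas),
      connectome_b = read_connectome(file.path(dir, paste0(id, "_algB.tsv")),
                                     nodes = atlas),
      clinical = clinical[i, ]
    )
  })
  list(subjects = subjects, clinical = clinical, atlas = atlas)
}

# edge-strength + scalar-metric feature table for one hemispheric view
view_feature_table <- function(pairs, edges, scalars, view) {
  regions <- pairs[[1]]$regions
  feats <- NULL
  if (nrow(edges)) {
    i <- match(edges$node_i, regions)
    j <- match(edges$node_j, regions)
    fe <- vapply(pairs, function(p) {
      switch(view,
             ipsi = p$ipsi$weights[cbind(i, j)],
             contra = p$contra$weights[cbind(i, j)],
             diff = p$contra$weights[cbind(i, j)] -
               p$ipsi$weights[cbind(i, j)])
    }, numeric(nrow(edges)))
    if (is.null(dim(fe))) fe <- matrix(fe, nrow = 1)  # single-edge case
    feats <- t(fe)
    colnames(feats) <- paste0(edges$node_i, "--", edges$node_j)
    feats <- as.data.frame(feats)
  }
  sc <- switch(view,
               ipsi = scalars$ipsi,
               contra = scalars$contra,
               diff = scalars$contra - scalars$ipsi)
  if (!is.null(sc)) {
    if (is.null(feats)) feats <- sc else feats <- cbind(feats, sc)
  }
  feats
}

#' Run the full analysis pipeline
#'
#' For each tractography replicate (algA, algB) and each configured subgroup
#' with at least 3 subjects: hemispheric split, TFNBS in both directions,
#' per-hemisphere topology metric sets, paired hemisphere comparisons,
#' FDR-corrected Spearman correlations of TFNBS-selected edge strengths and
#' scalar metrics with the clinical variables (ipsilesional, contralesional
#' and difference views), and the cross-algorithm Pearson agreement table.
#'
#' @param config \code{\link{analysis_config}}.
#' @return A \code{report_bundle} list; written to \code{config$out_dir}
#'   when set.
#' @export
run_pipeline <- function(config = analysis_config()) {
  root <- config$seed
  if (config$mode == "synthetic") {
    gen <- config$generator
    gen$seed <- seed_stream(root, 1)
    cohort <- simulate_cohort(gen)
  } else {
    cohort <- read_cohort(config$input_dir)
  }
  clinical <- cohort$clinical
  n <- nrow(clinical)
  algs <- c(algA = "connectome_a", algB = "connectome_b")
  pairs <- lapply(algs, function(field) {
    lapply(seq_len(n), function(i) {
      split_hemispheres(cohort$subjects[[i]][[field]],
                        clinical$lesion_side[i])
    })
  })

  tfnbs_blocks <- list()
  k <- 0L
  for (alg in names(algs)) {
    for (sg in config$subgroups) {
      sel <- which(in_subgroup(clinical, sg))
      if (length(sel) < 3) {
        warning(sprintf("subgroup %s has n=%d < 3; block skipped",
                        sg, length(sel)))
        next
      }
      for (dir in config$directions) {
        k <- k + 1L
        par <- config$tfnbs
        par$seed <- seed_stream(root, 10 + k)
        res <- permutation_fwe(pairs[[alg]][sel],
                               clinical$lesion_side[sel], par, dir)
        tfnbs_blocks[[paste(alg, sg, dir, sep = ".")]] <- list(
          algorithm = alg, subgroup = sg, direction = dir, n = length(sel),
          result = res, significant = significant_edges(res))
      }
    }
  }

  metrics <- NULL
  paired_tests <- NULL
  correlations <- NULL
  agreement <- NULL
  if (config$compute_metrics) {
    scalar_rows <- list()
    scalar_tabs <- list()
    for (alg in names(algs)) {
      for (hemi in c("ipsi", "contra")) {
        ms <- lapply(seq_len(n), function(i) {
          metric_set(pairs[[alg]][[i]][[hemi]], n_rand = config$n_rand,
                     seed = seed_stream(root, 2))
        })
        tab <- do.call(rbind, lapply(ms, metric_scalars))
        tab <- cbind(data.frame(subject_id = clinical$subject_id,
                                algorithm = alg, hemisphere = hemi,
                                stringsAsFactors = FALSE), tab)
        scalar_rows[[paste(alg, hemi, sep = ".")]] <- tab
        scalar_tabs[[paste(alg, hemi, sep = ".")]] <-
          tab[, !(names(tab) %in% c("subject_id", "algorithm", "hemisphere"))]
      }
    }
    metrics <- do.call(rbind, scalar_rows)
    rownames(metrics) <- NULL

    scalar_names <- names(scalar_tabs[["algA.ipsi"]])
    pt <- list()
    for (alg in names(algs)) {
      for (mname in scalar_names) {
        vi <- scalar_tabs[[paste0(alg, ".ipsi")]][[mname]]
        vc <- scalar_tabs[[paste0(alg, ".contra")]][[mname]]
        ok <- !is.na(vi) & !is.na(vc)
        if (sum(ok) < 3) next
        row <- paired_compare(vi[ok], vc[ok])
        pt[[length(pt) + 1]] <- cbind(
          data.frame(algorithm = alg, metric = mname,
                     stringsAsFactors = FALSE), row)
      }
    }
    paired_tests <- do.call(rbind, pt)

    clin_feats <- clinical[, config$clinical_vars, drop = FALSE]
    corr <- list()
    for (alg in names(algs)) {
      sig <- unique(do.call(rbind, lapply(tfnbs_blocks, function(b) {
        if (b$algorithm == alg && b$subgroup == "all") {
          b$significant[, c("node_i", "node_j")]
        } else NULL
      })))
      if (is.null(sig)) sig <- data.frame(node_i = character(0),
                                          node_j = character(0))
      scal <- list(ipsi = scalar_tabs[[paste0(alg, ".ipsi")]],
                   contra = scalar_tabs[[paste0(alg, ".contra")]])
      for (view in c("ipsi", "contra", "diff")) {
        ft <- view_feature_table(pairs[[alg]], sig, scal, view)
        if (is.null(ft) || ncol(ft) == 0) next
        res <- suppressWarnings(spearman_fdr(ft, clin_feats))
        if (nrow(res)) {
          corr[[length(corr) + 1]] <- cbind(
            data.frame(algorithm = alg, view = view,
                       stringsAsFactors = FALSE), res)
        }
      }
    }
    correlations <- if (length(corr)) do.call(rbind, corr) else NULL
    if (!is.null(correlations)) rownames(correlations) <- NULL

    agreement <- cross_algorithm_agreement(
      metrics[metrics$algorithm == "algA",
              c("hemisphere", scalar_names)],
      metrics[metrics$algorithm == "algB",
              c("hemisphere", scalar_names)],
      pooled = FALSE)
  }

  manifest <- list(
    seed = root,
    package_version = as.character(utils::packageVersion("hemiconn")),
    mode = config$mode,
    n_subjects = n,
    tfnbs = unclass(config$tfnbs),
    subgroups = config$subgroups,
    directions = config$directions,
    n_rand = config$n_rand
  )
  tf <- tempfile()
  jsonlite::write_json(manifest, tf, auto_unbox = TRUE, digits = NA)
  manifest$config_hash <- unname(tools::md5sum(tf))
  unlink(tf)

  bundle <- structure(list(
    tfnbs = tfnbs_blocks, metrics = metrics, paired_tests = paired_tests,
    correlations = correlations, agreement = agreement,
    clinical = clinical, manifest = manifest, config = config
  ), class = "report_bundle")
  if (!is.null(config$out_dir)) write_report(bundle, config$out_dir)
  bundle
}

#' Write a report bundle to disk
#'
#' @param bundle a \code{report_bundle}.
#' @param dir output directory.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  sig <- do.call(rbind, lapply(names(bundle$tfnbs), function(nm) {
    b <- bundle$tfnbs[[nm]]
    if (nrow(b$significant) == 0) return(NULL)
    cbind(data.frame(algorithm = b$algorithm, subgroup = b$subgroup,
                     stringsAsFactors = FALSE), b$significant)
  }))
  if (is.null(sig)) {
    sig <- data.frame(algorithm = character(0), subgroup = character(0),
                      node_i = character(0), node_j = character(0),
                      t = numeric(0), score = numeric(0),
                      p_fwe = numeric(0), direction = character(0))
  }
  wt(sig, "significant_edges.tsv")
  if (!is.null(bundle$metrics)) wt(bundle$metrics, "metrics.tsv")
  if (!is.null(bundle$paired_tests)) {
    wt(bundle$paired_tests, "paired_tests.tsv")
  }
  if (!is.null(bundle$correlations)) {
    wt(bundle$correlations, "correlations.tsv")
  }
  if (!is.null(bundle$agreement)) wt(bundle$agreement, "agreement.tsv")
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(summarize_report(bundle), file.path(dir, "summary.md"))
  invisible(NULL)
}

#' Human-readable summary of a report bundle
#'
#' @param bundle a \code{report_bundle}.
#' @return Character vector of markdown lines.
#' @export
summarize_report <- function(bundle) {
  lines <- c("# Hemispheric connectome asymmetry report", "",
             sprintf("Cohort: n = %d subjects; seed %d; config %s",
                     nrow(bundle$clinical), bundle$manifest$seed,
                     bundle$manifest$config_hash), "",
             "## TFNBS significant edges")
  for (nm in names(bundle$tfnbs)) {
    b <- bundle$tfnbs[[nm]]
    lines <- c(lines, sprintf("- %s / %s / %s (n=%d): %d significant edges",
                              b$algorithm, b$subgroup, b$direction, b$n,
                              nrow(b$significant)))
  }
  if (!is.null(bundle$metrics)) {
    lines <- c(lines, "", "## Efficiency by hemisphere (mean +- SD)")
    for (mname in c("global_efficiency", "local_efficiency")) {
      for (alg in unique(bundle$metrics$algorithm)) {
        for (hemi in c("ipsi", "contra")) {
          v <- bundle$metrics[[mname]][bundle$metrics$algorithm == alg &
                                         bundle$metrics$hemisphere == hemi]
          lines <- c(lines, sprintf("- %s %s %s: %.0f +- %.0f", mname, alg,
                                    hemi, mean(v), stats::sd(v)))
        }
      }
    }
  }
  if (!is.null(bundle$paired_tests)) {
    lines <- c(lines, "", "## Paired hemisphere tests")
    for (i in seq_len(nrow(bundle$paired_tests))) {
      r <- bundle$paired_tests[i, ]
      lines <- c(lines, sprintf(
        "- %s %s: t(%d) = %.2f, p = %.4g; Wilcoxon V = %s, p = %.4g",
        r$algorithm, r$metric, r$df, r$statistic_t, r$p_t,
        format(r$statistic_wilcoxon), r$p_wilcoxon))
    }
  }
  if (!is.null(bundle$correlations)) {
    nsig <- sum(bundle$correlations$p_fdr < 0.05, na.rm = TRUE)
    lines <- c(lines, "", sprintf(
      "## Clinical correlations: %d FDR-significant of %d tested",
      nsig, nrow(bundle$correlations)))
  }
  if (!is.null(bundle$agreement)) {
    lines <- c(lines, "", "## Cross-algorithm agreement (Pearson r)")
    eff <- bundle$agreement[bundle$agreement$feature %in%
                              c("global_efficiency", "local_efficiency"), ]
    for (i in seq_len(nrow(eff))) {
      lines <- c(lines, sprintf("- %s (%s): r = %.3f (n=%d)",
                                eff$feature[i], eff$variable[i],
                                eff$rho[i], eff$n[i]))
    }
  }
  lines
}
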