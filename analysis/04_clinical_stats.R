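#!/usr/bin/env Rscript
# Step 4 — clinical correlations and cross-algorithm agreement.
#
# Correlates the TFNBS-selected edge strengths and the scalar topology
# metrics with the clinical variables (MRC, NIHSS, RMT ratio, tumor volume,
# WHO grade) for the ipsilesional, contralesional and difference views,
# with Benjamini-Hochberg FDR per declared family, and computes the Pearson
# agreement between the two tractography replicates. Outputs:
# results/correlations.tsv, results/agreement.tsv.

library(hemiconn)

cohort <- read_cohort("results/cohort")
clinical <- cohort$clinical
n <- nrow(clinical)
metrics <- read.delim("results/metrics.tsv")
sig <- read.delim("results/tfnbs_significant_edges.tsv")
clin_vars <- clinical[, c("mrc", "nihss", "rmt_ratio", "tumor_volume_cm3",
                          "who_grade")]
scalar_names <- setdiff(names(metrics),
                        c("subject_id", "algorithm", "hemisphere"))

corr <- list()
for (alg in c("algA", "algB")) {
  field <- if (alg == "algA") "connectome_a" else "connectome_b"
  pairs <- lapply(seq_len(n), function(i) {
    split_hemispheres(cohort$subjects[[i]][[field]],
                      clinical$lesion_side[i])
  })
  edges <- unique(sig[sig$algorithm == alg & sig$subgroup == "all",
                      c("node_i", "node_j")])
  regions <- pairs[[1]]$regions
  pick <- function(hemi) {
    tab <- metrics[metrics$algorithm == alg & metrics$hemisphere == hemi,
                   scalar_names]
    rownames(tab) <- NULL
    tab
  }
  for (view in c("ipsi", "contra", "diff")) {
    ew <- NULL
    if (nrow(edges)) {
      i <- match(edges$node_i, regions)
      j <- match(edges$node_j, regions)
      ew <- t(sapply(pairs, function(p) {
        switch(view,
               ipsi = p$ipsi$weights[cbind(i, j)],
               contra = p$contra$weights[cbind(i, j)],
               diff = p$contra$weights[cbind(i, j)] -
                 p$ipsi$weights[cbind(i, j)])
      }))
      if (nrow(edges) == 1) ew <- t(ew)
      colnames(ew) <- paste0(edges$node_i, "--", edges$node_j)
    }
    sc <- switch(view, ipsi = pick("ipsi"), contra = pick("contra"),
                 diff = pick("contra") - pick("ipsi"))
    feats <- if (is.null(ew)) sc else cbind(as.data.frame(ew), sc)
    res <- suppressWarnings(spearman_fdr(feats, clin_vars))
    if (nrow(res)) {
      corr[[length(corr) + 1]] <- cbind(
        data.frame(algorithm = alg, view = view), res)
    }
  }
}
correlations <- do.call(rbind, corr)
rownames(correlations) <- NULL
write.table(correlations, "results/correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
found <- correlations[correlations$p_fdr < 0.05, ]
cat(sprintf("FDR-significant correlations (q < 0.05): %d of %d tested\n",
            nrow(found), nrow(correlations)))
if (nrow(found)) {
  for (i in seq_len(nrow(found))) {
    cat(sprintf("  %s/%s: %s ~ %s rho = %.2f (q = %.4f)\n",
                found$algorithm[i], found$view[i], found$feature[i],
                found$variable[i], found$rho[i], found$p_fdr[i]))
  }
}

a <- metrics[metrics$algorithm == "algA", c("hemisphere", scalar_names)]
b <- metrics[metrics$algorithm == "algB", c("hemisphere", scalar_names)]
agreement <- cross_algorithm_agreement(a, b, pooled = FALSE)
write.table(agreement, "results/agreement.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
eff <- agreement[agreement$feature %in% c("global_efficiency",
                                          "local_efficiency"), ]
cat("Cross-algorithm Pearson agreement:\n")
for (i in seq_len(nrow(eff))) {
  cat(sprintf("  %s (%s): r = %.3f\n", eff$feature[i], eff$variable[i],
              eff$rho[i]))
}
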