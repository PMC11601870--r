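#!/usr/bin/env Rscript
# Temporal structure: fuzzy c-means clustering of z-scored group-mean
# trajectories (m = 1.5, c = 9 by the elbow default, cores at membership
# >= 0.5, class ORA per core), and 5-point logFC trajectory correlations
# between the sexes.

library(lipidcourse)
study <- readRDS("results/study.rds")
pre <- readRDS("results/preprocessed.rds")
diff <- readRDS("results/differential.rds")
animals <- study$design$animals

assign_rows <- list()
for (tissue in c("liver", "heart", "WAT-SC")) {
  nm <- pre$normalized[[tissue]]
  meta <- animals[match(colnames(nm$values), animals$animal_id), ]
  tm <- trajectory_matrix(nm$values, meta)
  pick <- choose_c(tm, c_range = 2:12, seed = 202, n_restarts = 5)
  fit <- cmeans_fuzzy(tm, c = 9, seed = 202)
  core_n <- colSums(fit$core)
  message(sprintf("%-8s elbow c = %d%s; c = 9 core sizes: %s", tissue, pick$c,
                  if (pick$low_confidence) " (low confidence)" else "",
                  paste(core_n, collapse = ", ")))
  assign_rows[[tissue]] <- data.frame(
    tissue = tissue, name = rownames(tm),
    cluster = fit$cluster, core = apply(fit$core, 1, any),
    membership = apply(fit$membership, 1, max))
}
write.table(do.call(rbind, assign_rows), "results/cluster_assignments.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

# male vs female logFC trajectory concordance per tissue (5-point Pearson)
sx <- sex_trajectory_correlations(diff[diff$sex %in% c("male", "female"), ],
                                  study$annotations)
med <- correlation_density_summary(sx$r, sx[, "tissue", drop = FALSE])$medians
message("male-female trajectory correlation medians: ",
        paste(sprintf("%s=%.2f", med$group, med$median_r), collapse = ", "))
write.table(sx, "results/sex_trajectory_correlations.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message("wrote results/cluster_assignments.tsv, sex_trajectory_correlations.tsv")
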