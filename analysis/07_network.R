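#!/usr/bin/env Rscript
# Network stage: per-sex cross-tissue sample-level correlation networks
# (Bonferroni-adjusted p < 0.05; intra- vs inter-tissue edges, tissue-pair
# edge counts by sign), and per-tissue signed-TOM co-expression modules
# with hub lipids, class ORA of hubs, and module-phenotype correlations.

library(lipidcourse)
study <- readRDS("results/study.rds")
pre <- readRDS("results/preprocessed.rds")
animals <- study$design$animals

for (sx in c("male", "female")) {
  ids <- animals$animal_id[animals$sex == sx]
  mats <- lapply(pre$normalized, function(nm)
    nm$values[, colnames(nm$values) %in% ids, drop = FALSE])
  net <- build_correlation_network(mats)
  message(sprintf("%s network: %d nodes, %d edges (%d inter-tissue), %d pairs tested",
                  sx, nrow(net$nodes), nrow(net$edges),
                  sum(net$edges$scope == "inter"), net$n_tested))
  write_network(net, sprintf("results/network_edges_%s.tsv", sx),
                sprintf("results/network_nodes_%s.tsv", sx))
}

mod_rows <- list(); ph_rows <- list()
for (tissue in c("liver", "WAT-SC", "heart")) {
  v <- pre$normalized[[tissue]]$values
  ms <- detect_modules(tom_similarity(v, beta = 6), v)
  sizes <- lengths(ms$modules)
  message(sprintf("%-8s modules: %s (grey %d)", tissue,
                  paste(sprintf("%s=%d", names(sizes), sizes)[names(sizes) != "grey"],
                        collapse = ", "), sizes[["grey"]]))
  mod_rows[[tissue]] <- data.frame(tissue = tissue, name = names(ms$labels),
                                   module = unname(ms$labels))
  if (is.null(ms$eigenprofiles)) next
  mp <- module_phenotype_correlation(ms, study$phenotypes)
  sig <- mp$correlations[mp$correlations$significant, ]
  if (nrow(sig))
    message("  phenotype links (p < 0.05): ",
            paste(sprintf("%s~%s r=%.2f", sig$module, sig$phenotype, sig$r),
                  collapse = "; "))
  ph_rows[[tissue]] <- cbind(tissue = tissue, mp$correlations)
}
write.table(do.call(rbind, mod_rows), "results/module_assignments.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(do.call(rbind, ph_rows), "results/module_phenotype_correlations.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
message("wrote results/network_*.tsv, module_assignments.tsv, module_phenotype_correlations.tsv")
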