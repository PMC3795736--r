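#!/usr/bin/env Rscript
# Template-based network classification: each phenotype against the pooled
# rest (apparent + LOOCV accuracy per network, pooled permutation p and FDR)
# and the key pairwise comparison between the two GBM subtypes.
suppressPackageStartupMessages(library(diracnet))

out <- "results/analysis"
ranks <- read_expression_tsv(file.path(out, "ranks.tsv"), layer = "rank")
labels <- read_labels_tsv(file.path(out, "cohort", "labels.tsv"))
networks <- read_gmt(file.path(out, "cohort", "networks.gmt"))
seed <- 20260919L
n_perm <- 200L

loocv_means <- c()
for (target in levels(labels)) {
  ovr <- one_vs_rest(ranks, labels, networks, target, n_perm = n_perm,
                     seed = stage_seed(seed, paste0("classify_", target)),
                     top_k = 10)
  write.table(ovr$summary,
              file.path(out, sprintf("classify_%s_vs_rest.tsv", target)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  loocv_means[target] <- ovr$mean_loocv_accuracy
  cat(sprintf("%s vs rest: mean LOOCV %.3f; best %s (apparent %.3f, p = %.3g, FDR = %.3g)\n",
              target, ovr$mean_loocv_accuracy, ovr$top$network[1],
              ovr$top$accuracy[1], ovr$top$p[1], ovr$top$fdr[1]))
}

# the hard comparison: primary vs secondary GBM (same grade, shared history)
pg <- classification_significance(ranks, labels, networks, "pGBM", "sGBM",
                                  n_perm = n_perm,
                                  seed = stage_seed(seed, "classify_pg_sg"))
best <- pg$network[1]
cv <- loocv(ranks, labels, networks[[best]], "pGBM", "sGBM", best)
cat(sprintf("pGBM vs sGBM: best network %s apparent %.3f (p = %.3g), LOOCV %.3f\n",
            best, pg$accuracy[1], pg$p[1], cv$accuracy))
write.table(pg, file.path(out, "classify_pGBM_vs_sGBM.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
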