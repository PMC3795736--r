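#!/usr/bin/env Rscript
# Global network regulation across the grade ladder: per-(network, phenotype)
# rank conservation indices with the two GBM subtypes merged into one Grade 4
# endpoint, the global dysregulation means, one-way ANOVA across phenotypes,
# and pairwise paired t-tests.
suppressPackageStartupMessages(library(diracnet))

out <- "results/analysis"
ranks <- read_expression_tsv(file.path(out, "ranks.tsv"), layer = "rank")
labels <- read_labels_tsv(file.path(out, "cohort", "labels.tsv"))
networks <- read_gmt(file.path(out, "cohort", "networks.gmt"))

merged <- merge_gbm(labels)
ct <- conservation_table(ranks, merged, networks)
write.table(data.frame(network = rownames(ct), ct, check.names = FALSE),
            file.path(out, "conservation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

g <- global_dysregulation(ct)
an <- anova_conservation(ct)
tt <- pairwise_t_tests(ct)
jsonlite::write_json(list(global = as.list(g), anova = an,
                          pairwise_t_p = as.data.frame(tt$p)),
                     file.path(out, "conservation_summary.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE,
                     na = "null")

cat("global mean conservation per phenotype:\n")
print(round(g, 4))
cat(sprintf("grade ladder strictly decreasing: %s\n",
            all(diff(g[c("Normal", "G2", "G3", "GBM")]) < 0)))
cat(sprintf("one-way ANOVA: F = %.2f, p = %.3g\n", an$F, an$p))
cat(sprintf("largest pairwise paired-t p: %.3g\n",
            max(tt$p[upper.tri(tt$p)], na.rm = TRUE)))
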