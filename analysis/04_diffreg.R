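#!/usr/bin/env Rscript
# Most differentially regulated networks between adjacent grades: observed
# conservation-index differences with a pooled permutation null, plus the
# binomial test asking whether significant networks are predominantly more
# dysregulated in the higher grade.
suppressPackageStartupMessages(library(diracnet))

out <- "results/analysis"
ranks <- read_expression_tsv(file.path(out, "ranks.tsv"), layer = "rank")
labels <- read_labels_tsv(file.path(out, "cohort", "labels.tsv"))
networks <- read_gmt(file.path(out, "cohort", "networks.gmt"))
seed <- 20260919L
n_perm <- 200L

comparisons <- list(c("Normal", "G2"), c("G2", "G3"),
                    c("G3", "pGBM"), c("G3", "sGBM"), c("pGBM", "sGBM"))
for (cmp in comparisons) {
  dr <- differential_regulation(
    ranks, labels, networks, cmp[1], cmp[2], n_perm = n_perm,
    seed = stage_seed(seed, paste0("diffreg_", cmp[1], "_", cmp[2])))
  write.table(dr, file.path(out, sprintf("diffreg_%s_vs_%s.tsv", cmp[1], cmp[2])),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- dr[dr$p < 0.01, , drop = FALSE]
  msg <- sprintf("%s vs %s: %d networks at p < 0.01; top %s (|delta| = %.3f, %s)",
                 cmp[1], cmp[2], nrow(sig), dr$network[1], abs(dr$delta[1]),
                 dr$direction[1])
  if (nrow(sig) > 0) {
    k <- sum(sig$delta > 0)  # more conserved in the lower grade
    msg <- sprintf("%s; binomial direction p = %.3g (%d/%d more dysregulated in %s)",
                   msg, binomial_direction_test(k, nrow(sig)), k, nrow(sig), cmp[2])
  }
  cat(msg, "\n")
}
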