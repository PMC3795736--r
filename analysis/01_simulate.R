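#!/usr/bin/env Rscript
# Build the synthetic multi-grade astrocytoma cohort used by every later
# stage: five phenotypes on the grade ladder, a noise ladder that makes
# higher grades more heterogeneous, planted monotonic genes, planted
# dysregulated networks, batch effects, and a probe layer.
suppressPackageStartupMessages(library(diracnet))

out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(
  n_genes = 1000L,
  phenotypes = c(Normal = 25L, G2 = 25L, G3 = 25L, pGBM = 25L, sGBM = 25L),
  n_networks = 248L, network_sizes = c(5L, 50L),
  sigma_by_phenotype = c(Normal = 0.5, G2 = 0.7, G3 = 0.9,
                         pGBM = 1.1, sGBM = 1.1),
  planted_increasing = sprintf("g%04d", 1:10),
  planted_decreasing = sprintf("g%04d", 11:20),
  delta = 3,
  planted_dysreg = list(
    list(network = "NET_001", phenotype = "G2", extra_sigma = 3),
    list(network = "NET_002", phenotype = "G3", extra_sigma = 3),
    list(network = "NET_003", phenotype = "pGBM", extra_sigma = 3)),
  n_batches = 3L, batch_sigma = 0.5,
  n_silent_probes = 5L, silent_phenotype = "G2",
  seed = 20260919L)

cohort <- generate_cohort(cfg)
write_cohort(cohort, file.path(out, "cohort"))

cat(sprintf("cohort: %d genes x %d samples, %d networks, %d probes\n",
            nrow(cohort$expr), ncol(cohort$expr), length(cohort$networks),
            nrow(cohort$probes$intensity)))
cat(sprintf("planted: %d increasing / %d decreasing genes, %d dysregulated networks\n",
            length(cfg$planted_increasing), length(cfg$planted_decreasing),
            length(cfg$planted_dysreg)))
cat("written to", file.path(out, "cohort"), "\n")
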