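#' Configuration for a full pipeline run
#'
#' Bundles a cohort source (a [sim_config()] simulate block, or paths to an
#' expression TSV + labels TSV + GMT), the comparisons to run, permutation
#' and threshold parameters, the output directory, and the single top-level
#' seed from which every stage derives its own sub-stream (see
#' [stage_seed()]).
#'
#' @param simulate A [sim_config()], or `NULL` when `inputs` is given.
#' @param inputs Named list with `expression`, `labels`, `networks` (GMT)
#'   paths; `probes` (directory) optional.
#' @param comparisons List of length-2 character vectors: phenotype pairs for
#'   differential network regulation.
#' @param one_vs_rest_targets Phenotypes to classify against the pooled rest.
#' @param n_perm Permutations for differential regulation, classification and
#'   directionality nulls.
#' @param n_rep,frac,min_support Subsampling-robustness parameters.
#' @param alpha Significance level for DEG Bonferroni correction.
#' @param top_k Rows of the best-network classification tables.
#' @param out_dir Output directory.
#' @param seed Integer top-level seed.
#' @param stages Which stages to run (subset of the default vector, in order).
#' @return Validated `run_config` list.
#' @export
run_config <- function(simulate = sim_config(),
                       inputs = NULL,
                       comparisons = list(c("Normal", "G2"), c("G2", "G3"),
                                          c("G3", "pGBM"), c("G3", "sGBM"),
                                          c("pGBM", "sGBM")),
                       one_vs_rest_targets = c("Normal", "G2", "G3", "pGBM", "sGBM"),
                       n_perm = 1000L,
                       n_rep = 1000L, frac = 0.8, min_support = 500L,
                       alpha = 0.05,
                       top_k = 10L,
                       out_dir = "dirac_run",
                       seed = 1L,
                       stages = c("simulate", "preprocess", "conserve",
                                  "diffreg", "monotonic", "classify",
                                  "report")) {
  if (is.null(simulate) && is.null(inputs)) {
    stop("either a simulate block or input paths must be given")
  }
  if (!is.null(inputs)) {
    need <- c("expression", "labels", "networks")
    if (!all(need %in% names(inputs))) {
      stop("inputs must name: ", paste(need, collapse = ", "))
    }
  }
  known <- if (!is.null(simulate)) names(simulate$phenotypes) else {
    unique(as.character(read_labels_tsv(inputs$labels)))
  }
  referenced <- unique(c(unlist(comparisons), one_vs_rest_targets))
  bad <- setdiff(referenced, known)
  if (length(bad)) {
    stop("comparison references unknown phenotype(s): ",
         paste(bad, collapse = ", "))
  }
  if (n_perm < 1 || n_rep < 0) stop("invalid permutation counts")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]")
  bad_stage <- setdiff(stages, c("simulate", "preprocess", "conserve",
                                 "diffreg", "monotonic", "classify", "report"))
  if (length(bad_stage)) stop("unknown stage(s): ", paste(bad_stage, collapse = ", "))
  structure(list(simulate = simulate, inputs = inputs,
                 comparisons = comparisons,
                 one_vs_rest_targets = one_vs_rest_targets,
                 n_perm = as.integer(n_perm), n_rep = as.integer(n_rep),
                 frac = frac, min_support = as.integer(min_support),
                 alpha = alpha, top_k = as.integer(top_k),
                 out_dir = out_dir, seed = as.integer(seed),
                 stages = stages), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order (simulate or load, preprocess,
#' conservation, differential regulation, monotonic genes, classification,
#' report), writing each stage's tables under `config$out_dir` and a run
#' manifest (`manifest.json`: config, seed, package version, per-file md5
#' checksums, per-stage timing). Identical config + seed reproduces
#' bit-identical outputs.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  timing <- list()
  clock <- function(stage, expr) {
    t <- system.time(r <- force(expr))
    timing[[stage]] <<- unname(t["elapsed"])
    r
  }

  # --- cohort -----------------------------------------------------------
  if ("simulate" %in% config$stages && !is.null(config$simulate)) {
    cohort <- clock("simulate", generate_cohort(config$simulate))
    write_cohort(cohort, file.path(out, "cohort"))
    expr <- cohort$expr
    labels <- cohort$labels
    networks <- cohort$networks
    probes <- cohort$probes
  } else {
    expr <- read_expression_tsv(config$inputs$expression)
    labels <- read_labels_tsv(config$inputs$labels,
                              phenotype_levels = unique(as.character(
                                utils::read.delim(config$inputs$labels)$phenotype)))
    networks <- read_gmt(config$inputs$networks)
    probes <- if (!is.null(config$inputs$probes)) {
      read_probe_layer(config$inputs$probes)
    }
  }

  # --- preprocess -------------------------------------------------------
  if ("preprocess" %in% config$stages) {
    pp <- clock("preprocess", {
      if (!is.null(probes)) {
        kept <- filter_probes_by_present_call(probes, labels)
        gene_int <- collapse_probes_to_genes(kept)
      } else {
        kept <- NULL
        gene_int <- expr
      }
      ranks <- rank_transform(gene_int)
      list(intensity = gene_int, ranks = ranks,
           qc = list(
             n_probes_removed = if (!is.null(kept)) attr(kept, "n_removed") else NA,
             n_genes = nrow(gene_int),
             mean_correlation_intensity = mean_sample_correlation(gene_int),
             mean_correlation_rank = mean_sample_correlation(ranks)))
    })
    write_expression_tsv(pp$ranks, file.path(out, "ranks.tsv"))
    jsonlite::write_json(pp$qc, file.path(out, "preprocess_qc.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    ranks <- pp$ranks
  } else {
    ranks <- rank_transform(expr)
  }

  # --- conservation -----------------------------------------------------
  if ("conserve" %in% config$stages) {
    cons <- clock("conserve", {
      merged <- merge_gbm(labels)
      ct <- conservation_table(ranks, merged, networks)
      list(table = ct,
           global = global_dysregulation(ct),
           anova = anova_conservation(ct),
           t_tests = pairwise_t_tests(ct))
    })
    utils::write.table(
      data.frame(network = rownames(cons$table), cons$table, check.names = FALSE),
      file.path(out, "conservation.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    jsonlite::write_json(
      list(global = as.list(cons$global), anova = cons$anova,
           pairwise_t_p = as.data.frame(cons$t_tests$p)),
      file.path(out, "conservation_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  }

  # --- differential regulation ------------------------------------------
  if ("diffreg" %in% config$stages) {
    clock("diffreg", for (cmp in config$comparisons) {
      dr <- differential_regulation(
        ranks, labels, networks, cmp[1], cmp[2],
        n_perm = config$n_perm,
        seed = stage_seed(config$seed, paste0("diffreg_", cmp[1], "_", cmp[2])))
      sig <- dr[dr$p < 0.01, , drop = FALSE]
      more_in_higher <- sum(sig$delta > 0)  # higher grade is cmp[2]: delta>0 = less conserved in cmp[2]
      dr$binomial_p <- NA_real_
      if (nrow(sig) > 0) {
        dr$binomial_p[1] <- binomial_direction_test(more_in_higher, nrow(sig))
      }
      utils::write.table(dr, file.path(out, sprintf("diffreg_%s_vs_%s.tsv",
                                                    cmp[1], cmp[2])),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }

  # --- monotonic genes --------------------------------------------------
  if ("monotonic" %in% config$stages) {
    mono <- clock("monotonic", {
      report <- find_monotonic(adjacent_degs(ranks, labels, config$alpha),
                               ranks, labels)
      robust <- subsample_robustness(
        ranks, labels, n_rep = config$n_rep, frac = config$frac,
        min_support = config$min_support,
        seed = stage_seed(config$seed, "robustness"),
        alpha = config$alpha, report = report)
      dirp <- directionality_test(
        ranks, labels, n_perm = config$n_perm,
        seed = stage_seed(config$seed, "directionality"), alpha = config$alpha)
      list(robust = robust, dirp = dirp)
    })
    utils::write.table(mono$robust, file.path(out, "monotonic_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      mono$dirp[c("n_increasing", "n_decreasing", "p_increasing", "p_decreasing")],
      file.path(out, "monotonic_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  # --- classification ---------------------------------------------------
  if ("classify" %in% config$stages) {
    clock("classify", for (target in config$one_vs_rest_targets) {
      ovr <- one_vs_rest(ranks, labels, networks, target,
                         n_perm = config$n_perm,
                         seed = stage_seed(config$seed, paste0("classify_", target)),
                         top_k = config$top_k)
      utils::write.table(ovr$summary,
                         file.path(out, sprintf("classify_%s_vs_rest.tsv", target)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }

  # --- report + manifest ------------------------------------------------
  if ("report" %in% config$stages) report_run(out)

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("diracnet")),
    stages = config$stages,
    config = config[setdiff(names(config), "simulate")],
    sim_config = if (!is.null(config$simulate)) {
      config$simulate[setdiff(names(config$simulate), "gene_ids")]
    },
    checksums = as.list(tools::md5sum(files)),
    timing_sec = timing)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

#' Compose a human-readable run summary
#'
#' Reads whatever stage outputs exist under `dir` and writes `report.txt`
#' with five sections: global dysregulation, differentially regulated
#' networks, monotonic genes, classification, preprocessing QC. Missing stage
#' outputs are flagged as skipped rather than failing.
#'
#' @param dir A [run_all()] output directory.
#' @return Path of the report, invisibly.
#' @export
report_run <- function(dir) {
  lines <- c("DIRAC grade-ladder analysis report",
             strrep("=", 40), "")
  has <- function(f) file.exists(file.path(dir, f))

  lines <- c(lines, "## Preprocessing QC")
  if (has("preprocess_qc.json")) {
    qc <- jsonlite::read_json(file.path(dir, "preprocess_qc.json"))
    lines <- c(lines,
               sprintf("probes removed by present-call filter: %s", qc$n_probes_removed),
               sprintf("genes after collapse: %s", qc$n_genes),
               sprintf("mean sample-sample correlation (intensity): %.4f",
                       qc$mean_correlation_intensity),
               sprintf("mean sample-sample correlation (rank): %.4f",
                       qc$mean_correlation_rank))
  } else lines <- c(lines, "[section skipped: no preprocessing output]")
  lines <- c(lines, "")

  lines <- c(lines, "## Global network dysregulation")
  if (has("conservation_summary.json")) {
    cs <- jsonlite::read_json(file.path(dir, "conservation_summary.json"))
    lines <- c(lines,
               vapply(names(cs$global), function(p)
                 sprintf("mean conservation %-7s %.4f", p, cs$global[[p]]),
                 character(1)),
               sprintf("one-way ANOVA across phenotypes: F = %.3f, p = %.3g",
                       cs$anova$F, cs$anova$p))
  } else lines <- c(lines, "[section skipped: no conservation output]")
  lines <- c(lines, "")

  lines <- c(lines, "## Differentially regulated networks")
  dr_files <- list.files(dir, "^diffreg_.*\\.tsv$")
  if (length(dr_files)) {
    for (f in dr_files) {
      dr <- utils::read.delim(file.path(dir, f))
      sig <- dr[dr$p < 0.01, , drop = FALSE]
      lines <- c(lines, sprintf("%s: %d significant networks (p < 0.01)%s",
                                sub("^diffreg_|\\.tsv$", "", f), nrow(sig),
                                if (nrow(sig)) sprintf("; top |delta| = %.3f (%s)",
                                                       abs(dr$delta[1]), dr$network[1])
                                else ""))
    }
  } else lines <- c(lines, "[section skipped: no differential-regulation output]")
  lines <- c(lines, "")

  lines <- c(lines, "## Monotonically changing genes")
  if (has("monotonic_summary.json")) {
    ms <- jsonlite::read_json(file.path(dir, "monotonic_summary.json"))
    lines <- c(lines, sprintf("increasing: %d (directionality p = %.4g)",
                              ms$n_increasing, ms$p_increasing),
               sprintf("decreasing: %d (directionality p = %.4g)",
                       ms$n_decreasing, ms$p_decreasing))
    if (has("monotonic_genes.tsv")) {
      mg <- utils::read.delim(file.path(dir, "monotonic_genes.tsv"))
      lines <- c(lines, sprintf("high-confidence genes: %d of %d",
                                sum(mg$high_confidence), nrow(mg)))
    }
  } else lines <- c(lines, "[section skipped: no monotonic-gene output]")
  lines <- c(lines, "")

  lines <- c(lines, "## DIRAC classification (one vs rest)")
  cl_files <- list.files(dir, "^classify_.*\\.tsv$")
  if (length(cl_files)) {
    for (f in cl_files) {
      cl <- utils::read.delim(file.path(dir, f))
      cl <- cl[order(-cl$accuracy, cl$network), ]
      cv <- if ("loocv_accuracy" %in% names(cl)) {
        sprintf("mean LOOCV accuracy %.3f; ", mean(cl$loocv_accuracy))
      } else ""
      lines <- c(lines, sprintf(
        "%s: %sbest network %s (apparent %.3f, p = %.3g)",
        sub("^classify_|\\.tsv$", "", f), cv,
        cl$network[1], cl$accuracy[1], cl$p[1]))
    }
  } else lines <- c(lines, "[section skipped: no classification output]")

  writeLines(lines, file.path(dir, "report.txt"))
  invisible(file.path(dir, "report.txt"))
}
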