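#' Configuration for the synthetic multi-grade cohort generator
#'
#' Defines a cohort spanning the ordered astrocytoma phenotypes
#' Normal < G2 < G3 < {pGBM, sGBM} with known ground truth: planted
#' monotonically changing genes, planted dysregulated (network, phenotype)
#' pairs, additive batch (lab) effects, and a probe-level layer with
#' present-call masks and multi-gene probes.
#'
#' The generative model for gene `g` in sample `s` is
#' `mu_g + step(s) * delta_g * dir_g + batch(b(s), g) + N(0, sd(g, s))`
#' where `step` is the grade step (0, 1, 2, 3, 3 for Normal, G2, G3, pGBM,
#' sGBM; the two glioblastoma subtypes are parallel endpoints of the
#' progression), `dir_g` is +1/-1 for planted increasing/decreasing genes and
#' 0 otherwise, batch effects are per-gene shifts shared by all samples of a
#' batch, and `sd(g, s)` is the phenotype noise scale plus `extra_sigma` when
#' `g` belongs to a network planted as dysregulated in that sample's
#' phenotype.
#'
#' @param n_genes Number of genes in the universe (ids `g0001`, ...).
#' @param phenotypes Named integer vector of per-phenotype sample counts in
#'   grade order. Defaults mirror a multi-study astrocytoma compilation
#'   (30 normal, 31 G2, 57 G3, 174 pGBM, 44 sGBM).
#' @param n_networks,network_sizes Number of gene networks and inclusive size
#'   range; each network samples its genes without replacement from the
#'   universe. Defaults: 248 networks of 5-50 genes, the size of a curated
#'   signaling-pathway collection.
#' @param sigma_by_phenotype Named numeric vector of per-phenotype noise SDs
#'   (controls within-phenotype ordering consistency; larger = more
#'   dysregulated).
#' @param mu_range Range of the i.i.d. uniform per-gene baseline means. Wide
#'   relative to the noise so an unperturbed global ordering exists.
#' @param planted_dysreg List of `list(network =, phenotype =, extra_sigma =)`
#'   entries adding noise to one network's genes in one phenotype.
#' @param planted_increasing,planted_decreasing Gene ids planted to shift by
#'   `delta` per grade step, up or down.
#' @param delta Mean shift per grade step for planted monotonic genes.
#' @param n_batches,batch_sigma Number of batches (labs) samples are assigned
#'   to, and the SD of the per-gene additive batch shifts.
#' @param probe_sigma SD of per-probe measurement noise around the gene value.
#' @param present_prob Bernoulli probability that a probe is called present in
#'   a sample.
#' @param frac_multi_gene Fraction (of `n_genes`) of extra ambiguous probes
#'   that map to two genes each.
#' @param n_silent_probes,silent_phenotype Optionally force the first
#'   `n_silent_probes` single-gene probes to 0% present calls in
#'   `silent_phenotype`, exercising the present-call filter.
#' @param seed Integer seed; the full output is determined by it.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_genes = 1000L,
                       phenotypes = c(Normal = 30L, G2 = 31L, G3 = 57L,
                                      pGBM = 174L, sGBM = 44L),
                       n_networks = 248L,
                       network_sizes = c(5L, 50L),
                       sigma_by_phenotype = c(Normal = 0.5, G2 = 0.7, G3 = 0.9,
                                              pGBM = 1.1, sGBM = 1.1),
                       mu_range = c(0, 20),
                       planted_dysreg = list(),
                       planted_increasing = character(),
                       planted_decreasing = character(),
                       delta = 3,
                       n_batches = 3L,
                       batch_sigma = 0.5,
                       probe_sigma = 0.2,
                       present_prob = 0.95,
                       frac_multi_gene = 0.05,
                       n_silent_probes = 0L,
                       silent_phenotype = NULL,
                       seed = 1L) {
  if (n_genes < 2) stop("n_genes must be >= 2")
  if (is.null(names(phenotypes)) || any(names(phenotypes) == "")) {
    stop("phenotypes must be a named vector of sample counts")
  }
  if (any(phenotypes <= 0)) stop("all phenotype sample counts must be > 0")
  if (!all(names(phenotypes) %in% names(sigma_by_phenotype))) {
    stop("sigma_by_phenotype must name every phenotype")
  }
  if (any(sigma_by_phenotype < 0)) stop("sigma values must be >= 0")
  if (length(network_sizes) != 2 || network_sizes[1] > network_sizes[2]) {
    stop("network_sizes must be c(min, max) with min <= max")
  }
  if (network_sizes[2] > n_genes) {
    stop("maximum network size exceeds the gene universe")
  }
  if (network_sizes[1] < 2) stop("networks need at least 2 genes")
  universe <- sprintf("g%04d", seq_len(n_genes))
  planted <- c(planted_increasing, planted_decreasing)
  if (length(planted) && !all(planted %in% universe)) {
    stop("planted gene id(s) outside the gene universe: ",
         paste(setdiff(planted, universe), collapse = ", "))
  }
  if (anyDuplicated(planted)) stop("a gene cannot be planted in both directions")
  for (pd in planted_dysreg) {
    if (!all(c("network", "phenotype", "extra_sigma") %in% names(pd))) {
      stop("each planted_dysreg entry needs network, phenotype, extra_sigma")
    }
    if (!pd$phenotype %in% names(phenotypes)) {
      stop("planted_dysreg phenotype not in cohort: ", pd$phenotype)
    }
    if (pd$extra_sigma < 0) stop("extra_sigma must be >= 0")
  }
  if (delta < 0) stop("delta must be >= 0")
  if (n_batches < 1) stop("n_batches must be >= 1")
  if (batch_sigma < 0 || probe_sigma < 0) stop("sigmas must be >= 0")
  if (present_prob <= 0 || present_prob > 1) stop("present_prob must be in (0, 1]")
  if (n_silent_probes > 0 && is.null(silent_phenotype)) {
    stop("silent_phenotype required when n_silent_probes > 0")
  }
  if (!is.null(silent_phenotype) && !silent_phenotype %in% names(phenotypes)) {
    stop("silent_phenotype not in cohort")
  }
  grade_step <- stats::setNames(
    ifelse(names(phenotypes) %in% c("pGBM", "sGBM"), 3,
           match(names(phenotypes), c("Normal", "G2", "G3")) - 1),
    names(phenotypes))
  if (anyNA(grade_step)) {
    # non-standard phenotype names: steps follow list order
    grade_step <- stats::setNames(seq_along(phenotypes) - 1, names(phenotypes))
  }
  structure(list(
    n_genes = as.integer(n_genes), gene_ids = universe,
    phenotypes = phenotypes, grade_step = grade_step,
    n_networks = as.integer(n_networks),
    network_sizes = as.integer(network_sizes),
    sigma_by_phenotype = sigma_by_phenotype[names(phenotypes)],
    mu_range = mu_range,
    planted_dysreg = planted_dysreg,
    planted_increasing = planted_increasing,
    planted_decreasing = planted_decreasing,
    delta = delta,
    n_batches = as.integer(n_batches), batch_sigma = batch_sigma,
    probe_sigma = probe_sigma, present_prob = present_prob,
    frac_multi_gene = frac_multi_gene,
    n_silent_probes = as.integer(n_silent_probes),
    silent_phenotype = silent_phenotype,
    seed = as.integer(seed)), class = "sim_config")
}

# Run `expr` with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a named gene-set collection
#'
#' Samples `n_networks` gene sets from the configured universe, each of a size
#' drawn uniformly from the configured range, genes drawn without replacement
#' within a network. Deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Named list of character vectors (class `gene_set_collection`).
#' @export
generate_networks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(stage_seed(config$seed, "networks"), {
    sizes <- sample(seq(config$network_sizes[1], config$network_sizes[2]),
                    config$n_networks, replace = TRUE)
    sets <- lapply(sizes, function(k) sample(config$gene_ids, k))
    names(sets) <- sprintf("NET_%03d", seq_len(config$n_networks))
    structure(sets, class = "gene_set_collection")
  })
}

#' Generate a synthetic multi-grade cohort with ground truth
#'
#' Emits a gene-level intensity matrix, phenotype labels, a probe layer
#' (probe-to-gene multimap, probe intensities, present-call mask), and a
#' `truth` record describing everything that was planted. See [sim_config()]
#' for the generative model.
#'
#' @param config A [sim_config()].
#' @param networks Optional pre-generated [generate_networks()] collection;
#'   regenerated from the config seed when omitted (needed to resolve planted
#'   dysregulated networks).
#' @return List with elements `expr` (intensity [expression_matrix()]),
#'   `labels` ([phenotype_labels()]), `probes` (probe layer list), `truth`,
#'   and `networks`.
#' @export
generate_cohort <- function(config, networks = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(networks)) networks <- generate_networks(config)
  phen <- config$phenotypes
  n_samples <- sum(phen)
  labels <- phenotype_labels(
    rep(names(phen), phen),
    phenotype_levels = names(phen),
    sample_ids = sprintf("%s_%03d", rep(names(phen), phen),
                         unlist(lapply(phen, seq_len))))
  g <- config$gene_ids

  dir_g <- stats::setNames(numeric(config$n_genes), g)
  dir_g[config$planted_increasing] <- 1
  dir_g[config$planted_decreasing] <- -1

  # per-sample noise SD per gene: phenotype sigma, plus extra for planted pairs
  sd_mat <- matrix(rep(config$sigma_by_phenotype[as.character(labels)],
                       each = config$n_genes),
                   nrow = config$n_genes,
                   dimnames = list(g, names(labels)))
  for (pd in config$planted_dysreg) {
    if (!pd$network %in% names(networks)) {
      stop("planted_dysreg references unknown network: ", pd$network)
    }
    rows <- networks[[pd$network]]
    cols <- names(labels)[labels == pd$phenotype]
    sd_mat[rows, cols] <- sd_mat[rows, cols] + pd$extra_sigma
  }

  mu <- with_seed(stage_seed(config$seed, "baseline"), {
    v <- stats::setNames(stats::runif(config$n_genes,
                                      config$mu_range[1],
                                      config$mu_range[2]), g)
    # planted trend genes keep headroom for the full trajectory inside the
    # dynamic range, else the trend saturates at the array extremes
    span <- max(config$grade_step) * config$delta
    hi <- max(config$mu_range[2] - span, config$mu_range[1])
    lo <- min(config$mu_range[1] + span, config$mu_range[2])
    inc <- config$planted_increasing
    dec <- config$planted_decreasing
    if (length(inc)) v[inc] <- stats::runif(length(inc), config$mu_range[1], hi)
    if (length(dec)) v[dec] <- stats::runif(length(dec), lo, config$mu_range[2])
    v
  })
  batch <- with_seed(stage_seed(config$seed, "batch"), {
    assignment <- sample(seq_len(config$n_batches), n_samples, replace = TRUE)
    shifts <- matrix(stats::rnorm(config$n_genes * config$n_batches,
                                  sd = config$batch_sigma),
                     nrow = config$n_genes)
    list(assignment = stats::setNames(assignment, names(labels)),
         shifts = shifts)
  })
  step <- config$grade_step[as.character(labels)]

  values <- with_seed(stage_seed(config$seed, "noise"), {
    noise <- matrix(stats::rnorm(config$n_genes * n_samples), nrow = config$n_genes) * sd_mat
    mu + outer(dir_g * config$delta, step) +
      batch$shifts[, batch$assignment] + noise
  })
  dimnames(values) <- list(g, names(labels))
  expr <- expression_matrix(values, layer = "intensity")

  probes <- with_seed(stage_seed(config$seed, "probes"),
                      simulate_probe_layer(config, expr, labels))

  truth <- list(
    baseline_means = as.list(mu),
    planted_increasing = config$planted_increasing,
    planted_decreasing = config$planted_decreasing,
    delta = config$delta,
    planted_dysreg = config$planted_dysreg,
    batch_assignment = as.list(batch$assignment),
    seed = config$seed)

  list(expr = expr, labels = labels, probes = probes, truth = truth,
       networks = networks)
}

# Probe layer: 1-3 probes per gene plus a tail of two-gene (ambiguous) probes;
# probe intensity = mean of mapped gene values + probe noise; present calls
# Bernoulli, with optional probes silenced in one phenotype.
simulate_probe_layer <- function(config, expr, labels) {
  g <- rownames(expr)
  n_per_gene <- sample(1:3, length(g), replace = TRUE, prob = c(0.7, 0.2, 0.1))
  map <- data.frame(probe = character(0), gene = character(0))
  single <- data.frame(gene = rep(g, n_per_gene))
  n_multi <- round(config$frac_multi_gene * length(g))
  probe_ids <- sprintf("P%05d", seq_len(nrow(single) + n_multi))
  map <- data.frame(probe = probe_ids[seq_len(nrow(single))], gene = single$gene,
                    stringsAsFactors = FALSE)
  if (n_multi > 0) {
    multi_ids <- probe_ids[nrow(single) + seq_len(n_multi)]
    pairs <- t(vapply(seq_len(n_multi), function(i) sample(g, 2), character(2)))
    map <- rbind(map,
                 data.frame(probe = rep(multi_ids, each = 2),
                            gene = as.character(t(pairs)),
                            stringsAsFactors = FALSE))
  }
  intensity <- t(vapply(probe_ids, function(p) {
    gm <- map$gene[map$probe == p]
    v <- if (length(gm) == 1) expr[gm, ] else colMeans(expr[gm, , drop = FALSE])
    v + stats::rnorm(ncol(expr), sd = config$probe_sigma)
  }, numeric(ncol(expr))))
  dimnames(intensity) <- list(probe_ids, colnames(expr))
  calls <- matrix(stats::runif(length(intensity)) < config$present_prob,
                  nrow = nrow(intensity), dimnames = dimnames(intensity))
  if (config$n_silent_probes > 0) {
    single_ids <- unique(map$probe[!map$probe %in% map$probe[duplicated(map$probe)]])
    silent <- utils::head(single_ids, config$n_silent_probes)
    calls[silent, labels[colnames(calls)] == config$silent_phenotype] <- FALSE
  }
  probe_layer(map, intensity, calls)
}

#' Construct a probe layer
#'
#' @param map Data frame with columns `probe`, `gene` (one row per mapping;
#'   probes may map to more than one gene, genes may have several probes).
#' @param intensity Numeric probes-by-samples matrix.
#' @param calls Logical present-call matrix, same shape as `intensity`.
#' @return `probe_layer` list.
#' @export
probe_layer <- function(map, intensity, calls) {
  stopifnot(is.data.frame(map), all(c("probe", "gene") %in% names(map)))
  if (!all(dim(intensity) == dim(calls))) {
    stop("present-call matrix must match the intensity matrix shape")
  }
  if (!setequal(rownames(intensity), unique(map$probe))) {
    stop("every probe must appear in both the map and the intensity matrix")
  }
  structure(list(map = map[, c("probe", "gene")],
                 intensity = intensity,
                 calls = calls),
            class = "probe_layer")
}
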