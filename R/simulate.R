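#' Simulation configuration
#'
#' Describes a synthetic four-group probe-level experiment with a planted
#' ground truth: a small number of "regulator" genes expressed only in the
#' target and target-stem groups (the pattern the screen is designed to
#' isolate) and, for every other on/off pattern over the four roles, a batch
#' of confounder genes — so each elimination path of the screen is
#' exercised. All remaining genes are background (off everywhere).
#'
#' Intensity model per probe pair and sample:
#' `PM = B + s * a * e` and `MM = B' + mm_leak * s * a * e'`, where `B`, `B'`
#' are independent `N(background_mean, background_sd^2)` background draws,
#' `s` is the gene's true signal (`signal_scale` when off,
#' `signal_scale * 2^effect_log2` when on), `a` a per-probe affinity drawn
#' once (log-normal, median 1, `affinity_sdlog`) and shared across samples,
#' and `e`, `e'` independent multiplicative log-normal noise draws with
#' coefficient of variation `noise_cv`.
#'
#' @param n_genes total number of genes.
#' @param probesets_per_gene_probs probability of a gene owning 1, 2, ...
#'   probe sets (default `c(0.9, 0.1)`: 1 with probability 0.9, 2 with 0.1),
#'   emulating genes represented by more than one probe set.
#' @param pairs_per_probeset probe pairs per probe set (default 11, the
#'   typical size on the emulated array type).
#' @param replicates_per_group biological replicates per group (default 3).
#' @param n_regulators planted true-positive regulator genes (default 3).
#' @param n_confounders_per_pattern decoy genes for each of the 15
#'   non-target on/off patterns (default 20).
#' @param effect_log2 log2 expression elevation of "on" genes (default 4).
#' @param background_mean,background_sd normal background parameters in
#'   intensity units.
#' @param signal_scale true signal of an "off" gene, intensity units.
#' @param mm_leak fraction of the true signal leaking into MM probes
#'   (in \[0, 1)).
#' @param noise_cv coefficient of variation of the multiplicative
#'   log-normal noise.
#' @param affinity_sdlog sdlog of the per-probe affinity distribution.
#' @param tf_decoy_fraction fraction of confounder genes tagged as
#'   transcription factors alongside the planted regulators.
#' @param seed integer RNG seed; the full artifact set is deterministic
#'   given the seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       probesets_per_gene_probs = c(0.9, 0.1),
                       pairs_per_probeset = 11L,
                       replicates_per_group = 3L,
                       n_regulators = 3L,
                       n_confounders_per_pattern = 20L,
                       effect_log2 = 4.0,
                       background_mean = 1000,
                       background_sd = 10,
                       signal_scale = 10,
                       mm_leak = 0.05,
                       noise_cv = 0.1,
                       affinity_sdlog = 0.3,
                       tf_decoy_fraction = 0.5,
                       seed = 1L) {
  cfg <- structure(
    list(n_genes = as.integer(n_genes),
         probesets_per_gene_probs = probesets_per_gene_probs,
         pairs_per_probeset = as.integer(pairs_per_probeset),
         replicates_per_group = as.integer(replicates_per_group),
         n_regulators = as.integer(n_regulators),
         n_confounders_per_pattern = as.integer(n_confounders_per_pattern),
         effect_log2 = effect_log2,
         background_mean = background_mean,
         background_sd = background_sd,
         signal_scale = signal_scale,
         mm_leak = mm_leak,
         noise_cv = noise_cv,
         affinity_sdlog = affinity_sdlog,
         tf_decoy_fraction = tf_decoy_fraction,
         seed = as.integer(seed)),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  problems <- character()
  n_patterns <- 15L  # all 2^4 on/off patterns except (off, off, on, on)
  need <- cfg$n_regulators + n_patterns * cfg$n_confounders_per_pattern
  if (need > cfg$n_genes) {
    problems <- c(problems, sprintf(
      "n_genes = %d cannot hold %d regulators + %d confounders",
      cfg$n_genes, cfg$n_regulators, n_patterns * cfg$n_confounders_per_pattern))
  }
  if (cfg$pairs_per_probeset < 1L) problems <- c(problems, "pairs_per_probeset must be >= 1")
  if (cfg$replicates_per_group < 1L) problems <- c(problems, "replicates_per_group must be >= 1")
  if (cfg$n_regulators < 0L) problems <- c(problems, "n_regulators must be >= 0")
  if (!(cfg$background_mean > 0)) problems <- c(problems, "background_mean must be > 0")
  if (cfg$background_sd < 0) problems <- c(problems, "background_sd must be >= 0")
  if (!(cfg$signal_scale > 0)) problems <- c(problems, "signal_scale must be > 0")
  if (cfg$mm_leak < 0 || cfg$mm_leak >= 1) problems <- c(problems, "mm_leak must lie in [0, 1)")
  if (cfg$noise_cv < 0) problems <- c(problems, "noise_cv must be >= 0")
  if (any(cfg$probesets_per_gene_probs < 0) ||
      abs(sum(cfg$probesets_per_gene_probs) - 1) > 1e-8) {
    problems <- c(problems, "probesets_per_gene_probs must be a probability vector")
  }
  if (cfg$tf_decoy_fraction < 0 || cfg$tf_decoy_fraction > 1) {
    problems <- c(problems, "tf_decoy_fraction must lie in [0, 1]")
  }
  if (length(problems) > 0L) {
    stop("invalid sim_config:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  cfg
}

# The 15 non-target on/off patterns over (source, source_origin, target,
# target_stem), as a logical matrix; the target pattern (F, F, T, T) is
# reserved for planted regulators.
confounder_patterns <- function() {
  g <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 4L)))
  colnames(g) <- screen_roles()
  target <- c(FALSE, FALSE, TRUE, TRUE)
  g[!apply(g, 1L, function(r) all(r == target)), , drop = FALSE]
}

#' Simulate a probe-level dataset with planted regulators
#'
#' Generates the full artifact set the pipeline consumes: a
#' [probe_dataset()], the matching [group_design()] (group labels equal the
#' role names), a probe-set to gene map, a transcription-factor
#' [annotation_set()] containing all planted regulators plus
#' `tf_decoy_fraction` of the confounder genes, and the simulation truth.
#'
#' Random draws occur in a fixed, documented order so the stream is
#' reproducible across releases: (1) probe sets per gene; (2) the sample of
#' confounder genes tagged as TF; (3) per-probe affinities in probe order;
#' (4) for each sample in order: PM background, MM background, PM noise, MM
#' noise. The caller's RNG state is restored on exit.
#'
#' @param config a [sim_config()].
#' @return List with elements `dataset`, `design`, `gene_map`, `tf_set` and
#'   `truth`. `truth` is a `sim_truth` object: list with `regulators` (gene
#'   symbols with the target pattern) and `pattern_of` (logical gene x role
#'   matrix).
#' @export
simulate_dataset <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n_genes <- config$n_genes
  genes <- sprintf("g%05d", seq_len(n_genes))
  pat <- confounder_patterns()
  pattern_of <- matrix(FALSE, nrow = n_genes, ncol = 4L,
                       dimnames = list(genes, screen_roles()))
  reg_idx <- seq_len(config$n_regulators)
  pattern_of[reg_idx, c("target", "target_stem")] <- TRUE
  conf_idx <- integer()
  if (config$n_confounders_per_pattern > 0L) {
    conf_idx <- config$n_regulators +
      seq_len(nrow(pat) * config$n_confounders_per_pattern)
    pattern_of[conf_idx, ] <-
      pat[rep(seq_len(nrow(pat)), each = config$n_confounders_per_pattern), ]
  }
  # remaining genes are background: off in all four roles (already FALSE)

  # (1) probe sets per gene
  n_ps_per_gene <- sample.int(length(config$probesets_per_gene_probs),
                              n_genes, replace = TRUE,
                              prob = config$probesets_per_gene_probs)
  # (2) TF decoys
  n_tf_decoys <- round(config$tf_decoy_fraction * length(conf_idx))
  tf_decoys <- if (n_tf_decoys > 0L) sort(sample(conf_idx, n_tf_decoys)) else integer()
  tf_set <- annotation_set(genes[c(reg_idx, tf_decoys)], class_id = "synthetic-TF")

  ps_gene_idx <- rep(seq_len(n_genes), n_ps_per_gene)
  ps_within <- unlist(lapply(n_ps_per_gene, seq_len), use.names = FALSE)
  probesets <- sprintf("%s_ps%d_at", genes[ps_gene_idx], ps_within)
  n_ps <- length(probesets)
  n_pairs <- n_ps * config$pairs_per_probeset
  pair_gene <- rep(ps_gene_idx, each = config$pairs_per_probeset)

  # (3) per-probe affinities, shared across samples
  affinity <- stats::rlnorm(n_pairs, meanlog = 0, sdlog = config$affinity_sdlog)

  roles <- screen_roles()
  reps <- config$replicates_per_group
  samples <- paste(rep(roles, each = reps), rep(seq_len(reps), 4L), sep = "_")
  sample_role <- rep(roles, each = reps)

  s_on <- config$signal_scale * 2^config$effect_log2
  s_off <- config$signal_scale
  sdlog_noise <- if (config$noise_cv > 0) sqrt(log(1 + config$noise_cv^2)) else 0
  # median-1 log-normal noise keeps log2 effects centered on effect_log2
  rnoise <- function(n) {
    if (sdlog_noise == 0) rep(1, n) else stats::rlnorm(n, 0, sdlog_noise)
  }

  pm <- matrix(NA_real_, nrow = n_pairs, ncol = length(samples),
               dimnames = list(NULL, samples))
  mm <- pm
  for (j in seq_along(samples)) {
    on <- pattern_of[pair_gene, sample_role[j]]
    sig <- ifelse(on, s_on, s_off) * affinity
    # (4) per-sample draw order: PM background, MM background, PM noise, MM noise
    bg_pm <- stats::rnorm(n_pairs, config$background_mean, config$background_sd)
    bg_mm <- stats::rnorm(n_pairs, config$background_mean, config$background_sd)
    pm[, j] <- pmax(bg_pm + sig * rnoise(n_pairs), 1e-6)
    mm[, j] <- pmax(bg_mm + config$mm_leak * sig * rnoise(n_pairs), 1e-6)
  }

  dataset <- probe_dataset(
    probeset_id = rep(probesets, each = config$pairs_per_probeset),
    pair_index = rep(seq_len(config$pairs_per_probeset) - 1L, n_ps),
    pm = pm, mm = mm
  )
  design <- group_design(
    assignments = stats::setNames(rep(roles, each = reps), samples),
    roles = stats::setNames(roles, roles)
  )
  gene_map <- stats::setNames(genes[ps_gene_idx], probesets)
  truth <- structure(
    list(regulators = genes[reg_idx], pattern_of = pattern_of,
         tf_genes = tf_set$genes),
    class = "sim_truth"
  )
  list(dataset = dataset, design = design, gene_map = gene_map,
       tf_set = tf_set, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Simulation truth:", length(x$regulators), "planted regulators (",
      paste(x$regulators, collapse = ", "), ")\n")
  invisible(x)
}

#' The gene set an ideal screen must output
#'
#' Genes whose on/off pattern over the roles is exactly (off, off, on, on)
#' — off in source and source-origin, on in target and target-stem —
#' intersected with the transcription-factor set. A noise-free screen with
#' default thresholds returns exactly this set.
#'
#' @param truth a `sim_truth` from [simulate_dataset()].
#' @param tf an [annotation_set()].
#' @return Sorted character vector of gene symbols.
#' @export
expected_screen_truth <- function(truth, tf) {
  stopifnot(inherits(truth, "sim_truth"))
  p <- truth$pattern_of
  match_pattern <- !p[, "source"] & !p[, "source_origin"] &
    p[, "target"] & p[, "target_stem"]
  sort(intersect(rownames(p)[match_pattern], tf$genes))
}

#' Write the full synthetic artifact set to a directory
#'
#' Emits the probe table, design file, gene map, TF list and a truth JSON
#' in the package's text dialects.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    probe_table = file.path(dir, "probe_table.tsv"),
    design = file.path(dir, "design.txt"),
    gene_map = file.path(dir, "gene_map.tsv"),
    tf_list = file.path(dir, "tf_list.txt"),
    truth = file.path(dir, "truth.json")
  )
  write_probe_table(sim$dataset, paths[["probe_table"]])
  write_design(sim$design, paths[["design"]])
  write_gene_map(sim$gene_map, paths[["gene_map"]])
  write_gene_list(sim$tf_set, paths[["tf_list"]])
  jsonlite::write_json(
    list(regulators = sim$truth$regulators,
         pattern_of = as.data.frame(sim$truth$pattern_of)),
    paths[["truth"]], auto_unbox = TRUE, pretty = TRUE
  )
  invisible(paths)
}
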