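test_that("simulation is deterministic given the seed", {
  cfg <- small_sim_config(seed = 99)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$dataset$pm, s2$dataset$pm)
  expect_identical(s1$dataset$mm, s2$dataset$mm)
  expect_identical(s1$gene_map, s2$gene_map)
  expect_identical(s1$tf_set$genes, s2$tf_set$genes)
  s3 <- simulate_dataset(small_sim_config(seed = 100))
  expect_false(identical(s1$dataset$pm, s3$dataset$pm))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(1)
  a <- runif(1)
  set.seed(1)
  invisible(simulate_dataset(small_sim_config(seed = 7)))
  expect_identical(runif(1), a)
})

test_that("dataset dimensions follow the configuration exactly", {
  cfg <- small_sim_config(seed = 2)
  sim <- simulate_dataset(cfg)
  ds <- sim$dataset
  expect_length(ds$samples, 4L * cfg$replicates_per_group)
  sizes <- probeset_sizes(ds)
  expect_true(all(sizes == cfg$pairs_per_probeset))
  # each gene owns 1 or 2 probe sets; totals line up with the gene map
  expect_identical(length(ds$probesets), length(sim$gene_map))
  expect_identical(sort(unique(unname(sim$gene_map))),
                   sprintf("g%05d", seq_len(cfg$n_genes)))
  expect_length(ds$probeset_id,
                length(ds$probesets) * cfg$pairs_per_probeset)
})

test_that("the planted truth has the advertised structure", {
  sim <- simulate_dataset(small_sim_config(seed = 3))
  pat <- sim$truth$pattern_of
  reg <- sim$truth$regulators
  expect_length(reg, 3L)
  expect_true(all(!pat[reg, "source"] & !pat[reg, "source_origin"] &
                    pat[reg, "target"] & pat[reg, "target_stem"]))
  # regulators are the ONLY genes with the target pattern
  has_target_pattern <- !pat[, "source"] & !pat[, "source_origin"] &
    pat[, "target"] & pat[, "target_stem"]
  expect_setequal(rownames(pat)[has_target_pattern], reg)
  # every other on/off pattern is represented among the confounders
  other <- unique(apply(pat[!has_target_pattern, ], 1, paste, collapse = ""))
  expect_length(other, 15L)
  # all regulators are in the TF list, plus some decoys
  expect_true(all(reg %in% sim$tf_set$genes))
  expect_gt(length(sim$tf_set$genes), length(reg))
})

test_that("invalid configurations list their violations", {
  expect_error(sim_config(n_genes = 10), "cannot hold")
  expect_error(sim_config(mm_leak = 1), "mm_leak")
  expect_error(sim_config(signal_scale = 0), "signal_scale")
})

test_that("the noiseless limit recovers exactly the planted regulators", {
  cfg <- small_sim_config(seed = 4, noise_cv = 0, mm_leak = 0,
                          background_sd = 0)
  sim <- simulate_dataset(cfg)
  calls <- mas5_calls(sim$dataset)
  expr <- rma(sim$dataset)
  res <- run_screen(expr, calls, sim$design, screen_config(),
                    sim$gene_map, sim$tf_set)
  expect_identical(res$tf_genes,
                   expected_screen_truth(sim$truth, sim$tf_set))
})

test_that("expected_screen_truth filters patterns and TF membership", {
  truth <- structure(
    list(regulators = c("gA"),
         pattern_of = matrix(
           c(FALSE, FALSE, TRUE, TRUE,   # gA: the target pattern
             FALSE, FALSE, TRUE, TRUE,   # gB: target pattern but not a TF
             TRUE, TRUE, TRUE, TRUE),    # gC: on everywhere
           nrow = 3, byrow = TRUE,
           dimnames = list(c("gA", "gB", "gC"), screen_roles()))),
    class = "sim_truth")
  tf <- annotation_set(c("gA", "gC"))
  expect_identical(expected_screen_truth(truth, tf), "gA")
  # with no decoys sharing the pattern, the truth equals the regulators
  sim <- simulate_dataset(small_sim_config(seed = 6))
  expect_identical(expected_screen_truth(sim$truth, sim$tf_set),
                   sort(sim$truth$regulators))
})

test_that("on/off cells get reliable P/A calls at default separation", {
  sim <- simulate_dataset(small_sim_config(seed = 8))
  calls <- mas5_calls(sim$dataset)
  role_of <- sim$design$assignments
  ps_gene <- sim$gene_map[rownames(calls$calls)]
  on <- sim$truth$pattern_of[ps_gene, ][, role_of[colnames(calls$calls)]]
  expect_gte(mean(calls$calls[on] == "P"), 0.99)
  expect_gte(mean(calls$calls[!on] == "A"), 0.99)
})

test_that("planted effects survive RMA within a +-1 log2 envelope", {
  sim <- simulate_dataset(small_sim_config(seed = 9))
  expr <- rma(sim$dataset)
  pat <- sim$truth$pattern_of
  ps_gene <- sim$gene_map[rownames(expr)]
  d <- group_mean(expr, sim$design, "target") -
    group_mean(expr, sim$design, "source")
  sel <- pat[ps_gene, "target"] & !pat[ps_gene, "source"]
  expect_gte(mean(abs(d[sel] - 4) <= 1), 0.9)
})

test_that("simulation artifacts round trip through the text formats", {
  sim <- simulate_dataset(small_sim_config(seed = 10))
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  expect_true(all(file.exists(paths)))
  ds <- read_probe_table(paths[["probe_table"]])
  expect_equal(ds$pm, sim$dataset$pm)
  expect_identical(read_design(paths[["design"]])$assignments,
                   sim$design$assignments)
  expect_identical(read_gene_map(paths[["gene_map"]]), sim$gene_map)
  expect_identical(suppressMessages(read_gene_list(paths[["tf_list"]]))$genes,
                   sim$tf_set$genes)
})
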