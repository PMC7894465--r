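test_that("group means average replicates and ignore sample order", {
  fx <- toy_screen_fixture()
  expr <- fx$expr
  expr["p01", c("target_1", "target_2")] <- c(4, 6)
  expect_equal(group_mean(expr, fx$design, "target")[["p01"]], 5)
  perm <- expr[, rev(colnames(expr))]
  expect_equal(group_mean(perm, fx$design, "target"),
               group_mean(expr, fx$design, "target"))
  expect_error(group_mean(expr, fx$design, "nope"), "unknown or empty group")
})

test_that("up_set applies the threshold with the configured strictness", {
  fx <- toy_screen_fixture()
  expr <- matrix(2, nrow = 2, ncol = ncol(fx$expr),
                 dimnames = list(c("ps1", "ps2"), colnames(fx$expr)))
  tgt <- names(fx$design$assignments)[fx$design$assignments == "target"]
  expr["ps1", tgt] <- 5.0   # diff 3.0
  expr["ps2", tgt] <- 3.5   # diff 1.5
  expect_identical(up_set(expr, fx$design, "target", "source", 2), "ps1")
  # equal means everywhere -> empty
  expect_length(up_set(matrix(2, 2, ncol(fx$expr),
                              dimnames = dimnames(expr)),
                       fx$design, "target", "source", 2), 0L)
  # boundary: strict excludes an exact-threshold difference, >= keeps it
  expr["ps2", tgt] <- 4.0   # diff exactly 2
  expect_identical(up_set(expr, fx$design, "target", "source", 2), "ps1")
  expect_setequal(up_set(expr, fx$design, "target", "source", 2,
                         strict = FALSE), c("ps1", "ps2"))
  expect_error(up_set(expr, fx$design, "hepatocyte", "source", 2),
               "unresolved role")
})

test_that("call aggregation distinguishes all from majority and handles M", {
  design <- group_design(
    c(a = "G", b = "G", c = "G", d = "H", e = "I", f = "J"),
    c(source = "G", source_origin = "H", target = "I", target_stem = "J"))
  cm <- matrix(c("P", "P", "M",
                 "A", "A", "A",
                 "P", "A", "A"), nrow = 3, byrow = TRUE,
               dimnames = list(c("ps1", "ps2", "ps3"), c("a", "b", "c")))
  expect_identical(aggregate_calls(cm, design, "G", "P", "all"), character(0))
  expect_identical(aggregate_calls(cm, design, "G", "P", "majority"), "ps1")
  expect_identical(aggregate_calls(cm, design, "G", "A", "all"), "ps2")
  expect_setequal(aggregate_calls(cm, design, "G", "A", "majority"),
                  c("ps2", "ps3"))
  # marginal counted as present only when asked
  expect_identical(aggregate_calls(cm, design, "G", "P", "all",
                                   include_marginal = TRUE), "ps1")
  expect_error(aggregate_calls(cm, design, "G", "P", "sometimes"),
               "unknown aggregation mode")
})

test_that("single-replicate groups reduce aggregation to the plain call", {
  design <- group_design(
    c(x = "G", y = "H", z = "I", w = "J"),
    c(source = "G", source_origin = "H", target = "I", target_stem = "J"))
  cm <- matrix(c("P", "A", "P", "M"), nrow = 2, ncol = 4, byrow = TRUE,
               dimnames = list(c("ps1", "ps2"), c("x", "y", "z", "w")))
  expect_identical(aggregate_calls(cm, design, "G", "P", "all"),
                   rownames(cm)[cm[, "x"] == "P"])
  expect_identical(aggregate_calls(cm, design, "G", "P", "majority"),
                   rownames(cm)[cm[, "x"] == "P"])
})

test_that("the enumerable fixture matches the from-definition oracle", {
  fx <- toy_screen_fixture()
  for (mode in c("all", "majority")) {
    cfg <- screen_config(call_aggregation = mode)
    res <- run_screen(fx$expr, fx$calls, fx$design, cfg, fx$gene_map, fx$tf_set)
    orc <- oracle_screen(fx$expr, fx$calls, fx$design, cfg, fx$gene_map,
                         fx$tf_set$genes)
    expect_identical(res$up_sets, orc$up_sets, info = mode)
    expect_identical(res$fold_intersection, orc$fold_intersection)
    expect_identical(res$present_sets, orc$present_sets)
    expect_identical(res$absent_sets, orc$absent_sets)
    expect_identical(res$call_intersection, orc$call_intersection)
    expect_identical(res$combined, orc$combined)
    expect_identical(res$tf_genes, orc$tf_genes)
  }
})

test_that("two probe sets of one gene collapse to a single candidate", {
  fx <- toy_screen_fixture()
  res <- run_screen(fx$expr, fx$calls, fx$design, screen_config(),
                    fx$gene_map, fx$tf_set)
  expect_setequal(res$combined, fx$regulator_ps)  # both probe sets pass
  expect_identical(res$tf_genes, "geneA")         # one gene in the output
})

test_that("an empty TF set empties only the final stage", {
  fx <- toy_screen_fixture()
  full <- run_screen(fx$expr, fx$calls, fx$design, screen_config(),
                     fx$gene_map, fx$tf_set)
  none <- run_screen(fx$expr, fx$calls, fx$design, screen_config(),
                     fx$gene_map, annotation_set(character()))
  expect_identical(none$tf_genes, character(0))
  expect_identical(none$combined, full$combined)
  expect_identical(none$up_sets, full$up_sets)
  expect_identical(none$call_intersection, full$call_intersection)
})

test_that("unannotated probe sets are dropped only at the gene stage", {
  fx <- toy_screen_fixture()
  gm <- fx$gene_map
  gm[fx$regulator_ps[2]] <- NA    # second regulator probe set unannotated
  res <- run_screen(fx$expr, fx$calls, fx$design, screen_config(),
                    gm, fx$tf_set)
  expect_setequal(res$combined, fx$regulator_ps)  # probe-set stages unchanged
  expect_identical(res$n_unannotated_dropped, 1L)
  expect_identical(res$tf_genes, "geneA")         # still found via probe set 1
})

test_that("raising the fold threshold never enlarges any stage", {
  sim <- simulate_dataset(small_sim_config(seed = 51))
  run <- run_pipeline(sim$dataset, sim$design, sim$gene_map, sim$tf_set)
  prev <- NULL
  for (thr in c(1, 2, 3, 4)) {
    res <- run_screen(run$expr, run$calls, sim$design,
                      screen_config(fold_threshold = thr),
                      sim$gene_map, sim$tf_set)
    if (!is.null(prev)) {
      for (nm in names(res$up_sets)) {
        expect_true(all(res$up_sets[[nm]] %in% prev$up_sets[[nm]]))
      }
      expect_true(all(res$fold_intersection %in% prev$fold_intersection))
      expect_true(all(res$combined %in% prev$combined))
      expect_true(all(res$tf_genes %in% prev$tf_genes))
    }
    expect_true(all(res$combined %in% res$fold_intersection))
    expect_true(all(res$combined %in% res$call_intersection))
    prev <- res
  }
})

test_that("switching majority to all never enlarges the call intersection", {
  sim <- simulate_dataset(small_sim_config(seed = 52))
  calls <- mas5_calls(sim$dataset)
  expr <- rma(sim$dataset)
  res_all <- run_screen(expr, calls, sim$design,
                        screen_config(call_aggregation = "all"),
                        sim$gene_map, sim$tf_set)
  res_maj <- run_screen(expr, calls, sim$design,
                        screen_config(call_aggregation = "majority"),
                        sim$gene_map, sim$tf_set)
  expect_true(all(res_all$call_intersection %in% res_maj$call_intersection))
})

test_that("screen output is invariant to probe-set and sample order", {
  fx <- toy_screen_fixture()
  res <- run_screen(fx$expr, fx$calls, fx$design, screen_config(),
                    fx$gene_map, fx$tf_set)
  set.seed(53)
  rp <- sample(nrow(fx$expr))
  cp <- sample(ncol(fx$expr))
  res2 <- run_screen(fx$expr[rp, cp], fx$calls[rp, cp], fx$design,
                     screen_config(), fx$gene_map, fx$tf_set)
  expect_identical(res2$up_sets, res$up_sets)
  expect_identical(res2$combined, res$combined)
  expect_identical(res2$tf_genes, res$tf_genes)
})

test_that("mismatched probe-set universes are rejected", {
  fx <- toy_screen_fixture()
  expect_error(run_screen(fx$expr[-1, ], fx$calls, fx$design,
                          screen_config(), fx$gene_map, fx$tf_set),
               "probe-set universe")
})

test_that("stage counts table mirrors the result sets", {
  fx <- toy_screen_fixture()
  res <- run_screen(fx$expr, fx$calls, fx$design, screen_config(),
                    fx$gene_map, fx$tf_set)
  counts <- stage_counts(res)
  expect_identical(nrow(counts), 11L)
  expect_identical(counts$count[counts$stage == "combined"],
                   length(res$combined))
  expect_identical(counts$count[counts$stage == "fold_intersection"],
                   length(res$fold_intersection))
})
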