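# Fixtures built in code at test time.

# Minimal hand-sized probe dataset: 2 probe sets x 3 pairs x 2 samples.
toy_probe_dataset <- function() {
  pm <- matrix(c(100, 200, 300, 400, 500, 600,
                 110, 210, 310, 410, 510, 610),
               ncol = 2, dimnames = list(NULL, c("s1", "s2")))
  mm <- matrix(c(50, 60, 70, 80, 90, 95,
                 55, 65, 75, 85, 95, 99),
               ncol = 2, dimnames = list(NULL, c("s1", "s2")))
  probe_dataset(
    probeset_id = rep(c("ps1", "ps2"), each = 3),
    pair_index = rep(0:2, 2),
    pm = pm, mm = mm
  )
}

toy_design <- function(reps = 2L) {
  roles <- screen_roles()
  samples <- paste(rep(roles, each = reps), seq_len(reps), sep = "_")
  group_design(
    assignments = stats::setNames(rep(roles, each = reps), samples),
    roles = stats::setNames(roles, roles)
  )
}

# Enumerable screen fixture: one probe set per 2^4 on/off pattern (plus one
# extra probe set sharing geneA with the regulator pattern, to exercise
# multi-probe-set gene collapsing), expression and calls constructed
# directly so every Venn region is represented and the truth is countable
# by hand.
toy_screen_fixture <- function(reps = 2L, on_expr = 10, off_expr = 2) {
  design <- toy_design(reps)
  patterns <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 4)))
  colnames(patterns) <- screen_roles()
  ps <- sprintf("p%02d", seq_len(nrow(patterns)))
  # extra probe set with the regulator pattern (FALSE, FALSE, TRUE, TRUE)
  reg_row <- which(apply(patterns, 1, function(r)
    identical(unname(r), c(FALSE, FALSE, TRUE, TRUE))))
  patterns <- rbind(patterns, patterns[reg_row, ])
  ps <- c(ps, "p17")
  samples <- names(design$assignments)
  role_of <- design$assignments  # group label == role name here
  expr <- sapply(samples, function(s) {
    ifelse(patterns[, role_of[[s]]], on_expr, off_expr)
  })
  rownames(expr) <- ps
  calls <- sapply(samples, function(s) {
    ifelse(patterns[, role_of[[s]]], "P", "A")
  })
  rownames(calls) <- ps
  gene_map <- stats::setNames(sprintf("gene%02d", seq_len(nrow(patterns))), ps)
  gene_map[c(ps[reg_row], "p17")] <- "geneA"   # collapse two probe sets
  tf_set <- annotation_set(c("geneA", "gene01"))
  list(design = design, expr = expr, calls = calls, patterns = patterns,
       gene_map = gene_map, tf_set = tf_set, regulator_ps = c(ps[reg_row], "p17"))
}

# Small-but-realistic simulation settings for fast end-to-end tests.
small_sim_config <- function(seed = 1L, ...) {
  sim_config(n_genes = 350L, n_confounders_per_pattern = 2L, seed = seed, ...)
}
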