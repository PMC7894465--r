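# Independent oracles for the core algorithms. Deliberately naive and slow:
# each re-derives its result straight from the definition, sharing no code
# with the implementation under test.

# One-sided signed-rank p-value by literal enumeration of all 2^n sign
# assignments of the nonzero differences.
oracle_signrank_p <- function(scores, tau) {
  d <- scores - tau
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  hits <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    if (sum(r[signs]) >= w_obs) hits <- hits + 1L
  }
  hits / 2^n
}

# Iterative median-sweep fit of the additive two-way model, rows first,
# run to tight convergence; returns overall + column effects.
oracle_medpolish_summary <- function(x, eps = 1e-13, maxiter = 3000L) {
  x <- as.matrix(x)
  t <- 0
  r <- numeric(nrow(x))
  c <- numeric(ncol(x))
  z <- x
  for (iter in seq_len(maxiter)) {
    change <- 0
    rd <- apply(z, 1L, stats::median)
    z <- z - rd
    r <- r + rd
    change <- max(change, max(abs(rd)))
    dc <- stats::median(c)
    c <- c - dc
    t <- t + dc
    cd <- apply(z, 2L, stats::median)
    z <- z - rep(cd, each = nrow(z))
    c <- c + cd
    change <- max(change, max(abs(cd)))
    dr <- stats::median(r)
    r <- r - dr
    t <- t + dr
    if (change < eps) break
  }
  t + c
}

# E[signal | observed = x] under the normal+exponential convolution, by
# direct numerical integration of the posterior over the signal. The
# posterior is a truncated normal centered near x - mu, so the integration
# window brackets that spike explicitly.
oracle_normexp_conditional_mean <- function(x, mu, sigma, alpha) {
  joint <- function(s) {
    stats::dexp(s, rate = 1 / alpha) * stats::dnorm(x - s, mean = mu, sd = sigma)
  }
  lo <- max(0, x - mu - 15 * sigma)
  hi <- max(x - mu, 0) + 15 * sigma
  num <- stats::integrate(function(s) s * joint(s), lo, hi,
                          rel.tol = 1e-10)$value
  den <- stats::integrate(joint, lo, hi, rel.tol = 1e-10)$value
  num / den
}

# Every screen stage recomputed directly from the definitions with plain
# loops over probe sets and samples.
oracle_screen <- function(expr, call_matrix, design, config, gene_map, tf_genes) {
  ps <- rownames(expr)
  gmean <- function(role) {
    s <- names(design$assignments)[design$assignments == design$roles[[role]]]
    sapply(ps, function(p) mean(expr[p, s]))
  }
  cmp <- if (config$strict) `>` else `>=`
  upset <- function(hi, lo) {
    d <- gmean(hi) - gmean(lo)
    ps[cmp(d, config$fold_threshold)]
  }
  ups <- list(
    target_vs_source_origin = upset("target", "source_origin"),
    target_stem_vs_source_origin = upset("target_stem", "source_origin"),
    target_vs_source = upset("target", "source"),
    target_stem_vs_source = upset("target_stem", "source")
  )
  fold_int <- ps
  for (u in ups) fold_int <- fold_int[fold_int %in% u]
  agg <- function(role, wanted, include_marginal) {
    s <- names(design$assignments)[design$assignments == design$roles[[role]]]
    accept <- if (include_marginal) c(wanted, "M") else wanted
    keep <- sapply(ps, function(p) {
      k <- sum(call_matrix[p, s] %in% accept)
      if (config$call_aggregation == "all") k == length(s) else k > length(s) / 2
    })
    ps[keep]
  }
  present <- list(target = agg("target", "P", config$include_marginal_as_present),
                  target_stem = agg("target_stem", "P", config$include_marginal_as_present))
  absent <- list(source = agg("source", "A", config$include_marginal_as_absent),
                 source_origin = agg("source_origin", "A", config$include_marginal_as_absent))
  call_int <- ps
  for (u in c(present, absent)) call_int <- call_int[call_int %in% u]
  combined <- fold_int[fold_int %in% call_int]
  sym <- unname(gene_map[combined])
  genes <- sort(unique(sym[!is.na(sym)]))
  list(up_sets = lapply(ups, sort),
       fold_intersection = sort(fold_int),
       present_sets = lapply(present, sort),
       absent_sets = lapply(absent, sort),
       call_intersection = sort(call_int),
       combined = sort(combined),
       tf_genes = sort(genes[genes %in% tf_genes]))
}
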