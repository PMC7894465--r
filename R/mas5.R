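#' Detection-call parameters
#'
#' Parameters of the MAS5-style Present/Marginal/Absent detection call. The
#' defaults (`tau = 0.015`, `alpha1 = 0.04`, `alpha2 = 0.06`) are the
#' Affymetrix Statistical Algorithms defaults used by the classic
#' `mas5calls` routine. A probe set is called `P` when the detection p-value
#' is strictly below `alpha1`, `A` when strictly above `alpha2`, and `M`
#' otherwise.
#'
#' @param tau discrimination-score threshold (dimensionless, >= 0).
#' @param alpha1 Present p-value cutoff (0 < alpha1 < alpha2).
#' @param alpha2 Absent p-value cutoff (alpha1 < alpha2 < 1).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(tau = 0.015, alpha1 = 0.04, alpha2 = 0.06) {
  if (!(tau >= 0)) stop("tau must be >= 0", call. = FALSE)
  if (!(alpha1 > 0 && alpha1 < alpha2 && alpha2 < 1)) {
    stop("need 0 < alpha1 < alpha2 < 1", call. = FALSE)
  }
  structure(list(tau = tau, alpha1 = alpha1, alpha2 = alpha2),
            class = "detection_params")
}

#' Probe-pair discrimination scores
#'
#' `(PM - MM) / (PM + MM)` per probe pair; each score lies in (-1, 1) for
#' positive intensities. The scores are the test statistics underlying the
#' detection call.
#'
#' @param pm,mm equal-length numeric vectors of positive intensities.
#' @return Numeric vector of scores.
#' @export
discrimination_scores <- function(pm, mm) {
  if (length(pm) != length(mm)) {
    stop("pm and mm must have equal length", call. = FALSE)
  }
  if (any(pm <= 0) || any(mm <= 0)) {
    stop("intensities must be positive", call. = FALSE)
  }
  (pm - mm) / (pm + mm)
}

#' One-sided Wilcoxon signed-rank p-value for detection
#'
#' Tests H1: median(score) > tau. Scores equal to `tau` are discarded
#' (zero-removal convention); if all are discarded the p-value is 1. Tied
#' absolute differences receive average ranks. For `n <= exact_limit`
#' remaining scores the tail probability `P(W >= w_obs)` is exact over all
#' `2^n` sign assignments (computed by a dynamic program over the rank-sum
#' distribution, which enumerates the same space); above that a normal
#' approximation with tie correction and 0.5 continuity correction is used.
#' With the default 11 probe pairs per probe set, calls are always exact.
#'
#' @param scores numeric vector of discrimination scores (>= 1 value).
#' @param tau discrimination threshold.
#' @param exact_limit largest n handled exactly (default 12).
#' @return One-sided p-value in \[0, 1\].
#' @export
wilcoxon_signed_rank_p <- function(scores, tau = 0.015, exact_limit = 12L) {
  if (length(scores) == 0L) stop("empty score vector", call. = FALSE)
  if (anyNA(scores)) stop("scores must not contain NA", call. = FALSE)
  .cpp_signrank_p(as.numeric(scores) - tau, as.integer(exact_limit))
}

#' Detection call for one probe set in one sample
#'
#' @param pm,mm the probe set's PM and MM intensities in one sample.
#' @param params a [detection_params()].
#' @return List with `call` (one of `"P"`, `"M"`, `"A"`) and `p`.
#' @export
detection_call <- function(pm, mm, params = detection_params()) {
  p <- wilcoxon_signed_rank_p(discrimination_scores(pm, mm), params$tau)
  list(call = call_from_p(p, params), p = p)
}

call_from_p <- function(p, params) {
  ifelse(p < params$alpha1, "P", ifelse(p > params$alpha2, "A", "M"))
}

#' MAS5-style detection calls for a whole dataset
#'
#' Computes the detection p-value and P/M/A call for every (probe set,
#' sample) cell. Calls operate on the raw (un-normalized) PM/MM intensities;
#' the RMA expression path and this call path are independent computations
#' over the same dataset. All probe pairs enter the test (no saturation
#' handling or probe-pair discarding).
#'
#' @param dataset a [probe_dataset()].
#' @param params a [detection_params()].
#' @return An object of class `mas5_calls`: list with character matrix
#'   `calls` and numeric matrix `pvalues` (probe sets x samples), plus the
#'   `params` used.
#' @export
mas5_calls <- function(dataset, params = detection_params()) {
  stopifnot(inherits(dataset, "probe_dataset"),
            inherits(params, "detection_params"))
  blk <- contiguous_blocks(dataset)
  pv <- .cpp_mas5_pvalues(dataset$pm[blk$order, , drop = FALSE],
                          dataset$mm[blk$order, , drop = FALSE],
                          blk$starts, blk$lens, params$tau, 12L)
  dimnames(pv) <- list(dataset$probesets, dataset$samples)
  calls <- matrix(call_from_p(pv, params), nrow = nrow(pv),
                  dimnames = dimnames(pv))
  structure(list(calls = calls, pvalues = pv, params = params),
            class = "mas5_calls")
}

#' @export
print.mas5_calls <- function(x, ...) {
  tab <- table(factor(x$calls, levels = c("P", "M", "A")))
  cat("MAS5-style detection calls:", nrow(x$calls), "probe sets x",
      ncol(x$calls), "samples\n")
  cat(sprintf("  P: %d  M: %d  A: %d  (tau = %g, alpha1 = %g, alpha2 = %g)\n",
              tab[["P"]], tab[["M"]], tab[["A"]],
              x$params$tau, x$params$alpha1, x$params$alpha2))
  invisible(x)
}
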