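#' Summarize one probe-set block by median polish
#'
#' Fits the additive model `value = overall + probe effect + sample effect`
#' by Tukey's median polish (alternating subtraction of row and column
#' medians, rows first) and returns `overall + sample effect` per sample —
#' the RMA probe-set summary. Medians of even-length vectors are the mean of
#' the central pair. Iteration stops when the largest absolute change of any
#' residual within a sweep falls below `eps`, or after `maxiter` sweeps; the
#' defaults run to numerical convergence, which typical probe-set blocks
#' reach within a handful of sweeps, making the summary a well-defined fixed
#' point rather than an iteration-count artifact.
#'
#' @param block numeric matrix of log2 PM values, probes x samples, from a
#'   single probe set (>= 1 probe row).
#' @param eps convergence tolerance on residual change (log2 units).
#' @param maxiter maximum number of sweeps.
#' @return Numeric vector of length `ncol(block)`, named by its column
#'   names: one log2 summary per sample.
#' @export
median_polish_summarize <- function(block, eps = 1e-12, maxiter = 1000L) {
  block <- as.matrix(block)
  if (nrow(block) == 0L || ncol(block) == 0L) {
    stop("empty probe-set block", call. = FALSE)
  }
  if (!is.numeric(block) || anyNA(block)) {
    stop("block must be a complete numeric matrix", call. = FALSE)
  }
  out <- .cpp_medpolish_summary(block, eps, as.integer(maxiter))
  stats::setNames(as.numeric(out), colnames(block))
}

#' RMA-summarized expression matrix
#'
#' Runs the full RMA pipeline on a probe-level dataset: per-array
#' normal+exponential background adjustment of PM intensities
#' ([normexp_fit()] + [normexp_adjust()]), across-array quantile
#' normalization ([quantile_normalize()]), log2 transformation, and
#' per-probe-set median polish ([median_polish_summarize()]). MM intensities
#' are ignored by this path (they feed only the detection calls).
#'
#' @param dataset a [probe_dataset()].
#' @param background apply background correction (default `TRUE`).
#' @param normalize apply quantile normalization (default `TRUE`).
#' @param eps,maxiter median-polish convergence controls.
#' @return Numeric matrix of log2 expression, probe sets x samples, rows in
#'   probe-set appearance order.
#' @export
rma <- function(dataset, background = TRUE, normalize = TRUE,
                eps = 1e-12, maxiter = 1000L) {
  stopifnot(inherits(dataset, "probe_dataset"))
  pm <- dataset$pm
  if (background) {
    for (j in seq_len(ncol(pm))) {
      params <- normexp_fit(pm[, j])
      pm[, j] <- normexp_adjust(pm[, j], params)
    }
  }
  if (normalize) {
    pm <- quantile_normalize(pm)
  }
  lg <- log2(pm)
  blk <- contiguous_blocks(dataset)
  expr <- .cpp_medpolish_blocks(lg[blk$order, , drop = FALSE],
                                blk$starts, blk$lens, eps,
                                as.integer(maxiter))
  dimnames(expr) <- list(dataset$probesets, dataset$samples)
  expr
}

# Row permutation making each probe set's pairs contiguous, in probe-set
# appearance order, plus 1-based block starts and lengths.
contiguous_blocks <- function(dataset) {
  f <- factor(dataset$probeset_id, levels = dataset$probesets)
  ord <- order(as.integer(f))
  lens <- tabulate(f, nbins = length(dataset$probesets))
  starts <- cumsum(c(1L, lens[-length(lens)]))
  list(order = ord, starts = as.integer(starts), lens = as.integer(lens))
}
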