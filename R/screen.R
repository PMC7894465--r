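#' Screen configuration
#'
#' @param fold_threshold log2 group-mean difference cutoff for the
#'   fold-change up-sets (default 2.0, i.e. fourfold).
#' @param call_aggregation how detection calls are aggregated across a
#'   group's replicates: `"all"` (every replicate must carry the wanted
#'   call; the default) or `"majority"` (more than half must).
#' @param include_marginal_as_present,include_marginal_as_absent whether a
#'   Marginal call counts toward Present / Absent during aggregation
#'   (default `FALSE`: Marginal counts as neither).
#' @param strict use strict `>` at the fold threshold (default `TRUE`); set
#'   `FALSE` for `>=`.
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(fold_threshold = 2.0,
                          call_aggregation = c("all", "majority"),
                          include_marginal_as_present = FALSE,
                          include_marginal_as_absent = FALSE,
                          strict = TRUE) {
  if (!(fold_threshold > 0)) stop("fold_threshold must be > 0", call. = FALSE)
  call_aggregation <- match.arg(call_aggregation)
  structure(
    list(fold_threshold = fold_threshold,
         call_aggregation = call_aggregation,
         include_marginal_as_present = isTRUE(include_marginal_as_present),
         include_marginal_as_absent = isTRUE(include_marginal_as_absent),
         strict = isTRUE(strict)),
    class = "screen_config"
  )
}

#' Per-probe-set mean expression of a group
#'
#' @param expr log2 expression matrix (probe sets x samples) as returned by
#'   [rma()].
#' @param design a [group_design()].
#' @param group a group label present in the design.
#' @return Named numeric vector: arithmetic mean of log2 values across the
#'   group's samples.
#' @export
group_mean <- function(expr, design, group) {
  s <- group_samples(design, group)
  missing <- setdiff(s, colnames(expr))
  if (length(missing) > 0L) {
    stop("samples missing from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rowMeans(expr[, s, drop = FALSE])
}

#' Fold-change up-set between two roles
#'
#' The set of probe sets whose mean log2 expression in the `higher` role's
#' group exceeds the `lower` role's group by more than `threshold` (strict
#' inequality by default).
#'
#' @param expr log2 expression matrix.
#' @param design a [group_design()].
#' @param higher,lower role names (see [screen_roles()]).
#' @param threshold log2 difference cutoff.
#' @param strict use `>` (default) rather than `>=`.
#' @return Character vector of probe-set IDs.
#' @export
up_set <- function(expr, design, higher, lower, threshold = 2.0,
                   strict = TRUE) {
  for (r in c(higher, lower)) {
    if (!r %in% names(design$roles)) {
      stop("unresolved role '", r, "'", call. = FALSE)
    }
  }
  diff <- group_mean(expr, design, design$roles[[higher]]) -
    group_mean(expr, design, design$roles[[lower]])
  keep <- if (strict) diff > threshold else diff >= threshold
  rownames(expr)[keep]
}

#' Aggregate detection calls across a group's replicates
#'
#' @param calls a `mas5_calls` object (or a character call matrix).
#' @param design a [group_design()].
#' @param group a group label.
#' @param wanted `"P"` or `"A"`: the call being screened for.
#' @param mode `"all"` (every replicate) or `"majority"` (> half).
#' @param include_marginal whether `M` counts as the wanted call.
#' @return Character vector of probe-set IDs satisfying the aggregation
#'   rule.
#' @export
aggregate_calls <- function(calls, design, group, wanted = c("P", "A"),
                            mode = c("all", "majority"),
                            include_marginal = FALSE) {
  cm <- if (inherits(calls, "mas5_calls")) calls$calls else calls
  wanted <- match.arg(wanted)
  if (!is.character(mode) || !all(mode %in% c("all", "majority"))) {
    stop("unknown aggregation mode: ", paste(mode, collapse = ", "),
         call. = FALSE)
  }
  mode <- match.arg(mode)
  s <- group_samples(design, group)
  accept <- if (include_marginal) c(wanted, "M") else wanted
  hits <- matrix(cm[, s, drop = FALSE] %in% accept, nrow = nrow(cm))
  k <- rowSums(hits)
  keep <- if (mode == "all") k == length(s) else k > length(s) / 2
  rownames(cm)[keep]
}

#' Run the full candidate-regulator screen
#'
#' Executes the multi-contrast screen over an expression matrix and a
#' detection-call matrix sharing one probe-set universe:
#' \enumerate{
#'   \item four fold-change up-sets — `target > source_origin`,
#'     `target_stem > source_origin`, `target > source`,
#'     `target_stem > source` — and their intersection;
#'   \item Present-sets for `target` and `target_stem`, Absent-sets for
#'     `source` and `source_origin` (aggregated over replicates), and their
#'     four-way intersection;
#'   \item the combined overlap of the two intersections;
#'   \item mapping of combined probe sets to gene symbols (unannotated probe
#'     sets are dropped here, with the count recorded) and intersection with
#'     the transcription-factor set. A gene passes if at least one of its
#'     probe sets passes, so multiple probe sets collapse to one gene.
#' }
#'
#' @param expr log2 expression matrix from [rma()].
#' @param calls a `mas5_calls` object from [mas5_calls()].
#' @param design a [group_design()].
#' @param config a [screen_config()].
#' @param gene_map named character vector `probeset_id -> symbol` (`NA` for
#'   unannotated probe sets); see [read_gene_map()].
#' @param tf_set an [annotation_set()] of transcription-factor symbols.
#' @return An object of class `screen_result` with the per-stage probe-set
#'   sets, the final `tf_genes` character vector (sorted, deduplicated) and
#'   per-stage cardinalities.
#' @export
run_screen <- function(expr, calls, design, config = screen_config(),
                       gene_map = NULL, tf_set = annotation_set(character())) {
  cm <- if (inherits(calls, "mas5_calls")) calls$calls else calls
  if (!setequal(rownames(expr), rownames(cm))) {
    stop("expression and call matrices disagree on the probe-set universe",
         call. = FALSE)
  }
  up_pairs <- list(
    target_vs_source_origin = c("target", "source_origin"),
    target_stem_vs_source_origin = c("target_stem", "source_origin"),
    target_vs_source = c("target", "source"),
    target_stem_vs_source = c("target_stem", "source")
  )
  up_sets <- lapply(up_pairs, function(p) {
    sort(up_set(expr, design, p[1L], p[2L],
                threshold = config$fold_threshold, strict = config$strict))
  })
  fold_intersection <- sort(Reduce(intersect, up_sets))

  present_sets <- lapply(
    stats::setNames(c("target", "target_stem"), c("target", "target_stem")),
    function(r) sort(aggregate_calls(
      cm, design, design$roles[[r]], wanted = "P",
      mode = config$call_aggregation,
      include_marginal = config$include_marginal_as_present))
  )
  absent_sets <- lapply(
    stats::setNames(c("source", "source_origin"), c("source", "source_origin")),
    function(r) sort(aggregate_calls(
      cm, design, design$roles[[r]], wanted = "A",
      mode = config$call_aggregation,
      include_marginal = config$include_marginal_as_absent))
  )
  call_intersection <- sort(Reduce(intersect, c(present_sets, absent_sets)))
  combined <- sort(intersect(fold_intersection, call_intersection))

  n_unannotated <- 0L
  genes <- character()
  if (length(combined) > 0L && !is.null(gene_map)) {
    sym <- gene_map[combined]
    sym[!combined %in% names(gene_map)] <- NA_character_
    n_unannotated <- sum(is.na(sym))
    genes <- sort(unique(sym[!is.na(sym)]))
  }
  tf_genes <- sort(intersect(genes, tf_set$genes))

  structure(
    list(up_sets = up_sets,
         fold_intersection = fold_intersection,
         present_sets = present_sets,
         absent_sets = absent_sets,
         call_intersection = call_intersection,
         combined = combined,
         combined_genes = genes,
         n_unannotated_dropped = n_unannotated,
         tf_genes = tf_genes,
         config = config),
    class = "screen_result"
  )
}

#' Per-stage cardinalities of a screen result
#'
#' Stage order mirrors the published Venn layout: the four up-set counts,
#' the fold-change intersection, the four call counts (Present in target and
#' target-stem, Absent in source-origin and source), the call intersection,
#' and the combined overlap.
#'
#' @param result a `screen_result`.
#' @return data.frame with columns `stage` and `count` (11 rows).
#' @export
stage_counts <- function(result) {
  stopifnot(inherits(result, "screen_result"))
  data.frame(
    stage = c(paste0("up_", names(result$up_sets)),
              "fold_intersection",
              "present_target", "present_target_stem",
              "absent_source_origin", "absent_source",
              "call_intersection", "combined"),
    count = c(vapply(result$up_sets, length, 0L),
              length(result$fold_intersection),
              length(result$present_sets$target),
              length(result$present_sets$target_stem),
              length(result$absent_sets$source_origin),
              length(result$absent_sets$source),
              length(result$call_intersection),
              length(result$combined)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Candidate master-regulator screen\n")
  counts <- stage_counts(x)
  for (i in seq_len(nrow(counts))) {
    cat(sprintf("  %-30s %d\n", counts$stage[i], counts$count[i]))
  }
  if (x$n_unannotated_dropped > 0L) {
    cat("  (", x$n_unannotated_dropped,
        "combined probe sets without gene annotation dropped )\n")
  }
  cat("  TF-filtered genes:",
      if (length(x$tf_genes)) paste(x$tf_genes, collapse = ", ") else "(none)",
      "\n")
  invisible(x)
}

#' @export
summary.screen_result <- function(object, ...) {
  counts <- stage_counts(object)
  structure(
    list(counts = counts,
         combined_genes = object$combined_genes,
         tf_genes = object$tf_genes,
         n_unannotated_dropped = object$n_unannotated_dropped,
         config = object$config),
    class = "summary.screen_result"
  )
}

#' @export
print.summary.screen_result <- function(x, ...) {
  cat("Screen stage cardinalities:\n")
  print(x$counts, row.names = FALSE)
  cat("Combined genes:", length(x$combined_genes),
      " TF-filtered:", length(x$tf_genes), "\n")
  invisible(x)
}
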