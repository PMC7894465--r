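#' Probe-level dataset
#'
#' Container for raw perfect-match/mismatch (PM/MM) probe intensities of an
#' expression array experiment. Probe pairs are grouped into probe sets, each
#' probe set interrogating one transcript; every sample covers the identical
#' probe-pair universe.
#'
#' @param probeset_id character vector, one probe-set identifier per probe
#'   pair (row).
#' @param pair_index integer vector (>= 0), the index of the pair within its
#'   probe set. `(probeset_id, pair_index)` must be unique.
#' @param pm,mm numeric matrices of strictly positive intensities, one row
#'   per probe pair and one column per sample. Column names are the sample
#'   identifiers and must agree between `pm` and `mm`.
#'
#' @return An object of class `probe_dataset`: a list with elements
#'   `samples`, `probesets` (unique IDs in order of first appearance),
#'   `probeset_id`, `pair_index`, `pm`, `mm`.
#' @export
probe_dataset <- function(probeset_id, pair_index, pm, mm) {
  pm <- as.matrix(pm)
  mm <- as.matrix(mm)
  probeset_id <- as.character(probeset_id)
  pair_index <- as.integer(pair_index)
  x <- structure(
    list(
      samples = colnames(pm),
      probesets = unique(probeset_id),
      probeset_id = probeset_id,
      pair_index = pair_index,
      pm = pm,
      mm = mm
    ),
    class = "probe_dataset"
  )
  validate_probe_dataset(x)
}

validate_probe_dataset <- function(x) {
  if (is.null(colnames(x$pm)) || is.null(colnames(x$mm))) {
    stop("pm and mm must carry sample names as column names", call. = FALSE)
  }
  if (!identical(colnames(x$pm), colnames(x$mm))) {
    stop("pm and mm sample sets differ: pm has [",
         paste(colnames(x$pm), collapse = ", "), "], mm has [",
         paste(colnames(x$mm), collapse = ", "), "]", call. = FALSE)
  }
  if (anyDuplicated(x$samples)) {
    stop("duplicated sample identifiers: ",
         paste(unique(x$samples[duplicated(x$samples)]), collapse = ", "),
         call. = FALSE)
  }
  n <- length(x$probeset_id)
  if (nrow(x$pm) != n || nrow(x$mm) != n || length(x$pair_index) != n) {
    stop("probeset_id, pair_index, pm and mm disagree on the number of probe pairs",
         call. = FALSE)
  }
  key <- paste(x$probeset_id, x$pair_index, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop("duplicated probe pair (", x$probeset_id[d], ", ", x$pair_index[d],
         ") at row ", d, call. = FALSE)
  }
  bad <- !is.finite(x$pm) | x$pm <= 0 | !is.finite(x$mm) | x$mm <= 0
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("non-positive or non-finite intensity at probe pair row ", idx[1L],
         ", sample '", x$samples[idx[2L]], "'", call. = FALSE)
  }
  if (any(x$pair_index < 0L)) {
    stop("pair_index must be >= 0", call. = FALSE)
  }
  x
}

#' @export
print.probe_dataset <- function(x, ...) {
  cat("Probe-level dataset:", length(x$probesets), "probe sets,",
      length(x$probeset_id), "probe pairs,",
      length(x$samples), "samples\n")
  cat("Samples:", paste(x$samples, collapse = ", "), "\n")
  invisible(x)
}

#' Number of probe pairs per probe set
#'
#' @param x a `probe_dataset`.
#' @return Named integer vector, pairs per probe set (probe-set appearance
#'   order).
#' @export
probeset_sizes <- function(x) {
  stopifnot(inherits(x, "probe_dataset"))
  tab <- table(factor(x$probeset_id, levels = x$probesets))
  stats::setNames(as.integer(tab), names(tab))
}

# Row indices of each probe set, as a named list in probe-set order.
probeset_index <- function(x) {
  split(seq_along(x$probeset_id),
        factor(x$probeset_id, levels = x$probesets))
}

#' Experimental design: sample groups and screen roles
#'
#' Assigns each sample to a group and names the four groups playing the
#' screen's roles: `source` (the cells to be reprogrammed), `source_origin`
#' (the population the source cells derive from), `target` (the desired
#' mature cell type) and `target_stem` (the target lineage's stem/progenitor
#' population).
#'
#' @param assignments named character vector: `sample -> group label`.
#' @param roles named character vector with exactly the names `source`,
#'   `source_origin`, `target`, `target_stem`, mapping each role to a
#'   distinct group label.
#' @return An object of class `group_design`.
#' @export
group_design <- function(assignments, roles) {
  x <- structure(
    list(assignments = assignments, roles = roles[screen_roles()]),
    class = "group_design"
  )
  validate_group_design(x)
}

#' The four screen roles, in canonical order
#' @return `c("source", "source_origin", "target", "target_stem")`.
#' @export
screen_roles <- function() c("source", "source_origin", "target", "target_stem")

validate_group_design <- function(x) {
  if (is.null(names(x$assignments)) || any(names(x$assignments) == "")) {
    stop("assignments must be a named vector (sample -> group)", call. = FALSE)
  }
  if (anyDuplicated(names(x$assignments))) {
    stop("duplicated sample in design: ",
         paste(unique(names(x$assignments)[duplicated(names(x$assignments))]),
               collapse = ", "), call. = FALSE)
  }
  if (!setequal(names(x$roles), screen_roles()) || anyNA(x$roles)) {
    stop("roles must name all four of: ",
         paste(screen_roles(), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(unname(x$roles))) {
    stop("the four roles must map to four distinct group labels", call. = FALSE)
  }
  for (r in screen_roles()) {
    if (!any(x$assignments == x$roles[[r]])) {
      stop("role '", r, "' (group '", x$roles[[r]],
           "') has no assigned samples", call. = FALSE)
    }
  }
  x
}

#' @export
print.group_design <- function(x, ...) {
  cat("Group design:", length(x$assignments), "samples,",
      length(unique(x$assignments)), "groups\n")
  for (r in screen_roles()) {
    s <- names(x$assignments)[x$assignments == x$roles[[r]]]
    cat(sprintf("  %-13s %s  [%s]\n", r, x$roles[[r]],
                paste(s, collapse = ", ")))
  }
  invisible(x)
}

# Samples belonging to a group label; errors on unknown group.
group_samples <- function(design, group) {
  s <- names(design$assignments)[design$assignments == group]
  if (length(s) == 0L) stop("unknown or empty group '", group, "'", call. = FALSE)
  s
}

# Check that every sample assigned in the design exists in the dataset.
check_design_covers <- function(dataset, design) {
  missing <- setdiff(names(design$assignments), dataset$samples)
  if (length(missing) > 0L) {
    stop("design assigns samples absent from the dataset: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Gene annotation set (e.g. a transcription-factor class)
#'
#' A set of gene symbols with an optional class identifier, such as the
#' PANTHER protein-class "Transcription factor" list (class ID PC00218) used
#' to restrict screen candidates to transcription factors. Symbols are
#' matched case-sensitively (mouse symbol capitalization is meaningful).
#'
#' @param genes character vector of gene symbols; trimmed, deduplicated.
#' @param class_id optional class identifier string.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(genes, class_id = "") {
  genes <- trimws(as.character(genes))
  genes <- unique(genes[genes != ""])
  structure(list(class_id = class_id, genes = sort(genes)),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("Annotation set", if (nzchar(x$class_id)) paste0("[", x$class_id, "]"),
      ":", length(x$genes), "gene symbols\n")
  invisible(x)
}
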