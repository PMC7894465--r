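#' Read a probe-level intensity table
#'
#' The probe table dialect is tab-separated text with a header row naming, in
#' order: `probeset_id`, `pair_index`, then one `pm:<sample>` / `mm:<sample>`
#' column pair per sample. Sample order in the returned dataset equals column
#' order. This plain-text dialect replaces binary CEL files; converting CEL
#' files to it is an external preprocessing step.
#'
#' @param path path to a probe table file.
#' @return A [probe_dataset()].
#' @export
read_probe_table <- function(path) {
  if (!file.exists(path)) stop("probe table not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  cn <- colnames(tab)
  if (length(cn) < 4L || cn[1L] != "probeset_id" || cn[2L] != "pair_index") {
    stop("probe table format error: header must start with 'probeset_id', ",
         "'pair_index' followed by pm:/mm: sample columns", call. = FALSE)
  }
  rest <- cn[-(1:2)]
  pm_cols <- grep("^pm:", rest, value = TRUE)
  mm_cols <- grep("^mm:", rest, value = TRUE)
  if (length(pm_cols) + length(mm_cols) != length(rest)) {
    stop("probe table format error: unrecognized columns: ",
         paste(setdiff(rest, c(pm_cols, mm_cols)), collapse = ", "),
         call. = FALSE)
  }
  pm_samples <- sub("^pm:", "", pm_cols)
  mm_samples <- sub("^mm:", "", mm_cols)
  if (!setequal(pm_samples, mm_samples)) {
    stop("probe table format error: pm and mm sample sets differ (pm: ",
         paste(pm_samples, collapse = ", "), "; mm: ",
         paste(mm_samples, collapse = ", "), ")", call. = FALSE)
  }
  as_intensity <- function(cols, prefix) {
    m <- matrix(NA_real_, nrow = nrow(tab), ncol = length(cols),
                dimnames = list(NULL, sub(paste0("^", prefix, ":"), "", cols)))
    for (j in seq_along(cols)) {
      v <- suppressWarnings(as.numeric(tab[[cols[j]]]))
      bad <- which(!is.finite(v) | v <= 0)
      if (length(bad) > 0L) {
        stop("value error in probe table: non-positive or non-numeric ",
             "intensity at data row ", bad[1L], ", column '", cols[j], "'",
             call. = FALSE)
      }
      m[, j] <- v
    }
    m
  }
  pm <- as_intensity(pm_cols, "pm")
  mm <- as_intensity(mm_cols, "mm")[, pm_samples, drop = FALSE]
  key <- paste(tab$probeset_id, tab$pair_index, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop("probe table format error: duplicated probe pair (",
         tab$probeset_id[d], ", ", tab$pair_index[d], ") at data row ", d,
         call. = FALSE)
  }
  probe_dataset(tab$probeset_id, as.integer(tab$pair_index), pm, mm)
}

#' Write a probe-level intensity table
#'
#' Inverse of [read_probe_table()]; `read_probe_table(write_probe_table(x))`
#' reproduces `x`, and writing the same dataset twice yields byte-identical
#' files (intensities are serialized with full precision).
#'
#' @param dataset a [probe_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "probe_dataset"))
  cols <- c("probeset_id", "pair_index",
            as.vector(rbind(paste0("pm:", dataset$samples),
                            paste0("mm:", dataset$samples))))
  n <- length(dataset$probeset_id)
  body <- matrix("", nrow = n, ncol = length(cols))
  body[, 1L] <- dataset$probeset_id
  body[, 2L] <- as.character(dataset$pair_index)
  for (j in seq_along(dataset$samples)) {
    body[, 2L * j + 1L] <- format_num(dataset$pm[, j])
    body[, 2L * j + 2L] <- format_num(dataset$mm[, j])
  }
  lines <- c(paste(cols, collapse = "\t"),
             apply(body, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# Full-precision, locale-independent number serialization.
format_num <- function(x) {
  sprintf("%.17g", x)
}

#' Read a design file
#'
#' Plain-text grammar, one `key=value` entry per line:
#' \preformatted{
#' role:source=DFAT
#' role:source_origin=AC
#' role:target=HC
#' role:target_stem=RLSC
#' sample:GSM0001=DFAT
#' ...}
#' Blank lines and lines starting with `#` are ignored. Group membership
#' lives exclusively in this file and is never inferred from sample names.
#'
#' @param path path to a design file.
#' @return A [group_design()].
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  m <- regmatches(lines, regexec("^(role|sample):([^=]+)=(.*)$", lines))
  bad <- which(lengths(m) == 0L)
  if (length(bad) > 0L) {
    stop("design format error at line: '", lines[bad[1L]], "'", call. = FALSE)
  }
  kind <- vapply(m, `[`, "", 2L)
  key <- trimws(vapply(m, `[`, "", 3L))
  val <- trimws(vapply(m, `[`, "", 4L))
  roles <- stats::setNames(val[kind == "role"], key[kind == "role"])
  assignments <- stats::setNames(val[kind == "sample"], key[kind == "sample"])
  group_design(assignments, roles)
}

#' Write a design file
#'
#' @param design a [group_design()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "group_design"))
  lines <- c(
    paste0("role:", screen_roles(), "=", design$roles[screen_roles()]),
    paste0("sample:", names(design$assignments), "=", design$assignments)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a probe-set to gene-symbol map
#'
#' Two tab-separated columns: `probeset_id <TAB> symbol`. An empty symbol
#' marks an unannotated probe set. A gene symbol may own multiple probe sets
#' (e.g. Hnf4a is represented by more than one probe set on the Mouse Genome
#' 430 2.0 array); a probe set appears at most once.
#'
#' @param path path to the map file.
#' @return Named character vector `probeset_id -> symbol` (`NA` where
#'   unannotated).
#' @export
read_gene_map <- function(path) {
  if (!file.exists(path)) stop("gene map not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[trimws(lines) != "" & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- trimws(vapply(parts, `[`, "", 1L))
  sym <- trimws(vapply(parts, function(p) if (length(p) >= 2L) p[2L] else "", ""))
  if (anyDuplicated(ids)) {
    stop("gene map format error: probe set '", ids[duplicated(ids)][1L],
         "' mapped more than once", call. = FALSE)
  }
  sym[sym == ""] <- NA_character_
  stats::setNames(sym, ids)
}

#' Write a probe-set to gene-symbol map
#' @param map named character vector `probeset_id -> symbol`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_map <- function(map, path) {
  sym <- ifelse(is.na(map), "", map)
  writeLines(paste(names(map), sym, sep = "\t"), path)
  invisible(path)
}

#' Read a gene list (one symbol per line)
#'
#' Blank lines and lines starting with `#` are ignored; symbols are trimmed
#' and deduplicated, matched case-sensitively downstream. An empty resulting
#' set triggers a warning (the screen would then return an empty gene list)
#' but is not an error.
#'
#' @param path path to the list file.
#' @param class_id optional class identifier to attach (e.g. `"PC00218"`).
#' @return An [annotation_set()].
#' @export
read_gene_list <- function(path, class_id = "") {
  if (!file.exists(path)) stop("gene list not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  set <- annotation_set(lines, class_id = class_id)
  if (length(set$genes) == 0L) {
    warning("gene list '", path, "' is empty; downstream screens will ",
            "return an empty gene list", call. = FALSE)
  }
  message("read_gene_list: ", length(set$genes), " unique symbols from ", path)
  set
}

#' Write a gene list (one symbol per line, sorted)
#' @param set an [annotation_set()] or character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(set, path) {
  genes <- if (inherits(set, "annotation_set")) set$genes else
    sort(unique(trimws(as.character(set))))
  writeLines(genes, path)
  invisible(path)
}

#' Write all stage sets and the summary of a screen result
#'
#' Emits one ID-per-line text file per stage set (lexicographically sorted,
#' so repeated runs are byte-identical), a per-stage counts table
#' (`stage_counts.tsv`) for side-by-side comparison with published Venn
#' counts, and a machine-readable `summary.json` with all stage
#' cardinalities and the final gene list.
#'
#' @param result a `screen_result` from [run_screen()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_screen_result <- function(result, dir) {
  stopifnot(inherits(result, "screen_result"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) {
      stop("cannot create output directory: ", dir, call. = FALSE)
    }
  }
  write_set <- function(ids, file) {
    writeLines(sort(ids), file.path(dir, file))
  }
  for (nm in names(result$up_sets)) {
    write_set(result$up_sets[[nm]], paste0("up_", nm, ".txt"))
  }
  write_set(result$fold_intersection, "fold_intersection.txt")
  for (nm in names(result$present_sets)) {
    write_set(result$present_sets[[nm]], paste0("present_", nm, ".txt"))
  }
  for (nm in names(result$absent_sets)) {
    write_set(result$absent_sets[[nm]], paste0("absent_", nm, ".txt"))
  }
  write_set(result$call_intersection, "call_intersection.txt")
  write_set(result$combined, "combined.txt")
  writeLines(result$tf_genes, file.path(dir, "tf_genes.txt"))
  counts <- stage_counts(result)
  writeLines(c("stage\tcount", paste(counts$stage, counts$count, sep = "\t")),
             file.path(dir, "stage_counts.tsv"))
  summary <- list(
    counts = as.list(stats::setNames(counts$count, counts$stage)),
    tf_genes = result$tf_genes,
    n_unannotated_dropped = result$n_unannotated_dropped,
    config = unclass(result$config)
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Write a numeric or character matrix as TSV (rows = probe sets)
#' @param m matrix with row and column names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  body <- if (is.numeric(m)) {
    apply(m, 1:2, format_num)
  } else {
    m
  }
  lines <- c(paste(c("probeset_id", colnames(m)), collapse = "\t"),
             paste(rownames(m), apply(body, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
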