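# A gene map is itself a named character vector, so only an unnamed
# length-1 character is treated as a file path.
is_path <- function(x) {
  is.character(x) && length(x) == 1L && is.null(names(x))
}

#' Run the full screen pipeline on a probe-level dataset
#'
#' Orchestrates preprocess -> screen -> report: RMA expression, MAS5-style
#' detection calls, the multi-contrast screen, and (optionally) all output
#' artifacts — expression and call TSV dumps, per-stage ID lists, the
#' stage-count table, `summary.json` and a run manifest capturing every
#' parameter (including the defaults the published analysis leaves
#' unstated: tau/alpha1/alpha2, aggregation mode, inequality strictness),
#' so a run is reproducible from its manifest alone.
#'
#' @param dataset a [probe_dataset()], or a path to a probe table.
#' @param design a [group_design()], or a path to a design file.
#' @param gene_map named character vector or path to a gene-map TSV.
#' @param tf_set an [annotation_set()] or path to a gene-list file.
#' @param config a [screen_config()].
#' @param params a [detection_params()].
#' @param out_dir output directory; `NULL` (default) writes nothing.
#' @return A list of class `pipeline_run` with `expr`, `calls`, `screen`
#'   and (when writing) `paths`.
#' @export
run_pipeline <- function(dataset, design, gene_map = NULL, tf_set = NULL,
                         config = screen_config(),
                         params = detection_params(),
                         out_dir = NULL) {
  if (is.character(dataset)) dataset <- read_probe_table(dataset)
  if (is.character(design)) design <- read_design(design)
  if (is_path(gene_map)) gene_map <- read_gene_map(gene_map)
  if (is_path(tf_set)) tf_set <- read_gene_list(tf_set)
  if (is.null(tf_set)) tf_set <- annotation_set(character())
  check_design_covers(dataset, design)

  expr <- rma(dataset)
  calls <- mas5_calls(dataset, params)
  screen <- run_screen(expr, calls, design, config, gene_map, tf_set)

  paths <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_matrix_tsv(expr, file.path(out_dir, "expression.tsv"))
    write_matrix_tsv(calls$calls, file.path(out_dir, "calls.tsv"))
    write_screen_result(screen, out_dir)
    manifest <- list(
      package = "mrscreen",
      version = as.character(utils::packageVersion("mrscreen")),
      detection_params = unclass(params),
      screen_config = unclass(screen$config),
      samples = dataset$samples,
      n_probesets = length(dataset$probesets)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    paths <- out_dir
  }
  structure(list(expr = expr, calls = calls, screen = screen, paths = paths),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run:", nrow(x$expr), "probe sets,", ncol(x$expr), "samples\n")
  print(x$screen)
  invisible(x)
}

#' Published stage counts for the deposited arrays
#'
#' The eleven Venn-stage cardinalities published for the DFAT-to-hepatocyte
#' screen of the deposited GEO arrays (series GSE156495 plus GSM785818-20
#' and GSM162863; Mouse Genome 430 2.0), in [stage_counts()] order. Roles:
#' source = DFAT, source-origin = AC (mature adipocytes), target = HC
#' (hepatocytes), target-stem = RLSC (resident liver stem cells).
#'
#' @return Named integer vector of length 11.
#' @export
geo_reference_counts <- function() {
  c(up_target_vs_source_origin = 1626L,       # HC > AC
    up_target_stem_vs_source_origin = 2636L,  # RLSC > AC
    up_target_vs_source = 1418L,              # HC > DFAT
    up_target_stem_vs_source = 1042L,         # RLSC > DFAT
    fold_intersection = 126L,
    present_target = 18031L,                  # HC_P
    present_target_stem = 21402L,             # RLSC_P
    absent_source_origin = 19275L,            # AC_A
    absent_source = 19599L,                   # DFAT_A
    call_intersection = 164L,
    combined = 33L)
}

#' Reproduce the published screen on externally converted GEO arrays
#'
#' Runs the full pipeline on user-supplied probe tables (CEL files converted
#' to the probe-table dialect externally) and reports each stage count side
#' by side with the published reference value, flagging matches. This is a
#' reporting command: it never fails on a mismatch, because bit-level
#' agreement with another RMA implementation's estimator internals is not
#' guaranteed — per-stage deltas are what it is for.
#'
#' @param dataset,design,gene_map,tf_set as in [run_pipeline()] (objects or
#'   paths).
#' @param config,params as in [run_pipeline()].
#' @param reference named integer vector of reference counts, by default
#'   [geo_reference_counts()].
#' @param aggregation optionally a character vector of aggregation modes to
#'   report (e.g. `c("all", "majority")`); overrides `config$call_aggregation`
#'   and adds one count column per mode.
#' @return A data.frame of class `geo_reproduction` with columns `stage`,
#'   one count column per aggregation mode, `reference`, `delta` (first mode
#'   minus reference) and `match`.
#' @export
reproduce_geo <- function(dataset, design, gene_map, tf_set,
                          config = screen_config(),
                          params = detection_params(),
                          reference = geo_reference_counts(),
                          aggregation = NULL) {
  modes <- if (is.null(aggregation)) config$call_aggregation else aggregation
  if (is.character(dataset)) dataset <- read_probe_table(dataset)
  if (is.character(design)) design <- read_design(design)
  if (is_path(gene_map)) gene_map <- read_gene_map(gene_map)
  if (is_path(tf_set)) tf_set <- read_gene_list(tf_set)
  check_design_covers(dataset, design)

  expr <- rma(dataset)
  calls <- mas5_calls(dataset, params)
  out <- NULL
  genes <- list()
  for (m in modes) {
    cfg <- config
    cfg$call_aggregation <- m
    res <- run_screen(expr, calls, design, cfg, gene_map, tf_set)
    counts <- stage_counts(res)
    names(counts)[names(counts) == "count"] <- paste0("count_", m)
    out <- if (is.null(out)) counts else cbind(out, counts[2L])
    genes[[m]] <- res$tf_genes
  }
  ref <- reference[out$stage]
  out$reference <- as.integer(ref)
  out$delta <- out[[2L]] - out$reference
  out$match <- !is.na(out$reference) & out$delta == 0L
  attr(out, "tf_genes") <- genes
  class(out) <- c("geo_reproduction", class(out))
  out
}

#' @export
print.geo_reproduction <- function(x, ...) {
  cat("Stage counts vs published reference:\n")
  print.data.frame(x, row.names = FALSE)
  genes <- attr(x, "tf_genes")
  for (m in names(genes)) {
    cat("TF-filtered genes (", m, "): ",
        paste(genes[[m]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
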