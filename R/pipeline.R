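#' Parameters of the end-to-end DNB pipeline
#'
#' @param p_thresh DEG p-value cutoff (default 0.05).
#' @param fc_thresh DEG fold-change cutoff, linear scale (default 1.5).
#' @param correction `"none"` or `"BH"` for the DEG p column.
#' @param contrast_timepoint Treatment timepoint for the DEG contrast
#'   (`NULL` pools all treatment samples).
#' @param k_clusters Number of hierarchical clusters (default 60; capped
#'   at the number of DEGs at run time).
#' @param min_size Minimum DNB size (default 10; capped likewise).
#' @param ratio_thresh Cluster index-ratio threshold (default 2).
#' @param edge_pcc Correlation-network edge threshold (default 0.4).
#' @param ppi_score PPI combined-score threshold (default 0.7; used by
#'   [load_ppi_edges()] when a PPI file is supplied).
#' @param log2_offset `NULL` if the input is already log2 (default);
#'   otherwise the offset passed to [log2_transform()].
#' @param var_equal Student (TRUE, default) vs Welch t-test.
#' @param eps Near-zero-mean guard for CV computations.
#' @return A validated `pipeline_params` list.
#' @export
pipeline_params <- function(p_thresh = 0.05, fc_thresh = 1.5,
                            correction = c("none", "BH"),
                            contrast_timepoint = NULL,
                            k_clusters = 60, min_size = 10,
                            ratio_thresh = 2, edge_pcc = 0.4,
                            ppi_score = 0.7, log2_offset = NULL,
                            var_equal = TRUE, eps = 1e-8) {
  correction <- match.arg(correction)
  stopifnot(p_thresh > 0, p_thresh <= 1, fc_thresh >= 1,
            k_clusters >= 1, min_size >= 2, ratio_thresh >= 0,
            edge_pcc >= 0, edge_pcc < 1, ppi_score >= 0, ppi_score <= 1)
  structure(list(p_thresh = p_thresh, fc_thresh = fc_thresh,
                 correction = correction,
                 contrast_timepoint = contrast_timepoint,
                 k_clusters = k_clusters, min_size = min_size,
                 ratio_thresh = ratio_thresh, edge_pcc = edge_pcc,
                 ppi_score = ppi_score, log2_offset = log2_offset,
                 var_equal = var_equal, eps = eps),
            class = "pipeline_params")
}

#' Read a pipeline run configuration from YAML
#'
#' The file may hold any [pipeline_params()] field plus optional
#' `expr_path`, `meta_path` and `out_dir` entries.
#'
#' @param path Path to a YAML file.
#' @return List with `params` (a `pipeline_params`), `expr_path`,
#'   `meta_path`, `out_dir` (each `NULL` when absent).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  paths <- raw[intersect(names(raw), c("expr_path", "meta_path", "out_dir"))]
  par_fields <- setdiff(names(raw), c("expr_path", "meta_path", "out_dir"))
  unknown <- setdiff(par_fields, names(formals(pipeline_params)))
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  params <- do.call(pipeline_params, raw[par_fields])
  list(params = params,
       expr_path = paths$expr_path %||% NULL,
       meta_path = paths$meta_path %||% NULL,
       out_dir = paths$out_dir %||% NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full DNB therapeutic-effect pipeline
#'
#' Executes, in order: optional log2 transform, batch adjustment (when
#' the metadata has more than one batch), DEG selection,
#' control-referenced standardization, hierarchical clustering of the
#' DEGs, DNB selection, the TEI trajectory with pre-stable detection,
#' and per-timepoint correlation networks over the DNB. The analysis is
#' deterministic: identical inputs and parameters give identical
#' outputs.
#'
#' @param expr Expression matrix (genes x samples), or a path readable
#'   by [read_expression()].
#' @param meta Sample metadata data frame, or a path readable by
#'   [read_metadata()].
#' @param params A [pipeline_params()] list.
#' @param out_dir Optional directory; when given, every intermediate
#'   artifact is written there (DEG and volcano tables, DNB member
#'   list, cluster scores, TEI trajectory, per-timepoint networks, a
#'   machine-readable `summary.json` and a timestamped `run.log`). A
#'   failing stage leaves a `FAILED` marker naming the stage.
#' @return A `dnb_pipeline` list: `deg`, `standardized`, `clusters`,
#'   `dnb`, `trajectory`, `networks`, `edge_counts`, `summary`,
#'   `batch_report` and the parameters used.
#' @export
run_pipeline <- function(expr, meta, params = pipeline_params(),
                         out_dir = NULL) {
  stopifnot(inherits(params, "pipeline_params"))
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines,
                    paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...))
  }
  current_stage <- "setup"
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  stage <- function(name, code) {
    current_stage <<- name
    note("stage ", name, " started")
    out <- withCallingHandlers(
      tryCatch(code, error = function(e) {
        if (!is.null(out_dir)) {
          writeLines(c(paste("failed stage:", name), conditionMessage(e)),
                     file.path(out_dir, "FAILED"))
          writeLines(log_lines, file.path(out_dir, "run.log"))
        }
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      }),
      message = function(m) {
        note("[", name, "] ", sub("\n$", "", conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
    note("stage ", name, " done")
    out
  }

  if (is.character(expr)) expr <- read_expression(expr)
  if (is.character(meta)) meta <- read_metadata(meta)
  meta <- stage("validate", validate_metadata(meta, expr))

  if (!is.null(params$log2_offset)) {
    expr <- stage("log2", log2_transform(expr, params$log2_offset))
  }
  batch_report <- NULL
  if (length(unique(meta$batch)) > 1L) {
    ba <- stage("batch_adjust", batch_adjust(expr, meta))
    expr <- ba$matrix
    batch_report <- ba$report
  }

  deg <- stage("select_degs", select_degs(
    expr, meta, contrast_timepoint = params$contrast_timepoint,
    p_thresh = params$p_thresh, fc_thresh = params$fc_thresh,
    correction = params$correction, var_equal = params$var_equal))
  deg_genes <- deg$gene[deg$is_deg]
  if (length(deg_genes) < 2L) {
    stage("select_degs_check",
          stop(length(deg_genes), " DEG(s) selected; need at least 2 to proceed"))
  }
  note("selected ", length(deg_genes), " DEGs")

  sm <- stage("standardize", standardize_treatment(expr, meta))
  smd <- sm[intersect(deg_genes, rownames(sm)), , drop = FALSE]

  k_eff <- min(params$k_clusters, nrow(smd))
  ca <- stage("cluster", cluster_degs(smd, k_eff))
  dnb <- stage("select_dnb", select_dnb(
    ca, smd, expr, meta, min_size = min(params$min_size, nrow(smd)),
    ratio_thresh = params$ratio_thresh, eps = params$eps))
  note("DNB has ", length(dnb$members), " member gene(s)")

  traj <- stage("tei", tei_trajectory(dnb, expr, meta, eps = params$eps))
  pre_stable <- attr(traj, "pre_stable")

  tps <- traj$timepoint_order
  networks <- stage("networks", lapply(tps, function(t) {
    correlation_network(dnb$members, expr, meta, t,
                        threshold = params$edge_pcc)
  }))
  names(networks) <- paste0("t", tps)
  edge_counts <- data.frame(
    timepoint = tps,
    is_health = traj$is_health,
    n_edges = vapply(networks, function(n) nrow(n$edges), integer(1L)))
  rownames(edge_counts) <- NULL

  summary <- list(
    n_genes = nrow(expr), n_samples = ncol(expr),
    n_deg = length(deg_genes), k_clusters = k_eff,
    dnb_size = length(dnb$members),
    pre_stable = pre_stable,
    distance_to_health = attr(traj, "distance_to_health"),
    edge_counts = stats::setNames(edge_counts$n_edges,
                                  paste0("t", edge_counts$timepoint)),
    tei = stats::setNames(traj$tei, paste0("t", traj$timepoint_order)))

  result <- structure(list(
    deg = deg, standardized = smd, clusters = ca, dnb = dnb,
    trajectory = traj, networks = networks, edge_counts = edge_counts,
    summary = summary, batch_report = batch_report, params = params),
    class = "dnb_pipeline")

  if (!is.null(out_dir)) {
    stage("write_outputs", .write_pipeline_outputs(result, out_dir))
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  result$log <- log_lines
  result
}

.write_pipeline_outputs <- function(result, out_dir) {
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(as.data.frame(result$deg), "deg_table.tsv")
  wt(volcano_table(result$deg), "volcano.tsv")
  writeLines(result$dnb$members, file.path(out_dir, "dnb_members.txt"))
  wt(result$dnb$scores, "cluster_scores.tsv")
  wt(as.data.frame(result$trajectory), "tei_trajectory.tsv")
  wt(result$edge_counts, "edge_counts.tsv")
  for (nm in names(result$networks)) {
    export_network(result$networks[[nm]],
                   file.path(out_dir, paste0("network_", nm, ".graphml")),
                   format = "graphml")
    export_network(result$networks[[nm]],
                   file.path(out_dir, paste0("network_", nm, ".edgelist")),
                   format = "edgelist")
  }
  s <- result$summary
  s$edge_counts <- as.list(s$edge_counts)  # keep names in the JSON object
  s$tei <- as.list(s$tei)
  jsonlite::write_json(s, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  unlink(file.path(out_dir, "FAILED"))
  invisible(out_dir)
}

#' @export
print.dnb_pipeline <- function(x, ...) {
  s <- x$summary
  cat("DNB pipeline run: ", s$n_genes, " genes x ", s$n_samples, " samples\n",
      "  DEGs: ", s$n_deg, "  clusters: ", s$k_clusters,
      "  DNB size: ", s$dnb_size, "\n",
      "  pre-stable state: timepoint ", s$pre_stable,
      " (|TEI - TEI_health| = ", signif(s$distance_to_health, 4), ")\n",
      sep = "")
  print(as.data.frame(x$trajectory), digits = 4)
  invisible(x)
}
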