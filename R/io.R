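#' Read a genes x samples expression matrix
#'
#' Reads a delimited text file whose first column holds gene (or probe)
#' identifiers and whose header row holds sample identifiers. Values are
#' expected to be log2 intensities (or any finite real numbers).
#'
#' @param path Path to a TSV or CSV file.
#' @param dialect `"auto"` (by file extension, default TSV), `"tsv"` or
#'   `"csv"`.
#' @return A numeric matrix with gene ids as row names and sample ids as
#'   column names, in file order.
#' @details Duplicate gene or sample identifiers and non-numeric or
#'   non-finite cells are hard errors that name the offending entry.
#' @seealso [write_expression()], [read_metadata()]
#' @export
read_expression <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("expression file not found: ", path)
  }
  sep <- .dialect_sep(path, dialect)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"")
  if (ncol(df) < 2L) {
    stop("expression file needs an id column plus at least one sample column")
  }
  gene_ids <- as.character(df[[1L]])
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) {
    stop("duplicate gene ids in ", path, ": ", paste(dup_g, collapse = ", "))
  }
  vals <- df[, -1L, drop = FALSE]
  sample_ids <- colnames(vals)
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) {
    stop("duplicate sample ids in ", path, ": ", paste(dup_s, collapse = ", "))
  }
  for (j in seq_along(vals)) {
    x <- vals[[j]]
    if (!is.numeric(x)) {
      num <- suppressWarnings(as.numeric(x))
      bad <- which(is.na(num) & !is.na(x))[1L]
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                   x[bad], gene_ids[bad], sample_ids[j]))
    }
  }
  m <- as.matrix(vals)
  storage.mode(m) <- "double"
  rownames(m) <- gene_ids
  if (anyNA(m) || any(!is.finite(m))) {
    ij <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 gene_ids[ij[1L]], sample_ids[ij[2L]]))
  }
  m
}

#' Write an expression matrix to a delimited text file
#'
#' @param m Numeric matrix, genes x samples, with dimnames.
#' @param path Output path.
#' @param dialect See [read_expression()].
#' @param id_column Header for the identifier column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, dialect = c("auto", "tsv", "csv"),
                             id_column = "gene_id") {
  dialect <- match.arg(dialect)
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  sep <- .dialect_sep(path, dialect)
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(m))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

.dialect_sep <- function(path, dialect) {
  switch(dialect,
         auto = if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t",
         tsv = "\t",
         csv = ",")
}

.meta_columns <- c("sample_id", "group", "timepoint_label",
                   "timepoint_order", "batch")
.meta_groups <- c("control", "treatment", "health")

#' Read sample metadata
#'
#' Reads the per-sample annotation table: which samples are the diagnosis
#' controls, which are treated samples at which ordered timepoint, and
#' which belong to the healthy reference group.
#'
#' @param path Path to a TSV/CSV file with columns `sample_id`, `group`
#'   (one of `control`, `treatment`, `health`), `timepoint_label`,
#'   `timepoint_order` (non-negative integer; strictly increasing along
#'   the stated time axis) and `batch`.
#' @param dialect See [read_expression()].
#' @return A data frame with those five columns.
#' @export
read_metadata <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("metadata file not found: ", path)
  }
  sep <- .dialect_sep(path, dialect)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"")
  missing_cols <- setdiff(.meta_columns, colnames(df))
  if (length(missing_cols)) {
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, .meta_columns]
  df$sample_id <- as.character(df$sample_id)
  df$group <- as.character(df$group)
  df$timepoint_label <- as.character(df$timepoint_label)
  df$batch <- as.character(df$batch)
  .check_metadata(df)
  df
}

.check_metadata <- function(meta) {
  bad_group <- setdiff(unique(meta$group), .meta_groups)
  if (length(bad_group)) {
    stop("unknown group value(s): ", paste(bad_group, collapse = ", "),
         " (expected control/treatment/health)")
  }
  dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
  if (length(dup)) {
    stop("duplicate sample_id in metadata: ", paste(dup, collapse = ", "))
  }
  ord <- meta$timepoint_order
  if (anyNA(ord) || any(ord != round(ord)) || any(ord < 0)) {
    stop("timepoint_order must be non-negative integers")
  }
  meta$timepoint_order <- as.integer(ord)
  ctrl_tp <- unique(meta$timepoint_order[meta$group == "control"])
  if (length(ctrl_tp) > 1L) {
    stop("control samples must share a single timepoint (diagnosis); found orders ",
         paste(ctrl_tp, collapse = ", "))
  }
  trt_tp <- meta$timepoint_order[meta$group == "treatment"]
  hlt_tp <- unique(meta$timepoint_order[meta$group == "health"])
  if (length(hlt_tp) > 1L) {
    stop("health samples must share a single timepoint; found orders ",
         paste(hlt_tp, collapse = ", "))
  }
  if (length(hlt_tp) == 1L && length(trt_tp) && hlt_tp <= max(trt_tp)) {
    stop("the health reference timepoint must come after every treatment timepoint")
  }
  invisible(meta)
}

#' Validate metadata against an expression matrix
#'
#' Checks that every matrix sample is annotated, and returns the metadata
#' restricted to the matrix samples, in matrix column order.
#'
#' @param meta Metadata data frame (see [read_metadata()]).
#' @param m Expression matrix whose columns are sample ids.
#' @return The reordered metadata, invisibly usable as a canonical form.
#' @export
validate_metadata <- function(meta, m) {
  .check_metadata(meta)
  missing <- setdiff(colnames(m), meta$sample_id)
  if (length(missing)) {
    stop("matrix sample(s) missing from metadata: ",
         paste(missing, collapse = ", "))
  }
  out <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out$timepoint_order <- as.integer(out$timepoint_order)
  out
}

#' Collapse a probe-level matrix to gene symbols by averaging
#'
#' Probe sets mapping to the same gene symbol are replaced by the
#' unweighted arithmetic mean of their rows (on the log2 scale); probes
#' without a mapping are dropped.
#'
#' @param m Expression matrix keyed by probe ids.
#' @param probe_map Data frame with columns `probe_id`, `gene_symbol`; a
#'   probe may map to at most one symbol.
#' @return Expression matrix keyed by gene symbol (sorted symbol order).
#' @export
collapse_probes <- function(m, probe_map) {
  stopifnot(is.matrix(m))
  if (!all(c("probe_id", "gene_symbol") %in% colnames(probe_map))) {
    stop("probe_map needs columns probe_id and gene_symbol")
  }
  pm <- probe_map[, c("probe_id", "gene_symbol")]
  pm$probe_id <- as.character(pm$probe_id)
  pm$gene_symbol <- as.character(pm$gene_symbol)
  dup <- unique(pm$probe_id[duplicated(pm$probe_id)])
  if (length(dup)) {
    stop("probe(s) mapped to more than one gene symbol: ",
         paste(dup, collapse = ", "))
  }
  keep <- intersect(rownames(m), pm$probe_id)
  if (!length(keep)) {
    stop("no probe of the matrix appears in the probe map")
  }
  sub <- m[keep, , drop = FALSE]
  grp <- pm$gene_symbol[match(keep, pm$probe_id)]
  sums <- rowsum(sub, group = grp)
  counts <- as.vector(rowsum(rep(1, length(grp)), group = grp))
  out <- sums / counts
  out
}

#' Merge expression datasets on their common genes
#'
#' Keeps the strict intersection of gene identifiers across all inputs
#' (row order taken from the first matrix) and concatenates samples.
#'
#' @param ms List of at least two expression matrices with pairwise
#'   disjoint sample ids.
#' @return The merged expression matrix.
#' @export
merge_datasets <- function(ms) {
  if (!is.list(ms) || length(ms) < 2L) {
    stop("merge_datasets needs a list of at least two matrices")
  }
  all_samples <- unlist(lapply(ms, colnames))
  dup <- unique(all_samples[duplicated(all_samples)])
  if (length(dup)) {
    stop("duplicate sample id(s) across datasets: ", paste(dup, collapse = ", "))
  }
  common <- Reduce(intersect, lapply(ms, rownames))
  if (!length(common)) {
    stop("empty gene intersection across datasets")
  }
  common <- rownames(ms[[1L]])[rownames(ms[[1L]]) %in% common]
  do.call(cbind, lapply(ms, function(x) x[common, , drop = FALSE]))
}

# Sample ids measured at timepoint t (controls excluded: the diagnosis
# group is the standardization reference, not a trajectory point).
samples_at <- function(meta, t, group = NULL) {
  sel <- meta$timepoint_order == t & meta$group != "control"
  if (!is.null(group)) sel <- sel & meta$group %in% group
  meta$sample_id[sel]
}
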