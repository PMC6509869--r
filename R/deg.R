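#' Two-sample Student's t-test for a single gene
#'
#' Thin wrapper around [stats::t.test()] with the equal-variance
#' (Student) statistic by default; Welch is available via `var_equal`.
#'
#' @param control_vals,treat_vals Numeric vectors of length >= 2.
#' @param var_equal Use the pooled-variance Student statistic (default)
#'   or Welch's approximation.
#' @return List with `t_statistic`, `p_value` and `tested`. When the
#'   pooled variance is zero (both groups constant) the test is
#'   undefined: `tested` is `FALSE` and the statistics are `NA`.
#' @export
ttest_gene <- function(control_vals, treat_vals, var_equal = TRUE) {
  if (length(control_vals) < 2L || length(treat_vals) < 2L) {
    stop("each group needs at least 2 samples")
  }
  if (stats::var(control_vals) == 0 && stats::var(treat_vals) == 0) {
    return(list(t_statistic = NA_real_, p_value = NA_real_, tested = FALSE))
  }
  ht <- stats::t.test(treat_vals, control_vals, var.equal = var_equal)
  list(t_statistic = unname(ht$statistic), p_value = ht$p.value,
       tested = TRUE)
}

#' Select differentially expressed genes (t-test + fold change)
#'
#' Tests every gene between the diagnosis controls and a treatment
#' contrast, and flags genes passing both the p-value cutoff and the
#' fold-change cutoff. Fold change is the difference of group means on
#' the log2 scale (treatment minus control), thresholded at
#' `log2(fc_thresh)`.
#'
#' @param m Expression matrix (log2 scale), genes x samples.
#' @param meta Sample metadata (see [read_metadata()]).
#' @param contrast_timepoint `NULL` to pool all treatment samples
#'   (default), or a single `timepoint_order` value restricting the
#'   contrast to that treatment timepoint.
#' @param p_thresh P-value cutoff (default 0.05).
#' @param fc_thresh Fold-change cutoff on the linear scale (default 1.5,
#'   i.e. |log2 FC| >= log2(1.5)).
#' @param correction `"none"` (raw p drives `pass_p`, the default) or
#'   `"BH"` (Benjamini-Hochberg adjusted p drives `pass_p`). The
#'   adjusted column is reported either way.
#' @param var_equal Passed to [ttest_gene()].
#' @return A `deg_table` data frame with one row per gene: `gene`,
#'   `t_statistic`, `p_value`, `adjusted_p`, `log2_fc`, `tested`,
#'   `pass_p`, `pass_fc`, `is_deg`. Genes with zero pooled variance are
#'   retained with `tested = FALSE` and never flagged as DEGs.
#' @export
select_degs <- function(m, meta, contrast_timepoint = NULL,
                        p_thresh = 0.05, fc_thresh = 1.5,
                        correction = c("none", "BH"), var_equal = TRUE) {
  correction <- match.arg(correction)
  stopifnot(p_thresh > 0, p_thresh <= 1, fc_thresh >= 1)
  meta <- validate_metadata(meta, m)
  ctrl <- meta$sample_id[meta$group == "control"]
  if (is.null(contrast_timepoint)) {
    trt <- meta$sample_id[meta$group == "treatment"]
  } else {
    trt <- meta$sample_id[meta$group == "treatment" &
                            meta$timepoint_order == contrast_timepoint]
  }
  if (length(trt) == 0L) stop("empty treatment contrast")
  if (length(ctrl) < 2L || length(trt) < 2L) {
    stop("control and contrast groups each need at least 2 samples")
  }
  genes <- rownames(m)
  mc <- m[, ctrl, drop = FALSE]
  mt <- m[, trt, drop = FALSE]
  res <- vapply(seq_along(genes), function(i) {
    r <- ttest_gene(mc[i, ], mt[i, ], var_equal = var_equal)
    c(r$t_statistic, r$p_value, as.numeric(r$tested))
  }, numeric(3L))
  t_stat <- res[1L, ]
  p_val <- res[2L, ]
  tested <- res[3L, ] > 0
  if (any(!tested)) {
    message("select_degs: ", sum(!tested),
            " gene(s) excluded for zero pooled variance: ",
            paste(utils::head(genes[!tested], 5L), collapse = ", "),
            if (sum(!tested) > 5L) ", ..." else "")
  }
  adj <- rep(NA_real_, length(genes))
  adj[tested] <- stats::p.adjust(p_val[tested], method = "BH")
  lfc <- rowMeans(mt) - rowMeans(mc)
  p_used <- if (correction == "BH") adj else p_val
  pass_p <- tested & !is.na(p_used) & p_used < p_thresh
  pass_fc <- abs(lfc) >= log2(fc_thresh)
  out <- data.frame(
    gene = genes, t_statistic = t_stat, p_value = p_val, adjusted_p = adj,
    log2_fc = lfc, tested = tested, pass_p = pass_p, pass_fc = pass_fc,
    is_deg = pass_p & pass_fc,
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("deg_table", "data.frame")
  attr(out, "params") <- list(p_thresh = p_thresh, fc_thresh = fc_thresh,
                              correction = correction,
                              contrast_timepoint = contrast_timepoint,
                              n_control = length(ctrl), n_treat = length(trt))
  out
}

#' Volcano-plot records from a DEG table
#'
#' @param deg A `deg_table` from [select_degs()].
#' @return Data frame with `gene`, `log2_fc`, `neg_log10_p`, `is_deg`.
#' @export
volcano_table <- function(deg) {
  stopifnot(inherits(deg, "deg_table"))
  data.frame(gene = deg$gene, log2_fc = deg$log2_fc,
             neg_log10_p = -log10(deg$p_value), is_deg = deg$is_deg,
             stringsAsFactors = FALSE)
}
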