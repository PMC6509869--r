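#' Standardize non-control samples against the diagnosis controls
#'
#' Each gene's treatment (and health) values are converted to
#' control-referenced z-scores: `(value - mean(control)) / sd(control)`,
#' with the sample (n-1) SD. Genes whose control SD is zero are excluded
#' and reported.
#'
#' @param m Expression matrix (log2 scale) containing control and
#'   non-control samples.
#' @param meta Sample metadata; >= 2 control samples required.
#' @return Matrix of standardized values for the non-control samples,
#'   columns ordered by `timepoint_order` (treatment timepoints then
#'   health). Attributes `control_mean`, `control_sd` (named per gene)
#'   and `excluded` (zero-SD gene ids) are attached.
#' @export
standardize_treatment <- function(m, meta) {
  meta <- validate_metadata(meta, m)
  ctrl <- meta$sample_id[meta$group == "control"]
  if (length(ctrl) < 2L) stop("standardize_treatment: need >= 2 control samples")
  nc <- meta[meta$group != "control", , drop = FALSE]
  if (!nrow(nc)) stop("standardize_treatment: no non-control samples")
  nc <- nc[order(nc$timepoint_order, match(nc$sample_id, meta$sample_id)), ]
  xc <- m[, ctrl, drop = FALSE]
  mu <- rowMeans(xc)
  sdv <- sqrt(rowSums((xc - mu)^2) / (length(ctrl) - 1L))
  keep <- sdv > 0
  if (!all(keep)) {
    message("standardize_treatment: excluded ", sum(!keep),
            " gene(s) with zero control SD: ",
            paste(utils::head(rownames(m)[!keep], 5L), collapse = ", "),
            if (sum(!keep) > 5L) ", ..." else "")
  }
  if (!any(keep)) stop("standardize_treatment: every gene has zero control SD")
  out <- (m[keep, nc$sample_id, drop = FALSE] - mu[keep]) / sdv[keep]
  attr(out, "control_mean") <- mu[keep]
  attr(out, "control_sd") <- sdv[keep]
  attr(out, "excluded") <- rownames(m)[!keep]
  out
}

#' Hierarchical clustering of DEG profiles by correlation distance
#'
#' Agglomerative clustering of gene profiles (rows) with distance
#' `1 - PCC` and average linkage, cut at exactly `k` clusters.
#'
#' @param sm Standardized matrix restricted to the DEGs (genes x
#'   non-control samples, time-ordered); >= 3 samples required.
#' @param k Number of clusters, `1 <= k <= nrow(sm)`.
#' @return A `cluster_assignment` list: `assignment` (named integer
#'   vector gene -> cluster id in `1..k`), `k`, `linkage`, and the
#'   `hclust` tree.
#' @export
cluster_degs <- function(sm, k) {
  stopifnot(is.matrix(sm))
  if (ncol(sm) < 3L) stop("cluster_degs: need >= 3 samples for correlation")
  if (k < 1L || k > nrow(sm)) {
    stop("cluster_degs: k must be between 1 and the number of genes (",
         nrow(sm), "), got ", k)
  }
  cm <- suppressWarnings(stats::cor(t(sm)))
  if (anyNA(cm)) {
    stop("cluster_degs: constant gene profile(s) make the correlation ",
         "distance undefined: ",
         paste(utils::head(rownames(sm)[apply(is.na(cm), 1L, any)], 5L),
               collapse = ", "))
  }
  d <- stats::as.dist(1 - cm)
  tree <- stats::hclust(d, method = "average")
  assignment <- stats::cutree(tree, k = k)
  structure(list(assignment = assignment, k = as.integer(k),
                 linkage = "average", tree = tree),
            class = "cluster_assignment")
}

#' Composite module index CV x PCC / OPCC at a timepoint
#'
#' The per-cluster score used during DNB selection: the module's average
#' coefficient of variation times its average absolute internal
#' correlation, divided by its average absolute correlation to the rest
#' of the candidate genes. All three components are computed on the raw
#' log2 matrix (see the package vignette for why CV is not taken on
#' standardized values).
#'
#' @param genes Candidate module (>= 2 gene ids).
#' @param sm Standardized candidate matrix; its rownames define the gene
#'   universe, so the out-group is `setdiff(rownames(sm), genes)`.
#' @param raw Expression matrix (log2 scale).
#' @param meta Sample metadata.
#' @param t Timepoint (`timepoint_order`) with >= 3 samples.
#' @param eps Near-zero-mean guard for the CV component.
#' @return The composite index (non-negative real).
#' @export
composite_index <- function(genes, sm, raw, meta, t, eps = 1e-8) {
  if (length(genes) < 2L) stop("composite_index: need >= 2 genes")
  others <- setdiff(rownames(sm), genes)
  if (!length(others)) {
    stop("composite_index: no out-of-module genes in the candidate universe")
  }
  cv <- cv_at(genes, raw, meta, t, eps = eps)
  if (cv == 0) return(0)  # constant module: the correlation part is moot
  pw <- pcc_within(genes, raw, meta, t)
  op <- opcc_between(genes, others, raw, meta, t)
  if (op == 0) stop("composite_index: OPCC is zero at timepoint ", t)
  cv * pw / op
}

#' Select the dynamic network biomarker gene set from clusters
#'
#' Scores each cluster of >= 2 genes by the ratio of its composite index
#' at the first treatment timepoint to its composite index at the
#' healthy reference: a large ratio means strong disease-state
#' covariation that resolves toward the healthy level. Clusters are
#' ranked by this ratio (descending; ties broken by larger cluster, then
#' by lexicographically smallest gene id); the DNB is the union of all
#' clusters with ratio >= `ratio_thresh`, extended down the ranking
#' until it holds at least `min_size` genes.
#'
#' @param ca A `cluster_assignment` from [cluster_degs()].
#' @param sm Standardized candidate matrix (gene universe for the
#'   out-group).
#' @param raw Expression matrix (log2 scale).
#' @param meta Sample metadata (must contain treatment and health
#'   samples).
#' @param min_size Minimum DNB size (default 10).
#' @param ratio_thresh Minimum index ratio for unconditional inclusion
#'   (default 2).
#' @param eps Near-zero-mean guard for the CV component.
#' @return A `dnb_result` list: `members`, `non_members` (the remaining
#'   candidate genes; the two partition the candidate set), `scores`
#'   (per-cluster table with the index at the first treatment timepoint,
#'   at health, the ratio, and selection flags) and the rule parameters.
#' @export
select_dnb <- function(ca, sm, raw, meta, min_size = 10, ratio_thresh = 2,
                       eps = 1e-8) {
  stopifnot(inherits(ca, "cluster_assignment"))
  meta_v <- validate_metadata(meta, raw)
  trt_tp <- meta_v$timepoint_order[meta_v$group == "treatment"]
  hlt_tp <- unique(meta_v$timepoint_order[meta_v$group == "health"])
  if (!length(trt_tp)) stop("select_dnb: no treatment samples")
  if (length(hlt_tp) != 1L) stop("select_dnb: need a healthy reference timepoint")
  t_first <- min(trt_tp)
  universe <- names(ca$assignment)
  if (min_size > length(universe)) {
    stop("select_dnb: min_size (", min_size, ") exceeds the candidate set (",
         length(universe), " genes)")
  }
  clusters <- split(names(ca$assignment), ca$assignment)
  eligible <- clusters[lengths(clusters) >= 2L]
  if (!length(eligible)) stop("select_dnb: no cluster with >= 2 genes")
  score_one <- function(genes) {
    i1 <- composite_index(genes, sm, raw, meta, t_first, eps = eps)
    ih <- composite_index(genes, sm, raw, meta, hlt_tp, eps = eps)
    ratio <- if (ih == 0) {
      if (i1 > 0) Inf else 0
    } else i1 / ih
    c(index_first = i1, index_health = ih, ratio = ratio)
  }
  sc <- t(vapply(eligible, score_one, numeric(3L)))
  scores <- data.frame(
    cluster = as.integer(names(eligible)),
    size = lengths(eligible),
    index_first = sc[, "index_first"],
    index_health = sc[, "index_health"],
    ratio = sc[, "ratio"],
    stringsAsFactors = FALSE, row.names = NULL)
  first_gene <- vapply(eligible, function(g) min(g), character(1L))
  ord <- order(-scores$ratio, -scores$size, first_gene)
  scores <- scores[ord, , drop = FALSE]
  ranked <- eligible[ord]
  members <- character(0)
  selected <- logical(nrow(scores))
  for (i in seq_along(ranked)) {
    if (scores$ratio[i] >= ratio_thresh || length(members) < min_size) {
      members <- c(members, ranked[[i]])
      selected[i] <- TRUE
    } else {
      break
    }
  }
  scores$selected <- selected
  rownames(scores) <- NULL
  structure(list(
    members = sort(members),
    non_members = sort(setdiff(universe, members)),
    scores = scores,
    params = list(min_size = min_size, ratio_thresh = ratio_thresh,
                  first_treatment = t_first, health = hlt_tp)),
    class = "dnb_result")
}

#' @export
print.dnb_result <- function(x, ...) {
  cat("DNB selection: ", length(x$members), " member gene(s), ",
      length(x$non_members), " non-member(s)\n", sep = "")
  cat("cluster scores (index at t=", x$params$first_treatment,
      " / index at health t=", x$params$health, "):\n", sep = "")
  print(x$scores, digits = 4)
  invisible(x)
}
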