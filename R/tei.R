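#' Pearson correlation coefficient between two expression profiles
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return The Pearson correlation, in `[-1, 1]`.
#' @details A constant vector makes the correlation undefined; this is
#'   signalled as a condition of class `dnbtei_constant_input` so callers
#'   can distinguish it from numeric failure.
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop(errorCondition("constant vector: Pearson correlation undefined",
                        class = c("dnbtei_constant_input", "error", "condition")))
  }
  stats::cor(x, y)
}

#' Average coefficient of variation of a gene set at a timepoint
#'
#' The mean over genes of (sample SD across the timepoint's samples)
#' divided by |mean across those samples|, computed on the raw log2
#' matrix. Genes whose absolute mean is below `eps` have an unstable CV
#' and are skipped (reported via a message).
#'
#' @param genes Character vector of gene ids (length >= 1).
#' @param raw Expression matrix (log2 scale).
#' @param meta Sample metadata.
#' @param t Timepoint (`timepoint_order` value); its non-control samples
#'   are used (>= 2 required).
#' @param eps Near-zero-mean guard (default 1e-8).
#' @return The average CV (non-negative real).
#' @export
cv_at <- function(genes, raw, meta, t, eps = 1e-8) {
  s <- samples_at(meta, t)
  if (length(s) < 2L) stop("cv_at: fewer than 2 samples at timepoint ", t)
  if (length(genes) < 1L) stop("cv_at: empty gene set")
  x <- raw[genes, s, drop = FALSE]
  mu <- rowMeans(x)
  sdv <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1L))
  keep <- abs(mu) > eps
  if (!all(keep)) {
    message("cv_at: skipped ", sum(!keep),
            " gene(s) with |mean| <= ", eps, " at timepoint ", t)
  }
  if (!any(keep)) stop("cv_at: every gene has near-zero mean at timepoint ", t)
  mean(sdv[keep] / abs(mu[keep]))
}

#' Average absolute within-set correlation at a timepoint
#'
#' Mean over all unordered gene pairs of |Pearson correlation| across the
#' timepoint's samples. Pairs involving a constant gene are skipped.
#'
#' @inheritParams cv_at
#' @param genes Character vector of >= 2 gene ids.
#' @return Mean absolute pairwise correlation, in `[0, 1]`.
#' @export
pcc_within <- function(genes, raw, meta, t) {
  s <- samples_at(meta, t)
  if (length(s) < 3L) stop("pcc_within: fewer than 3 samples at timepoint ", t)
  if (length(genes) < 2L) stop("pcc_within: need at least 2 genes")
  cm <- suppressWarnings(stats::cor(t(raw[genes, s, drop = FALSE])))
  v <- abs(cm[upper.tri(cm)])
  ok <- !is.na(v)
  if (!all(ok)) {
    message("pcc_within: skipped ", sum(!ok),
            " pair(s) with a constant gene at timepoint ", t)
  }
  if (!any(ok)) stop("pcc_within: no valid gene pair at timepoint ", t)
  mean(v[ok])
}

#' Average absolute cross-correlation between two gene sets
#'
#' Mean over all pairs (i in `genes`, j in `others`) of |Pearson
#' correlation| across the timepoint's samples; the OPCC of the
#' therapeutic effect index. Pairs involving a constant gene are skipped.
#'
#' @inheritParams cv_at
#' @param genes In-module gene ids (non-empty).
#' @param others Out-of-module gene ids (non-empty, disjoint from
#'   `genes`).
#' @return Mean absolute cross-pair correlation, in `[0, 1]`.
#' @export
opcc_between <- function(genes, others, raw, meta, t) {
  s <- samples_at(meta, t)
  if (length(s) < 3L) stop("opcc_between: fewer than 3 samples at timepoint ", t)
  if (!length(genes) || !length(others)) {
    stop("opcc_between: both gene sets must be non-empty")
  }
  overlap <- intersect(genes, others)
  if (length(overlap)) {
    stop("opcc_between: gene sets overlap: ",
         paste(utils::head(overlap, 5L), collapse = ", "))
  }
  cm <- suppressWarnings(stats::cor(t(raw[genes, s, drop = FALSE]),
                                    t(raw[others, s, drop = FALSE])))
  v <- abs(as.vector(cm))
  ok <- !is.na(v)
  if (!all(ok)) {
    message("opcc_between: skipped ", sum(!ok),
            " pair(s) with a constant gene at timepoint ", t)
  }
  if (!any(ok)) stop("opcc_between: no valid cross pair at timepoint ", t)
  mean(v[ok])
}

#' Therapeutic effect index trajectory of a DNB gene set
#'
#' Computes, at every non-control timepoint (treatment timepoints in
#' order, then the healthy reference), the module's average coefficient
#' of variation (CV), average absolute within-module correlation (PCC),
#' average absolute module-to-outside correlation (OPCC), and the
#' therapeutic effect index `TEI = CV * PCC / OPCC`. The pre-stable
#' state is the treatment timepoint minimizing TEI.
#'
#' @param dnb A [select_dnb()] result, or any list with character fields
#'   `members` and `non_members`.
#' @param raw Expression matrix (log2 scale) containing all samples.
#' @param meta Sample metadata.
#' @param eps Near-zero-mean guard passed to [cv_at()].
#' @return A `tei_trajectory` data frame with columns `timepoint_order`,
#'   `timepoint_label`, `is_health`, `cv`, `pcc`, `opcc`, `tei`,
#'   `is_pre_stable`, plus attributes `pre_stable` (the detected
#'   `timepoint_order`) and `distance_to_health` (|TEI at the pre-stable
#'   point - TEI at health|, `NA` without a health group).
#' @details If `dnb$non_members` is empty (the module absorbed every
#'   candidate gene), the out-group falls back to all remaining genes of
#'   `raw`, with a message.
#' @export
tei_trajectory <- function(dnb, raw, meta, eps = 1e-8) {
  members <- dnb$members
  others <- dnb$non_members
  if (length(members) < 2L) stop("tei_trajectory: need >= 2 member genes")
  if (!length(others)) {
    others <- setdiff(rownames(raw), members)
    if (!length(others)) stop("tei_trajectory: no out-of-module genes available")
    message("tei_trajectory: non_members empty; using all ", length(others),
            " remaining genes of the matrix as the out-group")
  }
  meta <- validate_metadata(meta, raw)
  nc <- meta[meta$group != "control", , drop = FALSE]
  if (!nrow(nc)) stop("tei_trajectory: no non-control samples")
  tps <- sort(unique(nc$timepoint_order))
  rows <- lapply(tps, function(t) {
    cv <- cv_at(members, raw, meta, t, eps = eps)
    pw <- pcc_within(members, raw, meta, t)
    op <- opcc_between(members, others, raw, meta, t)
    if (op == 0) stop("tei_trajectory: OPCC is zero at timepoint ", t)
    data.frame(
      timepoint_order = t,
      timepoint_label = nc$timepoint_label[match(t, nc$timepoint_order)],
      is_health = any(nc$group[nc$timepoint_order == t] == "health"),
      cv = cv, pcc = pw, opcc = op, tei = cv * pw / op,
      stringsAsFactors = FALSE)
  })
  traj <- do.call(rbind, rows)
  rownames(traj) <- NULL
  class(traj) <- c("tei_trajectory", "data.frame")
  ps <- detect_pre_stable(traj)
  traj$is_pre_stable <- traj$timepoint_order == ps & !traj$is_health
  attr(traj, "pre_stable") <- as.integer(ps)
  attr(traj, "distance_to_health") <- attr(ps, "distance_to_health")
  traj
}

#' Detect the pre-stable state on a TEI trajectory
#'
#' The pre-stable state is the treatment timepoint with the lowest TEI
#' (the healthy reference is excluded from the argmin); ties resolve to
#' the earliest timepoint.
#'
#' @param traj A `tei_trajectory` data frame (see [tei_trajectory()]).
#' @return The `timepoint_order` of the pre-stable state (integer), with
#'   attribute `distance_to_health` = |TEI(pre-stable) - TEI(health)|
#'   (`NA` when the trajectory has no health point).
#' @export
detect_pre_stable <- function(traj) {
  stopifnot(is.data.frame(traj),
            all(c("timepoint_order", "is_health", "tei") %in% colnames(traj)))
  trt <- traj[!traj$is_health, , drop = FALSE]
  if (!nrow(trt)) stop("detect_pre_stable: no treatment timepoint in trajectory")
  trt <- trt[order(trt$timepoint_order), , drop = FALSE]
  idx <- which.min(trt$tei)  # which.min takes the first minimum: earliest tie
  ps <- as.integer(trt$timepoint_order[idx])
  hlt <- traj$tei[traj$is_health]
  d <- if (length(hlt)) abs(trt$tei[idx] - hlt[1L]) else NA_real_
  structure(ps, distance_to_health = d)
}
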