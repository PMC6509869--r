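#' Log2-transform an expression matrix
#'
#' @param m Numeric expression matrix (linear-scale intensities).
#' @param offset Non-negative pseudo-value added before taking log2.
#' @return Matrix of `log2(m + offset)` values.
#' @export
log2_transform <- function(m, offset = 0) {
  stopifnot(is.matrix(m), is.numeric(offset), length(offset) == 1L, offset >= 0)
  shifted <- m + offset
  if (any(shifted <= 0)) {
    ij <- which(shifted <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "log2_transform: non-positive argument at gene '%s', sample '%s' (value %g, offset %g)",
      rownames(m)[ij[1L]], colnames(m)[ij[2L]], m[ij[1L], ij[2L]], offset))
  }
  log2(shifted)
}

#' Location-scale batch adjustment
#'
#' For each gene, every batch is centered and scaled by its own mean and
#' sample SD, then rescaled to the gene's pooled mean and pooled
#' within-batch SD. This removes additive and multiplicative batch
#' effects deterministically (no empirical-Bayes shrinkage of batch
#' parameters). Genes with zero variance inside some batch skip the
#' scale step (location-only adjustment) and are reported.
#'
#' The pooled SD is the ANOVA-style pooled within-batch SD,
#' `sqrt(sum_b (n_b - 1) s_b^2 / (N - B))`, which makes the operation
#' idempotent and mean-preserving.
#'
#' @param m Expression matrix (log2 scale), genes x samples.
#' @param meta Metadata with a `batch` column (see [read_metadata()]).
#' @return A list with `matrix` (adjusted values, same dimnames) and
#'   `report` (per gene x batch pre/post moments, the method tag, and the
#'   ids of genes whose scale step was skipped).
#' @export
batch_adjust <- function(m, meta) {
  meta <- validate_metadata(meta, m)
  batches <- split(meta$sample_id, meta$batch)
  nb <- lengths(batches)
  if (any(nb < 2L)) {
    stop("batch(es) with fewer than 2 samples: ",
         paste(names(batches)[nb < 2L], collapse = ", "))
  }
  if (length(batches) == 1L) {
    report <- list(method = "identity", scale_skipped = character(0),
                   moments = NULL)
    return(list(matrix = m, report = report))
  }
  n_tot <- ncol(m)
  b_mean <- sapply(batches, function(s) rowMeans(m[, s, drop = FALSE]))
  b_sd <- sapply(batches, function(s) {
    x <- m[, s, drop = FALSE]
    sqrt(rowSums((x - rowMeans(x))^2) / (ncol(x) - 1L))
  })
  pooled_mean <- rowMeans(m)
  pooled_sd <- sqrt(as.vector(b_sd^2 %*% (nb - 1L)) / (n_tot - length(batches)))
  scale_ok <- apply(b_sd > 0, 1L, all) & pooled_sd > 0
  if (any(!scale_ok)) {
    message("batch_adjust: scale step skipped for ", sum(!scale_ok),
            " gene(s) with zero within-batch variance: ",
            paste(utils::head(rownames(m)[!scale_ok], 5L), collapse = ", "),
            if (sum(!scale_ok) > 5L) ", ..." else "")
  }
  out <- m
  for (b in seq_along(batches)) {
    s <- batches[[b]]
    x <- m[, s, drop = FALSE]
    centred <- x - b_mean[, b]
    adj <- centred
    adj[scale_ok, ] <- centred[scale_ok, , drop = FALSE] /
      b_sd[scale_ok, b] * pooled_sd[scale_ok]
    out[, s] <- adj + pooled_mean
  }
  post_mean <- sapply(batches, function(s) rowMeans(out[, s, drop = FALSE]))
  post_sd <- sapply(batches, function(s) {
    x <- out[, s, drop = FALSE]
    sqrt(rowSums((x - rowMeans(x))^2) / (ncol(x) - 1L))
  })
  report <- list(
    method = "locscale",
    scale_skipped = rownames(m)[!scale_ok],
    moments = list(pre_mean = b_mean, pre_sd = b_sd,
                   post_mean = post_mean, post_sd = post_sd,
                   pooled_mean = pooled_mean, pooled_sd = pooled_sd))
  list(matrix = out, report = report)
}
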