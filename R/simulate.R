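#' Configuration for the synthetic time-course generator
#'
#' Builds and validates a generator configuration. The generator plants
#' a correlated, variance-inflated gene module (a shared latent factor
#' with loading `lambda[t]` on the module genes) whose dynamics decay to
#' the healthy level at a known pre-stable timepoint `t_star`, on top of
#' independent background genes — the statistical structure the DNB
#' criteria assume, at desk scale.
#'
#' @param preset `"strong"` (clear planted signal), `"weak"` (reduced
#'   effect sizes) or `"null"` (no planted dynamics: all loadings and
#'   the mean shift are zero).
#' @param ... Named overrides of any configuration field:
#'   `n_genes`, `n_dnb`, `n_timepoints`, `t_star`, `lambda` (length
#'   `n_timepoints`, non-increasing), `lambda_health`, `delta` (log2
#'   mean shift of module genes vs control, applied at timepoints before
#'   `t_star`), `noise_sd`, `baseline_mean`, `baseline_sd`,
#'   `n_control`, `n_per_treat`, `n_health`, `batch_offsets` (named
#'   numeric vector, or `NULL` for a single batch), `seed`.
#' @return A validated `dnb_sim_config` list.
#' @export
dnb_sim_config <- function(preset = c("strong", "weak", "null"), ...) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    strong = list(
      n_genes = 500L, n_dnb = 40L, n_timepoints = 3L, t_star = 3L,
      lambda = c(2.0, 1.0, 0.15), lambda_health = 0.15, delta = -3,
      noise_sd = 0.3, baseline_mean = 7, baseline_sd = 1,
      n_control = 10L, n_per_treat = 10L, n_health = 10L,
      batch_offsets = NULL, seed = 1L),
    weak = list(
      n_genes = 500L, n_dnb = 40L, n_timepoints = 3L, t_star = 3L,
      lambda = c(1.0, 0.6, 0.25), lambda_health = 0.25, delta = -1,
      noise_sd = 0.4, baseline_mean = 7, baseline_sd = 1,
      n_control = 10L, n_per_treat = 10L, n_health = 10L,
      batch_offsets = NULL, seed = 1L),
    null = list(
      n_genes = 500L, n_dnb = 40L, n_timepoints = 3L, t_star = 3L,
      lambda = c(0, 0, 0), lambda_health = 0, delta = 0,
      noise_sd = 0.3, baseline_mean = 7, baseline_sd = 1,
      n_control = 10L, n_per_treat = 10L, n_health = 10L,
      batch_offsets = NULL, seed = 1L))
  cfg$preset <- preset
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_dnb >= 2L, n_dnb < n_genes,
              n_timepoints >= 1L,
              t_star >= 1L, t_star <= n_timepoints,
              length(lambda) == n_timepoints,
              noise_sd > 0, baseline_sd >= 0,
              n_control >= 2L, n_health >= 2L)
    np <- rep_len(n_per_treat, n_timepoints)
    stopifnot(all(np >= 2L))
    if (any(diff(lambda) > 1e-12)) {
      stop("lambda must be non-increasing over treatment timepoints")
    }
    if (cfg$preset == "strong" &&
        abs(lambda[t_star] - lambda_health) > 1e-12) {
      stop("strong preset requires lambda[t_star] == lambda_health")
    }
    if (cfg$preset == "null" && (any(lambda != 0) || lambda_health != 0 ||
                                 delta != 0)) {
      stop("null preset requires lambda == 0 and delta == 0")
    }
    if (!is.null(batch_offsets) &&
        (is.null(names(batch_offsets)) || length(batch_offsets) < 2L)) {
      stop("batch_offsets must be a named numeric vector of >= 2 batches")
    }
  })
  invisible(cfg)
}

#' Catalog of the built-in generator presets
#'
#' @return Named list of validated `dnb_sim_config` objects (`strong`,
#'   `weak`, `null`).
#' @export
preset_catalog <- function() {
  list(strong = dnb_sim_config("strong"),
       weak = dnb_sim_config("weak"),
       null = dnb_sim_config("null"))
}

#' Generate a synthetic treatment time course with a planted DNB module
#'
#' Control samples (diagnosis, timepoint 0) and background genes are
#' baseline plus independent Gaussian noise. Module genes at treatment
#' timepoint `t` receive a log2 mean shift `delta` while `t < t_star`
#' and a shared per-sample latent factor with loading `lambda[t]`,
#' which simultaneously inflates their variance and their pairwise
#' correlation; at and after `t_star` the loading equals the healthy
#' level, so the module's collective dynamics have settled — `t_star` is
#' the planted pre-stable state. Healthy reference samples use the
#' healthy loading. Output is deterministic given `cfg$seed`.
#'
#' @param cfg A `dnb_sim_config` (see [dnb_sim_config()]).
#' @return List with `expr` (genes x samples log2 matrix), `meta`
#'   (sample metadata data frame) and `truth` (list: `dnb_genes`,
#'   `t_star` as a `timepoint_order` value, `health_timepoint`, `config`).
#' @export
simulate_dnb_data <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  T_ <- cfg$n_timepoints
  np <- rep_len(cfg$n_per_treat, T_)
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  dnb <- sort(sample(genes, cfg$n_dnb))
  is_dnb <- genes %in% dnb

  blocks <- list(data.frame(
    sample_id = sprintf("ctrl_%02d", seq_len(cfg$n_control)),
    group = "control", timepoint_label = "diagnosis",
    timepoint_order = 0L, stringsAsFactors = FALSE))
  for (t in seq_len(T_)) {
    blocks[[t + 1L]] <- data.frame(
      sample_id = sprintf("trt%d_%02d", t, seq_len(np[t])),
      group = "treatment", timepoint_label = sprintf("treat_%d", t),
      timepoint_order = t, stringsAsFactors = FALSE)
  }
  blocks[[T_ + 2L]] <- data.frame(
    sample_id = sprintf("hlt_%02d", seq_len(cfg$n_health)),
    group = "health", timepoint_label = "health",
    timepoint_order = T_ + 1L, stringsAsFactors = FALSE)
  meta <- do.call(rbind, blocks)

  baseline <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
  expr <- baseline +
    matrix(stats::rnorm(cfg$n_genes * nrow(meta), sd = cfg$noise_sd),
           nrow = cfg$n_genes)
  rownames(expr) <- genes
  colnames(expr) <- meta$sample_id

  add_factor <- function(sample_ids, loading, shift = 0) {
    z <- stats::rnorm(length(sample_ids))
    expr[is_dnb, sample_ids] <<- expr[is_dnb, sample_ids, drop = FALSE] +
      shift + matrix(loading * z, nrow = sum(is_dnb),
                     ncol = length(sample_ids), byrow = TRUE)
  }
  for (t in seq_len(T_)) {
    ids <- meta$sample_id[meta$timepoint_order == t & meta$group == "treatment"]
    add_factor(ids, cfg$lambda[t], shift = if (t < cfg$t_star) cfg$delta else 0)
  }
  add_factor(meta$sample_id[meta$group == "health"], cfg$lambda_health)

  if (!is.null(cfg$batch_offsets)) {
    meta$batch <- rep_len(names(cfg$batch_offsets), nrow(meta))
    expr <- expr + rep(cfg$batch_offsets[meta$batch], each = cfg$n_genes)
  } else {
    meta$batch <- "b1"
  }
  meta <- meta[, c("sample_id", "group", "timepoint_label",
                   "timepoint_order", "batch")]

  list(expr = expr, meta = meta,
       truth = list(dnb_genes = dnb, t_star = as.integer(cfg$t_star),
                    health_timepoint = T_ + 1L, config = cfg))
}
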