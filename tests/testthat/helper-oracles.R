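# Independent brute-force oracles (textbook formulas, explicit loops) and
# small fixture builders shared across the suite.

oracle_pcc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  num / den
}

oracle_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

oracle_cv <- function(mat) {
  # mean over genes of sd/|mean|, rows = genes
  mean(apply(mat, 1, function(r) oracle_sd(r) / abs(sum(r) / length(r))))
}

oracle_pcc_within <- function(mat) {
  n <- nrow(mat)
  vals <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      vals <- c(vals, abs(oracle_pcc(mat[i, ], mat[j, ])))
    }
  }
  mean(vals)
}

oracle_opcc <- function(mat_a, mat_b) {
  vals <- c()
  for (i in seq_len(nrow(mat_a))) {
    for (j in seq_len(nrow(mat_b))) {
      vals <- c(vals, abs(oracle_pcc(mat_a[i, ], mat_b[j, ])))
    }
  }
  mean(vals)
}

oracle_edges <- function(mat, threshold) {
  genes <- rownames(mat)
  out <- character(0)
  for (i in seq_len(nrow(mat) - 1)) {
    for (j in (i + 1):nrow(mat)) {
      if (abs(oracle_pcc(mat[i, ], mat[j, ])) > threshold) {
        pair <- sort(c(genes[i], genes[j]))
        out <- c(out, paste(pair[1], pair[2]))
      }
    }
  }
  sort(out)
}

jaccard <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

# Metadata for samples all measured at one treatment timepoint (kernel
# tests), with an optional control/health block.
kernel_meta <- function(sample_ids, t = 1L) {
  data.frame(sample_id = sample_ids, group = "treatment",
             timepoint_label = paste0("treat_", t),
             timepoint_order = as.integer(t), batch = "b1",
             stringsAsFactors = FALSE)
}

# Metadata spanning control (order 0), treatment timepoints 1..T and a
# health block; counts given per block.
toy_meta <- function(n_control, n_treat, n_health) {
  T_ <- length(n_treat)
  blocks <- list(data.frame(
    sample_id = sprintf("c%02d", seq_len(n_control)), group = "control",
    timepoint_label = "diagnosis", timepoint_order = 0L, batch = "b1",
    stringsAsFactors = FALSE))
  for (t in seq_len(T_)) {
    blocks[[t + 1]] <- data.frame(
      sample_id = sprintf("t%d_%02d", t, seq_len(n_treat[t])),
      group = "treatment", timepoint_label = sprintf("treat_%d", t),
      timepoint_order = t, batch = "b1", stringsAsFactors = FALSE)
  }
  blocks[[T_ + 2]] <- data.frame(
    sample_id = sprintf("h%02d", seq_len(n_health)), group = "health",
    timepoint_label = "health", timepoint_order = T_ + 1L, batch = "b1",
    stringsAsFactors = FALSE)
  do.call(rbind, blocks)
}

rand_expr <- function(n_genes, sample_ids, seed, mean = 7, sd = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n_genes * length(sample_ids), mean, sd),
              nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)), sample_ids))
  m
}

# The 50-replicate strong-preset pipeline study, cached so several test
# files can assert different aspects without recomputing. A replicate
# whose pipeline errors (a stochastic miss of the DEG filter) counts as
# a failed recovery.
.study_cache <- new.env(parent = emptyenv())

strong_study <- function(seeds = 1:50) {
  key <- paste0("s", paste(range(seeds), collapse = "_"))
  if (!is.null(.study_cache[[key]])) {
    return(.study_cache[[key]])
  }
  reps <- lapply(seeds, function(i) {
    sim <- simulate_dnb_data(dnb_sim_config("strong", seed = i))
    res <- tryCatch(
      suppressMessages(run_pipeline(
        sim$expr, sim$meta,
        pipeline_params(contrast_timepoint = 1, k_clusters = 10))),
      error = function(e) NULL)
    if (is.null(res)) {
      return(list(ok = FALSE))
    }
    ec <- res$edge_counts$n_edges[!res$edge_counts$is_health]
    list(ok = TRUE,
         recovered = res$summary$pre_stable == sim$truth$t_star,
         jaccard = jaccard(res$dnb$members, sim$truth$dnb_genes),
         tei_treat = res$trajectory$tei[!res$trajectory$is_health],
         trajectory = res$trajectory,
         edge_counts_treat = ec)
  })
  .study_cache[[key]] <- reps
  reps
}
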