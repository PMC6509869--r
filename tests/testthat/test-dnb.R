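test_that("standardization is control-referenced z-scoring with (n-1) SD", {
  meta <- toy_meta(3, c(2), 2)
  m <- rand_expr(3, meta$sample_id, seed = 91)
  ctrl <- meta$sample_id[meta$group == "control"]
  m["g001", ctrl] <- c(1, 2, 3)  # mean 2, sample SD 1
  t1 <- meta$sample_id[meta$timepoint_order == 1]
  m["g001", t1] <- c(2, 4)
  m["g002", ctrl] <- 5  # zero control SD: excluded

  expect_message(sm <- standardize_treatment(m, meta), "zero control SD")
  expect_false("g002" %in% rownames(sm))
  expect_equal(unname(sm["g001", t1]), c(0, 2))

  # the control samples themselves z-score to mean 0, SD 1 under the
  # recorded control moments
  mu <- attr(sm, "control_mean")
  sdv <- attr(sm, "control_sd")
  z <- (m[rownames(sm), ctrl] - mu) / sdv
  expect_equal(unname(rowMeans(z)), rep(0, nrow(z)), tolerance = 1e-10)
  expect_equal(unname(apply(z, 1, sd)), rep(1, nrow(z)), tolerance = 1e-10)

  # columns are the non-control samples in time order
  expect_identical(colnames(sm),
                   meta$sample_id[meta$group != "control"])
})

test_that("correlation-distance clustering recovers planted blocks", {
  # two blocks with within-block PCC exactly 1, across-block PCC 0
  s <- sprintf("s%d", 1:4)
  base1 <- c(1, 2, 3, 4)
  base2 <- c(1, -1, -1, 1)  # orthogonal to base1 after centering
  m <- rbind(a1 = base1, a2 = 2 * base1 + 1, b1 = base2, b2 = 3 * base2 - 2)
  colnames(m) <- s
  ca <- cluster_degs(m, 2)
  expect_equal(ca$assignment[["a1"]], ca$assignment[["a2"]])
  expect_equal(ca$assignment[["b1"]], ca$assignment[["b2"]])
  expect_false(ca$assignment[["a1"]] == ca$assignment[["b1"]])

  singletons <- cluster_degs(m, 4)
  expect_equal(sort(unname(singletons$assignment)), 1:4)
  expect_error(cluster_degs(m, 5), "between 1 and")
})

test_that("clustering recovers three correlated blocks almost surely", {
  skip_if_not_installed("mclust")
  hits <- vapply(1:20, function(seed) {
    set.seed(seed)
    truth <- rep(1:3, each = 4)
    z <- matrix(rnorm(3 * 30), 3)
    m <- z[truth, ] * sqrt(0.9) + matrix(rnorm(12 * 30), 12) * sqrt(0.1)
    rownames(m) <- sprintf("g%02d", 1:12)
    colnames(m) <- sprintf("s%d", 1:30)
    ca <- cluster_degs(m, 3)
    mclust::adjustedRandIndex(ca$assignment, truth)
  }, numeric(1))
  expect_gte(mean(hits >= 0.99), 0.95)
})

test_that("the composite index equals its brute-force decomposition", {
  meta <- kernel_meta(sprintf("s%d", 1:6))
  m <- rand_expr(6, meta$sample_id, seed = 97)
  genes <- rownames(m)[1:4]
  got <- composite_index(genes, m, m, meta, 1)
  manual <- oracle_cv(m[genes, ]) * oracle_pcc_within(m[genes, ]) /
    oracle_opcc(m[genes, ], m[5:6, ])
  expect_equal(got, manual, tolerance = 1e-12)

  # invariance under gene and sample relabeling
  perm_g <- sample(nrow(m))
  perm_s <- sample(ncol(m))
  m2 <- m[perm_g, perm_s]
  meta2 <- meta[perm_s, ]
  expect_equal(composite_index(genes, m2, m2, meta2, 1), got,
               tolerance = 1e-12)

  # constant module short-circuits through the zero CV component
  mc <- m
  mc[genes, ] <- 3
  expect_equal(composite_index(genes, mc, mc, meta, 1), 0)
})

test_that("DNB selection finds the planted module and partitions the DEGs", {
  hits <- vapply(1:20, function(i) {
    sim <- simulate_dnb_data(dnb_sim_config("strong", seed = 100 + i))
    # candidate universe: the planted cluster among clusters of
    # unstructured background genes; the ratio rule must pick the
    # planted one (clustering accuracy is covered by its own tests)
    background <- setdiff(rownames(sim$expr), sim$truth$dnb_genes)[1:30]
    sm <- suppressMessages(standardize_treatment(sim$expr, sim$meta))
    smd <- sm[c(sim$truth$dnb_genes, background), , drop = FALSE]
    assignment <- c(rep(1L, 40), rep(2:6, each = 6))
    names(assignment) <- rownames(smd)
    ca <- structure(list(assignment = assignment, k = 6L,
                         linkage = "average", tree = NULL),
                    class = "cluster_assignment")
    dnb <- select_dnb(ca, smd, sim$expr, sim$meta,
                      min_size = 10, ratio_thresh = 2)
    expect_setequal(c(dnb$members, dnb$non_members), rownames(smd))
    expect_length(intersect(dnb$members, dnb$non_members), 0)
    expect_gte(dnb$scores$ratio[dnb$scores$cluster == 1], 2)
    jaccard(dnb$members, sim$truth$dnb_genes)
  }, numeric(1))
  expect_gte(mean(hits >= 0.8), 0.9)
})

test_that("selection ties break by cluster size, then smallest gene id", {
  meta <- toy_meta(2, c(4), 4)
  profile <- c(1, 3, 2, 4)  # same profile at both timepoints
  m <- do.call(rbind, rep(list(c(profile, profile)), 5))
  rownames(m) <- c("d1", "d2", "a1", "a2", "a3")
  m <- m + 0  # identical rows: every pairwise PCC is 1
  colnames(m) <- meta$sample_id[meta$group != "control"]
  full <- cbind(matrix(rnorm(10, 7, 1), 5, 2), m)
  colnames(full) <- meta$sample_id
  rownames(full) <- rownames(m)

  ca <- structure(list(assignment = c(d1 = 1L, d2 = 1L, a1 = 2L, a2 = 2L,
                                      a3 = 2L),
                       k = 2L, linkage = "average", tree = NULL),
                  class = "cluster_assignment")
  # identical statistics in both clusters; ratio_thresh unreachable, so
  # min_size drives selection and the larger cluster wins the tie
  dnb <- select_dnb(ca, m, full, meta, min_size = 2, ratio_thresh = Inf)
  expect_setequal(dnb$members, c("a1", "a2", "a3"))

  ca2 <- structure(list(assignment = c(d1 = 1L, d2 = 1L, a1 = 2L, a2 = 2L),
                        k = 2L, linkage = "average", tree = NULL),
                   class = "cluster_assignment")
  dnb2 <- select_dnb(ca2, m[1:4, ], full[1:4, ], meta, min_size = 2,
                     ratio_thresh = Inf)
  expect_setequal(dnb2$members, c("a1", "a2"))  # lexicographically first

  expect_error(select_dnb(ca, m, full, meta, min_size = 99),
               "min_size")
})
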