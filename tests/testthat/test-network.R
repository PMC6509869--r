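test_that("edges obey the strict |PCC| threshold and carry node SDs", {
  meta <- kernel_meta(sprintf("s%d", 1:4))
  base <- c(1, 2, 3, 4)
  m <- rbind(gA = base, gB = 2 * base + 1, gC = c(1, 3, 2, 4))
  colnames(m) <- meta$sample_id

  net <- correlation_network(c("gA", "gB"), m, meta, 1)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 1)
  expect_equal(net$nodes$sd[net$nodes$gene == "gA"], sd(base))

  # pcc(gA, gC) is exactly 0.8: the strict rule deletes it at its own value
  expect_equal(pcc(m["gA", ], m["gC", ]), 0.8, tolerance = 1e-12)
  at_bound <- correlation_network(c("gA", "gC"), m, meta, 1, threshold = 0.8)
  expect_equal(nrow(at_bound$edges), 0)
  below <- correlation_network(c("gA", "gC"), m, meta, 1, threshold = 0.79)
  expect_equal(nrow(below$edges), 1)

  # constant genes get sd 0 and no edges
  mc <- rbind(m, gD = rep(5, 4))
  netc <- suppressWarnings(correlation_network(rownames(mc), mc, meta, 1,
                                               threshold = 0))
  expect_equal(netc$nodes$sd[netc$nodes$gene == "gD"], 0)
  expect_false(any(netc$edges$from == "gD" | netc$edges$to == "gD"))
})

test_that("edge sets match brute-force enumeration and agree with pcc", {
  set.seed(113)
  meta <- kernel_meta(sprintf("s%d", 1:7))
  for (trial in 1:10) {
    m <- matrix(rnorm(6 * 7), 6,
                dimnames = list(sprintf("g%d", 1:6), meta$sample_id))
    th <- runif(1, 0.1, 0.7)
    net <- correlation_network(rownames(m), m, meta, 1, threshold = th)
    expect_identical(sort(paste(net$edges$from, net$edges$to)),
                     oracle_edges(m, th))
    for (k in seq_len(nrow(net$edges))) {
      expect_equal(net$edges$weight[k],
                   pcc(m[net$edges$from[k], ], m[net$edges$to[k], ]),
                   tolerance = 1e-12)
    }
  }
})

test_that("edge sets shrink monotonically with the threshold", {
  set.seed(127)
  meta <- kernel_meta(sprintf("s%d", 1:6))
  m <- matrix(rnorm(8 * 6), 8,
              dimnames = list(sprintf("g%d", 1:8), meta$sample_id))
  ths <- sort(runif(5, 0, 0.9))
  keys <- lapply(ths, function(th) {
    e <- correlation_network(rownames(m), m, meta, 1, threshold = th)$edges
    paste(e$from, e$to)
  })
  for (i in seq_len(length(ths) - 1)) {
    expect_true(all(keys[[i + 1]] %in% keys[[i]]))
  }
})

test_that("edge-count trajectories track the per-timepoint networks", {
  meta <- toy_meta(2, c(3, 3), 3)
  # exactly orthogonal patterns at every timepoint: zero edges throughout
  p1 <- c(1, 0, -1)
  p2 <- c(1, -2, 1)  # orthogonal to p1
  m <- rbind(gA = rep(p1, 3), gB = rep(p2, 3))
  colnames(m) <- meta$sample_id[meta$group != "control"]
  full <- cbind(matrix(rnorm(4, 7, 1), 2, 2,
                       dimnames = list(rownames(m), NULL)), m)
  colnames(full) <- meta$sample_id
  tr <- edge_count_trajectory(rownames(m), full, meta, timepoints = 1:3,
                              threshold = 0.4)
  expect_equal(tr$n_edges, c(0, 0, 0))
  single <- edge_count_trajectory(rownames(m), full, meta, timepoints = 2)
  expect_equal(nrow(single), 1)
})

test_that("strong-preset DNB networks lose edges along treatment", {
  reps <- strong_study()
  done <- Filter(function(r) r$ok, reps)
  mono <- vapply(done, function(r) all(diff(r$edge_counts_treat) <= 0),
                 logical(1))
  expect_gte(sum(mono) / length(reps), 0.9)
})

test_that("PPI edge lists are normalized and thresholded inclusively", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein1\tprotein2\tcombined_score",
               "A\tB\t650", "B\tC\t700", "C\tD\t900", "D\tE\t1000"), f)
  ppi <- load_ppi_edges(f, 0.7)
  expect_equal(nrow(ppi), 3)  # 700 retained at the boundary
  expect_equal(max(ppi$score), 1.0)

  writeLines(c("protein1\tprotein2\tscore", "A\tB\t900"), f)
  expect_error(load_ppi_edges(f), "missing column")

  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_equal(nrow(load_ppi_edges(empty)), 0)

  # already-normalized scores pass through unscaled
  writeLines(c("protein1\tprotein2\tcombined_score",
               "A\tB\t0.65", "B\tC\t0.95"), f)
  expect_equal(load_ppi_edges(f)$score, 0.95)
})

test_that("networks survive GraphML and edge-list round trips", {
  meta <- kernel_meta(sprintf("s%d", 1:6))
  m <- rand_expr(6, meta$sample_id, seed = 131)
  net <- correlation_network(rownames(m), m, meta, 1, threshold = 0.1)
  expect_gt(nrow(net$edges), 0)

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  doc <- xml2::read_xml(gml)
  expect_equal(xml2::xml_name(doc), "graphml")
  back <- import_network(gml, "graphml")
  expect_setequal(back$nodes$gene, net$nodes$gene)
  expect_identical(back$edges[, c("from", "to")],
                   net$edges[, c("from", "to")])
  expect_equal(back$edges$weight, net$edges$weight, tolerance = 1e-9)
  expect_equal(back$nodes$sd[match(net$nodes$gene, back$nodes$gene)],
               net$nodes$sd, tolerance = 1e-9)

  el <- withr::local_tempfile(fileext = ".edgelist")
  export_network(net, el, "edgelist")
  expect_equal(length(readLines(el)) - 1, nrow(net$edges))
  back2 <- import_network(el, "edgelist")
  expect_identical(back2$edges[, c("from", "to")],
                   net$edges[, c("from", "to")])
  expect_equal(back2$edges$weight, net$edges$weight, tolerance = 1e-9)

  expect_error(export_network(net, gml, "dot"), "arg")
})
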