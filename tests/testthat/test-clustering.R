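test_that("absolute cosine similarity has the metric's defining properties", {
  a <- c(1, 0, -1, 0.5)
  b <- c(0.2, -1, 0.7, 0)
  expect_equal(abs_cos_similarity(a, a), 1)
  expect_equal(abs_cos_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(abs_cos_similarity(a, -a), 1) # parallelism regardless of sign
  expect_equal(abs_cos_similarity(a, b), abs_cos_similarity(b, a))
  expect_equal(abs_cos_similarity(3.7 * a, b), abs_cos_similarity(a, b))
  expect_equal(abs_cos_similarity(-2 * a, b), abs_cos_similarity(a, b))
  s <- abs_cos_similarity(a, b)
  expect_gte(s, 0)
  expect_lte(s, 1)
  expect_error(abs_cos_similarity(c(0, 0), a), "zero")
})

test_that("coverage batching makes quantile groups in descending coverage order", {
  set.seed(2)
  n <- 12000
  ids <- sprintf("u%05d", seq_len(n))
  cov <- stats::runif(n)
  b <- batch_by_coverage(ids, cov, batch_size = 1000, min_batches = 5)
  expect_length(b, 12)
  expect_true(all(lengths(b) == 1000))
  means <- vapply(b, function(x) mean(cov[match(x, ids)]), numeric(1))
  expect_true(all(diff(means) < 0))

  # fewer than min_batches batches: split into 5 quantiles instead
  b5 <- batch_by_coverage(ids[1:3000], cov[1:3000], 1000, 5)
  expect_length(b5, 5)
  expect_true(all(lengths(b5) == 600))

  # degenerate smallness: empties are dropped
  b_small <- batch_by_coverage(ids[1:4], cov[1:4], 1000, 5)
  expect_equal(sum(lengths(b_small)), 4)
  expect_true(all(lengths(b_small) > 0))
})

test_that("noiseless three-chromosome toy is recovered exactly", {
  toy <- toy3_ssf()
  g <- toy3_graph()

  # brute-force oracle: all pairwise similarities from first principles
  ids <- rownames(toy$values)
  sim_oracle <- outer(seq_along(ids), seq_along(ids), Vectorize(function(i, j) {
    abs_cos_similarity(toy$values[i, ], toy$values[j, ])
  }))
  within <- outer(toy$truth, toy$truth, "==")
  expect_true(all(sim_oracle[within] == 1))
  expect_true(all(sim_oracle[!within] < 0.6))

  cl <- cluster_unitigs(toy$ssf, g)
  expect_equal(adjusted_rand_index(cl$cluster, toy$truth[cl$unitig]), 1)
  expect_equal(length(unique(cl$cluster)), 3)
})

test_that("degenerate inputs stay unclustered or form the obvious pair", {
  libs <- paste0("l", 1:6)
  # a single unitig has no partner: UNCLUSTERED
  m1 <- rbind(u1 = c(1, 0, -1, 0, 1, 0))
  colnames(m1) <- libs
  g1 <- assembly_graph(tibble::tibble(unitig = "u1", length = 1e6))
  cl1 <- initial_clustering(make_ssf(m1, channel = "all_reads"), g1)
  expect_true(is.na(cl1$cluster))

  # two identical patterns exceed the creation threshold: one 2-cluster
  m2 <- rbind(u1 = c(1, 0, -1, 0, 1, 0), u2 = c(1, 0, -1, 0, 1, 0))
  colnames(m2) <- libs
  g2 <- assembly_graph(tibble::tibble(unitig = c("u1", "u2"), length = 1e6))
  cl2 <- initial_clustering(make_ssf(m2, channel = "all_reads"), g2)
  expect_equal(cl2$cluster[1], cl2$cluster[2])
  expect_false(any(is.na(cl2$cluster)))
  h <- attr(cl2, "history")
  expect_equal(h$op[1], "create")
  expect_equal(h$similarity[1], 1)
})

test_that("clustering is deterministic and flip-invariant", {
  toy <- toy3_ssf()
  g <- toy3_graph()
  cl_a <- cluster_unitigs(toy$ssf, g)
  cl_b <- cluster_unitigs(toy$ssf, g)
  expect_identical(tibble::as_tibble(cl_a), tibble::as_tibble(cl_b))
  expect_identical(attr(cl_a, "history"), attr(cl_b, "history"))

  # negating any subset of vectors leaves the partition unchanged
  set.seed(5)
  for (i in 1:5) {
    flip <- sample(rownames(toy$values), sample(1:8, 1))
    m <- toy$values
    m[flip, ] <- -m[flip, ]
    cl_f <- cluster_unitigs(make_ssf(m, channel = "all_reads"), g)
    expect_equal(adjusted_rand_index(cl_f$cluster, cl_a$cluster), 1)
  }
})

test_that("refinement dissolves small and under-represented clusters and absorbs singles", {
  libs <- paste0("l", 1:8)
  # component 1: one strong cluster of 4 + 1 unclustered-pattern unitig that
  # is absorbed; component 2: a tiny cluster below min size and below 2% bp
  pat1 <- c(1, 1, 0, -1, 0, 0, 1, 0)
  pat2 <- c(0, -1, 1, 0, 1, -1, 0, 0)
  m <- rbind(
    a1 = pat1, a2 = pat1, a3 = pat1, a4 = pat1,
    a5 = c(0.1, 0, 0, 0, 0, 0, -0.1, 0.2), # noise: never similar to anything
    b1 = pat2, b2 = pat2
  )
  colnames(m) <- libs
  g <- assembly_graph(
    tibble::tibble(
      unitig = rownames(m),
      length = c(rep(25e6, 4), 1e6, 0.5e6, 0.5e6)
    ),
    tibble::tibble(
      from = c("a1", "a2", "a3", "a4", "b1"),
      to = c("a2", "a3", "a4", "a5", "b2")
    )
  )
  ssf <- make_ssf(m, channel = "all_reads")
  cfg <- cluster_config(min_cluster_size = 3, component_frac = 0.02)
  cl0 <- initial_clustering(ssf, g, cfg)
  lab0 <- setNames(cl0$cluster, cl0$unitig)
  expect_false(is.na(lab0[["b1"]])) # the pair clusters initially
  ref <- refine_clusters(cl0, ssf, g, cfg)
  lab <- setNames(ref$cluster, ref$unitig)
  # b-cluster has 2 < min_cluster_size members: dissolved
  expect_true(is.na(lab[["b1"]]) && is.na(lab[["b2"]]))
  # noise unitig a5 is absorbed into the sole cluster of its component
  expect_equal(lab[["a5"]], lab[["a1"]])
})

test_that("cluster labels below the component bp fraction are dropped", {
  libs <- paste0("l", 1:8)
  pat1 <- c(1, 1, 0, -1, 0, 0, 1, 0)
  pat2 <- c(0, -1, 1, 0, 1, -1, 0, 0)
  pat3 <- c(0, 0, 0, 1, 1, 0, 0, 1)
  # one ~193 Mbp component carrying two strong clusters plus a spurious
  # cluster covering only ~1 Mbp (0.5% < 2%)
  m <- rbind(
    a1 = pat1, a2 = pat1, a3 = pat1, a4 = pat1,
    b1 = pat2, b2 = pat2, b3 = pat2, b4 = pat2,
    x1 = pat3, x2 = pat3, x3 = pat3
  )
  colnames(m) <- libs
  ids <- rownames(m)
  g <- assembly_graph(
    tibble::tibble(
      unitig = ids,
      length = c(rep(24e6, 8), rep(1e6 / 3, 3))
    ),
    tibble::tibble(from = ids[-length(ids)], to = ids[-1])
  )
  ssf <- make_ssf(m, channel = "all_reads")
  cfg <- cluster_config(min_cluster_size = 3, component_frac = 0.02)
  cl0 <- initial_clustering(ssf, g, cfg)
  expect_false(any(is.na(cl0$cluster)))
  ref <- refine_clusters(cl0, ssf, g, cfg)
  lab <- setNames(ref$cluster, ref$unitig)
  # the x-cluster covers < 2% of the component's bp on every pass: unclustered
  expect_true(all(is.na(lab[c("x1", "x2", "x3")])))
  expect_false(any(is.na(lab[c("a1", "a2", "a3", "a4", "b1", "b2", "b3", "b4")])))
  expect_false(lab[["a1"]] == lab[["b1"]])
})

test_that("internal adjusted Rand index matches the mclust implementation", {
  skip_if_not_installed("mclust")
  set.seed(9)
  for (i in 1:20) {
    x <- sample(1:4, 30, replace = TRUE)
    y <- sample(1:3, 30, replace = TRUE)
    expect_equal(
      adjusted_rand_index(x, y),
      mclust::adjustedRandIndex(x, y),
      tolerance = 1e-12
    )
  }
})
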