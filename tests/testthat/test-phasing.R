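test_that("the four-library toy reproduces the phase geometry exactly", {
  toy <- toy4_counts(d = 20)
  ssf_p <- compute_ssf(toy$phase)
  members <- attr(ssf_p, "unitig_ids")

  geo <- infer_plane_and_vphase(ssf_p, members, toy$v_clust)
  target <- c(0, 1, 0, -1) / sqrt(2)
  s <- sign(sum(geo$v_phase_raw * target)) # overall sign is arbitrary
  expect_equal(unname(s * geo$v_phase_raw), target, tolerance = 1e-10)
  expect_equal(unname(s * geo$v_phase), c(0, 1, 0, -1))
  expect_lt(abs(sum(geo$v_clust * geo$v_phase_raw)), 1e-8)

  vp <- s * geo$v_phase
  names(vp) <- toy$libs
  mk <- pool_markers(toy$phase, vp, members)
  got <- setNames(paste(mk$hap_a, mk$hap_b), mk$unitig)
  d <- toy$d
  expect_equal(unname(got[c("mat1", "mat2")]), rep(paste(2 * d, 0), 2))
  expect_equal(unname(got[c("pat1", "pat2")]), rep(paste(0, 2 * d), 2))
  expect_equal(unname(got[c("hom1", "hom2")]), rep(paste(d, d), 2))
})

test_that("negating the phase vector swaps the two haplotype labels exactly", {
  toy <- toy4_counts(d = 20)
  members <- attr(compute_ssf(toy$phase), "unitig_ids")
  vp <- c(0, 1, 0, -1)
  names(vp) <- toy$libs
  mk1 <- pool_markers(toy$phase, vp, members)
  mk2 <- pool_markers(toy$phase, -vp, members)
  expect_equal(mk1$hap_a, mk2$hap_b)
  expect_equal(mk1$hap_b, mk2$hap_a)
})

test_that("v_clust is the normalized size-weighted average", {
  libs <- paste0("l", 1:2)
  m <- rbind(u1 = c(1, 0), u2 = c(0, 1))
  colnames(m) <- libs
  ssf <- make_ssf(m, "all_reads")
  v <- compute_v_clust(ssf, c("u1", "u2"), c(u1 = 3, u2 = 1))
  expect_equal(unname(v), c(3, 1) / sqrt(10))

  # identical directions: weights are irrelevant
  m2 <- rbind(u1 = c(0.6, -0.8), u2 = c(0.6, -0.8))
  colnames(m2) <- libs
  v2 <- compute_v_clust(make_ssf(m2, "all_reads"), c("u1", "u2"), c(u1 = 1, u2 = 9))
  expect_equal(unname(v2), c(0.6, -0.8))

  # single unitig: its own unit vector
  v3 <- compute_v_clust(make_ssf(m2[1, , drop = FALSE], "all_reads"), "u1", c(u1 = 5))
  expect_equal(unname(v3), c(0.6, -0.8))
})

test_that("haploid clusters are detected by the PC-variance rule and merged", {
  libs <- paste0("l", 1:8)
  ray <- c(1, -1, 1, 1, -1, 1, -1, -1) / sqrt(8)
  hap <- t(vapply(1:4, function(i) ray * c(1, -1, 1, -1)[i], numeric(8)))
  rownames(hap) <- paste0("x", 1:4)
  mat <- c(1, 1, -1, -1, 1, 1, -1, -1) / sqrt(8)
  pat <- c(1, -1, -1, 1, 1, -1, -1, 1) / sqrt(8)
  dip <- rbind(a1 = mat, a2 = mat, a3 = pat, a4 = pat, a5 = (mat + pat) / sqrt(2))
  m <- rbind(hap, dip)
  colnames(m) <- libs
  clustering <- structure(
    tibble::tibble(
      unitig = rownames(m),
      cluster = c(rep(1L, 4), rep(2L, 5)),
      component = c(rep(1L, 4), rep(2L, 5))
    ),
    next_id = 3L,
    class = c("unitig_clustering", class(tibble::tibble()))
  )
  det <- detect_haploid_clusters(clustering, make_ssf(m))
  expect_true(det$is_haploid[det$cluster == 1])
  expect_false(det$is_haploid[det$cluster == 2])
  expect_gt(det$pc1_var[det$cluster == 1], 0.99)

  merged <- merge_haploid_clusters(clustering, det)
  expect_equal(attr(merged, "haploid_cluster"), 3L)
  expect_true(all(merged$cluster[1:4] == 3L))

  # the variance rule is a conjunction: PC1 = 75% with PC2 = 25% fails
  two_rays <- rbind(
    r1 = c(1, 0, 0, 0, 0, 0, 0, 0), r2 = c(1, 0, 0, 0, 0, 0, 0, 0),
    r3 = c(1, 0, 0, 0, 0, 0, 0, 0), r4 = c(0, 1, 0, 0, 0, 0, 0, 0)
  )
  colnames(two_rays) <- libs
  cl2 <- structure(
    tibble::tibble(unitig = rownames(two_rays), cluster = 1L, component = 1L),
    class = c("unitig_clustering", class(tibble::tibble()))
  )
  det2 <- detect_haploid_clusters(cl2, make_ssf(two_rays))
  expect_equal(det2$pc1_var, 0.75)
  expect_equal(det2$pc2_var, 0.25)
  expect_false(det2$is_haploid)
})

test_that("bisection correction recovers the analytic bisector", {
  libs <- paste0("l", 1:4)
  deg <- pi / 180
  ray <- function(a) c(cos(a * deg), sin(a * deg), 0, 0)
  geo <- structure(
    list(
      v_clust = c(1, 0, 0, 0), v_clust_inplane = c(1, 0, 0, 0),
      v_phase_raw = c(0, 1, 0, 0), v_phase = c(0, 1, 0, 0),
      pc_variance = c(0.6, 0.4), is_haploid = FALSE
    ),
    class = "cluster_geometry"
  )
  m <- rbind(r1 = ray(20), r2 = ray(20), r3 = ray(-40), r4 = ray(-40))
  colnames(m) <- libs
  out <- haploid_bisection_correction(geo, make_ssf(m), rownames(m))
  expect_true(out$is_haploid)
  ang <- atan2(out$v_clust[2], out$v_clust[1])
  expect_equal(ang, -10 * deg, tolerance = 1e-6)
  expect_lt(abs(sum(out$v_clust * out$v_phase_raw)), 1e-8)

  # rays already symmetric about v_clust: the correction is the identity
  m2 <- rbind(r1 = ray(30), r2 = ray(-30))
  colnames(m2) <- libs
  out2 <- haploid_bisection_correction(geo, make_ssf(m2), rownames(m2))
  expect_equal(out2$v_clust, geo$v_clust, tolerance = 1e-12)

  # a single ray (all products one sign) warns and skips
  m3 <- rbind(r1 = ray(20), r2 = ray(25))
  colnames(m3) <- libs
  expect_warning(
    out3 <- haploid_bisection_correction(geo, make_ssf(m3), rownames(m3)),
    "skipped"
  )
  expect_equal(out3$v_clust, geo$v_clust)
})

test_that("the haplotype caller applies the marker and purity thresholds", {
  mk <- tibble::tibble(
    unitig = c("a", "b", "c", "d"),
    hap_a = c(100, 2, 50, 2),
    hap_b = c(2, 100, 50, 1)
  )
  out <- call_haplotypes(mk, phase_config(min_markers = 10, purity = 0.9))
  expect_equal(out$call, c("HAP_A", "HAP_B", "HOMOZYGOUS", "UNASSIGNED"))
})

test_that("plane inference rejects degenerate clusters", {
  libs <- paste0("l", 1:4)
  one_ray <- rbind(u1 = c(1, 0, 0, 0), u2 = c(1, 0, 0, 0))
  colnames(one_ray) <- libs
  expect_error(
    infer_plane_and_vphase(make_ssf(one_ray), c("u1", "u2"), c(1, 0, 0, 0)),
    "haploid"
  )
  single <- one_ray[1, , drop = FALSE]
  expect_error(
    infer_plane_and_vphase(make_ssf(single), "u1", c(1, 0, 0, 0)),
    "at least 2"
  )
})
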