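test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_autosomes = 3, n_libraries = 12, seed = 21)
  s1 <- simulate_strandseq(cfg)
  s2 <- simulate_strandseq(cfg)
  expect_identical(s1$counts_all, s2$counts_all)
  expect_identical(s1$counts_phase, s2$counts_phase)
  expect_identical(s1$truth_unitigs, s2$truth_unitigs)
  expect_identical(s1$truth_states, s2$truth_states)
  s3 <- simulate_strandseq(sim_config(n_autosomes = 3, n_libraries = 12, seed = 22))
  expect_false(identical(s1$counts_all, s3$counts_all))
})

test_that("ground truth respects the strand-inheritance model", {
  sim <- simulate_strandseq(sim_config(n_autosomes = 4, n_libraries = 24, seed = 3))
  st <- sim$truth_states
  # haploid chromosomes carry exactly one homolog
  expect_true(all(is.na(st$state_b[st$chromosome == "chrX"])))
  expect_true(all(is.na(st$state_a[st$chromosome == "chrY"])))
  expect_false(any(is.na(st$state_a[st$chromosome == "chr1"])))
  # matched means equal homolog states
  autos <- st[!st$chromosome %in% c("chrX", "chrY"), ]
  expect_equal(autos$matched, autos$state_a == autos$state_b)
  # strand inheritance is close to fair at 50/50
  p <- mean(autos$state_a == "W")
  expect_lt(abs(p - 0.5), 4 * sqrt(0.25 / nrow(autos)))
  # chain graph: one component per chromosome
  expect_equal(
    length(unique(sim$graph$unitigs$component)),
    length(unique(sim$truth_unitigs$chromosome))
  )
})

test_that("phase-channel SSF expectations match the generative model", {
  # Monte-Carlo at depth 100 over many libraries: a homozygous unitig has
  # |SSF| near 1 in matched libraries and near 0 in unmatched ones
  sim <- simulate_strandseq(sim_config(
    n_autosomes = 2, include_xy = TRUE, n_libraries = 200, depth = 100,
    background_rate = 0, misorientation_rate = 0, seed = 8
  ))
  ssf <- compute_ssf(sim$counts_phase)
  truth <- sim$truth_unitigs
  hom <- truth$unitig[truth$haplotype == "HOM"][1]
  chrom <- truth$chromosome[truth$unitig == hom]
  states <- sim$truth_states[sim$truth_states$chromosome == chrom, ]
  v <- ssf_matrices(ssf, unitigs = hom)$values[1, states$library]
  matched <- states$matched
  expect_true(all(abs(v[matched]) == 1)) # no background: exactly +-1
  # unmatched: mean 0 with sd ~ 1/sqrt(depth) per library
  expect_lt(abs(mean(v[!matched])), 3 / sqrt(100 * sum(!matched)))

  # haploid unitigs: |SSF| = 1 in every library (the 1-D ray signature)
  xu <- truth$unitig[truth$chromosome == "chrX"][1]
  vx <- ssf_matrices(ssf, unitigs = xu)$values[1, ]
  expect_true(all(abs(vx) == 1))

  # two unitigs of the same haplotype and chromosome share their pattern sign
  pair <- truth$unitig[truth$chromosome == "chr1" & truth$haplotype == "A"][1:2]
  vp <- ssf_matrices(ssf, unitigs = pair)$values
  expect_true(all(vp[1, ] == vp[2, ]))
})

test_that("per-cell depth does not depend on the library (exchangeability)", {
  sim <- simulate_strandseq(sim_config(
    n_autosomes = 6, n_libraries = 30, depth = 20, seed = 13
  ))
  m <- count_matrices(sim$counts_phase)
  tot <- m$watson + m$crick
  per_lib <- colMeans(tot)
  expected <- 20 * (1 + 0.05) # depth plus symmetric background
  se <- sqrt(expected / nrow(tot))
  expect_true(all(abs(per_lib - expected) < 5 * se))
})

test_that("misorientation swaps the planted unitig's channels", {
  cfg0 <- sim_config(n_autosomes = 2, n_libraries = 10, misorientation_rate = 0, seed = 5)
  cfg1 <- sim_config(n_autosomes = 2, n_libraries = 10, misorientation_rate = 1, seed = 5)
  s0 <- simulate_strandseq(cfg0)
  s1 <- simulate_strandseq(cfg1)
  expect_true(all(s1$truth_unitigs$misoriented))
  m0 <- count_matrices(s0$counts_all)
  m1 <- count_matrices(s1$counts_all)
  expect_equal(m1$watson, m0$crick)
  expect_equal(m1$crick, m0$watson)
})

test_that("titration sets have the requested composition", {
  libs <- tibble::tibble(
    library = sprintf("lib%03d", 1:192),
    quality = rep(c("high", "low"), each = 96)
  )
  sets <- titrate_quality(libs, 0.5, n_sets = 4, seed = 2)
  expect_length(sets, 4)
  for (s in sets) {
    expect_length(s, 96)
    q <- libs$quality[match(s, libs$library)]
    expect_equal(sum(q == "high"), 48)
    expect_equal(sum(q == "low"), 48)
    expect_false(anyDuplicated(s) > 0)
  }
  expect_gt(length(unique(vapply(sets, paste, character(1), collapse = ","))), 1)

  # full-class compositions admit a single distinct set
  full <- titrate_quality(libs, 1.0, n_sets = 4, seed = 2)
  expect_length(full, 1)
  expect_setequal(full[[1]], libs$library[libs$quality == "high"])

  # infeasible request errors
  expect_error(
    titrate_quality(libs[1:50, ], 1.0, n_sets = 1),
    "Infeasible"
  )
})

test_that("simulation fixtures round-trip through the writers", {
  sim <- simulate_strandseq(sim_config(n_autosomes = 2, n_libraries = 8, seed = 1))
  dir <- withr::local_tempdir()
  write_sim(sim, dir)
  expect_setequal(
    list.files(dir),
    c(
      "counts_all.tsv", "counts_phase.tsv", "truth_unitigs.tsv",
      "truth_states.tsv", "libraries.tsv", "sim.gfa"
    )
  )
  back <- read_counts_tsv(file.path(dir, "counts_all.tsv"),
    unitig_ids = attr(sim$counts_all, "unitig_ids"),
    library_ids = attr(sim$counts_all, "library_ids"),
    channel = "all_reads"
  )
  expect_equal(count_matrices(back), count_matrices(sim$counts_all))
  g <- read_gfa(file.path(dir, "sim.gfa"))
  expect_equal(g$unitigs, sim$graph$unitigs)
})
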