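# Shared fixture builders. Everything is generated in code; the simulation
# fixtures used by several test files are cached per session.

# Build an `ssf` tibble directly from a dense matrix (unitig x library).
make_ssf <- function(m, channel = "phase_informative", weights = NULL) {
  w <- weights %||% matrix(100, nrow(m), ncol(m), dimnames = dimnames(m))
  df <- tibble::tibble(
    unitig = rep(rownames(m), ncol(m)),
    library = rep(colnames(m), each = nrow(m)),
    ssf = as.vector(m),
    weight = as.vector(w)
  )
  structure(df,
    unitig_ids = rownames(m), library_ids = colnames(m), channel = channel,
    class = c("ssf", class(tibble::tibble()))
  )
}

`%||%` <- rlang::`%||%`

# The 4-library worked toy: libraries L1/L3 matched, L2/L4 unmatched.
# Haplotype-A unitigs see Watson in L1/L2, Crick in L3/L4; haplotype-B
# unitigs differ in the unmatched libraries; homozygous unitigs are balanced
# there. Phase-channel depth d per covered cell.
toy4_counts <- function(d = 20) {
  libs <- paste0("L", 1:4)
  row <- function(u, w, c) {
    tibble::tibble(unitig = u, library = libs, watson = w, crick = c)
  }
  phase <- dplyr::bind_rows(
    row("mat1", c(d, d, 0, 0), c(0, 0, d, d)),
    row("mat2", c(d, d, 0, 0), c(0, 0, d, d)),
    row("pat1", c(d, 0, 0, d), c(0, d, d, 0)),
    row("pat2", c(d, 0, 0, d), c(0, d, d, 0)),
    row("hom1", c(d, d / 2, 0, d / 2), c(0, d / 2, d, d / 2)),
    row("hom2", c(d, d / 2, 0, d / 2), c(0, d / 2, d, d / 2))
  )
  all <- dplyr::bind_rows(lapply(
    c("mat1", "mat2", "pat1", "pat2", "hom1", "hom2"),
    function(u) row(u, c(2 * d, d, 0, d), c(0, d, 2 * d, d))
  ))
  list(
    phase = strand_counts(phase, channel = "phase_informative"),
    all = strand_counts(all, channel = "all_reads"),
    v_clust = c(1, 0, -1, 0) / sqrt(2),
    libs = libs,
    d = d
  )
}

# Noiseless 3-chromosome toy: 9 unitigs, 8 libraries, distinct +-1/0 state
# patterns per chromosome; within-chromosome |cos| = 1 exactly and
# cross-chromosome |cos| < 0.6 by construction.
toy3_ssf <- function() {
  libs <- paste0("L", 1:8)
  pat <- rbind(
    chrA = c(1, 1, 1, 1, 0, 0, 0, 0),
    chrB = c(0, 0, 1, -1, 1, -1, 0, 0),
    chrC = c(0, 1, 0, 0, -1, 0, 1, -1)
  )
  m <- pat[rep(1:3, each = 3), ]
  rownames(m) <- paste0("u", 1:9)
  colnames(m) <- libs
  truth <- rep(c("chrA", "chrB", "chrC"), each = 3)
  names(truth) <- rownames(m)
  list(ssf = make_ssf(m, channel = "all_reads"), truth = truth, values = m)
}

toy3_graph <- function() {
  ids <- paste0("u", 1:9)
  assembly_graph(
    tibble::tibble(unitig = ids, length = rep(1e6, 9)),
    tibble::tibble(
      from = c("u1", "u2", "u4", "u5", "u7", "u8"),
      to = c("u2", "u3", "u5", "u6", "u8", "u9")
    )
  )
}

# Study-condition fixtures (defaults of sim_config) cached across test files.
.fixture_cache <- new.env(parent = emptyenv())

study_fixture <- function(seed) {
  key <- paste0("study", seed)
  if (is.null(.fixture_cache[[key]])) {
    sim <- simulate_strandseq(sim_config(seed = seed))
    run <- suppressMessages(
      run_pipeline(sim$graph, sim$counts_all, sim$counts_phase)
    )
    .fixture_cache[[key]] <- list(sim = sim, run = run)
  }
  .fixture_cache[[key]]
}

noiseless_fixture <- function() {
  if (is.null(.fixture_cache$noiseless)) {
    sim <- simulate_strandseq(
      sim_config(background_rate = 0, misorientation_rate = 0.1, seed = 99)
    )
    run <- suppressMessages(
      run_pipeline(sim$graph, sim$counts_all, sim$counts_phase)
    )
    .fixture_cache$noiseless <- list(sim = sim, run = run)
  }
  .fixture_cache$noiseless
}
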