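#' Pipeline configuration
#'
#' One flat key-value configuration covering every stage. Every key has a
#' documented default; [read_run_config()] loads the same keys from a YAML
#' file, with unspecified keys falling back to these defaults.
#'
#' @param min_unitig_length Length filter threshold in bp (default 50000).
#' @param rdna_short_len Short-node threshold for rDNA-tangle removal
#'   (default = `min_unitig_length`).
#' @param tau SSF discretization threshold (default 0.5).
#' @param min_cell_count Minimum reads to call a cell's strand state
#'   (default 5).
#' @param max_unmatched_frac,min_unitigs_per_lib,min_unitig_count Library and
#'   unitig QC thresholds (defaults 0.8, 20, 10).
#' @param sim_threshold_grow,sim_threshold_create,sim_threshold_merge
#'   Clustering similarity thresholds (defaults 0.6).
#' @param batch_size,min_batches Coverage batching (defaults 1000, 5).
#' @param min_cluster_size,component_frac Refinement thresholds
#'   (defaults 3, 0.02).
#' @param flag_margin Orientation low-confidence margin (default 0.1).
#' @param pc1_min,pc2_max Haploid detection thresholds (defaults 0.70, 0.20).
#' @param vphase_rel_threshold Phase-vector discretization (default 0.5).
#' @param min_markers,purity Haplotype caller thresholds (defaults 10, 0.8).
#' @param centered_pca,continuous_weights See [phase_config()].
#' @param seed Seed for any stochastic stage (default 1).
#' @return A list of class `run_config`.
#' @export
run_config <- function(min_unitig_length = 50000,
                       rdna_short_len = min_unitig_length,
                       tau = 0.5,
                       min_cell_count = 5,
                       max_unmatched_frac = 0.8,
                       min_unitigs_per_lib = 20,
                       min_unitig_count = 10,
                       sim_threshold_grow = 0.6,
                       sim_threshold_create = 0.6,
                       sim_threshold_merge = 0.6,
                       batch_size = 1000,
                       min_batches = 5,
                       min_cluster_size = 3,
                       component_frac = 0.02,
                       flag_margin = 0.1,
                       pc1_min = 0.70,
                       pc2_max = 0.20,
                       vphase_rel_threshold = 0.5,
                       min_markers = 10,
                       purity = 0.8,
                       centered_pca = FALSE,
                       continuous_weights = FALSE,
                       seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file of flat `key: value` pairs; keys must be arguments
#'   of [run_config()]. Missing keys take their defaults.
#' @param overrides Named list applied on top of the file (CLI precedence:
#'   overrides > file > defaults).
#' @return A `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    vals <- yaml::read_yaml(path) %||% list()
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) cat("  ", k, ": ", format(x[[k]]), "\n", sep = "")
  invisible(x)
}

as_cluster_config <- function(cfg) {
  cluster_config(
    sim_threshold_grow = cfg$sim_threshold_grow,
    sim_threshold_create = cfg$sim_threshold_create,
    sim_threshold_merge = cfg$sim_threshold_merge,
    batch_size = cfg$batch_size,
    min_batches = cfg$min_batches,
    min_cluster_size = cfg$min_cluster_size,
    component_frac = cfg$component_frac
  )
}

as_phase_config <- function(cfg) {
  phase_config(
    pc1_min = cfg$pc1_min, pc2_max = cfg$pc2_max,
    vphase_rel_threshold = cfg$vphase_rel_threshold,
    min_markers = cfg$min_markers, purity = cfg$purity,
    centered_pca = cfg$centered_pca,
    continuous_weights = cfg$continuous_weights
  )
}

#' Restrict a count table to subsets of unitigs and libraries
#'
#' Used e.g. to run the pipeline on a titrated library subset.
#'
#' @param counts A [strand_counts()] object.
#' @param unitigs,libraries Ids to keep (default: all).
#' @return A restricted [strand_counts()] object.
#' @export
restrict_counts <- function(counts, unitigs = NULL, libraries = NULL) {
  unitigs <- sort(unitigs %||% attr(counts, "unitig_ids"))
  libraries <- sort(libraries %||% attr(counts, "library_ids"))
  keep <- counts$unitig %in% unitigs & counts$library %in% libraries
  strand_counts(
    as_tibble(counts)[keep, , drop = FALSE],
    unitig_ids = unitigs, library_ids = libraries,
    channel = attr(counts, "channel")
  )
}

#' Run the full phasing pipeline
#'
#' Executes, in order: graph reading, rDNA-tangle removal, length filtering,
#' SSF computation, library/unitig QC, chromosome clustering (initial +
#' refinement), orientation correction, haploid-cluster handling, phase
#' geometry inference, marker pooling and haplotype calling.
#'
#' @param graph An `assembly_graph` or a GFA1 path.
#' @param counts_all,counts_phase [strand_counts()] objects or TSV paths for
#'   the two evidence channels (all-reads and phase-informative).
#' @param config A [run_config()].
#' @return A `phase_run` object bundling every stage's result; see
#'   [tidy.phase_run()], [glance.phase_run()], [write_phase_run()].
#' @export
run_pipeline <- function(graph, counts_all, counts_phase,
                         config = run_config()) {
  set.seed(config$seed)
  if (is.character(graph)) graph <- read_gfa(graph)
  if (is.character(counts_all)) {
    counts_all <- read_counts_tsv(counts_all, channel = "all_reads")
  }
  if (is.character(counts_phase)) {
    counts_phase <- read_counts_tsv(counts_phase, channel = "phase_informative")
  }

  graph <- remove_rdna_tangle(graph, short_len = config$rdna_short_len)
  unitig_filter <- filter_by_length(graph, min_length = config$min_unitig_length)
  retained_len <- unitig_filter$unitig[unitig_filter$retained]

  # counts may lack unitigs absent from the graph and vice versa: count on
  # the intersection with the length-retained set
  universe <- sort(intersect(retained_len, attr(counts_all, "unitig_ids")))
  libs <- sort(intersect(
    attr(counts_all, "library_ids"),
    attr(counts_phase, "library_ids")
  ))
  counts_all_r <- restrict_counts(counts_all, universe, libs)

  ssf_all0 <- compute_ssf(counts_all_r)
  states <- discretize_states(ssf_all0,
    tau = config$tau,
    min_cell_count = config$min_cell_count
  )
  qc <- qc_filter(states, counts_all_r,
    max_unmatched_frac = config$max_unmatched_frac,
    min_unitigs_per_lib = config$min_unitigs_per_lib,
    min_unitig_count = config$min_unitig_count
  )
  kept_libs <- qc$libraries$library[qc$libraries$retained]
  kept_unitigs <- qc$unitigs$unitig[qc$unitigs$retained]

  counts_all_q <- restrict_counts(counts_all, kept_unitigs, kept_libs)
  counts_phase_q <- restrict_counts(counts_phase, kept_unitigs, kept_libs)
  ssf_all <- compute_ssf(counts_all_q)
  ssf_phase <- compute_ssf(counts_phase_q)

  ccfg <- as_cluster_config(config)
  clustering <- cluster_unitigs(ssf_all, graph, ccfg)
  orientation <- correct_orientation(clustering, ssf_all,
    flag_margin = config$flag_margin
  )
  phasing <- phase_clusters(
    clustering, orientation, ssf_all, ssf_phase, counts_phase_q, graph,
    as_phase_config(config)
  )

  structure(
    list(
      graph = graph,
      unitig_filter = unitig_filter,
      qc = qc,
      counts_all = counts_all_q,
      counts_phase = counts_phase_q,
      ssf_all = ssf_all,
      ssf_phase = ssf_phase,
      clustering = clustering,
      # per-cluster orientation from the refined clustering; the re-run on the
      # merged haploid cluster (where per-ray signs are arbitrary) is in
      # phasing$orientation and feeds the marker table
      orientation = orientation,
      phasing = phasing,
      config = config
    ),
    class = "phase_run"
  )
}

#' @export
print.phase_run <- function(x, ...) {
  cat("<phase_run>\n")
  print(x$graph)
  print(x$qc)
  print(x$clustering)
  print(x$phasing)
  invisible(x)
}

#' Tidy a phase run
#'
#' @param x A `phase_run`.
#' @param ... Unused.
#' @return The per-unitig marker/call table joined with chromosome cluster
#'   and component labels.
#' @method tidy phase_run
#' @export
tidy.phase_run <- function(x, ...) {
  x$phasing$markers %>%
    left_join(
      x$clustering %>% select("unitig", "component"),
      by = "unitig"
    )
}

#' One-row summary of a phase run
#'
#' @param x A `phase_run`.
#' @param ... Unused.
#' @return A one-row tibble with stage-level counts.
#' @method glance phase_run
#' @export
glance.phase_run <- function(x, ...) {
  dplyr::bind_cols(
    tibble(
      n_unitigs_input = nrow(x$unitig_filter),
      n_unitigs_length_filtered = sum(!x$unitig_filter$retained)
    ),
    glance(x$qc) %>%
      select(
        n_libraries_retained = "n_libraries_retained",
        n_unitigs_qc_retained = "n_unitigs_retained"
      ),
    glance(x$phasing$clustering),
    glance(x$phasing) %>% select(-"n_clusters"),
    tibble(n_flipped = sum(x$orientation$flip))
  )
}

#' Write all stage outputs of a run
#'
#' Writes `unitig_filter.tsv`, `library_qc.tsv`, `unitig_qc.tsv`,
#' `ssf_all_reads.tsv`, `ssf_phase_informative.tsv`, `clusters.tsv`,
#' `cluster_history.log`, `orientation.tsv`, `geometry.tsv`,
#' `marker_counts.tsv` and `summary.json`. The `marker_counts.tsv` columns
#' `node`, `hapA_markers`, `hapB_markers` form the input table expected by
#' graph-threading tools.
#'
#' @param run A `phase_run`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phase_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(
    run$unitig_filter %>% mutate(retained = as.integer(.data$retained)),
    file.path(dir, "unitig_filter.tsv")
  )
  readr::write_tsv(run$qc$libraries, file.path(dir, "library_qc.tsv"))
  readr::write_tsv(run$qc$unitigs, file.path(dir, "unitig_qc.tsv"))
  write_ssf_tsv(run$ssf_all, file.path(dir, "ssf_all_reads.tsv"))
  write_ssf_tsv(run$ssf_phase, file.path(dir, "ssf_phase_informative.tsv"))
  readr::write_tsv(
    as_tibble(run$phasing$clustering),
    file.path(dir, "clusters.tsv")
  )
  hist <- attr(run$phasing$clustering, "history")
  readr::write_tsv(hist, file.path(dir, "cluster_history.log"))
  readr::write_tsv(
    run$phasing$orientation %>%
      mutate(flip = as.integer(.data$flip), flagged = as.integer(.data$flagged)),
    file.path(dir, "orientation.tsv")
  )
  geo <- run$phasing$geometry %>%
    mutate(
      v_clust = vapply(
        .data$v_clust,
        function(v) paste(round(v, 6), collapse = ","), character(1)
      ),
      v_phase = vapply(
        .data$v_phase,
        function(v) paste(v, collapse = ","), character(1)
      ),
      v_phase_raw = vapply(
        .data$v_phase_raw,
        function(v) paste(round(v, 6), collapse = ","), character(1)
      )
    )
  readr::write_tsv(geo, file.path(dir, "geometry.tsv"))
  readr::write_tsv(
    run$phasing$markers %>%
      dplyr::transmute(
        node = .data$unitig,
        hapA_markers = round(.data$hap_a),
        hapB_markers = round(.data$hap_b),
        call = .data$call,
        cluster = .data$cluster,
        flip = as.integer(.data$flip)
      ),
    file.path(dir, "marker_counts.tsv")
  )
  jsonlite::write_json(
    as.list(glance(run)),
    file.path(dir, "summary.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
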