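#' Simulation configuration
#'
#' Describes the generative model of the synthetic Strand-seq generator:
#' each chromosome homolog independently retains its Watson or Crick template
#' strand in each library with probability 1/2; reads from a homolog align in
#' the orientation of the retained strand. Haplotype-specific unitigs draw
#' phase-channel reads exclusively from their own homolog (an idealization of
#' the unique-alignment filter; `leakage_rate` relaxes it), homozygous
#' unitigs from both, and the all-reads channel splits its depth 50/50
#' between homologs for diploid unitigs. Misoriented unitigs have Watson and
#' Crick swapped in both channels; background noise adds symmetric
#' Watson/Crick counts to every cell.
#'
#' @param n_autosomes Number of diploid autosomes (default 22).
#' @param include_xy Add two haploid chromosomes, X carrying haplotype A and
#'   Y haplotype B (default `TRUE`).
#' @param unitigs_per_haplotype Haplotype-specific unitigs per autosome and
#'   haplotype (default 5); haploid chromosomes get the same number.
#' @param homozygous_fraction Fraction of an autosome's unitigs that are
#'   homozygous (collapsed across both haplotypes; default 0.2).
#' @param n_libraries Number of Strand-seq libraries (default 96, a typical
#'   single preparation run).
#' @param depth Expected phase-channel reads per (unitig, library) cell for a
#'   high-quality library (default 20).
#' @param allreads_multiplier All-reads channel depth is this multiple of
#'   `depth` (default 2).
#' @param background_rate Background reads added symmetrically to Watson and
#'   Crick, as a fraction of the channel depth (default 0.05).
#' @param misorientation_rate Fraction of unitigs planted in reverse
#'   orientation (default 0.10).
#' @param library_quality Character vector (`"high"`/`"low"`) per library;
#'   default all high. Low-quality libraries model noisy chemistry:
#'   background scaled by `low_quality_background_factor` (default 6) and
#'   depth by `low_quality_depth_factor` (default 0.5).
#' @param low_quality_background_factor,low_quality_depth_factor See above.
#' @param leakage_rate Fraction of a haplotype-specific unitig's phase-channel
#'   depth drawn from the *other* homolog (default 0: perfect unique-alignment
#'   filtering).
#' @param mean_unitig_length,sd_log_length Unitig lengths are lognormal with
#'   this median (bp, default 1e6) and log-sd (default 0.4), floored at
#'   100 kbp.
#' @param seed Random seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_autosomes = 22, include_xy = TRUE,
                       unitigs_per_haplotype = 5,
                       homozygous_fraction = 0.2,
                       n_libraries = 96,
                       depth = 20,
                       allreads_multiplier = 2,
                       background_rate = 0.05,
                       misorientation_rate = 0.10,
                       library_quality = NULL,
                       low_quality_background_factor = 6,
                       low_quality_depth_factor = 0.5,
                       leakage_rate = 0,
                       mean_unitig_length = 1e6,
                       sd_log_length = 0.4,
                       seed = 1) {
  library_quality <- library_quality %||% rep("high", n_libraries)
  stopifnot(
    n_autosomes >= 1, unitigs_per_haplotype >= 1, n_libraries >= 1,
    depth > 0, allreads_multiplier > 0,
    background_rate >= 0, background_rate <= 1,
    misorientation_rate >= 0, misorientation_rate <= 1,
    homozygous_fraction >= 0, homozygous_fraction < 1,
    leakage_rate >= 0, leakage_rate <= 1,
    length(library_quality) == n_libraries,
    all(library_quality %in% c("high", "low"))
  )
  structure(
    as.list(environment()),
    class = "sim_config"
  )
}

#' Simulate Strand-seq count matrices with planted structure
#'
#' Generates per-(unitig, library) Watson/Crick counts for both evidence
#' channels, the planted ground truth, and a chain-topology assembly graph
#' (one connected component per chromosome: haplotype-A chain, homozygous
#' unitigs, haplotype-B chain linked in sequence). See [sim_config()] for the
#' generative model.
#'
#' @param config A [sim_config()].
#' @return A `strandseq_sim` list:
#'   * `counts_all`, `counts_phase`: [strand_counts()] for the two channels;
#'   * `truth_unitigs`: tibble `unitig`, `chromosome`, `haplotype`
#'     (`A`/`B`/`HOM`), `misoriented`, `length`, `haploid`;
#'   * `truth_states`: tibble `chromosome`, `library`, `state_a`, `state_b`
#'     (`W`/`C`, `NA` for the absent homolog of a haploid chromosome),
#'     `matched`;
#'   * `graph`: an `assembly_graph`;
#'   * `libraries`: tibble `library`, `quality`;
#'   * `config`: the input configuration.
#' @export
simulate_strandseq <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  chroms <- paste0("chr", seq_len(cfg$n_autosomes))
  haploid_chroms <- character(0)
  if (cfg$include_xy) {
    haploid_chroms <- c("chrX", "chrY")
    chroms <- c(chroms, haploid_chroms)
  }
  libs <- sprintf("lib%03d", seq_len(cfg$n_libraries))
  quality <- setNames(cfg$library_quality, libs)

  # per-library effective depth and background rate
  d_lib <- cfg$depth * ifelse(quality == "low", cfg$low_quality_depth_factor, 1)
  bg_lib <- cfg$background_rate *
    ifelse(quality == "low", cfg$low_quality_background_factor, 1)

  # homolog strand states: +1 = Watson template retained, -1 = Crick
  n_chr <- length(chroms)
  SA <- matrix(sample(c(1, -1), n_chr * cfg$n_libraries, replace = TRUE),
    n_chr, cfg$n_libraries,
    dimnames = list(chroms, libs)
  )
  SB <- matrix(sample(c(1, -1), n_chr * cfg$n_libraries, replace = TRUE),
    n_chr, cfg$n_libraries,
    dimnames = list(chroms, libs)
  )
  SA["chrY" == chroms, ] <- NA
  SB["chrX" == chroms, ] <- NA

  # unitig roster
  uph <- cfg$unitigs_per_haplotype
  n_hom <- round(cfg$homozygous_fraction * 2 * uph / (1 - cfg$homozygous_fraction))
  roster <- list()
  for (ch in chroms) {
    if (ch %in% haploid_chroms) {
      hap <- if (ch == "chrX") "A" else "B"
      roster[[ch]] <- tibble(
        chromosome = ch,
        haplotype = rep(hap, uph),
        haploid = TRUE
      )
    } else {
      roster[[ch]] <- tibble(
        chromosome = ch,
        haplotype = c(rep("A", uph), rep("HOM", n_hom), rep("B", uph)),
        haploid = FALSE
      )
    }
  }
  truth <- bind_rows(roster) %>%
    group_by(.data$chromosome) %>%
    mutate(idx = dplyr::row_number()) %>%
    ungroup() %>%
    mutate(
      unitig = sprintf("utg_%s_%02d", sub("^chr", "", .data$chromosome), .data$idx)
    ) %>%
    select(-"idx")
  n_u <- nrow(truth)
  truth$length <- pmax(
    100000,
    round(stats::rlnorm(n_u, log(cfg$mean_unitig_length), cfg$sd_log_length))
  )
  truth$misoriented <- stats::runif(n_u) < cfg$misorientation_rate

  nL <- cfg$n_libraries
  w_all <- matrix(0, n_u, nL, dimnames = list(truth$unitig, libs))
  c_all <- w_all
  w_ph <- w_all
  c_ph <- w_all

  for (i in seq_len(n_u)) {
    ch <- truth$chromosome[i]
    hap <- truth$haplotype[i]
    sA <- SA[ch, ]
    sB <- SB[ch, ]

    # ---- all-reads channel
    lam_all <- cfg$allreads_multiplier * d_lib / 2
    if (truth$haploid[i]) {
      s <- if (hap == "A") sA else sB
      n1 <- rpois(nL, lam_all)
      w_all[i, ] <- n1 * (s == 1)
      c_all[i, ] <- n1 * (s == -1)
    } else {
      n1 <- rpois(nL, lam_all)
      n2 <- rpois(nL, lam_all)
      w_all[i, ] <- n1 * (sA == 1) + n2 * (sB == 1)
      c_all[i, ] <- n1 * (sA == -1) + n2 * (sB == -1)
    }

    # ---- phase-informative channel
    if (hap == "HOM") {
      n1 <- rpois(nL, d_lib / 2)
      n2 <- rpois(nL, d_lib / 2)
      w_ph[i, ] <- n1 * (sA == 1) + n2 * (sB == 1)
      c_ph[i, ] <- n1 * (sA == -1) + n2 * (sB == -1)
    } else {
      own <- if (hap == "A") sA else sB
      oth <- if (hap == "A") sB else sA
      n1 <- rpois(nL, (1 - cfg$leakage_rate) * d_lib)
      w_ph[i, ] <- n1 * (own == 1)
      c_ph[i, ] <- n1 * (own == -1)
      if (cfg$leakage_rate > 0 && !truth$haploid[i]) {
        n2 <- rpois(nL, cfg$leakage_rate * d_lib)
        w_ph[i, ] <- w_ph[i, ] + n2 * (oth == 1)
        c_ph[i, ] <- c_ph[i, ] + n2 * (oth == -1)
      }
    }

    # ---- symmetric background, per channel
    w_all[i, ] <- w_all[i, ] + rpois(nL, bg_lib * cfg$allreads_multiplier * d_lib / 2)
    c_all[i, ] <- c_all[i, ] + rpois(nL, bg_lib * cfg$allreads_multiplier * d_lib / 2)
    w_ph[i, ] <- w_ph[i, ] + rpois(nL, bg_lib * d_lib / 2)
    c_ph[i, ] <- c_ph[i, ] + rpois(nL, bg_lib * d_lib / 2)

    # ---- planted misorientation: swap Watson and Crick in both channels
    if (truth$misoriented[i]) {
      tmp <- w_all[i, ]
      w_all[i, ] <- c_all[i, ]
      c_all[i, ] <- tmp
      tmp <- w_ph[i, ]
      w_ph[i, ] <- c_ph[i, ]
      c_ph[i, ] <- tmp
    }
  }

  to_counts <- function(w, c, channel) {
    nz <- which(w + c > 0, arr.ind = TRUE)
    strand_counts(
      tibble(
        unitig = rownames(w)[nz[, 1]],
        library = colnames(w)[nz[, 2]],
        watson = as.integer(w[nz]),
        crick = as.integer(c[nz])
      ),
      unitig_ids = sort(rownames(w)), library_ids = colnames(w),
      channel = channel
    )
  }

  # chain-topology graph: one component per chromosome
  links <- truth %>%
    group_by(.data$chromosome) %>%
    dplyr::reframe(
      from = .data$unitig[-length(.data$unitig)], to = .data$unitig[-1]
    ) %>%
    mutate(from_orient = "+", to_orient = "+") %>%
    select("from", "from_orient", "to", "to_orient")
  graph <- assembly_graph(
    truth[order(truth$unitig), c("unitig", "length")],
    links
  )

  states <- tidyr::expand_grid(chromosome = chroms, library = libs) %>%
    mutate(
      state_a = ifelse(is.na(SA[cbind(.data$chromosome, .data$library)]), NA,
        ifelse(SA[cbind(.data$chromosome, .data$library)] == 1, "W", "C")
      ),
      state_b = ifelse(is.na(SB[cbind(.data$chromosome, .data$library)]), NA,
        ifelse(SB[cbind(.data$chromosome, .data$library)] == 1, "W", "C")
      ),
      matched = .data$state_a == .data$state_b
    )

  structure(
    list(
      counts_all = to_counts(w_all, c_all, "all_reads"),
      counts_phase = to_counts(w_ph, c_ph, "phase_informative"),
      truth_unitigs = truth[
        order(truth$unitig),
        c("unitig", "chromosome", "haplotype", "misoriented", "length", "haploid")
      ],
      truth_states = states,
      graph = graph,
      libraries = tibble(library = libs, quality = unname(quality)),
      config = cfg
    ),
    class = "strandseq_sim"
  )
}

#' @export
print.strandseq_sim <- function(x, ...) {
  cat(
    "<strandseq_sim> ", nrow(x$truth_unitigs), " unitigs on ",
    length(unique(x$truth_unitigs$chromosome)), " chromosomes, ",
    nrow(x$libraries), " libraries (",
    sum(x$libraries$quality == "high"), " high-quality)\n",
    sep = ""
  )
  invisible(x)
}

#' Sample library sets for a quality titration
#'
#' Builds library sets of a fixed size containing a requested fraction of
#' high-quality libraries, sampling without replacement within each quality
#' class per set. When the requested composition uses a full class exactly
#' (fraction 0 or 1 with a class of exactly `set_size`), only one distinct
#' set exists and a single set is returned.
#'
#' @param libraries Tibble with columns `library` and `quality`
#'   (`"high"`/`"low"`), e.g. the `libraries` element of a
#'   [simulate_strandseq()] result.
#' @param high_fraction Fraction of the set drawn from the high-quality class.
#' @param n_sets Number of sets to sample.
#' @param set_size Set size (default 96, one preparation run).
#' @param seed Random seed.
#' @return A list of character vectors of library ids.
#' @export
titrate_quality <- function(libraries, high_fraction, n_sets, set_size = 96,
                            seed = 1) {
  stopifnot(high_fraction >= 0, high_fraction <= 1, n_sets >= 1)
  high <- sort(libraries$library[libraries$quality == "high"])
  low <- sort(libraries$library[libraries$quality == "low"])
  n_high <- round(high_fraction * set_size)
  n_low <- set_size - n_high
  if (n_high > length(high) || n_low > length(low)) {
    abort(sprintf(
      "Infeasible titration: need %d high and %d low libraries but have %d and %d",
      n_high, n_low, length(high), length(low)
    ))
  }
  set.seed(seed)
  forced <- (n_high == 0 || n_high == length(high)) &&
    (n_low == 0 || n_low == length(low))
  if (forced) {
    return(list(sort(c(
      if (n_high > 0) high else character(0),
      if (n_low > 0) low else character(0)
    ))))
  }
  lapply(seq_len(n_sets), function(i) {
    sort(c(
      sample(high, n_high, replace = FALSE),
      sample(low, n_low, replace = FALSE)
    ))
  })
}

#' Write a simulation to a fixture directory
#'
#' Writes `counts_all.tsv`, `counts_phase.tsv`, `truth_unitigs.tsv`,
#' `truth_states.tsv`, `libraries.tsv` and `sim.gfa`.
#'
#' @param sim A `strandseq_sim`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts_tsv(sim$counts_all, file.path(dir, "counts_all.tsv"))
  write_counts_tsv(sim$counts_phase, file.path(dir, "counts_phase.tsv"))
  readr::write_tsv(sim$truth_unitigs, file.path(dir, "truth_unitigs.tsv"))
  readr::write_tsv(sim$truth_states, file.path(dir, "truth_states.tsv"))
  readr::write_tsv(sim$libraries, file.path(dir, "libraries.tsv"))
  write_gfa(sim$graph, file.path(dir, "sim.gfa"))
  invisible(dir)
}

#' Write an assembly graph as GFA1
#'
#' Segments are written without sequence (`*`) and with an `LN:i:` tag.
#'
#' @param graph An `assembly_graph`.
#' @param path Output path.
#' @export
write_gfa <- function(graph, path) {
  s_lines <- sprintf(
    "S\t%s\t*\tLN:i:%d",
    graph$unitigs$unitig, as.integer(graph$unitigs$length)
  )
  l_lines <- sprintf(
    "L\t%s\t%s\t%s\t%s\t0M",
    graph$links$from, graph$links$from_orient,
    graph$links$to, graph$links$to_orient
  )
  writeLines(c("H\tVN:Z:1.0", s_lines, l_lines), path)
  invisible(path)
}
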