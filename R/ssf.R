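#' Compute strand-state frequencies
#'
#' The strand-state frequency (SSF) of a unitig in a library is
#' `(w - c) / (w + c)` where `w` and `c` are the Watson and Crick alignment
#' counts. A library that inherited a matched (WW/CC) strand state for the
#' unitig's chromosome pair yields an SSF near +1 or -1; an unmatched (WC/CW)
#' state yields an SSF near 0. The vector of SSF values over libraries is the
#' feature used for chromosome clustering and phasing.
#'
#' Cells with zero total count are defined as SSF 0 with weight 0 — "no
#' signal" — which is the unique value that contributes nothing to cosine
#' similarity.
#'
#' @param counts A [strand_counts()] object.
#' @return An `ssf` tibble with columns `unitig`, `library`, `ssf`, `weight`
#'   (`weight = w + c`), carrying the channel and the complete id sets as
#'   attributes. Implicitly absent cells are SSF 0, weight 0.
#' @export
compute_ssf <- function(counts) {
  stopifnot(inherits(counts, "strand_counts"))
  tot <- counts$watson + counts$crick
  out <- tibble(
    unitig = counts$unitig,
    library = counts$library,
    ssf = ifelse(tot > 0, (counts$watson - counts$crick) / tot, 0),
    weight = as.numeric(tot)
  )
  structure(out,
    unitig_ids = attr(counts, "unitig_ids"),
    library_ids = attr(counts, "library_ids"),
    channel = attr(counts, "channel"),
    class = c("ssf", class(tibble()))
  )
}

#' Dense SSF and weight matrices
#'
#' @param ssf An `ssf` tibble from [compute_ssf()].
#' @param unitigs,libraries Optional subsets (and ordering) of the id sets.
#' @return List with matrices `values` and `weights` (unitig x library).
#' @export
ssf_matrices <- function(ssf, unitigs = NULL, libraries = NULL) {
  u <- unitigs %||% attr(ssf, "unitig_ids")
  l <- libraries %||% attr(ssf, "library_ids")
  v <- matrix(0, length(u), length(l), dimnames = list(u, l))
  w <- v
  keep <- ssf$unitig %in% u & ssf$library %in% l
  s <- ssf[keep, , drop = FALSE]
  idx <- cbind(match(s$unitig, u), match(s$library, l))
  v[idx] <- s$ssf
  w[idx] <- s$weight
  list(values = v, weights = w)
}

# Rows scaled to unit norm; all-zero rows stay zero and are reported via the
# "zero_rows" attribute.
unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  zero <- nrm == 0
  nrm[zero] <- 1
  out <- m / nrm
  attr(out, "zero_rows") <- rownames(m)[zero]
  out
}

#' Discretize strand states
#'
#' Calls each (unitig, library) cell `matched` when `|SSF| >= tau`,
#' `unmatched` when `|SSF| < tau` with at least `min_cell_count` reads, and
#' `no_call` when the cell has fewer than `min_cell_count` reads.
#'
#' @param ssf An `ssf` tibble.
#' @param tau Threshold on `|SSF|` in (0, 1); default 0.5.
#' @param min_cell_count Minimum reads to call a state; default 5.
#' @return A tibble `unitig`, `library`, `state` for all cells (including
#'   implicit zero-weight cells, which are `no_call`).
#' @export
discretize_states <- function(ssf, tau = 0.5, min_cell_count = 5) {
  stopifnot(tau > 0, tau < 1)
  m <- ssf_matrices(ssf)
  state <- matrix("no_call", nrow(m$values), ncol(m$values),
    dimnames = dimnames(m$values)
  )
  state[m$weights >= min_cell_count & abs(m$values) >= tau] <- "matched"
  state[m$weights >= min_cell_count & abs(m$values) < tau] <- "unmatched"
  as_tibble(as.table(state), .name_repair = "minimal") %>%
    setNames(c("unitig", "library", "state")) %>%
    as_tibble()
}

#' Library and unitig quality control
#'
#' Each unitig is expected to inherit matched and unmatched strand states in
#' roughly a 50/50 ratio across libraries, so a library calling unmatched for
#' nearly every unitig indicates failed Strand-seq chemistry (no BrdU strand
#' removal) and is discarded. Libraries covering too few unitigs, and unitigs
#' with too few reads across the retained libraries, lack the evidence for a
#' confident call and are discarded too.
#'
#' QC runs on the all-reads channel once; the phase-informative channel
#' inherits the retained library and unitig sets.
#'
#' @param states Output of [discretize_states()].
#' @param counts The matching all-reads [strand_counts()] object.
#' @param max_unmatched_frac Drop a library when its fraction of unmatched
#'   calls among called cells exceeds this (default 0.8).
#' @param min_unitigs_per_lib Drop a library covering (calling a state on)
#'   fewer unitigs than this (default 20).
#' @param min_unitig_count Drop a unitig with fewer total reads than this
#'   across retained libraries (default 10).
#' @return A `strand_qc` object: list with tibbles `libraries`
#'   (`library`, `n_unitigs_covered`, `fraction_unmatched`, `retained`) and
#'   `unitigs` (`unitig`, `total_count`, `retained`).
#' @export
qc_filter <- function(states, counts, max_unmatched_frac = 0.8,
                      min_unitigs_per_lib = 20, min_unitig_count = 10) {
  libs <- states %>%
    group_by(.data$library) %>%
    summarise(
      n_unitigs_covered = sum(.data$state != "no_call"),
      fraction_unmatched = ifelse(
        .data$n_unitigs_covered > 0,
        sum(.data$state == "unmatched") / .data$n_unitigs_covered,
        1
      ),
      .groups = "drop"
    ) %>%
    mutate(retained = .data$fraction_unmatched <= max_unmatched_frac &
      .data$n_unitigs_covered >= min_unitigs_per_lib)
  if (!any(libs$retained)) {
    abort(paste0(
      "All libraries failed QC; review max_unmatched_frac (",
      max_unmatched_frac, ") and min_unitigs_per_lib (", min_unitigs_per_lib, ")"
    ))
  }
  kept_libs <- libs$library[libs$retained]
  m <- count_matrices(counts)
  tot <- rowSums(m$watson[, kept_libs, drop = FALSE]) +
    rowSums(m$crick[, kept_libs, drop = FALSE])
  unitigs <- tibble(
    unitig = names(tot),
    total_count = as.numeric(tot),
    retained = tot >= min_unitig_count
  )
  structure(list(libraries = libs, unitigs = unitigs), class = "strand_qc")
}

#' @export
print.strand_qc <- function(x, ...) {
  cat(
    "<strand_qc> libraries: ", sum(x$libraries$retained), "/",
    nrow(x$libraries), " retained; unitigs: ", sum(x$unitigs$retained), "/",
    nrow(x$unitigs), " retained\n",
    sep = ""
  )
  invisible(x)
}

#' @method tidy strand_qc
#' @export
tidy.strand_qc <- function(x, ...) {
  bind_rows(
    x$libraries %>% mutate(what = "library") %>%
      rename(id = "library"),
    x$unitigs %>% mutate(what = "unitig") %>%
      rename(id = "unitig")
  ) %>%
    select("what", "id", dplyr::everything())
}

#' @method glance strand_qc
#' @export
glance.strand_qc <- function(x, ...) {
  tibble(
    n_libraries = nrow(x$libraries),
    n_libraries_retained = sum(x$libraries$retained),
    n_unitigs = nrow(x$unitigs),
    n_unitigs_retained = sum(x$unitigs$retained)
  )
}

#' Write an SSF table as a unitig x library TSV matrix
#'
#' @param ssf An `ssf` tibble.
#' @param path Output path. Values are written with 6 decimal places.
#' @export
write_ssf_tsv <- function(ssf, path) {
  m <- ssf_matrices(ssf)$values
  df <- as.data.frame(round(m, 6))
  df <- cbind(unitig = rownames(m), df)
  readr::write_tsv(as_tibble(df), path)
  invisible(path)
}
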