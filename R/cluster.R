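#' Clustering configuration
#'
#' Thresholds and batching parameters for the agglomerative absolute-cosine
#' clustering of unitig SSF vectors.
#'
#' The three similarity thresholds default to 0.6: on ideal geometry,
#' same-chromosome similarity tends to 1 while cross-chromosome similarity
#' concentrates near the square root of the matched-library overlap
#' (about 0.5 for independent strand inheritance), so 0.6 separates the two
#' with margin once 48 or more libraries are available.
#'
#' @param sim_threshold_grow Minimum unitig-cluster similarity to attach a
#'   unitig to an existing cluster.
#' @param sim_threshold_create Minimum unitig-unitig similarity to seed a new
#'   two-unitig cluster.
#' @param sim_threshold_merge Minimum cluster-cluster similarity to merge two
#'   clusters.
#' @param batch_size Target coverage-batch size (default 1000).
#' @param min_batches If batching by `batch_size` yields fewer than this many
#'   batches, the unitigs are split into `min_batches` coverage quantiles
#'   instead (default 5).
#' @param min_cluster_size Clusters smaller than this are dissolved during
#'   refinement (default 3).
#' @param component_frac During refinement, cluster labels covering less than
#'   this fraction of a connected component's bp are dropped on that
#'   component (default 0.02).
#' @return A list of class `cluster_config`.
#' @export
cluster_config <- function(sim_threshold_grow = 0.6,
                           sim_threshold_create = 0.6,
                           sim_threshold_merge = 0.6,
                           batch_size = 1000,
                           min_batches = 5,
                           min_cluster_size = 3,
                           component_frac = 0.02) {
  stopifnot(
    sim_threshold_grow > 0, sim_threshold_grow < 1,
    sim_threshold_create > 0, sim_threshold_create < 1,
    sim_threshold_merge > 0, sim_threshold_merge < 1,
    batch_size >= 2, min_batches >= 1,
    min_cluster_size >= 1, component_frac >= 0, component_frac < 1
  )
  structure(
    list(
      sim_threshold_grow = sim_threshold_grow,
      sim_threshold_create = sim_threshold_create,
      sim_threshold_merge = sim_threshold_merge,
      batch_size = batch_size,
      min_batches = min_batches,
      min_cluster_size = min_cluster_size,
      component_frac = component_frac
    ),
    class = "cluster_config"
  )
}

#' Absolute cosine similarity
#'
#' `|cos(a, b)|` between two vectors. Taking the absolute value clusters by
#' parallelism regardless of direction, which makes the metric insensitive to
#' misoriented unitigs (whose SSF vectors are negated).
#'
#' @param a,b Numeric vectors of equal length, each with at least one non-zero
#'   component.
#' @return A number in `[0, 1]`.
#' @export
abs_cos_similarity <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    abort("abs_cos_similarity is undefined for zero vectors; exclude no-signal unitigs")
  }
  min(1, abs(sum(a * b)) / (na * nb))
}

#' Batch unitigs by coverage
#'
#' Unitigs are ranked by coverage (all-reads counts per bp) and split into
#' quantile batches of about `batch_size`, or into `min_batches` equal
#' quantiles when that would produce too few batches. Batches are returned in
#' descending order of mean coverage so clustering is seeded with high-signal
#' unitigs. Ties are broken by unitig id; empty batches are dropped.
#'
#' @param unitigs Character vector of unitig ids.
#' @param coverage Numeric coverage per unitig (reads per bp), parallel to
#'   `unitigs`.
#' @param batch_size,min_batches See [cluster_config()].
#' @return A list of character vectors.
#' @export
batch_by_coverage <- function(unitigs, coverage, batch_size = 1000, min_batches = 5) {
  stopifnot(length(unitigs) == length(coverage))
  n <- length(unitigs)
  if (n == 0L) {
    return(list())
  }
  nb <- ceiling(n / batch_size)
  if (nb < min_batches) nb <- min_batches
  ord <- order(-coverage, unitigs)
  bounds <- round(seq(0, n, length.out = nb + 1))
  batches <- list()
  for (k in seq_len(nb)) {
    idx <- ord[seq_len(n) > bounds[k] & seq_len(n) <= bounds[k + 1]]
    if (length(idx) > 0L) batches[[length(batches) + 1L]] <- unitigs[idx]
  }
  batches
}

# ---- agglomeration engine ----------------------------------------------------
#
# S: absolute-cosine similarity matrix over sorted unitig ids.
# labels: named integer vector (NA = unclustered). Ids with a label are always
# active; batch admission activates unclustered ids. All argmax ties are broken
# lexicographically by (unitig id, cluster id) for determinism.
agglomerate_engine <- function(S, comp_of, batches, labels, next_id, cfg) {
  ids <- rownames(S)
  history <- list()
  log_ev <- function(op, unitig, cluster_a, cluster_b, new_cluster, sim) {
    history[[length(history) + 1L]] <<- list(
      op = op, unitig = unitig, cluster_a = cluster_a,
      cluster_b = cluster_b, new_cluster = new_cluster, similarity = sim
    )
  }
  active <- !is.na(labels)

  members_of <- function() {
    idx <- which(!is.na(labels))
    split(idx, labels[idx])
  }

  best_grow <- function() {
    uncl <- which(active & is.na(labels))
    mem <- members_of()
    if (length(uncl) == 0L || length(mem) == 0L) {
      return(NULL)
    }
    cl_ids <- as.integer(names(mem))
    M <- vapply(mem, function(mi) {
      rowMeans(S[uncl, mi, drop = FALSE])
    }, numeric(length(uncl)))
    M <- matrix(M, nrow = length(uncl), ncol = length(mem))
    mx <- max(M)
    if (mx <= cfg$sim_threshold_grow) {
      return(NULL)
    }
    cand <- which(M == mx, arr.ind = TRUE)
    cand <- cand[order(ids[uncl[cand[, 1]]], cl_ids[cand[, 2]]), , drop = FALSE]
    list(unitig = uncl[cand[1, 1]], cluster = cl_ids[cand[1, 2]], sim = mx)
  }

  best_create <- function() {
    uncl <- which(active & is.na(labels))
    if (length(uncl) < 2L) {
      return(NULL)
    }
    P <- S[uncl, uncl, drop = FALSE]
    diag(P) <- -Inf
    mx <- max(P)
    if (mx <= cfg$sim_threshold_create) {
      return(NULL)
    }
    cand <- which(P == mx, arr.ind = TRUE)
    a <- pmin(cand[, 1], cand[, 2])
    b <- pmax(cand[, 1], cand[, 2])
    o <- order(ids[uncl[a]], ids[uncl[b]])
    list(u1 = uncl[a[o[1]]], u2 = uncl[b[o[1]]], sim = mx)
  }

  best_merge <- function(component_restricted) {
    mem <- members_of()
    if (length(mem) < 2L) {
      return(NULL)
    }
    cl_ids <- as.integer(names(mem))
    k <- length(mem)
    Msim <- matrix(-Inf, k, k)
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        if (component_restricted) {
          ci <- unique(comp_of[mem[[i]]])
          cj <- unique(comp_of[mem[[j]]])
          if (length(intersect(ci, cj)) == 0L) next
        }
        Msim[i, j] <- mean(S[mem[[i]], mem[[j]], drop = FALSE])
      }
    }
    mx <- max(Msim)
    if (mx <= cfg$sim_threshold_merge) {
      return(NULL)
    }
    cand <- which(Msim == mx, arr.ind = TRUE)
    o <- order(cl_ids[cand[, 1]], cl_ids[cand[, 2]])
    list(c1 = cl_ids[cand[o[1], 1]], c2 = cl_ids[cand[o[1], 2]], sim = mx)
  }

  for (batch in batches) {
    active[match(batch, ids)] <- TRUE
    repeat {
      fired <- FALSE
      repeat {
        g <- best_grow()
        if (is.null(g)) break
        labels[g$unitig] <- g$cluster
        fired <- TRUE
        log_ev("grow", ids[g$unitig], g$cluster, NA_integer_, NA_integer_, g$sim)
      }
      cr <- best_create()
      if (!is.null(cr)) {
        labels[c(cr$u1, cr$u2)] <- next_id
        log_ev(
          "create", paste(ids[cr$u1], ids[cr$u2], sep = ","),
          NA_integer_, NA_integer_, next_id, cr$sim
        )
        next_id <- next_id + 1L
        fired <- TRUE
        next
      }
      for (restricted in c(TRUE, FALSE)) {
        repeat {
          mg <- best_merge(restricted)
          if (is.null(mg)) break
          sel <- !is.na(labels) & labels %in% c(mg$c1, mg$c2)
          labels[sel] <- next_id
          log_ev(
            if (restricted) "merge_component" else "merge_global",
            NA_character_, mg$c1, mg$c2, next_id, mg$sim
          )
          next_id <- next_id + 1L
          fired <- TRUE
        }
      }
      if (!fired) break
    }
  }
  list(labels = labels, next_id = next_id, history = history)
}

# Build the |cos| similarity matrix over the non-zero SSF rows of the given
# unitigs (sorted by id). Zero-signal rows are excluded and reported.
similarity_matrix <- function(ssf, unitigs, libraries = NULL) {
  unitigs <- sort(unitigs)
  m <- ssf_matrices(ssf, unitigs = unitigs, libraries = libraries)
  V <- unit_rows(m$values)
  zero <- attr(V, "zero_rows")
  V <- V[!(rownames(V) %in% zero), , drop = FALSE]
  S <- abs(tcrossprod(V))
  S[S > 1] <- 1
  attr(S, "zero_signal") <- zero
  S
}

new_unitig_clustering <- function(labels, ids, comp_of, history, next_id, config,
                                  zero_signal = character(0)) {
  hist_tbl <- if (length(history) > 0L) {
    bind_rows(lapply(history, as_tibble))
  } else {
    tibble(
      op = character(0), unitig = character(0), cluster_a = integer(0),
      cluster_b = integer(0), new_cluster = integer(0), similarity = numeric(0)
    )
  }
  out <- tibble(
    unitig = ids,
    cluster = as.integer(labels[ids]),
    component = as.integer(comp_of[ids])
  )
  structure(out,
    history = hist_tbl, next_id = next_id, config = config,
    zero_signal = zero_signal,
    class = c("unitig_clustering", class(tibble()))
  )
}

#' Initial batched agglomerative clustering
#'
#' Runs the batched agglomerative absolute-cosine clustering: batches of
#' unitigs are admitted in descending coverage order, and within each
#' admission the engine repeatedly (i) grows clusters by attaching the
#' unclustered unitig with the highest mean pairwise similarity to a cluster,
#' (ii) creates a new two-unitig cluster from the best unclustered pair, and
#' (iii) merges the best cluster pair — first restricted to cluster pairs
#' sharing a connected component, then globally. Unitig-cluster and
#' cluster-cluster similarity are the mean pairwise absolute cosine similarity
#' over unit-normalized member SSF vectors. All unclustered unitigs from
#' previously admitted batches remain eligible.
#'
#' Unitigs whose SSF vector is all zero carry no signal and are excluded
#' before clustering (reported in the result's `"zero_signal"` attribute).
#'
#' @param ssf All-reads channel `ssf` tibble (restricted to QC-retained
#'   unitigs and libraries).
#' @param graph An `assembly_graph` providing lengths and component labels.
#' @param config A [cluster_config()].
#' @param unitigs Unitigs to cluster (default: all in `ssf`, intersected with
#'   the graph).
#' @return A `unitig_clustering` tibble (`unitig`, `cluster`, `component`;
#'   `cluster` is `NA` for unclustered unitigs), with the operation history
#'   in attribute `"history"`.
#' @export
initial_clustering <- function(ssf, graph, config = cluster_config(),
                               unitigs = NULL) {
  unitigs <- sort(unitigs %||% intersect(attr(ssf, "unitig_ids"), graph$unitigs$unitig))
  S <- similarity_matrix(ssf, unitigs)
  zero <- attr(S, "zero_signal")
  ids <- rownames(S)
  comp_of <- setNames(graph$unitigs$component, graph$unitigs$unitig)[ids]
  names(comp_of) <- ids
  cov <- coverage_of(ssf, graph, ids)
  batches <- batch_by_coverage(ids, cov, config$batch_size, config$min_batches)
  labels <- setNames(rep(NA_integer_, length(ids)), ids)
  res <- agglomerate_engine(S, comp_of, batches, labels, 1L, config)
  all_ids <- unitigs
  labels_full <- setNames(rep(NA_integer_, length(all_ids)), all_ids)
  labels_full[ids] <- res$labels
  comp_full <- setNames(graph$unitigs$component, graph$unitigs$unitig)[all_ids]
  new_unitig_clustering(
    labels_full, all_ids, comp_full, res$history, res$next_id,
    config,
    zero_signal = zero
  )
}

# all-reads coverage (reads per bp) used for batching
coverage_of <- function(ssf, graph, ids) {
  w <- ssf_matrices(ssf, unitigs = ids)$weights
  len <- setNames(graph$unitigs$length, graph$unitigs$unitig)[ids]
  as.numeric(rowSums(w) / len)
}

#' Refine a clustering
#'
#' Two rounds of cleanup around one round of re-clustering:
#' 1. dissolve clusters smaller than `min_cluster_size`;
#' 2. per connected component, drop cluster labels covering less than
#'    `component_frac` of the component's bp;
#' 3. on components carrying exactly one cluster, absorb the component's
#'    unclustered unitigs into it;
#' 4. re-run the agglomerative engine over all unclustered unitigs (existing
#'    clusters stay and may grow or merge);
#' 5. repeat steps 1-3.
#'
#' @inheritParams initial_clustering
#' @param clustering A `unitig_clustering` from [initial_clustering()].
#' @return A refined `unitig_clustering` with extended history.
#' @export
refine_clusters <- function(clustering, ssf, graph, config = cluster_config()) {
  ids <- clustering$unitig
  labels <- setNames(clustering$cluster, ids)
  comp_of <- setNames(clustering$component, ids)
  len <- setNames(graph$unitigs$length, graph$unitigs$unitig)[ids]
  zero <- attr(clustering, "zero_signal") %||% character(0)
  next_id <- attr(clustering, "next_id") %||% (max(c(0L, labels), na.rm = TRUE) + 1L)
  history <- list()

  cleanup <- function(labels) {
    # (1) minimum cluster size
    sz <- table(labels[!is.na(labels)])
    small <- as.integer(names(sz)[sz < config$min_cluster_size])
    labels[!is.na(labels) & labels %in% small] <- NA_integer_
    # (2) per-component bp fraction
    for (cp in sort(unique(comp_of))) {
      on_comp <- comp_of == cp
      tot_bp <- sum(len[on_comp])
      if (tot_bp == 0) next
      labs_here <- labels[on_comp]
      for (cl in sort(unique(labs_here[!is.na(labs_here)]))) {
        frac <- sum(len[on_comp][!is.na(labs_here) & labs_here == cl]) / tot_bp
        if (frac < config$component_frac) {
          labels[on_comp & !is.na(labels) & labels == cl] <- NA_integer_
        }
      }
      # (3) single-cluster absorption (recount after drops)
      labs_here <- labels[on_comp]
      present <- unique(labs_here[!is.na(labs_here)])
      if (length(present) == 1L) {
        absorb <- on_comp & is.na(labels) & !(ids %in% zero)
        labels[absorb] <- present
      }
    }
    labels
  }

  labels <- cleanup(labels)

  # (4) one more clustering round over unclustered unitigs
  uncl_ids <- ids[is.na(labels) & !(ids %in% zero)]
  S <- similarity_matrix(ssf, ids)
  sids <- rownames(S)
  if (length(uncl_ids) > 0L) {
    cov <- coverage_of(ssf, graph, uncl_ids)
    batches <- batch_by_coverage(uncl_ids, cov, config$batch_size, config$min_batches)
    res <- agglomerate_engine(
      S, comp_of[sids], batches, labels[sids], next_id, config
    )
    labels[sids] <- res$labels
    next_id <- res$next_id
    history <- res$history
  }

  # (5) second cleanup round
  labels <- cleanup(labels)

  out <- new_unitig_clustering(
    labels, ids, comp_of, history, next_id, config,
    zero_signal = zero
  )
  attr(out, "history") <- bind_rows(attr(clustering, "history"), attr(out, "history"))
  out
}

#' Cluster unitigs by chromosome
#'
#' Convenience wrapper running [initial_clustering()] followed by
#' [refine_clusters()].
#'
#' @inheritParams initial_clustering
#' @return A refined `unitig_clustering`.
#' @export
cluster_unitigs <- function(ssf, graph, config = cluster_config(), unitigs = NULL) {
  cl <- initial_clustering(ssf, graph, config, unitigs = unitigs)
  refine_clusters(cl, ssf, graph, config)
}

#' @export
print.unitig_clustering <- function(x, ...) {
  cat(
    "<unitig_clustering> ", nrow(x), " unitigs, ",
    length(unique(x$cluster[!is.na(x$cluster)])), " clusters, ",
    sum(is.na(x$cluster)), " unclustered\n",
    sep = ""
  )
  NextMethod()
}

#' @method tidy unitig_clustering
#' @export
tidy.unitig_clustering <- function(x, ...) {
  as_tibble(x)
}

#' @method glance unitig_clustering
#' @export
glance.unitig_clustering <- function(x, ...) {
  tibble(
    n_unitigs = nrow(x),
    n_clusters = length(unique(x$cluster[!is.na(x$cluster)])),
    n_unclustered = sum(is.na(x$cluster)),
    n_zero_signal = length(attr(x, "zero_signal") %||% character(0)),
    n_operations = nrow(attr(x, "history"))
  )
}
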