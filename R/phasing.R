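#' Phasing configuration
#'
#' @param pc1_min,pc2_max Haploid-cluster detection thresholds on the
#'   proportion of variance explained by the first two principal components
#'   of the phase-channel SSF vectors (defaults 0.70 and 0.20): haploid
#'   clusters point along a single line (PC1 near 100%), diploid clusters
#'   span the chromosome plane.
#' @param vphase_rel_threshold A component of the raw phase vector is
#'   discretized to its sign when its magnitude is at least this fraction of
#'   the largest component magnitude, else to 0 (default 0.5).
#' @param min_markers Minimum pooled markers for a haplotype call
#'   (default 10).
#' @param purity Minimum marker fraction for a HAP_A/HAP_B call
#'   (default 0.8); unitigs above `min_markers` but below purity on both
#'   haplotypes are called homozygous.
#' @param centered_pca Use mean-centered instead of uncentered PCA for the
#'   chromosome plane (default `FALSE`; the geometry reasons about directions
#'   from the origin, and centering would destroy the haploid single-ray
#'   signature — the flag exists for comparison).
#' @param continuous_weights Pool with the continuous `|v_phase_raw|` weights
#'   instead of the discretized ones (default `FALSE`).
#' @return A list of class `phase_config`.
#' @export
phase_config <- function(pc1_min = 0.70, pc2_max = 0.20,
                         vphase_rel_threshold = 0.5,
                         min_markers = 10, purity = 0.8,
                         centered_pca = FALSE,
                         continuous_weights = FALSE) {
  stopifnot(
    pc1_min > 0, pc1_min < 1, pc2_max > 0, pc2_max < 1,
    vphase_rel_threshold > 0, vphase_rel_threshold <= 1,
    min_markers >= 0, purity > 0.5, purity <= 1
  )
  structure(
    list(
      pc1_min = pc1_min, pc2_max = pc2_max,
      vphase_rel_threshold = vphase_rel_threshold,
      min_markers = min_markers, purity = purity,
      centered_pca = centered_pca, continuous_weights = continuous_weights
    ),
    class = "phase_config"
  )
}

# Uncentered PCA of the rows of X: principal directions (columns of v) and
# proportion of variance per component.
pca_uncentered <- function(X, centered = FALSE) {
  if (centered) X <- sweep(X, 2, colMeans(X))
  sv <- svd(X)
  list(
    directions = sv$v,
    var_frac = sv$d^2 / sum(sv$d^2),
    d = sv$d
  )
}

#' Detect haploid chromosome clusters
#'
#' Haploid chromosomes (X and Y in a male sample) carry one homolog, so their
#' unitigs' phase-channel SSF vectors point along a single line and an
#' (uncentered) PCA concentrates nearly all variance in the first component.
#' Diploid clusters contain maternal, paternal and homozygous directions
#' spanning a plane, giving a more balanced variance split. Clusters with
#' PC1 variance above `pc1_min` *and* PC2 variance below `pc2_max` are
#' flagged haploid; all flagged clusters are then merged into a single
#' cluster (so that e.g. the pseudoautosomal region is phased jointly),
#' which must be orientation-corrected again before phasing.
#'
#' Clusters with fewer than two non-zero phase vectors are skipped
#' (not flagged).
#'
#' @param clustering A `unitig_clustering` (post refinement).
#' @param ssf_phase Phase-informative channel `ssf` tibble (orientation
#'   corrected).
#' @param config A [phase_config()].
#' @return A tibble `cluster`, `n_vectors`, `pc1_var`, `pc2_var`,
#'   `is_haploid`.
#' @export
detect_haploid_clusters <- function(clustering, ssf_phase, config = phase_config()) {
  clustered <- clustering %>% filter(!is.na(.data$cluster))
  purrr::map(sort(unique(clustered$cluster)), function(cl) {
    members <- sort(clustered$unitig[clustered$cluster == cl])
    V <- unit_rows(ssf_matrices(ssf_phase, unitigs = members)$values)
    V <- V[!(rownames(V) %in% attr(V, "zero_rows")), , drop = FALSE]
    if (nrow(V) < 2L) {
      return(tibble(
        cluster = cl, n_vectors = nrow(V),
        pc1_var = NA_real_, pc2_var = NA_real_, is_haploid = FALSE
      ))
    }
    p <- pca_uncentered(V, centered = config$centered_pca)
    pc1 <- p$var_frac[1]
    pc2 <- if (length(p$var_frac) >= 2) p$var_frac[2] else 0
    tibble(
      cluster = cl, n_vectors = nrow(V), pc1_var = pc1, pc2_var = pc2,
      is_haploid = pc1 > config$pc1_min && pc2 < config$pc2_max
    )
  }) %>% bind_rows()
}

#' Merge haploid clusters into one
#'
#' @param clustering A `unitig_clustering`.
#' @param haploid Output of [detect_haploid_clusters()].
#' @return The clustering with all haploid clusters relabeled to a single new
#'   cluster id (recorded in the history); attribute `"haploid_cluster"`
#'   holds the merged id (or `NA` if no cluster was flagged).
#' @export
merge_haploid_clusters <- function(clustering, haploid) {
  hap_ids <- haploid$cluster[haploid$is_haploid]
  out <- clustering
  if (length(hap_ids) == 0L) {
    attr(out, "haploid_cluster") <- NA_integer_
    return(out)
  }
  new_id <- (attr(clustering, "next_id") %||%
    (max(clustering$cluster, na.rm = TRUE) + 1L))
  out$cluster[!is.na(out$cluster) & out$cluster %in% hap_ids] <- new_id
  attr(out, "next_id") <- new_id + 1L
  attr(out, "haploid_cluster") <- new_id
  attr(out, "history") <- bind_rows(
    attr(clustering, "history"),
    tibble(
      op = "merge_haploid", unitig = NA_character_,
      cluster_a = hap_ids[1], cluster_b = hap_ids[length(hap_ids)],
      new_cluster = new_id, similarity = NA_real_
    )
  )
  out
}

#' Cluster direction from orientation-corrected vectors
#'
#' The cluster vector `v_clust` is the size-weighted average of the
#' orientation-corrected unit SSF vectors of the cluster's unitigs,
#' normalized. Length weighting prevents differing fragmentation between
#' haplotypes from skewing the direction.
#'
#' @param ssf_all Orientation-corrected all-reads `ssf` tibble.
#' @param members Unitig ids of the cluster.
#' @param lengths Named vector of unitig lengths (bp).
#' @return A unit-norm numeric vector over the libraries of `ssf_all`.
#' @export
compute_v_clust <- function(ssf_all, members, lengths) {
  V <- unit_rows(ssf_matrices(ssf_all, unitigs = sort(members))$values)
  live <- setdiff(rownames(V), attr(V, "zero_rows"))
  V <- V[live, , drop = FALSE]
  if (nrow(V) == 0L) {
    abort("compute_v_clust: no non-zero vectors in cluster")
  }
  w <- as.numeric(lengths[live])
  v <- colSums(V * w)
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) {
    abort("compute_v_clust: size-weighted vectors cancel; cluster is unphasable")
  }
  v / nv
}

#' Infer the chromosome plane and the phase vector
#'
#' The phase-channel SSF vectors of a diploid cluster lie in the 2-D
#' "chromosome plane" spanned by the cluster direction and the phase
#' direction (the difference between the maternal and paternal haplotype
#' vectors). The plane is estimated as the first two principal directions of
#' the phase-channel unit vectors; `v_clust` is projected into the plane and
#' rotated 90 degrees (counterclockwise in plane coordinates) to obtain the
#' raw phase vector, which is orthogonal to `v_clust` by construction. The
#' raw vector is discretized per component to -1/0/+1 (see
#' [phase_config()]); its non-zero components mark the phase-informative
#' (unmatched strand state) libraries and their signs fix the Watson/Crick
#' to haplotype assignment. The overall sign is arbitrary: negating
#' `v_phase` swaps the two haplotype labels (parentage is unknown).
#'
#' @param ssf_phase Orientation-corrected phase-channel `ssf` tibble.
#' @param members Unitig ids of the cluster.
#' @param v_clust Cluster direction from [compute_v_clust()].
#' @param config A [phase_config()].
#' @return A `cluster_geometry` list: `v_clust`, `plane_basis` (library x 2
#'   matrix), `v_phase_raw`, `v_phase`, `pc_variance` (length-2), plus
#'   `is_haploid = FALSE` placeholder.
#' @export
infer_plane_and_vphase <- function(ssf_phase, members, v_clust,
                                   config = phase_config()) {
  V <- unit_rows(ssf_matrices(ssf_phase, unitigs = sort(members))$values)
  V <- V[!(rownames(V) %in% attr(V, "zero_rows")), , drop = FALSE]
  if (nrow(V) < 2L) {
    abort("infer_plane_and_vphase: need at least 2 non-zero phase vectors")
  }
  p <- pca_uncentered(V, centered = config$centered_pca)
  if (length(p$d) < 2L || p$d[2] < 1e-10 * p$d[1]) {
    abort(paste0(
      "infer_plane_and_vphase: second principal component is singular; ",
      "this cluster looks haploid and should go through the haploid path"
    ))
  }
  B <- p$directions[, 1:2, drop = FALSE]
  rownames(B) <- colnames(V)
  pr <- drop(crossprod(B, v_clust)) # in-plane coordinates of v_clust
  npr <- sqrt(sum(pr^2))
  if (npr < 1e-12) {
    abort("infer_plane_and_vphase: v_clust is orthogonal to the chromosome plane")
  }
  pr <- pr / npr
  rot <- c(-pr[2], pr[1]) # 90 deg counterclockwise in plane coordinates
  v_phase_raw <- drop(B %*% rot)
  geometry <- list(
    v_clust = v_clust,
    plane_basis = B,
    v_clust_inplane = drop(B %*% pr),
    v_phase_raw = v_phase_raw,
    v_phase = discretize_vphase(v_phase_raw, config$vphase_rel_threshold),
    pc_variance = p$var_frac[1:2],
    is_haploid = FALSE
  )
  structure(geometry, class = "cluster_geometry")
}

discretize_vphase <- function(v, rel_threshold) {
  thr <- rel_threshold * max(abs(v))
  out <- sign(v)
  out[abs(v) < thr] <- 0
  out
}

#' Balance the phase geometry of the merged haploid cluster
#'
#' Haploid chromosomes usually differ in size, so the size-weighted cluster
#' direction is rotated away from the line bisecting the two chromosomes'
#' rays. Each unitig vector is projected into the chromosome plane and
#' expressed in the (`v_clust`, `v_phase`) basis; the unitigs with the
#' largest and smallest coordinate product are taken as representatives of
#' the two rays, and the basis is rotated so that `v_clust` bisects them.
#' The phase vector is re-derived by 90 degree rotation and re-discretized.
#'
#' When all coordinate products share a sign (a single ray: one haploid
#' chromosome) the correction is skipped with a warning.
#'
#' @param geometry A `cluster_geometry` for the merged haploid cluster.
#' @param ssf_phase Orientation-corrected phase-channel `ssf` tibble.
#' @param members Unitig ids of the merged cluster.
#' @param config A [phase_config()].
#' @return The corrected `cluster_geometry` (`is_haploid = TRUE`).
#' @export
haploid_bisection_correction <- function(geometry, ssf_phase, members,
                                         config = phase_config()) {
  V <- unit_rows(ssf_matrices(ssf_phase, unitigs = sort(members))$values)
  V <- V[!(rownames(V) %in% attr(V, "zero_rows")), , drop = FALSE]
  b1 <- geometry$v_clust_inplane / sqrt(sum(geometry$v_clust_inplane^2))
  b2 <- geometry$v_phase_raw
  c1 <- drop(V %*% b1)
  c2 <- drop(V %*% b2)
  prod <- c1 * c2
  geometry$is_haploid <- TRUE
  if (max(prod) <= 0 || min(prod) >= 0) {
    warn(paste0(
      "haploid_bisection_correction: coordinate products do not straddle ",
      "zero (single haploid ray?); correction skipped"
    ))
    return(geometry)
  }
  i_max <- which.max(prod)
  i_min <- which.min(prod)
  theta_plus <- atan2(c2[i_max], c1[i_max])
  theta_minus <- atan2(c2[i_min], c1[i_min])
  delta <- (theta_plus + theta_minus) / 2
  b1_new <- cos(delta) * b1 + sin(delta) * b2
  b2_new <- -sin(delta) * b1 + cos(delta) * b2
  geometry$v_clust <- b1_new
  geometry$v_clust_inplane <- b1_new
  geometry$v_phase_raw <- b2_new
  geometry$v_phase <- discretize_vphase(b2_new, config$vphase_rel_threshold)
  geometry
}

#' Pool haplotype-informative reads into marker counts
#'
#' Libraries with a phase-vector value of -1 assign Watson reads to the
#' opposite haplotype from libraries with value +1, so their Watson and Crick
#' counts are swapped first; then each unitig's haplotype-A markers are the
#' dot product of its (swapped) Watson counts with `|v_phase|` and the
#' haplotype-B markers the same with the Crick counts. Only libraries with a
#' non-zero phase-vector component — the unmatched strand state libraries —
#' contribute.
#'
#' @param counts_phase Orientation-corrected phase-channel [strand_counts()]
#'   (restricted to retained libraries).
#' @param v_phase Discretized phase vector named by library (or a
#'   `cluster_geometry`, whose `v_phase` is used). With
#'   `continuous_weights` in the config, pass `v_phase_raw` weights instead.
#' @param members Unitig ids of the cluster.
#' @return A tibble `unitig`, `hap_a`, `hap_b`.
#' @export
pool_markers <- function(counts_phase, v_phase, members) {
  if (inherits(v_phase, "cluster_geometry")) v_phase <- v_phase$v_phase
  m <- count_matrices(counts_phase)
  libs <- colnames(m$watson)
  if (is.null(names(v_phase))) {
    stopifnot(length(v_phase) == length(libs))
    names(v_phase) <- libs
  }
  vp <- v_phase[libs]
  vp[is.na(vp)] <- 0
  members <- sort(intersect(members, rownames(m$watson)))
  W <- m$watson[members, , drop = FALSE]
  C <- m$crick[members, , drop = FALSE]
  swap <- vp < 0
  W2 <- W
  C2 <- C
  W2[, swap] <- C[, swap]
  C2[, swap] <- W[, swap]
  tibble(
    unitig = members,
    hap_a = as.numeric(W2 %*% abs(vp)),
    hap_b = as.numeric(C2 %*% abs(vp))
  )
}

#' Call haplotypes from pooled marker counts
#'
#' Internal fallback caller (production use feeds the marker counts to a
#' graph-threading tool): a unitig with fewer than `min_markers` total
#' markers is `UNASSIGNED`; otherwise it is `HAP_A` or `HAP_B` when the
#' corresponding marker fraction reaches `purity`, else `HOMOZYGOUS`
#' (homozygous unitigs attract reads from both homologs and show balanced
#' markers).
#'
#' @param markers Tibble with columns `unitig`, `hap_a`, `hap_b`.
#' @param config A [phase_config()].
#' @return The input with a `call` column added
#'   (`HAP_A`/`HAP_B`/`HOMOZYGOUS`/`UNASSIGNED`).
#' @export
call_haplotypes <- function(markers, config = phase_config()) {
  total <- markers$hap_a + markers$hap_b
  frac_a <- ifelse(total > 0, markers$hap_a / total, 0.5)
  markers$call <- dplyr::case_when(
    total < config$min_markers ~ "UNASSIGNED",
    frac_a >= config$purity ~ "HAP_A",
    (1 - frac_a) >= config$purity ~ "HAP_B",
    TRUE ~ "HOMOZYGOUS"
  )
  markers
}

#' Phase all clusters
#'
#' Runs the full per-cluster phasing pass: haploid detection and merging,
#' re-orientation of the merged haploid cluster, cluster direction, plane
#' and phase-vector inference, haploid bisection correction, marker pooling,
#' and haplotype calling.
#'
#' Clusters that cannot be phased (fewer than two independent phase vectors,
#' degenerate plane, cancelling cluster direction) are flagged unphasable and
#' their unitigs called `UNASSIGNED`.
#'
#' @param clustering A refined `unitig_clustering`.
#' @param orientation An `orientation` from [correct_orientation()].
#' @param ssf_all,ssf_phase Uncorrected `ssf` tibbles for the two channels
#'   (flips are applied internally).
#' @param counts_phase Phase-channel [strand_counts()] restricted to retained
#'   libraries.
#' @param graph An `assembly_graph` (unitig lengths).
#' @param config A [phase_config()].
#' @return A `phase_result` list: `geometry` (tibble per cluster: cluster,
#'   is_haploid, unphasable, pc1_var, pc2_var, and list-columns `v_clust`,
#'   `v_phase_raw`, `v_phase`), `markers` (tibble: unitig, cluster, flip,
#'   hap_a, hap_b, call), `haploid` (the detection table), and the final
#'   `clustering` and `orientation` (after haploid merging).
#' @export
phase_clusters <- function(clustering, orientation, ssf_all, ssf_phase,
                           counts_phase, graph, config = phase_config()) {
  lengths <- setNames(graph$unitigs$length, graph$unitigs$unitig)

  ssf_all_c <- apply_orientation(ssf_all, orientation)
  ssf_phase_c <- apply_orientation(ssf_phase, orientation)

  haploid <- detect_haploid_clusters(clustering, ssf_phase_c, config)
  merged <- merge_haploid_clusters(clustering, haploid)
  hap_cl <- attr(merged, "haploid_cluster")

  # the merged haploid cluster changed membership: re-run orientation on it
  if (!is.na(hap_cl)) {
    sub <- merged %>% filter(.data$cluster %in% hap_cl)
    reori <- correct_orientation(
      structure(sub, class = class(merged)), ssf_all
    )
    orientation <- bind_rows(
      orientation %>% filter(!(.data$unitig %in% reori$unitig)),
      reori
    ) %>% arrange(.data$unitig)
    ssf_all_c <- apply_orientation(ssf_all, orientation)
    ssf_phase_c <- apply_orientation(ssf_phase, orientation)
  }
  counts_phase_c <- apply_orientation_counts(counts_phase, orientation)

  clusters <- sort(unique(merged$cluster[!is.na(merged$cluster)]))
  geo_rows <- list()
  marker_rows <- list()
  for (cl in clusters) {
    members <- sort(merged$unitig[!is.na(merged$cluster) & merged$cluster == cl])
    is_hap <- !is.na(hap_cl) && cl == hap_cl
    geom <- NULL
    err <- NULL
    tryCatch(
      {
        v_clust <- compute_v_clust(ssf_all_c, members, lengths)
        geom <- infer_plane_and_vphase(ssf_phase_c, members, v_clust, config)
        if (is_hap) {
          geom <- haploid_bisection_correction(geom, ssf_phase_c, members, config)
        }
      },
      error = function(e) err <<- conditionMessage(e)
    )
    if (is.null(geom)) {
      warn(paste0("Cluster ", cl, " is unphasable: ", err))
      geo_rows[[length(geo_rows) + 1L]] <- tibble(
        cluster = cl, is_haploid = is_hap, unphasable = TRUE,
        pc1_var = NA_real_, pc2_var = NA_real_,
        v_clust = list(NULL), v_phase_raw = list(NULL), v_phase = list(NULL)
      )
      marker_rows[[length(marker_rows) + 1L]] <- tibble(
        unitig = members, cluster = cl, hap_a = 0, hap_b = 0,
        call = "UNASSIGNED"
      )
      next
    }
    geo_rows[[length(geo_rows) + 1L]] <- tibble(
      cluster = cl, is_haploid = is_hap, unphasable = FALSE,
      pc1_var = geom$pc_variance[1], pc2_var = geom$pc_variance[2],
      v_clust = list(geom$v_clust),
      v_phase_raw = list(geom$v_phase_raw),
      v_phase = list(geom$v_phase)
    )
    weights <- if (config$continuous_weights) geom$v_phase_raw else geom$v_phase
    names(weights) <- rownames(geom$plane_basis)
    mk <- pool_markers(counts_phase_c, weights, members) %>%
      call_haplotypes(config) %>%
      mutate(cluster = cl)
    marker_rows[[length(marker_rows) + 1L]] <- mk
  }

  geometry <- bind_rows(geo_rows)
  markers <- bind_rows(marker_rows) %>%
    left_join(
      orientation %>% select("unitig", "flip", "flagged"),
      by = "unitig"
    ) %>%
    select("unitig", "cluster", "flip", "flagged", "hap_a", "hap_b", "call") %>%
    arrange(.data$unitig)

  structure(
    list(
      geometry = geometry, markers = markers, haploid = haploid,
      clustering = merged, orientation = orientation
    ),
    class = "phase_result"
  )
}

#' @export
print.phase_result <- function(x, ...) {
  cat(
    "<phase_result> ", nrow(x$geometry), " clusters (",
    sum(x$geometry$is_haploid), " haploid, ",
    sum(x$geometry$unphasable), " unphasable), ",
    nrow(x$markers), " unitigs called\n",
    sep = ""
  )
  print(table(x$markers$call))
  invisible(x)
}

#' @method tidy phase_result
#' @export
tidy.phase_result <- function(x, ...) {
  x$markers
}

#' @method glance phase_result
#' @export
glance.phase_result <- function(x, ...) {
  tibble(
    n_clusters = nrow(x$geometry),
    n_haploid = sum(x$geometry$is_haploid),
    n_unphasable = sum(x$geometry$unphasable),
    n_hap_a = sum(x$markers$call == "HAP_A"),
    n_hap_b = sum(x$markers$call == "HAP_B"),
    n_homozygous = sum(x$markers$call == "HOMOZYGOUS"),
    n_unassigned = sum(x$markers$call == "UNASSIGNED")
  )
}
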