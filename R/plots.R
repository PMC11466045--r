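#' Plot pooled haplotype markers as a blob plot
#'
#' Each point is a unitig placed by its haplotype-A and haplotype-B marker
#' counts and sized by length when available; well-phased unitigs hug the
#' axes, homozygous unitigs sit on the diagonal.
#'
#' @param object A `phase_result` (or [autoplot] a `phase_run`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot phase_result
#' @export
autoplot.phase_result <- function(object, ...) {
  ggplot2::ggplot(
    object$markers,
    ggplot2::aes(x = .data$hap_a, y = .data$hap_b, colour = .data$call)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "haplotype A markers", y = "haplotype B markers",
      colour = "call", title = "Pooled haplotype markers"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.phase_result
#' @method autoplot phase_run
#' @export
autoplot.phase_run <- function(object, ...) {
  autoplot(object$phasing, ...)
}

#' Heatmap of an SSF matrix
#'
#' Unitigs by libraries, filled by the strand-state frequency: matched cells
#' show as +/-1 bands, unmatched cells as near-zero.
#'
#' @param object An `ssf` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ssf
#' @export
autoplot.ssf <- function(object, ...) {
  full <- tidyr::expand_grid(
    unitig = attr(object, "unitig_ids"),
    library = attr(object, "library_ids")
  ) %>%
    left_join(as_tibble(object), by = c("unitig", "library")) %>%
    mutate(ssf = dplyr::coalesce(.data$ssf, 0))
  ggplot2::ggplot(
    full,
    ggplot2::aes(x = .data$library, y = .data$unitig, fill = .data$ssf)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "#2166ac", mid = "white", high = "#b2182b", limits = c(-1, 1)
    ) +
    ggplot2::labs(
      x = "library", y = "unitig", fill = "SSF",
      title = paste0("Strand-state frequencies (", attr(object, "channel"), ")")
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_blank(),
      axis.text.y = ggplot2::element_blank()
    )
}

#' Cluster composition bar plot
#'
#' Total bp per cluster; useful for spotting fragmented or spurious clusters
#' after refinement.
#'
#' @param object A `unitig_clustering`.
#' @param graph Optional `assembly_graph` supplying unitig lengths; without
#'   it, unitig counts are plotted.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot unitig_clustering
#' @export
autoplot.unitig_clustering <- function(object, graph = NULL, ...) {
  df <- as_tibble(object) %>%
    mutate(cluster = ifelse(is.na(.data$cluster), "unclustered",
      as.character(.data$cluster)
    ))
  if (!is.null(graph)) {
    df <- df %>%
      left_join(graph$unitigs %>% select("unitig", "length"), by = "unitig") %>%
      group_by(.data$cluster) %>%
      summarise(size = sum(.data$length), .groups = "drop")
    ylab <- "total bp"
  } else {
    df <- df %>% count(.data$cluster, name = "size")
    ylab <- "unitigs"
  }
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = stats::reorder(.data$cluster, -.data$size),
      y = .data$size
    )
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "cluster", y = ylab, title = "Cluster sizes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Chromosome-plane scatter for one cluster
#'
#' Projects the cluster's phase-channel unit vectors into the inferred plane
#' and draws them in (`v_clust`, `v_phase`) coordinates together with the two
#' basis directions; diploid clusters show three rays (haplotype A,
#' haplotype B, homozygous), the merged haploid cluster two.
#'
#' @param run A `phase_run`.
#' @param cluster Cluster id to plot.
#' @return A ggplot.
#' @export
plot_phase_plane <- function(run, cluster) {
  geo <- run$phasing$geometry %>% filter(.data$cluster == !!cluster)
  if (nrow(geo) == 0L || geo$unphasable[[1]]) {
    abort(paste0("Cluster ", cluster, " has no phase geometry"))
  }
  members <- run$phasing$clustering %>%
    filter(.data$cluster == !!cluster) %>%
    pull("unitig")
  ssf_c <- apply_orientation(run$ssf_phase, run$phasing$orientation)
  V <- unit_rows(ssf_matrices(ssf_c, unitigs = sort(members))$values)
  V <- V[!(rownames(V) %in% attr(V, "zero_rows")), , drop = FALSE]
  b2 <- geo$v_phase_raw[[1]]
  v_clust <- geo$v_clust[[1]]
  b1 <- v_clust - sum(v_clust * b2) * b2
  b1 <- b1 / sqrt(sum(b1^2))
  df <- tibble(
    unitig = rownames(V),
    x = as.numeric(V %*% b1),
    y = as.numeric(V %*% b2)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_segment(
      data = tibble(x = c(1, 0), y = c(0, 1), lab = c("v_clust", "v_phase")),
      ggplot2::aes(xend = .data$x, yend = .data$y, x = 0, y = 0),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.2, "cm")),
      colour = "grey40"
    ) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "v_clust coordinate", y = "v_phase coordinate",
      title = paste0("Chromosome plane, cluster ", cluster)
    ) +
    ggplot2::theme_minimal()
}
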