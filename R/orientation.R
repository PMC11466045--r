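#' Correct misoriented unitigs within chromosome clusters
#'
#' A misoriented unitig (assembled in reverse complement relative to its
#' cluster) has its SSF vector negated, so within a cluster the signed-cosine
#' geometry bisects into two antipodal bundles. For each cluster the member
#' vectors are augmented with their negated copies — guaranteeing both
#' orientations are present even when every unitig already agrees — and
#' average-linkage hierarchical clustering on distance `1 - cos` is cut at two
#' clusters. The side containing the un-flipped copy of the lexicographically
#' smallest unitig id is the (arbitrary but deterministic) reference
#' orientation; unitigs whose original copy falls on the other side are
#' flipped. Only relative orientation matters downstream, so the global sign
#' is arbitrary.
#'
#' A unitig whose original and negated copies land on the *same* side is
#' internally inconsistent (mixed signal); it is left unflipped and flagged,
#' with a warning. Zero-vector unitigs are likewise unflipped and flagged.
#' Assignments with a small margin (difference between the mean within-side
#' and cross-side signed cosine) are flagged as low-confidence.
#'
#' @param clustering A `unitig_clustering`.
#' @param ssf All-reads channel `ssf` tibble.
#' @param flag_margin Flag unitigs whose side margin falls below this
#'   (default 0.1).
#' @return An `orientation` tibble: `unitig`, `cluster`, `flip` (logical),
#'   `flagged` (logical).
#' @export
correct_orientation <- function(clustering, ssf, flag_margin = 0.1) {
  clustered <- clustering %>% filter(!is.na(.data$cluster))
  out <- purrr::map(
    sort(unique(clustered$cluster)),
    function(cl) {
      members <- sort(clustered$unitig[clustered$cluster == cl])
      res <- orient_cluster(ssf, members, flag_margin)
      res$cluster <- cl
      res
    }
  ) %>% bind_rows()
  if (nrow(out) == 0L) {
    out <- tibble(
      unitig = character(0), flip = logical(0),
      flagged = logical(0), cluster = integer(0)
    )
  }
  structure(
    out[, c("unitig", "cluster", "flip", "flagged")] %>% arrange(.data$unitig),
    class = c("orientation", class(tibble()))
  )
}

# One cluster: hierarchical 2-cut of {v_i} U {-v_i}.
orient_cluster <- function(ssf, members, flag_margin) {
  m <- ssf_matrices(ssf, unitigs = members)
  V <- unit_rows(m$values)
  zero <- attr(V, "zero_rows")
  live <- setdiff(members, zero)
  res <- tibble(
    unitig = members,
    flip = FALSE,
    flagged = members %in% zero
  )
  n <- length(live)
  if (n < 1L) {
    return(res)
  }
  U <- V[live, , drop = FALSE]
  A <- rbind(U, -U)
  C <- tcrossprod(A)
  C[C > 1] <- 1
  C[C < -1] <- -1
  D <- 1 - C
  hc <- hclust(as.dist(D), method = "average")
  side <- cutree(hc, k = 2)
  side_orig <- side[seq_len(n)]
  side_neg <- side[n + seq_len(n)]
  inconsistent <- side_orig == side_neg
  if (any(inconsistent)) {
    warn(paste0(
      "Orientation 2-cut inconsistent for unitig(s): ",
      paste(live[inconsistent], collapse = ", "),
      "; left unflipped and flagged"
    ))
  }
  consistent <- which(!inconsistent)
  if (length(consistent) > 0L) {
    ref <- consistent[[1]] # `live` is sorted, so this is the smallest id
    ref_side <- side_orig[ref]
    flips <- side_orig != ref_side
    flips[inconsistent] <- FALSE
    # margin: mean signed cosine to own side vs other side (original copies)
    margin <- vapply(seq_len(n), function(i) {
      own <- which(side == side[i])
      oth <- which(side != side[i])
      own <- setdiff(own, i)
      mo <- if (length(own) > 0L) mean(C[i, own]) else 1
      mx <- if (length(oth) > 0L) mean(C[i, oth]) else -1
      mo - mx
    }, numeric(1))
    idx <- match(live, res$unitig)
    res$flip[idx] <- flips
    res$flagged[idx] <- res$flagged[idx] | inconsistent | (margin < flag_margin)
  }
  res
}

#' Apply orientation flips to an SSF table
#'
#' Negates the SSF values of flipped unitigs (equivalent to swapping their
#' Watson and Crick counts).
#'
#' @param ssf An `ssf` tibble.
#' @param orientation An `orientation` tibble from [correct_orientation()].
#' @return The corrected `ssf` tibble.
#' @export
apply_orientation <- function(ssf, orientation) {
  flips <- orientation$unitig[orientation$flip]
  out <- ssf
  out$ssf[out$unitig %in% flips] <- -out$ssf[out$unitig %in% flips]
  out
}

#' Apply orientation flips to a count table
#'
#' Swaps Watson and Crick counts for flipped unitigs.
#'
#' @inheritParams apply_orientation
#' @param counts A [strand_counts()] object.
#' @return The corrected `strand_counts` object.
#' @export
apply_orientation_counts <- function(counts, orientation) {
  flips <- orientation$unitig[orientation$flip]
  sel <- counts$unitig %in% flips
  w <- counts$watson[sel]
  counts$watson[sel] <- counts$crick[sel]
  counts$crick[sel] <- w
  counts
}
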