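#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions (up to label names), about 0 for independent ones.
#' `NA` labels are treated as singleton clusters.
#'
#' @param x,y Label vectors of equal length.
#' @return A number `<= 1`.
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  fix_na <- function(v) {
    v <- as.character(v)
    nas <- is.na(v)
    v[nas] <- paste0(".na", seq_len(sum(nas)))
    v
  }
  x <- fix_na(x)
  y <- fix_na(y)
  tab <- table(x, y)
  n <- length(x)
  ch2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- ch2(as.numeric(tab))
  sum_a <- ch2(as.numeric(rowSums(tab)))
  sum_b <- ch2(as.numeric(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) {
    return(1)
  }
  (sum_ij - expected) / (maximum - expected)
}

#' Compare a clustering against the planted chromosome partition
#'
#' @param clustering A `unitig_clustering`.
#' @param truth A `truth_unitigs` tibble from [simulate_strandseq()].
#' @return A one-row tibble: `ari`, `n_clusters`, `n_unclustered`.
#' @export
clustering_recovery <- function(clustering, truth) {
  joined <- clustering %>%
    left_join(truth %>% select("unitig", "chromosome"), by = "unitig")
  tibble(
    ari = adjusted_rand_index(joined$cluster, joined$chromosome),
    n_clusters = length(unique(joined$cluster[!is.na(joined$cluster)])),
    n_unclustered = sum(is.na(joined$cluster))
  )
}

#' Compare corrected orientations against planted misorientations
#'
#' Orientation is only defined up to a global sign per cluster, so for each
#' cluster the predicted flips are compared to the planted misorientation
#' flags under the better of the two global signs.
#'
#' @param orientation An `orientation` tibble.
#' @param truth A `truth_unitigs` tibble.
#' @return A one-row tibble: `accuracy` (all unitigs),
#'   `misoriented_corrected` (fraction of planted misorientations fixed),
#'   `n_misoriented`.
#' @export
orientation_recovery <- function(orientation, truth) {
  joined <- orientation %>%
    left_join(truth %>% select("unitig", "misoriented"), by = "unitig")
  per_cluster <- joined %>%
    group_by(.data$cluster) %>%
    dplyr::group_split()
  rows <- purrr::map(per_cluster, function(g) {
    agree_id <- g$flip == g$misoriented
    s <- if (mean(agree_id) >= 0.5) agree_id else !agree_id
    tibble(
      ok = s, misoriented = g$misoriented
    )
  }) %>% bind_rows()
  tibble(
    accuracy = mean(rows$ok),
    misoriented_corrected = if (any(rows$misoriented)) {
      mean(rows$ok[rows$misoriented])
    } else {
      NA_real_
    },
    n_misoriented = sum(rows$misoriented)
  )
}

#' bp-weighted haplotype-call accuracy against planted truth
#'
#' Haplotype labels are only defined up to a per-cluster swap (parentage is
#' unknown), so for each cluster the mapping `A -> HAP_A, B -> HAP_B` or its
#' swap is chosen to maximize agreement, weighted by unitig length. Planted
#' homozygous unitigs must be called `HOMOZYGOUS`; `UNASSIGNED` never counts
#' as correct.
#'
#' @param markers The `markers` tibble of a `phase_result`.
#' @param truth A `truth_unitigs` tibble (provides haplotype and length).
#' @return A one-row tibble: `accuracy` (bp-weighted), `accuracy_n`
#'   (unweighted), `n_unassigned`.
#' @export
call_accuracy <- function(markers, truth) {
  joined <- markers %>%
    left_join(
      truth %>% select("unitig", "haplotype", "length"),
      by = "unitig"
    )
  expect_id <- c(A = "HAP_A", B = "HAP_B", HOM = "HOMOZYGOUS")
  expect_sw <- c(A = "HAP_B", B = "HAP_A", HOM = "HOMOZYGOUS")
  per_cluster <- joined %>%
    group_by(.data$cluster) %>%
    dplyr::group_split()
  rows <- purrr::map(per_cluster, function(g) {
    ok_id <- g$call == expect_id[g$haplotype]
    ok_sw <- g$call == expect_sw[g$haplotype]
    use_id <- sum(g$length * ok_id) >= sum(g$length * ok_sw)
    tibble(ok = if (use_id) ok_id else ok_sw, length = g$length, call = g$call)
  }) %>% bind_rows()
  tibble(
    accuracy = sum(rows$length * rows$ok) / sum(rows$length),
    accuracy_n = mean(rows$ok),
    n_unassigned = sum(rows$call == "UNASSIGNED")
  )
}
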