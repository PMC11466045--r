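#' Read a GFA1 assembly graph
#'
#' Parses the segment (`S`) and link (`L`) lines of a GFA1 file into an
#' `assembly_graph`. Segment length is taken from the `LN:i:` tag when present,
#' otherwise from the length of the stored sequence. Link end orientations are
#' retained but not interpreted by the phasing math, which operates on
#' alignment counts rather than graph walks. Self-links are permitted.
#'
#' Other GFA record types (headers, paths, walks, jumps, containments) are
#' ignored.
#'
#' @param path Path to a GFA1 file.
#' @return An `assembly_graph`: a list with
#'   * `unitigs`: tibble with columns `unitig`, `length`, `component`;
#'   * `links`: tibble with columns `from`, `from_orient`, `to`, `to_orient`.
#'   Connected-component labels are dense integers assigned in order of each
#'   component's lexicographically smallest member, so they do not depend on
#'   unitig input order.
#' @examples
#' gfa <- tempfile(fileext = ".gfa")
#' writeLines(c("S\tA\t*\tLN:i:100", "S\tB\tACGT", "L\tA\t+\tB\t+\t0M"), gfa)
#' read_gfa(gfa)
#' @export
read_gfa <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("GFA file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  seg_id <- character(0)
  seg_len <- integer(0)
  lk <- list()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(line)) next
    type <- substr(line, 1L, 1L)
    if (type == "S") {
      f <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(f) < 3L) {
        abort(paste0("Malformed S line at line ", i, ": expected at least 3 fields"))
      }
      len <- NA_integer_
      if (length(f) >= 4L) {
        ln_tag <- grep("^LN:i:", f[-(1:3)], value = TRUE)
        if (length(ln_tag) > 0L) {
          len <- suppressWarnings(as.integer(sub("^LN:i:", "", ln_tag[[1]])))
        }
      }
      if (is.na(len)) {
        if (f[[3]] != "*") {
          len <- nchar(f[[3]])
        } else {
          abort(paste0(
            "S line at line ", i, " (segment '", f[[2]],
            "') has neither a sequence nor an LN:i tag"
          ))
        }
      }
      seg_id <- c(seg_id, f[[2]])
      seg_len <- c(seg_len, len)
    } else if (type == "L") {
      f <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(f) < 5L || !(f[[3]] %in% c("+", "-")) || !(f[[5]] %in% c("+", "-"))) {
        abort(paste0("Malformed L line at line ", i))
      }
      lk[[length(lk) + 1L]] <- c(f[[2]], f[[3]], f[[4]], f[[5]])
    }
  }
  if (anyDuplicated(seg_id)) {
    abort(paste0(
      "Duplicate segment id(s): ",
      paste(unique(seg_id[duplicated(seg_id)]), collapse = ", ")
    ))
  }
  if (any(seg_len <= 0L)) {
    abort("All segment lengths must be positive")
  }
  links <- if (length(lk) > 0L) {
    m <- do.call(rbind, lk)
    tibble(
      from = m[, 1], from_orient = m[, 2],
      to = m[, 3], to_orient = m[, 4]
    )
  } else {
    tibble(
      from = character(0), from_orient = character(0),
      to = character(0), to_orient = character(0)
    )
  }
  unknown <- setdiff(unique(c(links$from, links$to)), seg_id)
  if (length(unknown) > 0L) {
    abort(paste0(
      "L line endpoint(s) reference unknown segment(s): ",
      paste(unknown, collapse = ", ")
    ))
  }
  assembly_graph(tibble(unitig = seg_id, length = as.numeric(seg_len)), links)
}

#' Construct an assembly graph from tibbles
#'
#' @param unitigs Tibble with columns `unitig` and `length`.
#' @param links Tibble with columns `from`, `from_orient`, `to`, `to_orient`
#'   (orientations default to `"+"` when absent).
#' @return An `assembly_graph` with connected components computed.
#' @export
assembly_graph <- function(unitigs, links = NULL) {
  unitigs <- as_tibble(unitigs)
  stopifnot(all(c("unitig", "length") %in% names(unitigs)))
  if (is.null(links)) {
    links <- tibble(
      from = character(0), from_orient = character(0),
      to = character(0), to_orient = character(0)
    )
  }
  links <- as_tibble(links)
  if (!"from_orient" %in% names(links)) links$from_orient <- rep("+", nrow(links))
  if (!"to_orient" %in% names(links)) links$to_orient <- rep("+", nrow(links))
  g <- structure(
    list(
      unitigs = unitigs[, c("unitig", "length")],
      links = links[, c("from", "from_orient", "to", "to_orient")]
    ),
    class = "assembly_graph"
  )
  g$unitigs$component <- graph_components(g)
  g
}

#' @export
print.assembly_graph <- function(x, ...) {
  cat(
    "<assembly_graph> ", nrow(x$unitigs), " unitigs, ", nrow(x$links),
    " links, ", length(unique(x$unitigs$component)), " components, ",
    format(sum(x$unitigs$length), big.mark = ","), " bp\n",
    sep = ""
  )
  invisible(x)
}

# Connected-component labels, deterministic in the unitig ids (not in input
# order): components are numbered by their lexicographically smallest member.
graph_components <- function(graph) {
  ids <- graph$unitigs$unitig
  ig <- igraph::graph_from_data_frame(
    d = graph$links[, c("from", "to")],
    directed = FALSE,
    vertices = data.frame(name = ids)
  )
  memb <- igraph::components(ig)$membership[ids]
  first_member <- vapply(
    split(ids, memb),
    function(v) min(v),
    character(1)
  )
  relabel <- rank(first_member[as.character(sort(unique(memb)))])
  as.integer(relabel[as.character(memb)])
}

#' Remove the rDNA tangle from an assembly graph
#'
#' In human assemblies the five acrocentric chromosomes are connected through
#' the ribosomal DNA array, a dense tangle of short nodes. This heuristic
#' identifies the connected component with the largest summed base-pair total
#' as the putative acrocentric component, finds the connected subgraphs within
#' it that are induced solely by nodes shorter than `short_len`, and removes
#' the largest such subgraph ("the tangle") together with all edges incident
#' to its nodes. Components are recomputed afterwards.
#'
#' Tangle size is measured by summed bp; ties are broken by node count, then
#' by lexicographically smallest member id. A graph whose bp-largest component
#' contains no sub-threshold node is returned unchanged.
#'
#' @param graph An `assembly_graph`.
#' @param short_len Length threshold in bp below which a node counts as short
#'   (default 50000, matching the unitig length filter).
#' @return An `assembly_graph` with the tangle nodes removed and components
#'   recomputed. The removed ids are attached as attribute `"removed"`.
#' @export
remove_rdna_tangle <- function(graph, short_len = 50000) {
  stopifnot(inherits(graph, "assembly_graph"), short_len > 0)
  un <- graph$unitigs
  comp_bp <- tapply(un$length, un$component, sum)
  big_comp <- as.integer(names(comp_bp)[which.max(comp_bp)])
  short_ids <- un$unitig[un$component == big_comp & un$length < short_len]
  if (length(short_ids) == 0L) {
    attr(graph, "removed") <- character(0)
    return(graph)
  }
  # connected subgraphs induced by the short nodes only
  sub_links <- graph$links[graph$links$from %in% short_ids &
    graph$links$to %in% short_ids, , drop = FALSE]
  ig <- igraph::graph_from_data_frame(
    d = sub_links[, c("from", "to")],
    directed = FALSE,
    vertices = data.frame(name = short_ids)
  )
  memb <- igraph::components(ig)$membership[short_ids]
  tangles <- split(short_ids, memb)
  len_of <- setNames(un$length, un$unitig)
  t_bp <- vapply(tangles, function(v) sum(len_of[v]), numeric(1))
  t_n <- lengths(tangles)
  t_min <- vapply(tangles, function(v) min(v), character(1))
  ord <- order(-t_bp, -t_n, t_min)
  tangle <- tangles[[ord[[1]]]]
  keep <- !(un$unitig %in% tangle)
  new_links <- graph$links[!(graph$links$from %in% tangle) &
    !(graph$links$to %in% tangle), , drop = FALSE]
  out <- assembly_graph(un[keep, c("unitig", "length")], new_links)
  attr(out, "removed") <- sort(tangle)
  out
}

#' Filter unitigs by length
#'
#' Short unitigs receive too few alignments for a reliable strand-state signal
#' or consist of degenerate sequence, so they are removed before phasing. The
#' boundary is inclusive: a unitig whose length equals `min_length` is
#' retained.
#'
#' @param graph An `assembly_graph`.
#' @param min_length Minimum unitig length in bp (default 50000).
#' @return A tibble with columns `unitig`, `length`, `component`,
#'   `retained` (logical), carrying the removed bp fraction as attribute
#'   `"removed_bp_fraction"` (also reported via a message).
#' @export
filter_by_length <- function(graph, min_length = 50000) {
  stopifnot(inherits(graph, "assembly_graph"), min_length >= 0)
  out <- graph$unitigs %>%
    mutate(retained = .data$length >= min_length) %>%
    arrange(.data$unitig)
  frac <- if (sum(out$length) > 0) {
    sum(out$length[!out$retained]) / sum(out$length)
  } else {
    0
  }
  attr(out, "removed_bp_fraction") <- frac
  inform(sprintf(
    "Length filter (>= %d bp): removed %d/%d unitigs (%.2f%% of total bp)",
    as.integer(min_length), sum(!out$retained), nrow(out), 100 * frac
  ))
  out
}
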