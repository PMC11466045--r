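#' Strand-seq alignment count tables
#'
#' A `strand_counts` object is a long tibble with one row per
#' (unitig, library) cell and columns `unitig`, `library`, `watson`, `crick`.
#' It carries the complete ordered id sets and the evidence channel
#' (`"all_reads"` or `"phase_informative"`) as attributes, so cells that are
#' absent from the table are implicit zeros.
#'
#' Orientation convention: reads aligning to a unitig's *reverse* strand are
#' counted as Watson and reads on the *forward* strand as Crick. The
#' downstream math is built on `|w - c|` patterns and sign-free clustering,
#' so any consistent convention only relabels Watson and Crick globally.
#'
#' @param x A data frame with columns `unitig`, `library`, `watson`, `crick`.
#' @param unitig_ids,library_ids Ordered complete id sets; default to the ids
#'   present in `x`.
#' @param channel `"all_reads"` or `"phase_informative"`.
#' @return A `strand_counts` tibble.
#' @export
strand_counts <- function(x, unitig_ids = NULL, library_ids = NULL,
                          channel = c("all_reads", "phase_informative")) {
  channel <- match.arg(channel)
  x <- as_tibble(x)
  stopifnot(all(c("unitig", "library", "watson", "crick") %in% names(x)))
  if (any(x$watson < 0) || any(x$crick < 0)) {
    abort("Counts must be non-negative")
  }
  unitig_ids <- unitig_ids %||% sort(unique(x$unitig))
  library_ids <- library_ids %||% sort(unique(x$library))
  if (anyDuplicated(unitig_ids) || anyDuplicated(library_ids)) {
    abort("unitig_ids and library_ids must be unique")
  }
  bad_u <- setdiff(unique(x$unitig), unitig_ids)
  if (length(bad_u) > 0L) {
    abort(paste0("Unknown unitig id(s) in counts: ", paste(head(bad_u, 5), collapse = ", ")))
  }
  bad_l <- setdiff(unique(x$library), library_ids)
  if (length(bad_l) > 0L) {
    abort(paste0("Unknown library id(s) in counts: ", paste(head(bad_l, 5), collapse = ", ")))
  }
  x <- x[, c("unitig", "library", "watson", "crick")]
  x <- x[order(x$unitig, x$library), , drop = FALSE]
  structure(x,
    unitig_ids = unitig_ids, library_ids = library_ids, channel = channel,
    class = c("strand_counts", class(tibble()))
  )
}

#' @export
print.strand_counts <- function(x, ...) {
  cat(
    "<strand_counts> channel=", attr(x, "channel"), ", ",
    length(attr(x, "unitig_ids")), " unitigs x ",
    length(attr(x, "library_ids")), " libraries, ",
    sum(x$watson) + sum(x$crick), " reads\n",
    sep = ""
  )
  NextMethod()
}

#' Dense Watson/Crick matrices from a count table
#'
#' @param counts A `strand_counts` object.
#' @return A list with integer matrices `watson` and `crick`
#'   (unitig x library, dimnames set).
#' @export
count_matrices <- function(counts) {
  u <- attr(counts, "unitig_ids")
  l <- attr(counts, "library_ids")
  w <- matrix(0, nrow = length(u), ncol = length(l), dimnames = list(u, l))
  cc <- w
  iu <- match(counts$unitig, u)
  il <- match(counts$library, l)
  w[cbind(iu, il)] <- counts$watson
  cc[cbind(iu, il)] <- counts$crick
  list(watson = w, crick = cc)
}

#' Filter paired-end alignment records for counting
#'
#' Retains first-mate, properly paired records that are not flagged as
#' duplicate, secondary, or supplementary. These are the records whose
#' alignment orientation carries the Strand-seq strand-state signal.
#'
#' @param records A tibble of alignment records with columns `read_id`,
#'   `library`, `unitig`, `strand` (`"forward"`/`"reverse"`), `mate`
#'   (`"first"`/`"second"`), and logical flag columns `duplicate`,
#'   `secondary`, `supplementary`, `proper_pair`.
#' @return The retained rows, same columns.
#' @export
filter_mem_alignments <- function(records) {
  records <- as_tibble(records)
  for (fl in c("duplicate", "secondary", "supplementary")) {
    if (!fl %in% names(records)) records[[fl]] <- FALSE
  }
  if (!"proper_pair" %in% names(records)) records$proper_pair <- TRUE
  records %>%
    filter(
      .data$mate == "first",
      !.data$duplicate, !.data$secondary, !.data$supplementary,
      .data$proper_pair
    )
}

#' Filter SMEM records to uniquely aligning reads
#'
#' A read whose entire alignable content is captured by a single super-maximal
#' exact match with a single hit aligns to sequence present exactly once in
#' the graph and is therefore haplotype-informative. Reads with several SMEMs,
#' or whose one SMEM hits several places, align to multi-copy sequence and are
#' dropped.
#'
#' @param records A tibble with columns `read_id`, `library`, `n_smem`, and
#'   list-column `matches` of tibbles with columns `unitig`, `strand`.
#' @return A tibble with columns `read_id`, `library`, `unitig`, `strand`,
#'   one row per retained read.
#' @export
filter_single_smem <- function(records) {
  records <- as_tibble(records)
  if (nrow(records) == 0L) {
    return(tibble(
      read_id = character(0), library = character(0),
      unitig = character(0), strand = character(0)
    ))
  }
  keep <- records$n_smem == 1L &
    vapply(records$matches, nrow, integer(1)) == 1L
  kept <- records[keep, , drop = FALSE]
  tibble(
    read_id = kept$read_id,
    library = kept$library,
    unitig = vapply(kept$matches, function(m) m$unitig[[1]], character(1)),
    strand = vapply(kept$matches, function(m) m$strand[[1]], character(1))
  )
}

#' Count filtered alignments into a Watson/Crick table
#'
#' Reverse-strand records count as Watson, forward-strand as Crick (see
#' [strand_counts()] for why the convention is arbitrary). Cells with no
#' records are zero.
#'
#' @param records Tibble with columns `library`, `unitig`, `strand`.
#' @param unitigs,libraries Complete ordered id sets; records referencing ids
#'   outside these sets raise an error naming the id.
#' @param channel Evidence channel for the resulting table.
#' @return A [strand_counts()] object.
#' @export
count_alignments <- function(records, unitigs, libraries,
                             channel = c("all_reads", "phase_informative")) {
  channel <- match.arg(channel)
  records <- as_tibble(records)
  bad_u <- setdiff(unique(records$unitig), unitigs)
  if (length(bad_u) > 0L) {
    abort(paste0("Record(s) reference unknown unitig: ", paste(head(bad_u, 5), collapse = ", ")))
  }
  bad_l <- setdiff(unique(records$library), libraries)
  if (length(bad_l) > 0L) {
    abort(paste0("Record(s) reference unknown library: ", paste(head(bad_l, 5), collapse = ", ")))
  }
  tab <- records %>%
    mutate(ori = if_else(.data$strand == "reverse", "watson", "crick")) %>%
    count(.data$unitig, .data$library, .data$ori) %>%
    tidyr::pivot_wider(
      names_from = "ori", values_from = "n", values_fill = 0L
    )
  for (colnm in c("watson", "crick")) {
    if (!colnm %in% names(tab)) tab[[colnm]] <- 0L
  }
  strand_counts(tab, unitig_ids = unitigs, library_ids = libraries, channel = channel)
}

#' Read Strand-seq alignments from SAM/BAM files
#'
#' One file per library; the library id is the file name stripped of its
#' `.bam`/`.sam` extension unless `library_ids` is given. SAM files are
#' converted on the fly. Requires the Rsamtools package.
#'
#' @param files Character vector of SAM or BAM paths.
#' @param library_ids Optional library ids, parallel to `files`.
#' @return A tibble of alignment records suitable for
#'   [filter_mem_alignments()].
#' @export
read_strandseq_alignments <- function(files, library_ids = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("Reading SAM/BAM requires the Rsamtools package")
  }
  library_ids <- library_ids %||% sub("\\.(bam|sam)$", "", basename(files))
  stopifnot(length(library_ids) == length(files))
  purrr::map2(files, library_ids, function(f, lib) {
    if (grepl("\\.sam$", f)) {
      f <- Rsamtools::asBam(f,
        destination = tempfile(), overwrite = TRUE,
        indexDestination = FALSE
      )
    }
    res <- Rsamtools::scanBam(
      f,
      param = Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "strand"))
    )[[1]]
    fl <- res$flag
    mapped <- bitwAnd(fl, 4L) == 0L
    tibble(
      read_id = res$qname[mapped],
      library = lib,
      unitig = as.character(res$rname)[mapped],
      strand = if_else(as.character(res$strand)[mapped] == "-", "reverse", "forward"),
      mate = if_else(bitwAnd(fl[mapped], 128L) != 0L, "second", "first"),
      duplicate = bitwAnd(fl[mapped], 1024L) != 0L,
      secondary = bitwAnd(fl[mapped], 256L) != 0L,
      supplementary = bitwAnd(fl[mapped], 2048L) != 0L,
      proper_pair = bitwAnd(fl[mapped], 2L) != 0L
    )
  }) %>% bind_rows()
}

#' Read bwa-fastmap SMEM output
#'
#' Parses the `SQ`/`EM` text format emitted by `bwa fastmap`: an `SQ` line
#' opens a read (`SQ <name> <length>`), each following `EM` line is one SMEM
#' (`EM <start> <end> <n_hits> <unitig>:<sign><pos> ...`), and `//` closes the
#' read. An `EM` line whose hit list is the single token `*` means the hit cap
#' was exceeded; such reads are repetitive by construction and are recorded
#' with an inflated `n_smem` so [filter_single_smem()] drops them.
#'
#' @param files Character vector of fastmap output paths, one per library.
#' @param library_ids Optional library ids, parallel to `files`.
#' @return A tibble with columns `read_id`, `library`, `n_smem`, and
#'   list-column `matches` (tibbles with `unitig`, `strand`).
#' @export
read_fastmap <- function(files, library_ids = NULL) {
  library_ids <- library_ids %||% sub("\\.[^.]*$", "", basename(files))
  stopifnot(length(library_ids) == length(files))
  purrr::map2(files, library_ids, function(f, lib) {
    lines <- readLines(f, warn = FALSE)
    reads <- list()
    cur_id <- NULL
    cur_ems <- list()
    capped <- FALSE
    flush <- function() {
      if (is.null(cur_id)) {
        return()
      }
      n_smem <- length(cur_ems) + if (capped) 1L else 0L
      first <- if (length(cur_ems) > 0L) cur_ems[[1]] else tibble(unitig = character(0), strand = character(0))
      reads[[length(reads) + 1L]] <<- list(
        read_id = cur_id, n_smem = n_smem, matches = first
      )
    }
    for (i in seq_along(lines)) {
      line <- lines[[i]]
      if (!nzchar(line)) next
      f1 <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (f1[[1]] == "SQ") {
        if (length(f1) < 2L) abort(paste0("Malformed SQ line at ", f, ":", i))
        cur_id <- f1[[2]]
        cur_ems <- list()
        capped <- FALSE
      } else if (f1[[1]] == "EM") {
        if (is.null(cur_id) || length(f1) < 5L) {
          abort(paste0("Malformed EM line at ", f, ":", i))
        }
        hits <- f1[-(1:4)]
        if (identical(hits, "*")) {
          capped <- TRUE
          cur_ems[[length(cur_ems) + 1L]] <- tibble(
            unitig = character(0), strand = character(0)
          )
        } else {
          parts <- strsplit(hits, ":", fixed = TRUE)
          ok <- vapply(parts, length, integer(1)) >= 2L
          if (!all(ok)) abort(paste0("Malformed EM hit at ", f, ":", i))
          cur_ems[[length(cur_ems) + 1L]] <- tibble(
            unitig = vapply(parts, `[[`, character(1), 1L),
            strand = if_else(
              substr(vapply(parts, `[[`, character(1), 2L), 1L, 1L) == "-",
              "reverse", "forward"
            )
          )
        }
      } else if (f1[[1]] == "//") {
        flush()
        cur_id <- NULL
      }
    }
    flush() # tolerate a missing trailing //
    if (length(reads) == 0L) {
      return(tibble(
        read_id = character(0), library = character(0),
        n_smem = integer(0), matches = list()
      ))
    }
    tibble(
      read_id = vapply(reads, `[[`, character(1), "read_id"),
      library = lib,
      n_smem = vapply(reads, `[[`, integer(1), "n_smem"),
      matches = lapply(reads, `[[`, "matches")
    )
  }) %>% bind_rows()
}

#' Read / write count tables as TSV
#'
#' The TSV has columns `unitig`, `library`, `watson`, `crick` and round-trips
#' bit-exactly with [write_counts_tsv()]. Zero cells may be omitted.
#'
#' @param path TSV path.
#' @param unitig_ids,library_ids,channel Passed to [strand_counts()].
#' @return A `strand_counts` object.
#' @export
read_counts_tsv <- function(path, unitig_ids = NULL, library_ids = NULL,
                            channel = c("all_reads", "phase_informative")) {
  x <- readr::read_tsv(path,
    col_types = readr::cols(
      unitig = readr::col_character(), library = readr::col_character(),
      watson = readr::col_integer(), crick = readr::col_integer()
    )
  )
  strand_counts(x,
    unitig_ids = unitig_ids, library_ids = library_ids,
    channel = match.arg(channel)
  )
}

#' @rdname read_counts_tsv
#' @param counts A `strand_counts` object.
#' @export
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(as_tibble(counts), path)
  invisible(path)
}
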