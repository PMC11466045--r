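sam_fixture <- function(path) {
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:U1\tLN:100000",
    "@SQ\tSN:U2\tLN:100000",
    # flags: 83 = paired+proper+reverse+first; 163 = paired+proper+mate of it
    paste("r1", "83", "U1", "100", "60", "50M", "=", "200", "150", "*", "*", sep = "\t"),
    paste("r1", "163", "U1", "200", "60", "50M", "=", "100", "-150", "*", "*", sep = "\t"),
    paste("r2", "99", "U2", "500", "60", "50M", "=", "700", "250", "*", "*", sep = "\t"),
    # 1107 = 83 + duplicate flag
    paste("r3", "1107", "U1", "900", "60", "50M", "=", "1000", "150", "*", "*", sep = "\t"),
    # 339 = 83 + secondary; 2147 = 83 + supplementary; 81 = 83 without proper
    paste("r4", "339", "U1", "950", "60", "50M", "=", "1100", "150", "*", "*", sep = "\t"),
    paste("r5", "2147", "U2", "10", "60", "50M", "=", "100", "90", "*", "*", sep = "\t"),
    paste("r6", "81", "U1", "40", "60", "50M", "=", "400", "360", "*", "*", sep = "\t")
  ), path)
  path
}

test_that("SAM records are read and filtered to first-mate proper unique alignments", {
  skip_if_not_installed("Rsamtools")
  sam <- sam_fixture(withr::local_tempfile(fileext = ".sam"))
  rec <- read_strandseq_alignments(sam, library_ids = "libA")
  expect_equal(nrow(rec), 7)
  f <- filter_mem_alignments(rec)
  # r1 first mate kept; second mate, duplicate, secondary, supplementary and
  # improper records all dropped
  expect_setequal(f$read_id, c("r1", "r2"))
  expect_equal(f$strand[f$read_id == "r1"], "reverse")
  expect_equal(f$strand[f$read_id == "r2"], "forward")
})

test_that("counting follows the reverse=Watson convention and conserves records", {
  rec <- tibble::tibble(
    read_id = sprintf("r%d", 1:4),
    library = "L1",
    unitig = "U",
    strand = c("reverse", "reverse", "reverse", "forward")
  )
  cnt <- count_alignments(rec, unitigs = "U", libraries = "L1")
  expect_equal(cnt$watson, 3L)
  expect_equal(cnt$crick, 1L)
  # conservation and permutation invariance
  cnt2 <- count_alignments(rec[sample.int(4), ], unitigs = "U", libraries = "L1")
  expect_equal(tibble::as_tibble(cnt), tibble::as_tibble(cnt2))
  expect_equal(sum(cnt$watson) + sum(cnt$crick), nrow(rec))
})

test_that("empty record sets give all-zero matrices of full shape", {
  rec <- tibble::tibble(
    read_id = character(0), library = character(0),
    unitig = character(0), strand = character(0)
  )
  cnt <- count_alignments(rec, unitigs = c("a", "b"), libraries = c("l1", "l2", "l3"))
  m <- count_matrices(cnt)
  expect_equal(dim(m$watson), c(2, 3))
  expect_true(all(m$watson == 0) && all(m$crick == 0))
})

test_that("unknown ids in records are rejected by name", {
  rec <- tibble::tibble(
    read_id = "r", library = "L1", unitig = "nope", strand = "forward"
  )
  expect_error(count_alignments(rec, "U", "L1"), "nope")
  rec$unitig <- "U"
  rec$library <- "badlib"
  expect_error(count_alignments(rec, "U", "L1"), "badlib")
})

test_that("swapping every record's strand swaps the Watson and Crick matrices", {
  set.seed(1)
  rec <- tibble::tibble(
    read_id = sprintf("r%d", 1:200),
    library = sample(c("L1", "L2"), 200, replace = TRUE),
    unitig = sample(c("a", "b", "c"), 200, replace = TRUE),
    strand = sample(c("forward", "reverse"), 200, replace = TRUE)
  )
  swapped <- rec
  swapped$strand <- ifelse(rec$strand == "forward", "reverse", "forward")
  m1 <- count_matrices(count_alignments(rec, c("a", "b", "c"), c("L1", "L2")))
  m2 <- count_matrices(count_alignments(swapped, c("a", "b", "c"), c("L1", "L2")))
  expect_equal(m1$watson, m2$crick)
  expect_equal(m1$crick, m2$watson)
})

test_that("fastmap records keep only single-SMEM single-hit reads", {
  fm <- withr::local_tempfile(fileext = ".fastmap")
  writeLines(c(
    "SQ\tread1\t150",
    "EM\t0\t150\t1\tU1:+1234",
    "//",
    "SQ\tread2\t150",
    "EM\t0\t80\t1\tU1:+10",
    "EM\t70\t150\t1\tU2:-55",
    "//",
    "SQ\tread3\t150",
    "EM\t0\t150\t2\tU1:+5\tU2:-9",
    "//",
    "SQ\tread4\t150",
    "EM\t0\t150\t600\t*",
    "//",
    "SQ\tread5\t150",
    "EM\t0\t150\t1\tU2:-77",
    "//"
  ), fm)
  sm <- read_fastmap(fm, library_ids = "libB")
  expect_equal(nrow(sm), 5)
  kept <- filter_single_smem(sm)
  # read2: two SMEMs; read3: one SMEM but two hits; read4: hit cap marker
  expect_equal(kept$read_id, c("read1", "read5"))
  expect_equal(kept$strand, c("forward", "reverse"))
  expect_equal(kept$unitig, c("U1", "U2"))

  # empty stream -> empty stream
  empty <- filter_single_smem(sm[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("count TSVs round-trip bit-exactly", {
  cnt <- strand_counts(
    tibble::tibble(
      unitig = c("a", "a", "b"), library = c("l1", "l2", "l1"),
      watson = c(3L, 0L, 7L), crick = c(1L, 5L, 0L)
    ),
    unitig_ids = c("a", "b", "c"), library_ids = c("l1", "l2"),
    channel = "all_reads"
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(cnt, path)
  back <- read_counts_tsv(path,
    unitig_ids = c("a", "b", "c"),
    library_ids = c("l1", "l2"), channel = "all_reads"
  )
  expect_equal(count_matrices(back), count_matrices(cnt))
})
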