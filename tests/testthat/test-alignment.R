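maf_fixture <- function(path, blocks) {
  lines <- c("##maf version=1")
  for (b in blocks) {
    lines <- c(lines, "", "a score=0.0", b)
  }
  writeLines(lines, path)
  path
}

s_line <- function(src, start, size, strand, src_size, text) {
  paste("s", src, start, size, strand, src_size, text)
}

test_that("MAF blocks round-trip with rows, starts and coordinates", {
  path <- withr::local_tempfile(fileext = ".maf")
  maf_fixture(path, list(
    c(
      s_line("dm3.chr2L", 10, 13, "+", 1000, "ACGACGCGTAGTA"),
      s_line("fly2.chr2L", 0, 13, "+", 500, "ACGACGCGTAGTA"),
      s_line("fly3.chr2L", 0, 13, "+", 500, "ACGACGTGTAGTA"),
      s_line("droSec1.sc1", 5, 13, "+", 800, "ACGACGCGTAGTA"),
      s_line("droEre2.er1", 7, 13, "+", 900, "ACGACGCGTAGTA")
    ),
    c(
      s_line("dm3.chr2L", 40, 4, "+", 1000, "AC-GT"),
      s_line("fly2.chr2L", 20, 5, "+", 500, "ACCGT"),
      s_line("fly3.chr2L", 20, 5, "+", 500, "ACCGT"),
      s_line("droSec1.sc1", 30, 5, "+", 800, "ACCGT"),
      s_line("droEre2.er1", 30, 5, "+", 900, "ACCGT")
    )
  ))
  roster <- species_roster(c("dm3", "fly2", "fly3"), c("droSec1", "droEre2"),
    reference = "dm3")
  blocks <- read_maf(path, roster)
  expect_length(blocks, 2)
  expect_equal(length(blocks[[1]]$text), 5)
  expect_equal(blocks[[1]]$start, 10)
  expect_equal(blocks[[1]]$chrom, "chr2L")
  # reference coordinate advances only on non-gap reference symbols
  cols <- alignment_columns(blocks[[2]], roster)
  expect_equal(cols$ref_pos0, c(40L, 41L, NA, 42L, 43L))
  expect_equal(cols$fly2, c("A", "C", "C", "G", "T"))
})

test_that("missing species, empty files and lowercase input are handled", {
  path <- withr::local_tempfile(fileext = ".maf")
  maf_fixture(path, list(c(
    s_line("dm3.chr2L", 0, 4, "+", 100, "acgt"),
    s_line("fly2.chr2L", 0, 4, "+", 100, "acgt"),
    s_line("droSec1.s", 0, 4, "+", 100, "acgt")
  )))
  roster <- species_roster(c("dm3", "fly2"), c("droSec1", "droEre2"), reference = "dm3")
  expect_warning(blocks <- read_maf(path, roster), "droEre2")
  expect_length(blocks, 1)
  expect_false("droEre2" %in% names(blocks[[1]]$text)) # absent, not gapped
  expect_equal(unname(blocks[[1]]$text[["dm3"]]), "ACGT") # soft-mask uppercased

  empty <- withr::local_tempfile(fileext = ".maf")
  writeLines("##maf version=1", empty)
  expect_length(read_maf(empty), 0)
})

test_that("minus-strand reference blocks are flipped to the plus strand", {
  path <- withr::local_tempfile(fileext = ".maf")
  maf_fixture(path, list(c(
    s_line("dm3.chr2L", 10, 6, "-", 100, "ACGTTT"),
    s_line("fly2.chr2L", 0, 6, "+", 100, "ACGTTT"),
    s_line("droSec1.s", 0, 6, "+", 100, "ACGTTT"),
    s_line("droEre2.e", 0, 6, "+", 100, "ACGTTT")
  )))
  roster <- species_roster(c("dm3", "fly2"), c("droSec1", "droEre2"), reference = "dm3")
  blocks <- read_maf(path, roster)
  expect_equal(unname(blocks[[1]]$text[["dm3"]]), "AAACGT")
  expect_equal(blocks[[1]]$start, 100 - (10 + 6))
})

test_that("aligned FASTA round-trips and ambiguity symbols pass through", {
  rows <- c(a = "ACG-TN", b = "ACGCTA", og1 = "ACGCTA", og2 = "ACGCTA")
  path <- withr::local_tempfile(fileext = ".afa")
  write_aligned_fasta(rows, path)
  blocks <- read_aligned_fasta(path)
  expect_identical(blocks[[1]]$text, rows)
  cols <- alignment_columns(blocks[[1]])
  expect_equal(cols$a, c("A", "C", "G", "-", "T", "N"))
  expect_equal(cols$ref_pos0, c(0L, 1L, 2L, NA, 3L, 4L))
  # non-gap reference symbols cover the reference span
  expect_equal(sum(!is.na(cols$ref_pos0)), nchar(gsub("-", "", rows[["a"]])))
})

test_that("rosters validate their invariants", {
  expect_error(species_roster("a", "b"), "outgroups")
  expect_error(species_roster(c("a", "b"), c("b", "c")), "disjoint")
  r <- species_roster(c("a", "b"), c("x", "y"))
  expect_equal(r$reference, "a")
})
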