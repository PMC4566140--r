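adapter3 <- "TGGAATTCTCGGGTGCCAAGG"
adapter5 <- "GTTCAGAGTTCTACAGTCCGACGATC"

make_read <- function(insert, read_len = 50) {
  substr(paste0(insert, adapter3, strrep("A", read_len)), 1, read_len)
}

test_that("FASTQ, FASTA and collapsed-FASTA parsing honours formats and counts", {
  fq <- tempfile(fileext = ".fq")
  writeLines(c("@r1", "TCGGACCAGGCTTCATTCCCC", "+", strrep("I", 21)), fq)
  lib <- read_small_rna(fq, label = "CK")
  expect_equal(nrow(lib), 1)
  expect_equal(nchar(lib$sequence), 21)
  expect_equal(n_reads(lib), 1)

  fa <- tempfile(fileext = ".fa")
  writeLines(c(">tag1_x257", "UCGGACCAGGCUUCAUUCCCC"), fa)
  lib2 <- read_small_rna(fa, format = "collapsed-fasta", label = "CK")
  expect_equal(lib2$count, 257L)
  expect_equal(lib2$sequence, "TCGGACCAGGCTTCATTCCCC")  # U -> T normalised

  empty <- tempfile(fileext = ".fq")
  file.create(empty)
  expect_equal(n_reads(read_small_rna(empty, label = "x")), 0)

  bad <- tempfile(fileext = ".fa")
  writeLines(c(">t1", "ACGT"), bad)
  expect_error(read_small_rna(bad, format = "collapsed-fasta"), "_x<count>")
})

test_that("cleaning trims the 3' adapter and applies every discard rule", {
  set.seed(1)
  reads <- c(
    make_read(paste0(strrep("ACGT", 5), "G")),  # 21-nt insert, kept
    make_read(rand_seq(16)),                 # too short after trimming
    make_read(rand_seq(30)),                 # 30 nt: >= max_len, discarded
    make_read(strrep("A", 21)),              # poly-A
    make_read(paste0(substr(adapter5, 15, 26), rand_seq(9))),  # 5' contaminant
    substr(paste0(adapter3, strrep("C", 50)), 1, 50),          # insert_null
    strrep("C", 50)                          # no adapter
  )
  lib <- raw_library(reads, label = "CK")
  cl <- clean_reads(lib, adapter3, adapter5)
  expect_equal(n_reads(cl), 1)
  expect_equal(nchar(cl$sequence), 21)
  d <- attr(cl, "discards")
  expect_equal(unname(d[c("too_short", "too_long", "polyA",
                          "adapter5_contaminant", "insert_null",
                          "adapter3_null")]),
               c(1, 1, 1, 1, 1, 1))
  expect_equal(sum(d) + n_reads(cl), attr(cl, "total_raw"))
})

test_that("adapter location tolerates one mismatch beyond the exact seed", {
  set.seed(11)
  ins <- rand_seq(21)
  a3_mut <- paste0("TGT", substr(adapter3, 4, nchar(adapter3)))  # mismatch at pos 3
  read <- substr(paste0(ins, a3_mut, strrep("G", 50)), 1, 50)
  cl <- clean_reads(raw_library(read, label = "x"), adapter3)
  expect_equal(cl$sequence, ins)
})

test_that("re-cleaning trimmed inserts with the non-adapter filters is a no-op", {
  set.seed(42)
  reads <- make_read(vapply(rep(21, 20), rand_seq, character(1)))
  cl <- clean_reads(raw_library(reads, label = "x"), adapter3, adapter5)
  cl2 <- clean_reads(cl, adapter3 = NULL, adapter5 = adapter5)
  expect_equal(cl2$sequence, cl$sequence)
  expect_equal(n_reads(cl2), n_reads(cl))
})

test_that("collapse conserves read counts and a written table round-trips", {
  lib <- raw_library(c("ACGTACGTACGTACGTACGTA", "ACGTACGTACGTACGTACGTA",
                       "GGGTACGTACGTACGTACGTA"),
                     count = c(2L, 3L, 1L), label = "CK")
  tags <- collapse_tags(lib)
  expect_equal(sum(tags$CK), n_reads(lib))
  expect_equal(nrow(tags), 2)
  expect_equal(tags$CK[tags$sequence == "ACGTACGTACGTACGTACGTA"], 5L)

  f <- tempfile(fileext = ".fa")
  write_collapsed_fasta(tags, f)
  back <- collapse_tags(read_small_rna(f, format = "collapsed-fasta", label = "CK"))
  expect_equal(as.data.frame(back), as.data.frame(tags))

  expect_equal(nrow(collapse_tags(raw_library(character(), label = "e"))), 0)
})

test_that("merging tag tables unions sequences and rejects duplicate labels", {
  a <- collapse_tags(raw_library(c("ACGTACGTACGTACGTACGTA"), label = "CK"))
  b <- collapse_tags(raw_library(c("ACGTACGTACGTACGTACGTA",
                                   "TTTTACGTACGTACGTACGTA"), label = "Cr200"))
  m <- merge_tag_tables(a, b)
  expect_equal(nrow(m), 2)
  expect_equal(m$CK[m$sequence == "TTTTACGTACGTACGTACGTA"], 0L)
  expect_error(merge_tag_tables(a, a), "duplicate")
})

test_that("length distribution totals match the library and the mode is reported", {
  lib <- raw_library(c("ACGTACGTACGTACGTACGTA",
                       "GGCCGGCCGGCCGGCCGGCCGGCC"),
                     count = c(5L, 3L), label = "CK")
  tags <- collapse_tags(lib)
  h <- length_distribution(tags)
  expect_equal(sum(h$reads), n_reads(lib))
  expect_equal(attr(h, "modal_length"), 21L)
  single <- collapse_tags(raw_library("ACGTACGTACGTACGTACGTACGT", label = "x"))
  expect_equal(attr(length_distribution(single), "modal_length"), 24L)
})

test_that("category accounting reproduces percentages and enforces the partition", {
  tab <- radish_cr_tables()$table1
  ck <- tab[tab$library == "CK" & tab$category != "total", ]
  # reconstruct a tag table whose category masses equal the printed ones
  tags <- data.frame(sequence = sprintf("S%02d", seq_len(nrow(ck))),
                     length = 21L, CK = ck$total)
  class(tags) <- c("tag_table", "data.frame")
  cats <- ifelse(ck$category == "unannotated", "unannotated", ck$category)
  st <- category_accounting(tags, cats, "CK")
  expect_equal(st$total_clean, 18127561)
  got <- st$table[match(c("miRNA", "unannotated"), st$table$category), "total_pct"]
  expect_equal(got, c(9.27, 82.36))
  expect_error(category_accounting(tags, rep(NA_character_, nrow(tags)), "CK"),
               "unassigned|exactly one")
  one <- category_accounting(tags[1, , drop = FALSE], "miRNA", "CK")
  expect_equal(one$table$total_pct[one$table$category == "miRNA"], 100)
})
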