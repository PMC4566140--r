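tags_from <- function(seqs, label = "CK", counts = 1L) {
  collapse_tags(raw_library(seqs, count = counts, label = label))
}

test_that("reference mapping is perfect-match only, on both strands", {
  set.seed(3)
  ref <- c(contig1 = rand_seq(500))
  tag_fwd <- substr(ref, 101, 121)
  tag_rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(substr(ref, 301, 321))))
  tag_mm <- paste0("T", substr(tag_fwd, 2, 21))
  if (tag_mm == tag_fwd) tag_mm <- paste0("G", substr(tag_fwd, 2, 21))
  m <- map_reference(tags_from(c(tag_fwd, tag_rev, tag_mm)), ref)
  fwd <- m$loci[m$loci$sequence == tag_fwd, ]
  expect_equal(c(fwd$start, fwd$end, fwd$strand), c("100", "121", "+"))
  rev <- m$loci[m$loci$sequence == tag_rev, ]
  expect_equal(c(rev$start, rev$end, rev$strand), c("300", "321", "-"))
  expect_false(tag_mm %in% m$loci$sequence)  # 1 mismatch -> unmapped
  expect_equal(sum(m$mapped), 2)
})

test_that("ncRNA exclusion matches substrings and applies class precedence", {
  set.seed(4)
  shared <- rand_seq(21)
  rrna <- paste0(rand_seq(30), shared, rand_seq(30))
  trna <- paste0(rand_seq(10), shared, rand_seq(40))
  db <- data.frame(id = c("r1", "t1"), class = c("rRNA", "tRNA"),
                   sequence = c(rrna, trna), stringsAsFactors = FALSE)
  other <- rand_seq(21)
  res <- filter_ncrna(tags_from(c(shared, other)), db)
  expect_equal(res$classified$class[res$classified$sequence == shared], "rRNA")
  expect_equal(res$remaining$sequence, other)

  # reading a class-labelled FASTA
  f <- tempfile(fileext = ".fa")
  writeLines(c(">r1 class=rRNA", rrna, ">t1 class=tRNA", trna), f)
  expect_equal(read_ncrna_fasta(f)$class, c("rRNA", "tRNA"))
  f2 <- tempfile(fileext = ".fa")
  writeLines(c(">bad", rrna), f2)
  expect_error(read_ncrna_fasta(f2), "class=")
})

test_that("known-miRNA matching agrees with the brute-force Hamming oracle", {
  set.seed(5)
  db <- setNames(vapply(sample(19:24, 10, replace = TRUE), rand_seq, character(1)),
                 sprintf("miR%d", 101:110))
  # tags: some identical, some perturbed, some random
  tag_seqs <- character(50)
  for (i in 1:50) {
    if (i <= 15) {
      base <- db[[sample(10, 1)]]
      nmm <- sample(0:3, 1)
      v <- strsplit(base, "")[[1]]
      for (p in sample(length(v), nmm)) v[p] <- sample(setdiff(c("A","C","G","T"), v[p]), 1)
      tag_seqs[i] <- paste(v, collapse = "")
    } else {
      tag_seqs[i] <- rand_seq(sample(19:24, 1))
    }
  }
  tag_seqs <- unique(tag_seqs)
  hits <- match_mirbase(tags_from(tag_seqs), db)
  for (s in tag_seqs) {
    o <- oracle_match(s, db)
    h <- hits[hits$sequence == s, ]
    if (is.infinite(o$mismatches)) {
      expect_equal(nrow(h), 0)
    } else {
      expect_setequal(h$mirna_id, o$ids)
      expect_true(all(h$mismatches == o$mismatches))
      expect_equal(h$mirna_id[h$primary], o$ids[1])  # database-order tie break
    }
  }
})

test_that("exact hits score zero mismatches and distant tags drop out", {
  db <- c(miRx = "ACGTACGTACGTACGTACGTA")
  hit <- match_mirbase(tags_from("ACGTACGTACGTACGTACGTA"), db)
  expect_equal(hit$mismatches, 0L)
  far <- match_mirbase(tags_from("ACCTACTTACGAACGTACGTA"), db)  # 3 mismatches
  expect_equal(nrow(far), 0)
})

test_that("family assignment strips prefixes/suffixes and applies merges", {
  expect_equal(assign_family("miR156a-3p"), "miR156/157")
  expect_equal(assign_family("miR408-5p"), "miR408")
  expect_equal(assign_family("miR9999x"), "miR9999")
  expect_equal(assign_family("osa-miR166g"), "miR165/166")
  expect_error(assign_family("not-a-mir"), "not-a-mir")
})

test_that("family summary reproduces normalized abundances from raw counts", {
  tab <- radish_cr_tables()
  counts <- data.frame(mirna_id = c("miR158a", "miR158b", "miR535a", "miR535b"),
                       CK = c(400000, 299489, 0, 34),
                       Cr200 = c(1000000, 730976, 2034, 0),
                       stringsAsFactors = FALSE)
  fam <- family_summary(counts, tab$totals)
  r158 <- fam[fam$family == "miR158", ]
  expect_equal(r158$n_members, 2L)
  expect_true(r158$conserved)
  expect_equal(round(r158$norm_CK, 2), 38587.04)
  expect_equal(round(r158$norm_Cr200, 2), 88530.74)
  expect_equal(round(r158$log2fc, 2), 1.20)
  r535 <- fam[fam$family == "miR535", ]
  expect_false(r535$conserved)
  expect_equal(round(r535$norm_Cr200, 4), 104.0289)
  # equal normalized expression in both libraries -> log2fc exactly 0
  eq <- family_summary(data.frame(mirna_id = "miR9999a", CK = 100, Cr200 = 100),
                       c(CK = 1e6, Cr200 = 1e6))
  expect_equal(eq$log2fc, 0)
})
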