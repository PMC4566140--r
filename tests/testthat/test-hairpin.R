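# Build a planted hairpin inside a contig and return its parts.
plant_hairpin <- function(mature_len = 21, target_len = 120, arm = "5p",
                          flank = 300) {
  mature <- rand_seq(mature_len)
  star <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(mature)))
  loop <- rand_seq(12)
  prec <- if (arm == "5p") paste0(mature, loop, star) else paste0(star, loop, mature)
  contig <- paste0(rand_seq(flank), prec, rand_seq(flank))
  mat_start <- if (arm == "5p") flank else flank + mature_len + 12
  list(mature = mature, star = star, precursor = prec, contig = contig,
       mat_start = mat_start)  # 0-based
}

test_that("candidate windows always contain the tag, on both arms", {
  set.seed(70)
  ref <- c(c1 = rand_seq(2000))
  locus <- data.frame(sequence = substr(ref, 501, 521), ref = "c1",
                      start = 500L, end = 521L, strand = "+",
                      stringsAsFactors = FALSE)
  w <- excise_candidates(locus, ref)
  expect_setequal(unique(w$arm), c("5p", "3p"))
  expect_true(all(w$start <= 500 & w$end >= 521))
  expect_true(all(substr(w$precursor, w$tag_offset, w$tag_offset + 20) ==
                    locus$sequence))
  expect_true(all(w$end - w$start <= 350))

  # truncation at the contig edge must not fail
  edge <- data.frame(sequence = substr(ref, 6, 26), ref = "c1",
                     start = 5L, end = 26L, strand = "+", stringsAsFactors = FALSE)
  we <- excise_candidates(edge, ref)
  expect_true(all(we$start >= 0))
  expect_true(all(substr(we$precursor, we$tag_offset, we$tag_offset + 20) ==
                    edge$sequence))
})

test_that("minus-strand windows excise the reverse complement", {
  set.seed(71)
  ref <- c(c1 = rand_seq(1200))
  tag <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(substr(ref, 601, 621))))
  locus <- data.frame(sequence = tag, ref = "c1", start = 600L, end = 621L,
                      strand = "-", stringsAsFactors = FALSE)
  w <- excise_candidates(locus, ref)
  expect_true(all(substr(w$precursor, w$tag_offset, w$tag_offset + 20) == tag))
})

test_that("a perfect inverted repeat is accepted with zero duplex mismatches", {
  set.seed(72)
  hp <- plant_hairpin()
  ref <- c(c1 = hp$contig)
  locus <- data.frame(sequence = hp$mature, ref = "c1", start = hp$mat_start,
                      end = hp$mat_start + 21L, strand = "+", stringsAsFactors = FALSE)
  w <- excise_candidates(locus, ref)
  verdicts <- lapply(seq_len(nrow(w)), function(i) evaluate_hairpin(w[i, ], hp$mature))
  acc <- Filter(function(v) v$accepted, verdicts)
  expect_gt(length(acc), 0)
  # a window matching the planted geometry is accepted with a clean duplex
  clean <- Filter(function(v) v$duplex_mismatches == 0 && v$mature$arm == "5p", acc)
  expect_gt(length(clean), 0)
  best <- acc[[which.min(vapply(acc, function(v) v$fold$mfe, numeric(1)))]]
  expect_lte(best$fold$mfe, -18)
})

test_that("a mature spanning the terminal loop is rejected for that reason", {
  set.seed(73)
  stem <- rand_seq(25)
  star <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(stem)))
  prec <- paste0(stem, rand_seq(8), star)
  # tag centred on the loop
  window <- data.frame(precursor = prec, tag_offset = 18L, stringsAsFactors = FALSE)
  v <- evaluate_hairpin(window, substr(prec, 18, 38))
  expect_false(v$accepted)
  expect_true(v$reason %in% c("mature-in-loop", "mature-spans-arms"))
})

test_that("every accepted candidate verifiably satisfies the criteria", {
  set.seed(74)
  crit <- hairpin_criteria()
  for (i in 1:6) {
    hp <- plant_hairpin(mature_len = sample(20:24, 1),
                        arm = sample(c("5p", "3p"), 1))
    ref <- c(c1 = hp$contig)
    locus <- data.frame(sequence = hp$mature, ref = "c1", start = hp$mat_start,
                        end = hp$mat_start + nchar(hp$mature), strand = "+",
                        stringsAsFactors = FALSE)
    w <- excise_candidates(locus, ref)
    for (j in seq_len(nrow(w))) {
      v <- evaluate_hairpin(w[j, ], hp$mature, criteria = crit)
      if (v$accepted) {
        expect_lte(v$fold$mfe, crit$mfe_max)
        expect_gte(nchar(v$precursor), crit$min_precursor)
        expect_lte(nchar(v$precursor), crit$max_precursor)
        expect_lte(v$duplex_mismatches, crit$max_duplex_mismatch)
        expect_lte(v$asymmetric_bulge, crit$max_asym_bulge)
      }
    }
  }
})

test_that("acceptance is monotone in the MFE threshold", {
  set.seed(75)
  hp <- plant_hairpin()
  ref <- c(c1 = hp$contig)
  locus <- data.frame(sequence = hp$mature, ref = "c1", start = hp$mat_start,
                      end = hp$mat_start + 21L, strand = "+", stringsAsFactors = FALSE)
  w <- excise_candidates(locus, ref)
  strict <- hairpin_criteria(mfe_max = -30)
  loose <- hairpin_criteria(mfe_max = -18)
  for (j in seq_len(nrow(w))) {
    vs <- evaluate_hairpin(w[j, ], hp$mature, criteria = strict)
    vl <- evaluate_hairpin(w[j, ], hp$mature, criteria = loose)
    if (vs$accepted) expect_true(vl$accepted)
  }
})

test_that("two tags from the two arms of one hairpin yield one record with star support", {
  set.seed(76)
  hp <- plant_hairpin()
  ref <- c(c1 = hp$contig)
  tags <- collapse_tags(raw_library(c(hp$mature, hp$star), count = c(10L, 3L),
                                    label = "CK"))
  mp <- map_reference(tags, ref)
  res <- call_novel(tags, mp$loci, ref, tag_table = tags)
  expect_equal(nrow(res$novel), 1)
  expect_true(res$novel$star_observed[1])
  expect_equal(res$novel$novel_id[1], "miRn-1")
})

test_that("no tags means no novel calls", {
  ref <- c(c1 = strrep("ACGT", 100))
  tags <- collapse_tags(raw_library(character(), label = "CK"))
  res <- call_novel(tags, data.frame(sequence = character(), ref = character(),
                                     start = integer(), end = integer(),
                                     strand = character()), ref)
  expect_equal(nrow(res$novel), 0)
})
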