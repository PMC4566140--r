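revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(chartr("U", "T", x))))
}

test_that("expectation scoring applies the penalty table with core doubling", {
  m <- rep("match", 21)
  expect_equal(score_alignment(m), 0)
  s <- m; s[5] <- "GU"
  expect_equal(score_alignment(s), 1.0)        # 0.5 x 2 in core
  s2 <- m; s2[c(15, 16)] <- "mismatch"; s2[20] <- "GU"
  expect_equal(score_alignment(s2), 2.5)       # 1 + 1 + 0.5 outside core
  s3 <- m; s3[3] <- "gap"
  expect_equal(score_alignment(s3), 4)         # gap 2 doubled in core
  expect_error(score_alignment(rep("gap", 2)), "one gap")
})

test_that("expectation is additive over concatenated state lists", {
  set.seed(50)
  states <- sample(c("match", "mismatch", "GU"), 24, replace = TRUE)
  a <- score_alignment(states[1:10], positions = 1:10)
  b <- score_alignment(states[11:24], positions = 11:24)
  expect_equal(score_alignment(states), a + b)
})

test_that("repression mode and structural filters follow the position rules", {
  m <- rep("match", 21)
  expect_equal(classify_mode(m), "cleavage")
  s <- m; s[10] <- "mismatch"
  expect_equal(classify_mode(s), "translation")
  s2 <- m; s2[15] <- "mismatch"
  expect_equal(classify_mode(s2), "cleavage")

  expect_true(schwab_filter(m)$pass)
  f1 <- schwab_filter(s)
  expect_false(f1$pass)
  expect_true("cleavage-site mismatch" %in% f1$reasons)
  s3 <- m; s3[c(3, 7)] <- "mismatch"
  f2 <- schwab_filter(s3)
  expect_false(f2$pass)
  expect_match(f2$reasons, "seed", all = FALSE)
  s4 <- m; s4[14:16] <- "mismatch"
  expect_match(schwab_filter(s4)$reasons, "consecutive", all = FALSE)
})

test_that("a perfect complementary site is found with E = 0", {
  set.seed(51)
  mir <- rand_seq(21)
  tx <- paste0(rand_seq(100), revcomp_chr(mir), rand_seq(80))
  hits <- find_sites(mir, tx, max_expectation = 3)
  perfect <- hits[hits$expectation == 0, ]
  expect_equal(nrow(perfect), 1)
  expect_equal(c(perfect$start, perfect$end), c(100, 121))
  expect_equal(perfect$mode, "cleavage")
  expect_true(perfect$schwab_pass)
})

test_that("planted imperfect sites respect the cutoff", {
  set.seed(52)
  mir <- rand_seq(21)
  site <- strsplit(revcomp_chr(mir), "")[[1]]
  # two non-core mismatches: miRNA positions 15 and 18 -> site columns 7 and 4
  for (col in c(21 - 15 + 1, 21 - 18 + 1)) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    mirbase <- strsplit(mir, "")[[1]][21 - col + 1]
    site[col] <- setdiff(c("A", "C", "G", "T"),
                         c(comp[[mirbase]],
                           if (mirbase == "G") "T" else if (mirbase == "T") "G"))[1]
  }
  tx <- paste0(rand_seq(60), paste(site, collapse = ""), rand_seq(60))
  found3 <- find_sites(mir, tx, max_expectation = 3)
  expect_true(any(found3$start == 60 & found3$expectation == 2))
  found15 <- find_sites(mir, tx, max_expectation = 1.5)
  expect_false(any(found15$start == 60 & found15$gap == "none"))
})

test_that("the site scan equals brute-force window/gap enumeration", {
  set.seed(53)
  for (i in 1:3) {
    mir <- rand_seq(sample(19:22, 1))
    tx <- rand_seq(400)
    got <- find_sites(mir, tx, max_expectation = 4)
    want <- oracle_find_sites(mir, tx, cutoff = 4)
    cols <- c("start", "end", "gap", "gap_pos", "expectation")
    g <- got[cols]; rownames(g) <- NULL
    w <- want[cols]; rownames(w) <- NULL
    expect_equal(g, w)
  }
})

test_that("lowering the cutoff never adds sites", {
  set.seed(54)
  mir <- rand_seq(21)
  tx <- rand_seq(800)
  keys <- function(df) paste(df$start, df$gap, df$gap_pos)
  loose <- find_sites(mir, tx, max_expectation = 5)
  tight <- find_sites(mir, tx, max_expectation = 3)
  expect_true(all(keys(tight) %in% keys(loose)))
  expect_lte(nrow(tight), nrow(loose))
})
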