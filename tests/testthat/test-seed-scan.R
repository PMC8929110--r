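test_that("base pairing rules follow Watson-Crick plus optional wobble", {
  expect_true(rna_pairs("G", "C"))
  expect_true(rna_pairs("A", "U"))
  expect_true(rna_pairs("G", "U", allow_wobble = TRUE))
  expect_false(rna_pairs("G", "U", allow_wobble = FALSE))
  expect_false(rna_pairs("A", "G"))
  expect_false(rna_pairs("A", "A"))
})

test_that("a planted seed site is found with the documented geometry", {
  mirna <- "UGAGGUAGUAGGUUGUAUAGUU"        # let-7a-like
  # CUACCUCA is the reverse complement of miRNA positions 1-8; flank with
  # G on the right (cannot pair U1) and left bases that cannot pair U9
  window <- paste0("CCCC", "CUACCUCA", "G", "CCC")
  hits <- find_seed_matches(window, mirna)
  a1 <- hits[hits$mirna_start == 1L, ]
  expect_equal(nrow(a1), 1L)
  expect_equal(a1$match_len, 8L)
  expect_equal(a1$full_len, 8L)
  expect_equal(a1$wobble_count, 0L)
  expect_equal(c(a1$target_start, a1$target_end), c(5L, 12L))

  # mutating the target base pairing miRNA position 8 to U leaves a G:U
  # wobble: full-length match when wobbles count, a 7-mer otherwise
  window_u <- paste0("CCCC", "UUACCUCA", "G", "CCC")
  h_on <- find_seed_matches(window_u, mirna, allow_wobble = TRUE)
  h_on1 <- h_on[h_on$mirna_start == 1L, ]
  expect_equal(h_on1$match_len, 8L)
  expect_equal(h_on1$wobble_count, 1L)
  h_off <- find_seed_matches(window_u, mirna, allow_wobble = FALSE)
  h_off1 <- h_off[h_off$mirna_start == 1L, ]
  expect_equal(h_off1$match_len, 7L)
  expect_equal(c(h_off1$target_start, h_off1$target_end), c(6L, 12L))

  # nothing pairs in a homopolymer of A against a poly-A miRNA
  expect_equal(nrow(find_seed_matches(strrep("A", 12L), strrep("A", 18L))),
               0L)
  # window shorter than the minimum run cannot match
  expect_equal(nrow(find_seed_matches("ACGUA", mirna)), 0L)
})

test_that("seed scan agrees with the brute-force oracle on fuzzed pairs", {
  set.seed(123)
  for (rep in 1:200) {
    window <- rand_rna(sample(10:45, 1L))
    mirna <- rand_rna(sample(16:26, 1L))
    for (wob in c(TRUE, FALSE)) {
      got <- find_seed_matches(window, mirna, allow_wobble = wob)
      want <- oracle_seed_matches(window, mirna, allow_wobble = wob)
      got <- got[names(want)]
      rownames(got) <- NULL
      expect_equal(got, want,
                   info = sprintf("w=%s m=%s wobble=%s", window, mirna, wob))
    }
  }
})

# Windows seeded with a partial complement of the miRNA 5' end so that
# matches are frequent enough to exercise the properties.
seeded_window <- function(mirna) {
  k <- sample(5:10, 1L)
  paste0(rand_rna(sample(5:15, 1L)), rna_revcomp(substr(mirna, 1L, k)),
         rand_rna(sample(5:15, 1L)))
}

test_that("wobble-off matches are a subset of wobble-on matches", {
  set.seed(321)
  exercised <- 0L
  for (rep in 1:100) {
    mirna <- rand_rna(22L)
    window <- seeded_window(mirna)
    on <- find_seed_matches(window, mirna, allow_wobble = TRUE)
    off <- find_seed_matches(window, mirna, allow_wobble = FALSE)
    # every wobble-free match interval is covered by a wobble-on match with
    # the same anchor and at least the same extent
    for (i in seq_len(nrow(off))) {
      covered <- any(on$mirna_start == off$mirna_start[i] &
                       on$target_start <= off$target_start[i] &
                       on$target_end >= off$target_end[i])
      expect_true(covered, info = paste(window, mirna, i))
      exercised <- exercised + 1L
    }
  }
  expect_gt(exercised, 20L)
})

test_that("output order is lexicographic in (target_start, mirna_start)", {
  set.seed(5)
  exercised <- 0L
  for (rep in 1:50) {
    mirna <- rand_rna(22L)
    hits <- find_seed_matches(seeded_window(mirna), mirna)
    if (nrow(hits) > 1L) {
      ord <- order(hits$target_start, hits$mirna_start)
      expect_equal(ord, seq_len(nrow(hits)))
      exercised <- exercised + 1L
    }
  }
  expect_gt(exercised, 5L)
})
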