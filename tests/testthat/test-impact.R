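site_row <- function(mirna, energy, method = "energy_scan",
                     allele = "REF", variant_id = "v") {
  data.frame(variant_id = variant_id, allele = allele, mirna_name = mirna,
             target_start = 1L, target_end = 8L, mirna_start = 1L,
             mirna_end = 8L, window_start = 1L,
             pairing = strrep("P", 8L), energy = energy,
             seed_class = "canonical_8", method = method,
             stringsAsFactors = FALSE)
}

test_that("allele summaries count distinct miRNAs and sum best energies", {
  s <- rbind(site_row("miR-a", -10), site_row("miR-b", -12))
  expect_equal(summarize_allele(s),
               list(n = 2L, w = -22, mirnas = c("miR-a", "miR-b")))
  s2 <- rbind(site_row("miR-a", -10), site_row("miR-a", -14))
  expect_equal(summarize_allele(s2), list(n = 1L, w = -14, mirnas = "miR-a"))
  expect_equal(summarize_allele(s2, sum_mode = "all")$w, -24)
  expect_equal(summarize_allele(s2[0, ]), list(n = 0L, w = 0,
                                               mirnas = character(0)))
  # invariant under reordering
  expect_equal(summarize_allele(s[2:1, ]), summarize_allele(s))
})

test_that("variant impact derives delta-N, delta-W and gained/lost sets", {
  ref <- list(n = 2L, w = -22, mirnas = c("miR-a", "miR-b"))
  alt <- list(n = 3L, w = -37, mirnas = c("miR-a", "miR-b", "miR-c"))
  imp <- variant_impact(ref, alt, "v1", "energy_scan")
  expect_equal(imp$delta_n, 1L)
  expect_equal(imp$delta_w, -15)
  expect_equal(imp$gained, "miR-c")
  expect_equal(imp$lost, "")

  same <- variant_impact(ref, ref, "v2", "energy_scan")
  expect_equal(c(same$delta_n, same$delta_w), c(0, 0))

  gone <- variant_impact(list(n = 1L, w = -10, mirnas = "miR-a"),
                         list(n = 0L, w = 0, mirnas = character(0)),
                         "v3", "seed_scan")
  expect_equal(gone$delta_n, -1L)
  expect_equal(gone$delta_w, 10)
  expect_equal(gone$lost, "miR-a")
})

test_that("swapping alleles negates delta-N and delta-W exactly", {
  set.seed(52)
  for (rep in 1:25) {
    mk <- function() {
      n <- sample(0:4, 1L)
      mirs <- sample(paste0("miR-", letters[1:6]), n)
      list(n = n, w = if (n) sum(runif(n, -30, -9)) else 0, mirnas = mirs)
    }
    a <- mk(); b <- mk()
    ab <- variant_impact(a, b, "v", "energy_scan")
    ba <- variant_impact(b, a, "v", "energy_scan")
    expect_equal(ab$delta_n, -ba$delta_n)
    expect_equal(ab$delta_w, -ba$delta_w)
    expect_equal(ab$gained, ba$lost)
  }
})

impacts_frame <- function(delta_w, delta_n = rep(0L, length(delta_w)),
                          method = "energy_scan") {
  do.call(rbind, lapply(seq_along(delta_w), function(i)
    variant_impact(list(n = 0L, w = 0, mirnas = character(0)),
                   list(n = delta_n[i], w = delta_w[i],
                        mirnas = rep("x", delta_n[i])),
                   sprintf("v%03d", i), method)))
}

test_that("Tukey fences flag the documented outlier patterns", {
  # {0 x 7, -30}: Q1 = Q3 = 0, IQR = 0 -> fence 0, only -30 flagged
  imp <- flag_outliers(impacts_frame(c(rep(0, 7), -30)))
  expect_equal(imp$outlier_w, c(rep(FALSE, 7), TRUE))

  # all equal: zero spread, nothing flagged
  imp2 <- flag_outliers(impacts_frame(rep(-3, 10)))
  expect_false(any(imp2$outlier_w))

  # delta-N {0 x 19, +5}: the single gain is flagged
  imp3 <- flag_outliers(impacts_frame(rep(0, 20), c(rep(0L, 19), 5L)))
  expect_equal(imp3$outlier_n, c(rep(FALSE, 19), TRUE))

  # flags are invariant under permutation of the input order
  set.seed(8)
  dw <- c(runif(30, -2, 2), -40, 25)
  base <- flag_outliers(impacts_frame(dw))
  perm <- sample(nrow(base))
  shuf <- flag_outliers(impacts_frame(dw[perm]))
  expect_equal(shuf$outlier_w, base$outlier_w[perm])
})

test_that("small cohorts warn and fall back to sign-based flags", {
  expect_warning(imp <- flag_outliers(impacts_frame(c(0, -5, 3))),
                 "fewer than 8")
  expect_equal(imp$outlier_w, c(FALSE, TRUE, FALSE))
})

test_that("candidates require gained miRNAs, stronger binding, outlier", {
  imp <- impacts_frame(c(-62.01, -40, 3, rep(0, 17)),
                       c(5L, 0L, 1L, rep(0L, 17)))
  imp$delta_n <- c(5L, -2L, 1L, rep(0L, 17))   # force a count-loss row
  imp <- flag_outliers(imp)
  cand <- select_candidates(imp)
  expect_equal(cand$variant_id, "v001")       # dN=5, dW=-62.01, outlier_w
  expect_true(all(cand$candidate))
  # sorted by ascending delta_w within method
  imp2 <- impacts_frame(c(-50, -70, rep(0, 18)), c(1L, 1L, rep(0L, 18)))
  cand2 <- select_candidates(flag_outliers(imp2))
  expect_equal(cand2$delta_w, c(-70, -50))
})
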