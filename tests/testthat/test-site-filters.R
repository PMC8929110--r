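# Build a site row directly from a pairing layout for classification tests.
fake_site <- function(pairing, mirna_end, energy = -20,
                      mirna_name = "miR-x", method = "energy_scan") {
  data.frame(variant_id = "v", allele = "REF", mirna_name = mirna_name,
             target_start = 1L, target_end = 1L,
             mirna_start = mirna_end - sum(strsplit(pairing, "")[[1]] %in%
                                             c("P", "W", "M")) + 1L,
             mirna_end = mirna_end, window_start = 1L, pairing = pairing,
             energy = energy, seed_class = NA_character_, method = method,
             stringsAsFactors = FALSE)
}

test_that("seed-pattern taxonomy follows the stated priority order", {
  # 8 contiguous Watson-Crick pairs at miRNA 1-8
  expect_equal(classify_site(fake_site(strrep("P", 8L), 8L)), "canonical_8")
  # 7 pairs at miRNA 2-8
  expect_equal(classify_site(fake_site(strrep("P", 7L), 8L)), "canonical_7")
  # 6 pairs at miRNA 2-7
  expect_equal(classify_site(fake_site(strrep("P", 6L), 7L)), "canonical_6")
  # a longer run is classified by its seed-region coverage
  expect_equal(classify_site(fake_site(strrep("P", 12L), 12L)),
               "canonical_8")
  # one wobble inside the seed still counts as canonical by default...
  expect_equal(classify_site(fake_site("PPPWPPPP", 8L)), "canonical_8")
  # ...but splits the run when wobbles are disallowed in canonical seeds
  cfg_nw <- filter_config(wobble_in_canonical = FALSE)
  expect_equal(classify_site(fake_site("PPPWPPPP", 8L), cfg_nw), "none")

  # 11 contiguous pairs at miRNA 4-14, no seed -> centered
  expect_equal(classify_site(fake_site(strrep("P", 11L), 14L)), "centered")
  # the same run starting at position 2 covers 7 seed bases -> canonical
  expect_equal(classify_site(fake_site(strrep("P", 11L), 12L)),
               "canonical_7")
  # 11 pairs starting at position 7 is neither centered nor canonical
  expect_equal(classify_site(fake_site(strrep("P", 11L), 17L)), "none")

  # seed 2-8 with one wobble-free defect plus a 4-pair 3' helix at 13-16:
  # layout (miRNA 16 -> 2): PPPP MMMM PP M PPPP = pairs at 13-16, loop over
  # 9-12, pairs 7-8, mismatch at 6, pairs 2-5
  comp <- "PPPPMMMMPPMPPPP"
  expect_equal(classify_site(fake_site(comp, 16L)), "compensatory")
  # with the 3' helix shortened to 3 pairs the compensation fails
  comp3 <- "PPPMMMMMPPMPPPP"
  expect_equal(classify_site(fake_site(comp3, 16L)), "none")
  # a seed wobble: canonical while wobbles count as pairs, compensatory
  # (the single permitted defect) once they do not
  compw <- "PPPPMMMMPPWPPPP"
  expect_equal(classify_site(fake_site(compw, 16L)), "canonical_7")
  expect_equal(classify_site(fake_site(compw, 16L), cfg_nw), "compensatory")
})

test_that("energy cutoff is boundary-inclusive and whitelist exact", {
  cfg <- filter_config(whitelist = c("miR-a"))
  sites <- rbind(
    fake_site(strrep("P", 8L), 8L, energy = -8.5, mirna_name = "miR-a"),
    fake_site(strrep("P", 8L), 8L, energy = -8.4, mirna_name = "miR-a"),
    fake_site(strrep("P", 8L), 8L, energy = -20, mirna_name = "miR-b"),
    fake_site("PP", 8L, energy = -30, mirna_name = "miR-a"))
  sites <- classify_sites(sites, cfg)
  kept <- filter_sites(sites, cfg)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$energy, -8.5)
  # class gate: a strong site with no recognizable seed pattern is dropped
  expect_false(any(kept$seed_class == "none"))
})

test_that("filtering is idempotent, order-preserving and monotone", {
  set.seed(31)
  sites <- do.call(rbind, lapply(1:40, function(i)
    fake_site(strrep("P", sample(6:12, 1L)), sample(8:14, 1L),
              energy = runif(1, -25, -2),
              mirna_name = sample(c("miR-a", "miR-b", "miR-c"), 1L))))
  cfg <- filter_config(whitelist = c("miR-a", "miR-b"))
  sites <- classify_sites(sites, cfg)
  once <- filter_sites(sites, cfg)
  twice <- filter_sites(once, cfg)
  expect_identical(once, twice)
  expect_true(all(diff(match(once$energy, sites$energy)) > 0))

  # stricter cutoff never retains more sites
  cuts <- seq(-2, -25, by = -0.5)
  counts <- vapply(cuts, function(cut)
    nrow(filter_sites(sites, filter_config(energy_cutoff = cut,
                                           whitelist = c("miR-a", "miR-b")))),
    integer(1))
  expect_true(all(diff(counts) <= 0L))

  # enlarging the whitelist never shrinks the retained set
  n_small <- nrow(filter_sites(sites, filter_config(whitelist = "miR-a")))
  n_large <- nrow(filter_sites(sites, cfg))
  expect_gte(n_large, n_small)
})

test_that("filter_config rejects non-negative cutoffs", {
  expect_error(filter_config(energy_cutoff = 1), "negative")
  expect_error(filter_config(energy_cutoff = 0), "negative")
})
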