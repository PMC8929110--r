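test_that("the embedded parameter set is complete and sane", {
  m <- energy_model()
  expect_equal(dim(m$stack), c(6L, 6L))
  expect_true(all(is.finite(m$stack)))
  expect_equal(m$stack, t(m$stack))          # nearest-neighbor symmetry
  # Watson-Crick-only steps are all stabilizing; only G-U self-stacks may
  # be destabilizing
  wc <- c("CG", "GC", "AU", "UA")
  expect_true(all(m$stack[wc, wc] < 0))
  expect_true(m$init_penalty > 0)
  expect_true(m$loop_open >= 0 && m$bulge_open >= 0)
})

test_that("score_structure sums helix stacks, initiation and loop terms", {
  m <- energy_model()
  # 8-bp helix: target = reverse complement of the miRNA 5' end
  mir <- "UGAGGCAGCAGGUUGUAUAGUU"
  helix <- rna_revcomp(substr(mir, 1L, 8L))   # pairs miRNA 1-8
  # hand-summed pair steps: helix target is CUGCCUCA pairing miRNA 8..1
  # (G,A,C,G,G,A,G,U); each step indexed [5' pair, reversed 3' pair]
  steps <- c(m$stack["CG", "AU"], m$stack["UA", "CG"], m$stack["GC", "GC"],
             m$stack["CG", "GC"], m$stack["CG", "AU"], m$stack["UA", "GC"],
             m$stack["CG", "UA"])
  expect_equal(score_structure(strrep("P", 8L), helix, mir, 1L, 1L, 8L, m),
               m$init_penalty + sum(steps), tolerance = 1e-9)

  # zero pairs -> no interaction sentinel
  expect_equal(score_structure("", "ACGU", "ACGU", 1L, 1L, 0L, m), Inf)

  # a 1-nt target bulge breaks one stack and adds the affine bulge cost
  target_b <- paste0(substr(helix, 1L, 4L), "A", substr(helix, 5L, 8L))
  e_helix <- score_structure(strrep("P", 8L), helix, mir, 1L, 1L, 8L, m)
  e_bulge <- score_structure("PPPPTPPPP", target_b, mir, 1L, 1L, 8L, m)
  broken <- m$stack["CG", "GC"]   # the step between target positions 4 and 5
  expect_equal(e_bulge,
               e_helix - broken + m$bulge_open + m$bulge_extend_per_nt,
               tolerance = 1e-9)

  # malformed structures are rejected
  expect_error(score_structure("TPPPPPPP", helix, mir, 1L, 1L, 8L, m),
               "begin and end with a pair")
  expect_error(score_structure("PPPPPPPP", "AAAAAAAA", mir, 1L, 1L, 8L, m),
               "cannot pair")
})

test_that("wobble pairs must be coded W and vice versa", {
  m <- energy_model()
  # G:U at the first position
  expect_error(score_structure("PP", "GC", "GU", 1L, 1L, 2L, m),
               "is a wobble")
  expect_silent(score_structure("WP", "GC", "GU", 1L, 1L, 2L, m))
})

test_that("duplex MFE equals exhaustive enumeration on small sequences", {
  set.seed(2024)
  m <- energy_model()
  n_checked <- 0L
  for (rep in 1:120) {
    target <- rand_rna(sample(6:8, 1L))   # duplex_mfe requires >= 6 nt
    mirna <- rand_rna(sample(4:8, 1L))
    want <- oracle_duplex_energy(target, mirna, m)
    site <- duplex_mfe(paste0(target), mirna, m, require_seed = FALSE)
    if (is.null(site)) {
      expect_true(want >= 0 || !is.finite(want),
                  info = paste(target, mirna))
    } else {
      expect_equal(site$energy, want, tolerance = 1e-6,
                   info = paste(target, mirna))
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 10L)   # the fuzz actually exercised favorable cases
})

test_that("every emitted site's energy is reproduced from its pairing", {
  set.seed(77)
  m <- energy_model()
  for (rep in 1:60) {
    window <- rand_rna(sample(30:50, 1L))
    mirna <- rand_rna(21L)
    for (rs in c(TRUE, FALSE)) {
      site <- duplex_mfe(window, mirna, m, require_seed = rs)
      if (is.null(site)) next
      e <- score_structure(site$pairing, window, mirna, site$target_start,
                           site$mirna_start, site$mirna_end, m)
      expect_equal(e, site$energy, tolerance = 1e-6)
    }
  }
})

test_that("perfect complements score as a single full-length helix", {
  m <- energy_model()
  mir <- fixture_mirna()
  window <- paste0("AAAAA", rna_revcomp(mir), "GGGGG")
  site <- duplex_mfe(window, mir, m, require_seed = TRUE)
  expect_equal(site$mirna_start, 1L)
  expect_equal(site$mirna_end, nchar(mir))
  expect_equal(site$pairing, strrep("P", nchar(mir)))
  expect_equal(site$energy,
               score_structure(site$pairing, window, mir, site$target_start,
                               1L, nchar(mir), m),
               tolerance = 1e-9)
})

test_that("MFE is monotone non-increasing under window extension", {
  set.seed(404)
  m <- energy_model()
  for (rep in 1:25) {
    mirna <- rand_rna(20L)
    core <- rand_rna(25L)
    ext <- paste0(rand_rna(8L), core, rand_rna(8L))
    e_core <- duplex_mfe(core, mirna, m, require_seed = FALSE)
    e_ext <- duplex_mfe(ext, mirna, m, require_seed = FALSE)
    e1 <- if (is.null(e_core)) 0 else e_core$energy
    e2 <- if (is.null(e_ext)) 0 else e_ext$energy
    expect_lte(e2, e1 + 1e-9)
  }
})

test_that("seed-constrained optimum is bounded below by the free optimum", {
  set.seed(808)
  m <- energy_model()
  for (rep in 1:40) {
    window <- rand_rna(40L)
    mirna <- rand_rna(21L)
    free <- duplex_mfe(window, mirna, m, require_seed = FALSE)
    cons <- duplex_mfe(window, mirna, m, require_seed = TRUE)
    if (is.null(cons)) next
    expect_false(is.null(free))
    expect_gte(cons$energy, free$energy - 1e-9)
    # the constrained structure really contains a >= 6-pair seed helix
    dec <- utrmirscan:::decode_pairing(cons$pairing, cons$mirna_end)
    hel <- dec$helices
    cover <- pmin(hel$m_hi, 8L) - pmax(hel$m_lo, 1L) + 1L
    expect_true(any(cover >= 6L))
  }
})

test_that("seed hits re-score in their exact hybrid configuration", {
  m <- energy_model()
  mir <- fixture_mirna()
  # seed-only context: complement of positions 1-8, no 3' pairing possible
  window <- paste0("AAAAAA", rna_revcomp(substr(mir, 1L, 8L)), "G")
  hits <- find_seed_matches(window, mir)
  hit <- hits[hits$mirna_start == 1L & hits$full_len == 8L, ][1, ]
  site <- rescore_seed_hit(hit, window, mir, m)
  expect_equal(site$method, "seed_scan")
  expect_equal(site$mirna_start, 1L)
  helix_e <- score_structure(strrep("P", 8L),
                             rna_revcomp(substr(mir, 1L, 8L)),
                             mir, 1L, 1L, 8L, m)
  # left extension may add favorable pairs only
  expect_lte(site$energy, helix_e + 1e-9)
  e <- score_structure(site$pairing, window, mir, site$target_start,
                       site$mirna_start, site$mirna_end, m)
  expect_equal(e, site$energy, tolerance = 1e-6)

  # an unfavorable hit is still returned (filtering is downstream)
  weak <- paste0("CCCCCC", "AUAUAU", "CCC")   # pairs a weak AU-only seed
  wk_m <- paste0("AUAUAU", rand_rna(15L))
  wh <- find_seed_matches(weak, wk_m)
  if (nrow(wh) > 0L) {
    ws <- rescore_seed_hit(wh[1, ], weak, wk_m, m)
    expect_true(is.finite(ws$energy))
  }
})
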