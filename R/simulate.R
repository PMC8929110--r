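# Synthetic ground-truth data: random UTR backgrounds with planted miRNA
# sites and variants that create, destroy, or leave sites untouched. The
# high-level generator (simulate_dataset) verifies every planted effect
# against the pipeline's own gates at plant time and re-rolls the local
# context otherwise, so its truth labels are guaranteed to hold under the
# configured filters.

RNA_BASES <- c("A", "C", "G", "U")

random_rna <- function(n, composition = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(RNA_BASES, n, replace = TRUE, prob = composition),
        collapse = "")
}

rna_complement <- function(bases) {
  chartr("ACGU", "UGCA", bases)
}

#' Reverse complement of an RNA sequence
#' @param seq RNA string.
#' @return The Watson-Crick reverse complement.
#' @export
rna_revcomp <- function(seq) {
  paste(rev(strsplit(rna_complement(seq), "")[[1]]), collapse = "")
}

# A base that pairs b neither Watson-Crick nor by wobble.
nonpairing_base <- function(b) {
  cand <- RNA_BASES[!rna_pairs(RNA_BASES, b, allow_wobble = TRUE)]
  sample(cand, 1L)
}

# Target segment realizing a site class for a miRNA: the exact antiparallel
# complement of the dictated miRNA interval, plus non-pairing guard bases
# where a run must not extend. var_offset marks the segment position whose
# mutation makes or breaks the site (pairs a mid-seed miRNA position).
site_segment <- function(mirna, site_class) {
  mb <- strsplit(mirna, "")[[1]]
  if (site_class == "canonical_8") {
    lo <- 1L; hi <- 12L
    core <- rna_revcomp(substr(mirna, lo, hi))
    seq <- core; core_at <- 1L
  } else if (site_class %in% c("canonical_7", "canonical_6")) {
    lo <- 1L; hi <- if (site_class == "canonical_7") 7L else 6L
    core <- rna_revcomp(substr(mirna, lo, hi))
    guard <- nonpairing_base(mb[hi + 1L])  # stop the run at miRNA hi
    seq <- paste0(guard, core); core_at <- 2L
  } else if (site_class == "centered") {
    lo <- 4L; hi <- 14L
    core <- rna_revcomp(substr(mirna, lo, hi))
    guard_l <- nonpairing_base(mb[hi + 1L])
    guard_r <- nonpairing_base(mb[lo - 1L])
    seq <- paste0(guard_l, core, guard_r); core_at <- 2L
  } else stop("unsupported site class for planting: ", site_class)
  # segment offset pairing miRNA position j: core_at + (hi - j)
  var_mirna_pos <- if (site_class == "centered") 8L else 4L
  list(seq = seq, m_lo = lo, m_hi = hi, core_at = core_at,
       var_offset = core_at + (hi - var_mirna_pos),
       var_mirna_pos = var_mirna_pos)
}

#' Specify one planted miRNA site
#'
#' @param mirna_name,mirna_seq The miRNA to plant a site for.
#' @param position 1-based UTR offset of the planted segment start.
#' @param site_class Seed class to plant (`canonical_8`, `canonical_7`,
#'   `canonical_6` or `centered`).
#' @param effect `"neutral"` (site present on both alleles),
#'   `"destroy_on_alt"` (site present on REF, broken by the variant) or
#'   `"create_on_alt"` (site broken on REF, completed by the variant).
#' @return A list of class `plant_spec`.
#' @export
plant_spec <- function(mirna_name, mirna_seq, position,
                       site_class = "canonical_8",
                       effect = c("neutral", "destroy_on_alt",
                                  "create_on_alt")) {
  effect <- match.arg(effect)
  structure(list(mirna_name = mirna_name,
                 mirna_seq = normalize_rna(mirna_seq, mirna_name)$sequence,
                 position = as.integer(position),
                 site_class = site_class, effect = effect),
            class = "plant_spec")
}

#' Generate a random UTR with planted miRNA sites
#'
#' Builds a uniform-composition (optionally AU-rich) random background and
#' writes each planted segment — the exact antiparallel complement dictated
#' by its site class — at its position. Segments must not overlap. For each
#' planted canonical site whose helix-only energy passes the default
#' -8.5 kcal/mol cutoff, the generator asserts that the seed scan recovers
#' the site at the planted interval.
#'
#' @param length UTR length (nt).
#' @param plants List of [plant_spec()] objects.
#' @param rng_seed Integer seed; all randomness flows from it.
#' @param composition Probabilities of A, C, G, U in the background.
#' @return List with `utr` (a [utr_sequence()]) and `truth` (data frame:
#'   one row per plant with the planted interval, class, effect, the
#'   site-making/-breaking variant position with its REF/ALT bases, and the
#'   helix-only energy of the planted duplex).
#' @export
generate_utr <- function(length, plants, rng_seed,
                         composition = c(0.25, 0.25, 0.25, 0.25)) {
  set.seed(rng_seed)
  segs <- lapply(plants, function(p) site_segment(p$mirna_seq, p$site_class))
  starts <- vapply(plants, function(p) p$position, integer(1))
  ends <- starts + vapply(segs, function(s) nchar(s$seq), integer(1)) - 1L
  if (any(ends > length))
    stop("planted site extends past the UTR end")
  ord <- order(starts)
  if (any(starts[ord][-1] <= ends[ord][-length(ord)]))
    stop("overlapping planted sites")

  bases <- strsplit(random_rna(length, composition), "")[[1]]
  truth <- list()
  for (i in seq_along(plants)) {
    p <- plants[[i]]; s <- segs[[i]]
    seg_bases <- strsplit(s$seq, "")[[1]]
    var_pos <- starts[i] + s$var_offset - 1L
    mb <- strsplit(p$mirna_seq, "")[[1]]
    pairing_base <- rna_complement(mb[s$var_mirna_pos])
    broken_base <- nonpairing_base(mb[s$var_mirna_pos])
    if (p$effect == "create_on_alt") {
      seg_bases[s$var_offset] <- broken_base
      ref_base <- broken_base; alt_base <- pairing_base
    } else {
      ref_base <- pairing_base
      alt_base <- if (p$effect == "destroy_on_alt") broken_base
                  else NA_character_
    }
    bases[starts[i]:ends[i]] <- seg_bases
    # planted complements are Watson-Crick throughout, so the helix-only
    # structure is all 'P'
    helix_target <- rna_revcomp(substr(p$mirna_seq, s$m_lo, s$m_hi))
    helix_energy <- score_structure(
      strrep("P", nchar(helix_target)),
      helix_target, p$mirna_seq, 1L, s$m_lo, s$m_hi)
    truth[[i]] <- data.frame(
      mirna_name = p$mirna_name, mirna_seq = p$mirna_seq,
      site_class = p$site_class, effect = p$effect,
      target_start = starts[i], target_end = ends[i],
      variant_pos = var_pos, ref_base = ref_base, alt_base = alt_base,
      helix_energy = helix_energy, stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth)
           else data.frame()
  utr <- utr_sequence("sim_utr", paste(bases, collapse = ""))

  # recall assertion for planted canonical sites present on REF
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    if (!startsWith(tr$site_class, "canonical") ||
        tr$effect == "create_on_alt" || tr$helix_energy > -8.5) next
    ctx_lo <- max(1L, tr$target_start - 10L)
    window <- substr(utr$sequence, ctx_lo,
                     min(nchar(utr$sequence), tr$target_end + 10L))
    hits <- find_seed_matches(window, tr$mirna_seq)
    # the seed anchor (miRNA position 1) pairs the rightmost core base
    core_end <- tr$target_end - ctx_lo + 1L
    if (!any(hits$mirna_start == 1L & hits$target_end == core_end))
      stop("planted canonical site not recovered by the seed scan ",
           "(internal generator error)")
  }
  list(utr = utr, truth = truth)
}

#' Derive the variant set implied by a planted truth table
#'
#' Emits the site-breaking SNP of every `destroy_on_alt` plant, the
#' site-completing SNP of every `create_on_alt` plant, and `n_neutral`
#' additional SNPs placed outside every planted window, with the expected
#' delta-N sign recorded per variant.
#'
#' @param utr The [utr_sequence()] from [generate_utr()].
#' @param truth The truth table from [generate_utr()].
#' @param n_neutral Number of neutral background SNPs to add.
#' @param rng_seed Integer seed.
#' @param window_len Window length used to keep neutral SNPs clear of
#'   planted sites.
#' @return Data frame with columns `variant_id`, `position`, `ref`, `alt`,
#'   `variant_class` and `expected_sign` (`"+"`, `"-"` or `"0"`).
#' @export
generate_variant_set <- function(utr, truth, n_neutral = 0L, rng_seed = 1L,
                                 window_len = 50L) {
  set.seed(rng_seed)
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    if (tr$effect == "neutral") next
    rows[[length(rows) + 1L]] <- data.frame(
      variant_id = sprintf("plant_%03d_%s", i,
                           if (tr$effect == "create_on_alt") "create"
                           else "destroy"),
      position = tr$variant_pos, ref = tr$ref_base, alt = tr$alt_base,
      expected_sign = if (tr$effect == "create_on_alt") "+" else "-",
      stringsAsFactors = FALSE)
  }
  if (n_neutral > 0L) {
    occupied <- rep(FALSE, nchar(utr$sequence))
    half <- window_len %/% 2L
    for (i in seq_len(nrow(truth))) {
      lo <- max(1L, truth$target_start[i] - half - window_len)
      hi <- min(nchar(utr$sequence), truth$target_end[i] + half + window_len)
      occupied[lo:hi] <- TRUE
    }
    free <- which(!occupied)
    if (length(free) < n_neutral)
      stop("UTR too short to place ", n_neutral, " neutral SNPs away from ",
           "all planted sites")
    pos <- sort(sample(free, n_neutral))
    for (j in seq_len(n_neutral)) {
      ref <- substr(utr$sequence, pos[j], pos[j])
      alt <- sample(setdiff(RNA_BASES, ref), 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = sprintf("neutral_%03d", j),
        position = pos[j], ref = ref, alt = alt, expected_sign = "0",
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  expected <- df$expected_sign
  df$expected_sign <- NULL
  df <- validate_variants(df, utr)
  df$expected_sign <- expected
  df
}

# Draw a pool of synthetic mature miRNAs (21 nt) suitable for planting:
# each candidate is rejection-sampled until (a) its 12-pair planted helix
# clears the default energy cutoff with margin, (b) the helix core matches
# only on the intended diagonal (no internal self-similarity), and (c)
# breaking the pair at miRNA position 4 removes every seed match for every
# possible non-pairing substitution. These are deterministic properties of
# the miRNA itself, so planted create/destroy variants cannot be undone by
# shifted self-matches.
draw_mirna_pool <- function(n, len = 21L, max_attempts = 500L) {
  seqs <- character(0)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (attempt in seq_len(max_attempts)) {
      cand <- random_rna(len)
      core <- rna_revcomp(substr(cand, 1L, 12L))
      helix_e <- score_structure(strrep("P", 12L), core, cand, 1L, 1L, 12L)
      if (helix_e > -12) next
      hits <- find_seed_matches(core, cand)
      if (nrow(hits) == 0L || any(hits$target_end < 11L)) next
      m4 <- substr(cand, 4L, 4L)
      bad <- FALSE
      for (b in RNA_BASES[!rna_pairs(RNA_BASES, m4, allow_wobble = TRUE)]) {
        broken <- core
        substr(broken, 9L, 9L) <- b        # core offset 9 pairs miRNA 4
        if (nrow(find_seed_matches(broken, cand)) > 0L) { bad <- TRUE; break }
      }
      if (bad || cand %in% seqs) next
      seqs <- c(seqs, cand)
      ok <- TRUE
      break
    }
    if (!ok) stop("could not draw a usable synthetic miRNA pool")
  }
  mirna_library(sprintf("sim-miR-%02d", seq_len(n)), seqs)
}

# Check one planted block against the pipeline's own gates: delta-N /
# delta-W per configured method must match the intended effect exactly.
verify_block <- function(ref_window, alt_window, mirnas, whitelist, cfg,
                         model, fcfg, effect, target_mirna) {
  summaries <- list()
  for (allele in c("REF", "ALT")) {
    window <- if (allele == "REF") ref_window else alt_window
    raw <- scan_window(window, mirnas, cfg, model, "blk", allele)
    raw <- classify_sites(raw, fcfg)
    summaries[[allele]] <- filter_sites(raw, fcfg)
  }
  for (method in cfg$methods) {
    rs <- summarize_allele(
      summaries$REF[summaries$REF$method == method, , drop = FALSE],
      cfg$sum_mode)
    as <- summarize_allele(
      summaries$ALT[summaries$ALT$method == method, , drop = FALSE],
      cfg$sum_mode)
    dn <- as$n - rs$n
    dw <- as$w - rs$w
    ok <- switch(effect,
      create_on_alt = dn == 1L && dw < 0 &&
        setequal(setdiff(as$mirnas, rs$mirnas), target_mirna),
      destroy_on_alt = dn == -1L && dw > 0 &&
        setequal(setdiff(rs$mirnas, as$mirnas), target_mirna),
      neutral = dn == 0L)
    if (!isTRUE(ok)) return(FALSE)
  }
  TRUE
}

#' Simulate a verified ground-truth dataset
#'
#' High-level generator used for validation: builds a block-structured UTR
#' in which each variant owns one window-sized block, planting strong
#' canonical sites (12-pair Watson-Crick helices against GC-biased-seed
#' 21-nt miRNAs) for create/destroy variants and leaving neutral blocks
#' site-free. Every block is verified against the full filter chain (both
#' routes, classification, energy cutoff, whitelist) and re-rolled until
#' its intended delta-N / delta-W signature holds exactly, so the returned
#' expectations are guaranteed under the supplied configuration.
#'
#' @param n_create,n_destroy,n_neutral Number of variants of each kind.
#' @param rng_seed Integer seed; all randomness flows from it.
#' @param pool_size Number of distinct miRNAs shared across blocks (the
#'   whitelist).
#' @param cfg A [run_config()].
#' @param composition Background base composition (A, C, G, U).
#' @param max_attempts Re-roll budget per block.
#' @return List with `utr`, `variants` (including `expected_sign`),
#'   `mirnas`, `whitelist` and `truth` (per-variant intended effect).
#' @export
simulate_dataset <- function(n_create = 0L, n_destroy = 0L, n_neutral = 0L,
                             rng_seed = 1L, pool_size = 6L,
                             cfg = run_config(),
                             composition = c(0.25, 0.25, 0.25, 0.25),
                             max_attempts = 100L) {
  set.seed(rng_seed)
  mirnas <- draw_mirna_pool(pool_size)
  whitelist <- mirnas$name
  model <- energy_model(cfg$max_internal_unpaired)
  fcfg <- filter_config(energy_cutoff = cfg$energy_cutoff,
                        whitelist = whitelist,
                        wobble_in_canonical = cfg$wobble_in_canonical)
  effects <- c(rep("create_on_alt", n_create),
               rep("destroy_on_alt", n_destroy),
               rep("neutral", n_neutral))
  if (length(effects) == 0L) stop("nothing to simulate")
  half <- cfg$window_len %/% 2L
  block_len <- cfg$window_len + 20L
  local_pos <- half + 10L                   # variant position within block

  blocks <- character(length(effects))
  vars <- list()
  for (b in seq_along(effects)) {
    effect <- effects[b]
    mir <- mirnas[(b - 1L) %% nrow(mirnas) + 1L, , drop = FALSE]
    mb <- strsplit(mir$sequence, "")[[1]]
    done <- FALSE
    for (attempt in seq_len(max_attempts)) {
      blk <- strsplit(random_rna(block_len, composition), "")[[1]]
      if (effect == "neutral") {
        ref_base <- blk[local_pos]
        alt_base <- sample(setdiff(RNA_BASES, ref_base), 1L)
      } else {
        core <- strsplit(rna_revcomp(substr(mir$sequence, 1L, 12L)),
                         "")[[1]]
        seg_start <- local_pos - 8L          # segment offset 9 pairs miRNA 4
        blk[seg_start:(seg_start + 11L)] <- core
        pairing_base <- rna_complement(mb[4L])
        broken_base <- nonpairing_base(mb[4L])
        if (effect == "create_on_alt") {
          blk[local_pos] <- broken_base
          ref_base <- broken_base; alt_base <- pairing_base
        } else {
          ref_base <- pairing_base; alt_base <- broken_base
        }
      }
      win_lo <- local_pos - half
      win_hi <- local_pos + half - 1L
      ref_window <- paste(blk[win_lo:win_hi], collapse = "")
      alt_blk <- blk
      alt_blk[local_pos] <- alt_base
      alt_window <- paste(alt_blk[win_lo:win_hi], collapse = "")
      if (verify_block(ref_window, alt_window, mirnas, whitelist, cfg,
                       model, fcfg, effect, mir$name)) {
        done <- TRUE
        break
      }
    }
    if (!done)
      stop("could not realize planted effect '", effect, "' for ",
           mir$name, " after ", max_attempts, " attempts")
    blocks[b] <- paste(blk, collapse = "")
    vars[[b]] <- data.frame(
      variant_id = sprintf("sim_%03d_%s", b, sub("_on_alt", "", effect)),
      position = (b - 1L) * block_len + local_pos,
      ref = ref_base, alt = alt_base,
      expected_sign = switch(effect, create_on_alt = "+",
                             destroy_on_alt = "-", neutral = "0"),
      mirna_name = mir$name,
      stringsAsFactors = FALSE)
  }
  utr <- utr_sequence("sim_utr", paste(blocks, collapse = ""))
  variants <- do.call(rbind, vars)
  extra <- variants[c("expected_sign", "mirna_name")]
  df <- validate_variants(variants[c("variant_id", "position", "ref", "alt")],
                          utr)
  df <- cbind(df, extra)
  list(utr = utr, variants = df, mirnas = mirnas, whitelist = whitelist,
       truth = data.frame(variant_id = df$variant_id,
                          effect = effects,
                          expected_sign = df$expected_sign,
                          stringsAsFactors = FALSE))
}
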