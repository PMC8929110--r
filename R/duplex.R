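# R surface over the C++ hybrid MFE search: site construction, the
# energy-route scan (duplex_mfe) and the re-scoring of seed-scan hits in
# their exact hybrid configuration.

empty_sites <- function() {
  data.frame(variant_id = character(), allele = character(),
             mirna_name = character(), target_start = integer(),
             target_end = integer(), mirna_start = integer(),
             mirna_end = integer(), window_start = integer(),
             pairing = character(),
             energy = numeric(), seed_class = character(),
             method = character(), stringsAsFactors = FALSE)
}

# Build the pairing string (codes P/W/T/M along the target 5'->3') from an
# ordered pair list (ascending target, descending miRNA).
pairing_string_from_pairs <- function(pairs, window, mirna) {
  wb <- strsplit(window, "")[[1]]
  mb <- strsplit(mirna, "")[[1]]
  out <- character(0)
  for (k in seq_len(nrow(pairs))) {
    if (k > 1L) {
      gt <- pairs[k, 1] - pairs[k - 1L, 1] - 1L
      gm <- pairs[k - 1L, 2] - pairs[k, 2] - 1L
      out <- c(out, rep("T", gt), rep("M", gm))
    }
    a <- wb[pairs[k, 1]]; b <- mb[pairs[k, 2]]
    out <- c(out, if (is_wobble_pair(a, b)) "W" else "P")
  }
  paste(out, collapse = "")
}

make_site <- function(res, window, mirna_name, mirna_seq, variant_id,
                      allele, method) {
  pairs <- res$pairs
  data.frame(variant_id = variant_id, allele = allele,
             mirna_name = mirna_name,
             target_start = pairs[1, 1],
             target_end = pairs[nrow(pairs), 1],
             mirna_start = pairs[nrow(pairs), 2],
             mirna_end = pairs[1, 2],
             window_start = NA_integer_,
             pairing = pairing_string_from_pairs(pairs, window, mirna_seq),
             energy = res$energy,
             seed_class = NA_character_,
             method = method,
             stringsAsFactors = FALSE)
}

#' Minimum-free-energy hybrid between a target window and a miRNA
#'
#' Dynamic-programming search over co-linear (non-crossing) antiparallel
#' hybrids under the nearest-neighbor model: stacking over adjacent pair
#' steps, affine interior-loop and bulge penalties (each side of a loop
#' bounded by `model$max_internal_unpaired`), plus a duplex-initiation
#' penalty. Only energetically favorable interactions are reported: if the
#' optimum is >= 0 kcal/mol the result is `NULL`. With `require_seed` the
#' optimum is constrained to contain an uninterrupted helix of >= 6 pairs
#' within miRNA positions 1-8 (the energetically favorable seed
#' interaction).
#'
#' @param window Target window sequence (RNA).
#' @param mirna miRNA sequence (RNA, 5'->3') or one-row [mirna_library()].
#' @param model An [energy_model()].
#' @param require_seed Constrain the hybrid to contain a seed helix.
#' @param variant_id,allele Labels stored on the returned site.
#' @return One-row interaction-site data frame (`method = "energy_scan"`),
#'   or `NULL` if no favorable hybrid exists.
#' @export
duplex_mfe <- function(window, mirna, model = energy_model(),
                       require_seed = TRUE,
                       variant_id = NA_character_, allele = NA_character_) {
  if (is.data.frame(mirna)) {
    mirna_name <- mirna$name[1]
    mirna <- mirna$sequence[1]
  } else {
    mirna_name <- NA_character_
  }
  if (nchar(window) < 6L) return(NULL)
  res <- cpp_duplex_mfe(window, mirna, unclass(model), require_seed)
  if (!isTRUE(res$found) || res$energy >= 0) return(NULL)
  make_site(res, window, mirna_name, mirna, variant_id, allele,
            "energy_scan")
}

#' Re-score a seed-scan hit as an explicit hybrid
#'
#' Builds the hybrid whose seed helix is exactly the matched run reported by
#' [find_seed_matches()] (the full run, not the capped interval), extends
#' the remaining miRNA 3' portion optimally onto the target to the left of
#' the helix, and scores the assembled structure under the energy model.
#' No energy filtering happens here; unfavorable sites are retained and
#' discarded downstream by [filter_sites()].
#'
#' @param match One row of a [find_seed_matches()] result.
#' @param window Target window the match was found in.
#' @param mirna miRNA sequence or one-row [mirna_library()].
#' @param model An [energy_model()].
#' @param variant_id,allele Labels stored on the returned site.
#' @return One-row interaction-site data frame (`method = "seed_scan"`).
#' @export
rescore_seed_hit <- function(match, window, mirna, model = energy_model(),
                             variant_id = NA_character_,
                             allele = NA_character_) {
  if (is.data.frame(mirna)) {
    mirna_name <- mirna$name[1]
    mirna <- mirna$sequence[1]
  } else {
    mirna_name <- if (!is.null(match$mirna_name)) match$mirna_name[1]
                  else NA_character_
  }
  full <- match$full_len[1]
  th_end <- match$target_end[1]
  th_start <- th_end - full + 1L
  mh_start <- match$mirna_start[1]
  mh_end <- mh_start + full - 1L
  res <- cpp_rescore_helix(window, mirna, unclass(energy_model_check(model)),
                           th_start, th_end, mh_start, mh_end)
  make_site(res, window, mirna_name, mirna, variant_id, allele, "seed_scan")
}

energy_model_check <- function(model) {
  if (!inherits(model, "energy_model")) stop("not an energy_model")
  model
}
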