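# Allele windows: the 50-nt reference and alternate target subsequences
# around each variant. Short windows in the variant vicinity are used instead
# of the whole UTR so that distal self-structure cannot shadow binding sites.

#' Apply a variant to a UTR sequence
#'
#' @param utr A [utr_sequence()].
#' @param variant One-row variant data frame (columns `position`, `ref`,
#'   `alt`) as produced by [read_variants()].
#' @return Full edited sequence (character scalar); its length differs from
#'   the UTR by `nchar(alt) - nchar(ref)`.
#' @export
apply_variant <- function(utr, variant) {
  pos <- variant$position
  ref <- variant$ref
  paste0(substr(utr$sequence, 1L, pos - 1L),
         variant$alt,
         substr(utr$sequence, pos + nchar(ref), nchar(utr$sequence)))
}

#' Extract the reference/alternate window pair around a variant
#'
#' The reference window covers positions
#' `[position - window_len/2, position + window_len/2 - 1]` of the UTR,
#' intersected with `[1, length]`; the alternate window is re-extracted with
#' the same arithmetic from the edited sequence, so indel windows return to
#' nominal length instead of inheriting the length change (keeping the
#' search space per allele comparable).
#'
#' @param utr A [utr_sequence()].
#' @param variant One-row variant data frame.
#' @param window_len Nominal window length (nucleotides, even, >= 20).
#' @param mirnas Optional [mirna_library()]; if given, a warning is raised
#'   when the window is shorter than the longest miRNA (some sites become
#'   undetectable).
#' @return A list of class `allele_window_pair`: `variant_id`, `ref_window`,
#'   `alt_window`, `ref_start` (UTR offset of `ref_window`), `alt_start`,
#'   `ref_anchor`/`alt_anchor` (offset of the variant within each window),
#'   `window_len`.
#' @export
extract_window_pair <- function(utr, variant, window_len = 50L,
                                mirnas = NULL) {
  stopifnot(window_len >= 20L, window_len %% 2L == 0L)
  if (!is.null(mirnas) && window_len < max(nchar(mirnas$sequence)))
    warning("window_len ", window_len, " is shorter than the longest miRNA; ",
            "some sites cannot be detected")
  half <- window_len %/% 2L
  pos <- variant$position

  ref_seq <- utr$sequence
  ref_start <- max(1L, pos - half)
  ref_end <- min(nchar(ref_seq), pos + half - 1L)
  ref_window <- substr(ref_seq, ref_start, ref_end)

  alt_seq <- apply_variant(utr, variant)
  alt_start <- max(1L, pos - half)
  alt_end <- min(nchar(alt_seq), pos + half - 1L)
  alt_window <- substr(alt_seq, alt_start, alt_end)

  structure(list(variant_id = variant$variant_id,
                 ref_window = ref_window,
                 alt_window = alt_window,
                 ref_start = ref_start,
                 alt_start = alt_start,
                 ref_anchor = pos - ref_start + 1L,
                 alt_anchor = pos - alt_start + 1L,
                 window_len = as.integer(window_len)),
            class = "allele_window_pair")
}
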