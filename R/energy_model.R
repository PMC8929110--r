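#' Nearest-neighbor RNA-RNA hybridization energy model (37 degrees C)
#'
#' Returns the embedded "reduced nearest-neighbor model v1" used to score
#' intermolecular RNA duplexes. Helix stability is the sum of stacking free
#' energies over consecutive base-pair steps (Turner 2004 values for the six
#' pair types AU, UA, CG, GC, GU, UG), plus a duplex initiation penalty and
#' affine penalties for interior loops and bulges separating helices.
#' Intramolecular structure and target-site accessibility are outside the
#' model: only the hybrid itself is scored.
#'
#' @details
#' Stack energies are indexed as `stack[p1, p2]` where `p1` is the 5' pair of
#' the step written target-base first (e.g. `"CG"` = target C paired to miRNA
#' G) and `p2` is the 3' pair written miRNA-base first, following the usual
#' nearest-neighbor motif convention `5'-XW-3' / 3'-YZ-5'`. All Watson-Crick
#' steps are stabilizing; the two G-U-on-G-U steps are mildly destabilizing,
#' as in the source table.
#'
#' Loop terms are an affine reduction of the tabulated loop costs: a bulge of
#' b unpaired nucleotides on one side costs `bulge_open + b * bulge_extend`,
#' an interior loop with u unpaired nucleotides in total over both sides
#' costs `loop_open + u * loop_extend`. No stacking term is applied across a
#' loop or bulge. Dangling ends and terminal mismatches are not scored.
#'
#' @param max_internal_unpaired Maximum unpaired stretch allowed per side of
#'   a single interior loop or bulge (nucleotides).
#' @return An object of class `energy_model`: a list with elements `stack`
#'   (6x6 numeric matrix, kcal/mol), `init_penalty`, `loop_open`,
#'   `loop_extend_per_nt`, `bulge_open`, `bulge_extend_per_nt`,
#'   `max_internal_unpaired`, `model_version` and `temperature_c`.
#' @examples
#' m <- energy_model()
#' m$stack["GC", "GC"]  # 5'-GC-3'/3'-CG-5', the strongest stack
#' @export
energy_model <- function(max_internal_unpaired = 15L) {
  stopifnot(is.numeric(max_internal_unpaired), max_internal_unpaired >= 0)
  pairs <- c("CG", "GC", "GU", "UG", "AU", "UA")
  stack <- matrix(c(
    # CG     GC     GU     UG     AU     UA
    -2.40, -3.30, -2.10, -1.40, -2.10, -2.10,  # CG
    -3.30, -3.40, -2.50, -1.50, -2.20, -2.40,  # GC
    -2.10, -2.50,  1.30, -0.50, -1.40, -1.30,  # GU
    -1.40, -1.50, -0.50,  0.30, -0.60, -1.00,  # UG
    -2.10, -2.20, -1.40, -0.60, -1.10, -0.90,  # AU
    -2.10, -2.40, -1.30, -1.00, -0.90, -1.30   # UA
  ), nrow = 6L, byrow = TRUE, dimnames = list(pairs, pairs))
  structure(list(
    stack = stack,
    init_penalty = 4.09,
    loop_open = 1.3,
    loop_extend_per_nt = 0.35,
    bulge_open = 3.2,
    bulge_extend_per_nt = 0.35,
    max_internal_unpaired = as.integer(max_internal_unpaired),
    model_version = "reduced-nn-v1",
    temperature_c = 37
  ), class = "energy_model")
}

# Pair type of (a, b) in the order used by the stack matrix, or NA if (a, b)
# is not one of the six allowed pair types.
pair_type <- function(a, b) {
  key <- paste0(a, b)
  ifelse(key %in% c("CG", "GC", "GU", "UG", "AU", "UA"), key, NA_character_)
}

#' Test whether two RNA bases can pair
#'
#' Watson-Crick pairs (A:U, C:G) always pair; the G:U wobble pairs only when
#' `allow_wobble` is `TRUE`.
#'
#' @param a,b Single RNA bases in `{A, C, G, U}` (vectorized).
#' @param allow_wobble Permit the G-U wobble pair.
#' @return Logical vector.
#' @examples
#' rna_pairs("G", "C")               # TRUE
#' rna_pairs("G", "U")               # TRUE (wobble)
#' rna_pairs("G", "U", FALSE)        # FALSE
#' @export
rna_pairs <- function(a, b, allow_wobble = TRUE) {
  key <- paste0(a, b)
  wc <- key %in% c("AU", "UA", "CG", "GC")
  if (allow_wobble) wc | key %in% c("GU", "UG") else wc
}

is_wobble_pair <- function(a, b) paste0(a, b) %in% c("GU", "UG")

#' Score a hybrid structure under the energy model
#'
#' Recomputes the free energy of an interaction site from its pairing string
#' and the two sequences: duplex initiation plus stacking over adjacent pair
#' steps plus affine loop/bulge penalties for unpaired stretches between
#' helices. This is the single source of truth for structure energies; the
#' dynamic-programming search must agree with it on every emitted site.
#'
#' @param pairing Pairing string over codes `P` (Watson-Crick pair), `W`
#'   (G-U wobble pair), `T` (unpaired target nucleotide), `M` (unpaired miRNA
#'   nucleotide), read along the target 5'->3'. The miRNA is consumed 3'->5'
#'   (antiparallel). First and last characters must be pairs.
#' @param target Target (window) sequence, RNA alphabet.
#' @param mirna miRNA sequence, RNA alphabet, 5'->3'.
#' @param target_start,mirna_start,mirna_end 1-based closed coordinates of
#'   the interaction interval on each molecule; the first pairing column
#'   pairs `target_start` with `mirna_end`.
#' @param model An [energy_model()].
#' @return Energy in kcal/mol; `Inf` if the structure contains no pairs.
#' @examples
#' # a contiguous helix: target GGGGG vs miRNA CCCCC
#' score_structure("PPPPP", "GGGGG", "CCCCC", 1, 1, 5)
#' @export
score_structure <- function(pairing, target, mirna, target_start,
                            mirna_start, mirna_end, model = energy_model()) {
  cols <- strsplit(pairing, "")[[1]]
  if (length(cols) == 0L) return(Inf)
  if (!all(cols %in% c("P", "W", "T", "M")))
    stop("malformed pairing string: unknown code in ", pairing)
  if (cols[1] %in% c("T", "M") || cols[length(cols)] %in% c("T", "M"))
    stop("malformed pairing string: must begin and end with a pair")
  tb <- strsplit(target, "")[[1]]
  mb <- strsplit(mirna, "")[[1]]

  ti <- target_start          # next target base to consume
  mi <- mirna_end             # next miRNA base to consume (walking 3'->5')
  energy <- model$init_penalty
  prev_pair <- NULL           # c(target base, mirna base) of last pair
  gap_t <- 0L; gap_m <- 0L    # unpaired run since last pair

  for (code in cols) {
    if (code == "T") { ti <- ti + 1L; gap_t <- gap_t + 1L; next }
    if (code == "M") { mi <- mi - 1L; gap_m <- gap_m + 1L; next }
    if (ti > length(tb) || mi < 1L)
      stop("malformed pairing string: runs off a sequence end")
    a <- tb[ti]; b <- mb[mi]
    ok <- rna_pairs(a, b, allow_wobble = TRUE)
    if (!ok) stop("malformed structure: ", a, ":", b, " cannot pair")
    if (code == "P" && is_wobble_pair(a, b))
      stop("malformed structure: ", a, ":", b, " is a wobble, coded P")
    if (code == "W" && !is_wobble_pair(a, b))
      stop("malformed structure: ", a, ":", b, " is not a wobble, coded W")
    if (!is.null(prev_pair)) {
      if (gap_t == 0L && gap_m == 0L) {
        energy <- energy +
          model$stack[pair_type(prev_pair[1], prev_pair[2]),
                      pair_type(b, a)]
      } else if (gap_t == 0L || gap_m == 0L) {
        b_len <- gap_t + gap_m
        energy <- energy + model$bulge_open + b_len * model$bulge_extend_per_nt
      } else {
        u <- gap_t + gap_m
        energy <- energy + model$loop_open + u * model$loop_extend_per_nt
      }
    }
    prev_pair <- c(a, b)
    gap_t <- 0L; gap_m <- 0L
    ti <- ti + 1L; mi <- mi - 1L
  }
  if (ti - 1L > length(tb) || mi + 1L < mirna_start - 1L)
    stop("malformed pairing string: interval mismatch")
  if (mi + 1L != mirna_start)
    stop("pairing string does not span [mirna_start, mirna_end]")
  energy
}
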