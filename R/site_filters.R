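# Site validation: seed-pattern taxonomy (canonical 6/7/8-mer, centered,
# 3'-compensatory), hybridization-energy cutoff and tissue-specific miRNA
# whitelist filtering.

#' Site filter configuration
#'
#' @param energy_cutoff Hybridization-energy cutoff in kcal/mol (must be
#'   negative). Sites with energy above (weaker than) the cutoff are
#'   discarded; a site exactly at the cutoff is retained.
#' @param whitelist Character vector of mature miRNA names expressed in the
#'   tissue of interest; matching is exact after whitespace trimming.
#' @param allowed_classes Seed classes that pass the pattern gate.
#' @param wobble_in_canonical Whether G-U wobbles count as pairs inside a
#'   canonical seed run (they always count as the single permitted defect of
#'   a compensatory site).
#' @param centered_min_pairs,centered_start_range Operational constants for
#'   the centered-site pattern: minimum contiguous pairs and the allowed
#'   miRNA start positions of the run.
#' @param compensatory_min_3p_pairs Minimum contiguous pairs within miRNA
#'   positions 13-17 required to compensate a single seed defect.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(energy_cutoff = -8.5,
                          whitelist = character(),
                          allowed_classes = c("canonical_6", "canonical_7",
                                              "canonical_8", "centered",
                                              "compensatory"),
                          wobble_in_canonical = TRUE,
                          centered_min_pairs = 11L,
                          centered_start_range = c(3L, 6L),
                          compensatory_min_3p_pairs = 4L) {
  if (!is.numeric(energy_cutoff) || energy_cutoff >= 0)
    stop("energy_cutoff must be negative (kcal/mol)")
  structure(list(energy_cutoff = energy_cutoff,
                 whitelist = whitelist,
                 allowed_classes = allowed_classes,
                 wobble_in_canonical = isTRUE(wobble_in_canonical),
                 centered_min_pairs = as.integer(centered_min_pairs),
                 centered_start_range = as.integer(centered_start_range),
                 compensatory_min_3p_pairs =
                   as.integer(compensatory_min_3p_pairs)),
            class = "filter_config")
}

# Decode a pairing string into helices over miRNA coordinates. Returns a
# list with `status` (named character vector P/W per paired miRNA position)
# and `helices` (data frame m_lo, m_hi, pure_wc of maximal uninterrupted
# runs, i.e. consecutive pair columns with no intervening loop).
decode_pairing <- function(pairing, mirna_end) {
  cols <- strsplit(pairing, "")[[1]]
  mi <- mirna_end
  status <- character(0)
  helices <- list()
  run <- NULL  # c(m_hi, m_lo) of the open helix, plus wobble flag
  close_run <- function(run, helices) {
    if (!is.null(run))
      helices[[length(helices) + 1L]] <-
        data.frame(m_lo = run$m_lo, m_hi = run$m_hi, has_wobble = run$wob)
    helices
  }
  for (code in cols) {
    if (code == "T") { helices <- close_run(run, helices); run <- NULL; next }
    if (code == "M") {
      helices <- close_run(run, helices); run <- NULL
      mi <- mi - 1L; next
    }
    status[as.character(mi)] <- code
    if (is.null(run)) run <- list(m_hi = mi, m_lo = mi, wob = code == "W")
    else { run$m_lo <- mi; run$wob <- run$wob || code == "W" }
    mi <- mi - 1L
  }
  helices <- close_run(run, helices)
  list(status = status,
       helices = if (length(helices)) do.call(rbind, helices)
                 else data.frame(m_lo = integer(), m_hi = integer(),
                                 has_wobble = logical()))
}

#' Classify an interaction site into the seed-pattern taxonomy
#'
#' Assigns exactly one class by first match in priority order
#' `canonical_8 > canonical_7 > canonical_6 > centered > compensatory >
#' none`:
#' \itemize{
#'   \item `canonical_k`: an uninterrupted paired run covering at least k
#'     miRNA positions within 1-8 (wobbles count as pairs when
#'     `cfg$wobble_in_canonical`).
#'   \item `centered`: an uninterrupted run of at least
#'     `cfg$centered_min_pairs` pairs whose miRNA interval starts at
#'     position 3-6.
#'   \item `compensatory`: seed region (miRNA 2-8) paired except exactly
#'     one wobble or mismatch, compensated by at least
#'     `cfg$compensatory_min_3p_pairs` contiguous pairs within miRNA
#'     positions 13-17.
#' }
#'
#' @param site One-row interaction-site data frame (needs `pairing` and
#'   `mirna_end`).
#' @param cfg A [filter_config()].
#' @return Character scalar: the seed class.
#' @export
classify_site <- function(site, cfg = filter_config()) {
  dec <- decode_pairing(site$pairing[1], site$mirna_end[1])
  hel <- dec$helices
  if (nrow(hel) == 0L) return("none")

  # split runs at wobbles if canonical pattern demands pure Watson-Crick
  hel_canon <- hel
  if (!cfg$wobble_in_canonical) {
    status <- dec$status
    paired <- sort(as.integer(names(status)[status == "P"]))
    hel_canon <- positions_to_runs(paired)
    # wobble-split runs are still contiguous-in-structure only if the
    # original helix contained them; intersect with original helices
    hel_canon <- intersect_runs(hel_canon, hel)
  }
  seed_cover <- if (nrow(hel_canon))
    pmax(0L, pmin(hel_canon$m_hi, 8L) - pmax(hel_canon$m_lo, 1L) + 1L)
  else integer(0)
  for (k in c(8L, 7L, 6L))
    if (any(seed_cover >= k)) return(paste0("canonical_", k))

  len <- hel$m_hi - hel$m_lo + 1L
  if (any(len >= cfg$centered_min_pairs &
          hel$m_lo >= cfg$centered_start_range[1] &
          hel$m_lo <= cfg$centered_start_range[2]))
    return("centered")

  status <- dec$status
  seed_pos <- as.character(2:8)
  st <- status[seed_pos]
  defects <- sum(is.na(st) | st == "W")
  cover_3p <- pmax(0L, pmin(hel$m_hi, 17L) - pmax(hel$m_lo, 13L) + 1L)
  if (defects == 1L && any(cover_3p >= cfg$compensatory_min_3p_pairs))
    return("compensatory")
  "none"
}

positions_to_runs <- function(pos) {
  if (length(pos) == 0L)
    return(data.frame(m_lo = integer(), m_hi = integer(),
                      has_wobble = logical()))
  breaks <- c(0L, which(diff(pos) != 1L), length(pos))
  do.call(rbind, lapply(seq_len(length(breaks) - 1L), function(i) {
    seg <- pos[(breaks[i] + 1L):breaks[i + 1L]]
    data.frame(m_lo = min(seg), m_hi = max(seg), has_wobble = FALSE)
  }))
}

intersect_runs <- function(runs, helices) {
  if (nrow(runs) == 0L || nrow(helices) == 0L) return(runs[0, , drop = FALSE])
  out <- list()
  for (i in seq_len(nrow(runs)))
    for (j in seq_len(nrow(helices))) {
      lo <- max(runs$m_lo[i], helices$m_lo[j])
      hi <- min(runs$m_hi[i], helices$m_hi[j])
      if (lo <= hi)
        out[[length(out) + 1L]] <-
          data.frame(m_lo = lo, m_hi = hi, has_wobble = FALSE)
    }
  if (length(out)) do.call(rbind, out)
  else runs[0, , drop = FALSE]
}

#' Classify every site in a site table
#'
#' @param sites Interaction-site data frame.
#' @param cfg A [filter_config()].
#' @return The same data frame with `seed_class` filled in.
#' @export
classify_sites <- function(sites, cfg = filter_config()) {
  if (nrow(sites) == 0L) return(sites)
  sites$seed_class <- vapply(seq_len(nrow(sites)), function(i)
    classify_site(sites[i, , drop = FALSE], cfg), character(1))
  sites
}

#' Filter classified sites by energy, whitelist and seed class
#'
#' Retains sites with `energy <= energy_cutoff` (boundary inclusive: a site
#' exactly at the cutoff has sufficient energy), `mirna_name` in the
#' whitelist, and `seed_class` in the allowed classes. Order is preserved;
#' filtering is idempotent.
#'
#' @param sites Classified interaction-site data frame.
#' @param cfg A [filter_config()].
#' @return The retained subset, in the original order.
#' @export
filter_sites <- function(sites, cfg = filter_config()) {
  if (nrow(sites) == 0L) return(sites)
  keep <- sites$energy <= cfg$energy_cutoff &
    sites$mirna_name %in% cfg$whitelist &
    sites$seed_class %in% cfg$allowed_classes
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
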