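# Seed-anchored complementarity scan ("canonical" route): find maximal
# uninterrupted antiparallel complementary runs that begin at the miRNA
# 5'-end (position 1 or 2) and pair a stretch of the target window, with
# G-U wobbles optionally counting as matches.

#' Find seed matches of a miRNA in a target window
#'
#' For every target offset and every miRNA anchor position (1 or 2), the
#' maximal uninterrupted antiparallel complementary run beginning at that
#' miRNA position is reported if it is at least `min_len` long. The miRNA
#' anchor pairs the rightmost target base of the match; the run extends
#' leftward on the target and 3'-ward on the miRNA. Runs longer than
#' `max_len` keep their full length in `full_len` but are reported (and
#' later classified) by their first `max_len` pairs. A match whose target
#' interval is strictly contained in another match with the same anchor is
#' dropped.
#'
#' @param window Target window sequence (RNA).
#' @param mirna miRNA sequence (RNA, 5'->3') or a one-row [mirna_library()].
#' @param min_len Minimum run length (>= 6, the canonical-seed minimum).
#' @param max_len Cap used for the reported interval and classification.
#' @param allow_wobble Count G-U wobbles as matches.
#' @return Data frame with columns `mirna_name`, `target_start`,
#'   `target_end` (1-based closed, within the window), `mirna_start` (1 or
#'   2), `match_len` (capped, in [min_len, max_len]), `full_len`,
#'   `wobble_count` (wobbles within the reported interval), ordered by
#'   (`target_start`, `mirna_start`).
#' @export
find_seed_matches <- function(window, mirna, min_len = 6L, max_len = 8L,
                              allow_wobble = TRUE) {
  if (min_len < 6L) stop("min_len must be >= 6")
  if (is.data.frame(mirna)) {
    mirna_name <- mirna$name[1]
    mirna <- mirna$sequence[1]
  } else {
    mirna_name <- NA_character_
  }
  wb <- strsplit(window, "")[[1]]
  mb <- strsplit(mirna, "")[[1]]
  n <- length(wb); m <- length(mb)
  out <- list()
  if (n >= min_len) {
    # pairable[t, k] for target base t against miRNA base k
    pairable <- outer(wb, mb, rna_pairs, allow_wobble = allow_wobble)
    wobble <- outer(wb, mb, is_wobble_pair)
    for (anchor in 1:2) {
      for (p in seq_len(n)) {
        # run along the diagonal: miRNA anchor+k pairs target p-k
        k <- 0L
        while (p - k >= 1L && anchor + k <= m && pairable[p - k, anchor + k])
          k <- k + 1L
        if (k >= min_len) {
          len <- min(k, max_len)
          ts <- p - len + 1L
          wob <- sum(vapply(0:(len - 1L), function(j)
            wobble[p - j, anchor + j], logical(1)))
          out[[length(out) + 1L]] <- data.frame(
            mirna_name = mirna_name, target_start = ts, target_end = p,
            mirna_start = anchor, match_len = len, full_len = k,
            wobble_count = wob, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(mirna_name = character(), target_start = integer(),
                      target_end = integer(), mirna_start = integer(),
                      match_len = integer(), full_len = integer(),
                      wobble_count = integer(), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df <- drop_contained_matches(df)
  df <- df[order(df$target_start, df$mirna_start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Drop matches whose target interval is strictly contained in another match
# with the same miRNA anchor.
drop_contained_matches <- function(df) {
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    contained <- df$mirna_start == df$mirna_start[i] &
      df$target_start <= df$target_start[i] &
      df$target_end >= df$target_end[i] &
      (df$target_start < df$target_start[i] |
         df$target_end > df$target_end[i])
    if (any(contained)) keep[i] <- FALSE
  }
  df[keep, , drop = FALSE]
}
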