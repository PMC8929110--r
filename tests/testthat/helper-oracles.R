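# Independent brute-force oracles used to validate the scanning and
# energy-minimization code, plus small fixture builders. The oracles follow
# the definitions directly (position-by-position extension; exhaustive
# enumeration of co-linear pairings) and share no code with the package
# implementation.

BASES <- c("A", "C", "G", "U")

rand_rna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(BASES, n, replace = TRUE, prob = prob), collapse = "")
}

base_pairs_ok <- function(a, b, allow_wobble) {
  (a == "A" && b == "U") || (a == "U" && b == "A") ||
    (a == "C" && b == "G") || (a == "G" && b == "C") ||
    (allow_wobble && ((a == "G" && b == "U") || (a == "U" && b == "G")))
}

# Enumerate every (target offset, miRNA anchor) pair and extend pairing base
# by base; report maximal runs >= min_len, capped at max_len, dropping
# matches strictly contained in another match with the same anchor.
oracle_seed_matches <- function(window, mirna, min_len = 6L, max_len = 8L,
                                allow_wobble = TRUE) {
  wb <- strsplit(window, "")[[1]]
  mb <- strsplit(mirna, "")[[1]]
  rows <- list()
  for (anchor in 1:2) {
    for (p in seq_along(wb)) {
      k <- 0L
      repeat {
        t <- p - k
        mi <- anchor + k
        if (t < 1L || mi > length(mb)) break
        if (!base_pairs_ok(wb[t], mb[mi], allow_wobble)) break
        k <- k + 1L
      }
      if (k >= min_len) {
        len <- min(k, max_len)
        wob <- 0L
        for (j in 0:(len - 1L)) {
          a <- wb[p - j]; b <- mb[anchor + j]
          if ((a == "G" && b == "U") || (a == "U" && b == "G"))
            wob <- wob + 1L
        }
        rows[[length(rows) + 1L]] <- data.frame(
          target_start = p - len + 1L, target_end = p,
          mirna_start = anchor, match_len = len, full_len = k,
          wobble_count = wob)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(target_start = integer(), target_end = integer(),
                      mirna_start = integer(), match_len = integer(),
                      full_len = integer(), wobble_count = integer()))
  df <- do.call(rbind, rows)
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    for (j in seq_len(nrow(df))) {
      if (i == j) next
      if (df$mirna_start[j] == df$mirna_start[i] &&
          df$target_start[j] <= df$target_start[i] &&
          df$target_end[j] >= df$target_end[i] &&
          (df$target_start[j] < df$target_start[i] ||
           df$target_end[j] > df$target_end[i])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$target_start, df$mirna_start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Exhaustive enumeration of all co-linear antiparallel pairings (wobble
# allowed), scored directly from the model terms: the minimum energy over
# every non-empty chain, or Inf when no pair is possible.
oracle_duplex_energy <- function(target, mirna, model) {
  tb <- strsplit(target, "")[[1]]
  mb <- strsplit(mirna, "")[[1]]
  n <- length(tb); m <- length(mb)
  maxu <- model$max_internal_unpaired
  best <- Inf
  extend <- function(i, j, e) {
    best <<- min(best, e)
    if (i < n) {
      for (p in (i + 1L):n) {
        for (q in seq_len(j - 1L)) {
          gt <- p - i - 1L; gm <- j - q - 1L
          if (gt > maxu || gm > maxu) next
          if (!base_pairs_ok(tb[p], mb[q], TRUE)) next
          cost <- if (gt == 0L && gm == 0L)
            model$stack[paste0(tb[i], mb[j]), paste0(mb[q], tb[p])]
          else if (gt == 0L || gm == 0L)
            model$bulge_open + (gt + gm) * model$bulge_extend_per_nt
          else
            model$loop_open + (gt + gm) * model$loop_extend_per_nt
          extend(p, q, e + cost)
        }
      }
    }
  }
  for (i in seq_len(n))
    for (j in seq_len(m))
      if (base_pairs_ok(tb[i], mb[j], TRUE))
        extend(i, j, model$init_penalty)
  best
}

# A strong synthetic miRNA/site pair used across tests: GC-rich seed so the
# planted helix comfortably clears the default energy cutoff.
fixture_mirna <- function() "UGAGGCAGCAGGUUGUAUAGUU"

# Window with a perfect complement of the miRNA's first `k` positions
# embedded at a known offset, padded with non-pairing A's on the left and a
# fixed flank on the right.
fixture_window <- function(mirna = fixture_mirna(), k = 12L,
                           left = "AAAAAA", right = "AAAAAA") {
  paste0(left, rna_revcomp(substr(mirna, 1L, k)), right)
}

tsv_write <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
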