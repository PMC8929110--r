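# End-to-end pipeline: scan variant windows with both prediction routes,
# filter the sites, compute per-variant impacts, flag outliers and select
# candidate downregulating variants.

#' Pipeline run configuration
#'
#' Defaults reproduce the study settings: 50-nt allele windows, seed runs of
#' at least 6 nt with G-U wobbles allowed, a -8.5 kcal/mol hybridization
#' energy cutoff, a seed-constrained energy route, and Tukey fences with
#' k = 1.5 over per-method delta-N / delta-W distributions.
#'
#' @param window_len Nominal allele-window length (nt, even).
#' @param min_seed Minimum seed-run length for the seed-scan route.
#' @param allow_wobble Count G-U wobbles as seed matches.
#' @param energy_cutoff Hybridization-energy cutoff (kcal/mol, negative).
#' @param fence_k Tukey fence multiplier for outlier flagging.
#' @param sum_mode `"best"` or `"all"`; see [summarize_allele()].
#' @param methods Prediction routes to run.
#' @param require_seed Constrain the energy route to seed-containing
#'   hybrids.
#' @param max_internal_unpaired Loop-size bound per side for the energy
#'   model.
#' @param wobble_in_canonical Whether wobbles count inside canonical seed
#'   runs during classification.
#' @return A list of class `run_config`.
#' @export
run_config <- function(window_len = 50L, min_seed = 6L, allow_wobble = TRUE,
                       energy_cutoff = -8.5, fence_k = 1.5,
                       sum_mode = c("best", "all"),
                       methods = c("seed_scan", "energy_scan"),
                       require_seed = TRUE, max_internal_unpaired = 15L,
                       wobble_in_canonical = TRUE) {
  sum_mode <- match.arg(sum_mode)
  methods <- match.arg(methods, c("seed_scan", "energy_scan"),
                       several.ok = TRUE)
  structure(list(window_len = as.integer(window_len),
                 min_seed = as.integer(min_seed),
                 allow_wobble = isTRUE(allow_wobble),
                 energy_cutoff = energy_cutoff,
                 fence_k = fence_k,
                 sum_mode = sum_mode,
                 methods = methods,
                 require_seed = isTRUE(require_seed),
                 max_internal_unpaired = as.integer(max_internal_unpaired),
                 wobble_in_canonical = isTRUE(wobble_in_canonical)),
            class = "run_config")
}

# All raw (unfiltered, unclassified) sites of one window/allele against a
# miRNA library, under the configured routes.
scan_window <- function(window, mirnas, cfg, model, variant_id, allele) {
  out <- list()
  for (i in seq_len(nrow(mirnas))) {
    name <- mirnas$name[i]
    seq <- mirnas$sequence[i]
    if ("seed_scan" %in% cfg$methods) {
      matches <- find_seed_matches(window, seq, min_len = cfg$min_seed,
                                   allow_wobble = cfg$allow_wobble)
      for (k in seq_len(nrow(matches))) {
        site <- rescore_seed_hit(matches[k, , drop = FALSE], window, seq,
                                 model, variant_id = variant_id,
                                 allele = allele)
        site$mirna_name <- name
        out[[length(out) + 1L]] <- site
      }
    }
    if ("energy_scan" %in% cfg$methods) {
      site <- duplex_mfe(window, seq, model,
                         require_seed = cfg$require_seed,
                         variant_id = variant_id, allele = allele)
      if (!is.null(site)) {
        site$mirna_name <- name
        out[[length(out) + 1L]] <- site
      }
    }
  }
  if (length(out) == 0L) empty_sites() else do.call(rbind, out)
}

#' Run the variant -> miRNA-site -> impact pipeline
#'
#' For each variant, extracts the reference/alternate window pair, scans
#' both windows with the configured routes (seed scan re-scored in its
#' exact hybrid configuration; seed-constrained MFE hybrid), classifies and
#' filters the sites (energy cutoff, whitelist, seed-pattern gate), and
#' summarizes each variant as delta-N / delta-W per method. Outliers are
#' flagged per method across all variants and candidate downregulating
#' variants selected.
#'
#' @param utr A [utr_sequence()].
#' @param variants Variant data frame from [read_variants()].
#' @param mirnas A [mirna_library()].
#' @param whitelist Character vector of tissue-expressed miRNA names.
#' @param cfg A [run_config()].
#' @param frequencies Optional frequency table from [read_frequencies()].
#' @param verbose Log stage counts with `message()`.
#' @return List with `sites` (retained interaction sites), `impacts`
#'   (per variant x method with outlier and candidate flags),
#'   `candidates` (sorted candidate subset) and `config`.
#' @export
run_scan <- function(utr, variants, mirnas, whitelist, cfg = run_config(),
                     frequencies = NULL, verbose = FALSE) {
  if (nrow(mirnas) == 0L) stop("empty miRNA library")
  model <- energy_model(cfg$max_internal_unpaired)
  fcfg <- filter_config(energy_cutoff = cfg$energy_cutoff,
                        whitelist = whitelist,
                        wobble_in_canonical = cfg$wobble_in_canonical)
  say <- function(...) if (verbose) message(...)
  say("loaded: ", nrow(variants), " variants, ", nrow(mirnas), " miRNAs, ",
      length(whitelist), " whitelisted")

  all_sites <- list()
  impacts <- list()
  n_raw <- 0L; n_classified <- 0L
  for (v in seq_len(nrow(variants))) {
    variant <- variants[v, , drop = FALSE]
    wp <- extract_window_pair(utr, variant, cfg$window_len)
    windows <- c(REF = wp$ref_window, ALT = wp$alt_window)
    retained <- list()
    for (allele in c("REF", "ALT")) {
      raw <- scan_window(windows[[allele]], mirnas, cfg, model,
                         variant$variant_id, allele)
      raw$window_start <- rep(if (allele == "REF") wp$ref_start
                              else wp$alt_start, nrow(raw))
      n_raw <- n_raw + nrow(raw)
      raw <- classify_sites(raw, fcfg)
      n_classified <- n_classified + sum(raw$seed_class != "none")
      retained[[allele]] <- filter_sites(raw, fcfg)
    }
    kept <- rbind(retained$REF, retained$ALT)
    if (nrow(kept) > 0L) all_sites[[length(all_sites) + 1L]] <- kept
    for (method in cfg$methods) {
      ref_sum <- summarize_allele(
        retained$REF[retained$REF$method == method, , drop = FALSE],
        cfg$sum_mode)
      alt_sum <- summarize_allele(
        retained$ALT[retained$ALT$method == method, , drop = FALSE],
        cfg$sum_mode)
      impacts[[length(impacts) + 1L]] <-
        variant_impact(ref_sum, alt_sum, variant$variant_id, method)
    }
  }
  sites <- if (length(all_sites)) do.call(rbind, all_sites) else empty_sites()
  rownames(sites) <- NULL
  impacts <- do.call(rbind, impacts)
  say("sites: ", n_raw, " raw, ", n_classified, " pattern-matched, ",
      nrow(sites), " retained after energy and whitelist filters")

  flagged <- list()
  for (method in cfg$methods) {
    sub <- impacts[impacts$method == method, , drop = FALSE]
    flagged[[method]] <- flag_outliers(sub, k = cfg$fence_k)
  }
  impacts <- do.call(rbind, flagged)
  rownames(impacts) <- NULL
  candidates <- select_candidates(impacts)
  key <- paste(impacts$variant_id, impacts$method)
  impacts$candidate <- key %in% paste(candidates$variant_id,
                                      candidates$method)
  if (!is.null(frequencies)) {
    idx <- match(impacts$variant_id, frequencies$variant_id)
    impacts$max_population_allele_frequency <-
      frequencies$max_population_allele_frequency[idx]
    idx <- match(candidates$variant_id, frequencies$variant_id)
    candidates$max_population_allele_frequency <-
      frequencies$max_population_allele_frequency[idx]
  }
  say("candidates: ", nrow(candidates))
  list(sites = sites, impacts = impacts, candidates = candidates,
       config = cfg)
}
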