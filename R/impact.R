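# Per-variant impact statistics: delta-N (change in the number of
# interacting miRNAs) and delta-W (change in the summed hybridization
# energies), Tukey-fence outlier flagging across variants, and candidate
# selection for predicted expression-downregulating variants.

#' Summarize the retained sites of one variant + allele + method
#'
#' @param sites Filtered interaction-site data frame for a single variant,
#'   allele and method (may be empty).
#' @param sum_mode `"best"` sums, over distinct miRNAs, the lowest-energy
#'   retained site per miRNA (so one miRNA with many overlapping sites
#'   cannot dominate the sum); `"all"` sums every retained site.
#' @return List with `n` (distinct interacting miRNAs), `w` (energy sum,
#'   kcal/mol; 0 when no sites) and `mirnas` (sorted character vector).
#' @export
summarize_allele <- function(sites, sum_mode = c("best", "all")) {
  sum_mode <- match.arg(sum_mode)
  if (is.null(sites) || nrow(sites) == 0L)
    return(list(n = 0L, w = 0, mirnas = character(0)))
  mirnas <- sort(unique(sites$mirna_name))
  w <- if (sum_mode == "best")
    sum(vapply(split(sites$energy, sites$mirna_name), min, numeric(1)))
  else sum(sites$energy)
  list(n = length(mirnas), w = w, mirnas = mirnas)
}

#' Per-variant impact of an allele change
#'
#' @param ref_summary,alt_summary [summarize_allele()] results for the
#'   reference and alternate allele (same method, same filter config).
#' @param variant_id,method Labels for the resulting row.
#' @return One-row data frame with `n_ref`, `n_alt`, `delta_n`
#'   (`n_alt - n_ref`), `w_ref`, `w_alt`, `delta_w` (`w_alt - w_ref`,
#'   kcal/mol; negative = stronger binding on ALT = predicted
#'   downregulation), `gained`/`lost` (comma-joined miRNA names), and unset
#'   `outlier_n`/`outlier_w`/`candidate` flags.
#' @export
variant_impact <- function(ref_summary, alt_summary,
                           variant_id = NA_character_,
                           method = NA_character_) {
  gained <- setdiff(alt_summary$mirnas, ref_summary$mirnas)
  lost <- setdiff(ref_summary$mirnas, alt_summary$mirnas)
  data.frame(variant_id = variant_id, method = method,
             n_ref = ref_summary$n, n_alt = alt_summary$n,
             delta_n = alt_summary$n - ref_summary$n,
             w_ref = ref_summary$w, w_alt = alt_summary$w,
             delta_w = alt_summary$w - ref_summary$w,
             gained = paste(gained, collapse = ","),
             lost = paste(lost, collapse = ","),
             outlier_n = FALSE, outlier_w = FALSE, candidate = FALSE,
             stringsAsFactors = FALSE)
}

#' Flag statistical outliers of the delta-N / delta-W distributions
#'
#' Tukey fences per method: a variant is a delta-W outlier when
#' `delta_w < Q1 - k * IQR` (unusually strong binding gain) and a delta-N
#' outlier when `delta_n > Q3 + k * IQR` (unusually many gained miRNAs).
#' Quartiles use the linear-interpolation convention (R `quantile`
#' type 7). With fewer than 8 variants in a method the fences are not
#' meaningful: flags are then set for any nonzero delta-N (positive) /
#' delta-W (negative) and a warning is raised.
#'
#' @param impacts Impact data frame for one method (rows from
#'   [variant_impact()]).
#' @param k Fence multiplier.
#' @return The same data frame with `outlier_n` and `outlier_w` set.
#' @export
flag_outliers <- function(impacts, k = 1.5) {
  if (nrow(impacts) == 0L) return(impacts)
  if (length(unique(impacts$method)) > 1L)
    stop("flag_outliers expects impacts from a single method")
  if (nrow(impacts) < 8L) {
    warning("fewer than 8 variants: outlier fences are not meaningful; ",
            "flagging nonzero impacts instead")
    impacts$outlier_n <- impacts$delta_n > 0L
    impacts$outlier_w <- impacts$delta_w < 0
    return(impacts)
  }
  qn <- stats::quantile(impacts$delta_n, c(0.25, 0.75), type = 7, names = FALSE)
  qw <- stats::quantile(impacts$delta_w, c(0.25, 0.75), type = 7, names = FALSE)
  iqr_n <- qn[2] - qn[1]
  iqr_w <- qw[2] - qw[1]
  impacts$outlier_n <- impacts$delta_n > qn[2] + k * iqr_n
  impacts$outlier_w <- impacts$delta_w < qw[1] - k * iqr_w
  impacts
}

#' Select candidate downregulating variants
#'
#' A variant is a candidate when it increases the target's affinity for the
#' miRNA pool: `delta_n >= 1`, `delta_w < 0`, and it is an outlier of at
#' least one of the two distributions. Candidates are sorted within method
#' by ascending delta-W (strongest predicted downregulation first).
#'
#' @param impacts Impact data frame with outlier flags set.
#' @return The candidate subset with `candidate = TRUE`, sorted.
#' @export
select_candidates <- function(impacts) {
  if (nrow(impacts) == 0L) return(impacts)
  cand <- impacts$delta_n >= 1L & impacts$delta_w < 0 &
    (impacts$outlier_n | impacts$outlier_w)
  out <- impacts[cand, , drop = FALSE]
  out$candidate <- rep(TRUE, nrow(out))
  out <- out[order(out$method, out$delta_w), , drop = FALSE]
  rownames(out) <- NULL
  out
}
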