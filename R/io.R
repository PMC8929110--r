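# Reading and writing the external files the pipeline touches. All sequences
# are normalized to the RNA alphabet {A,C,G,U} internally (T -> U, upper
# case); coordinates are 1-based, fully closed, local to the UTR record.

normalize_rna <- function(seq, record_id = "<sequence>") {
  s <- toupper(seq)
  alphabet <- if (grepl("T", s, fixed = TRUE)) "DNA" else "RNA"
  s <- gsub("T", "U", s, fixed = TRUE)
  bad <- regexpr("[^ACGU]", s)
  if (bad > 0L)
    stop("invalid character '", substr(s, bad, bad), "' in record '",
         record_id, "' at offset ", bad)
  list(sequence = s, source_alphabet = alphabet)
}

#' Construct a 3'-UTR sequence record
#'
#' @param record_id Record identifier (FASTA header up to first whitespace).
#' @param sequence Nucleotide sequence, DNA or RNA alphabet; stored as RNA.
#' @return An object of class `utr_sequence` with fields `record_id`,
#'   `sequence` (RNA, 5'->3') and `source_alphabet` (`"DNA"` or `"RNA"`).
#' @export
utr_sequence <- function(record_id, sequence) {
  if (!nzchar(sequence)) stop("empty sequence for record '", record_id, "'")
  norm <- normalize_rna(sequence, record_id)
  structure(list(record_id = record_id,
                 sequence = norm$sequence,
                 source_alphabet = norm$source_alphabet),
            class = "utr_sequence")
}

#' @export
print.utr_sequence <- function(x, ...) {
  cat("3'-UTR record", x$record_id, "(", nchar(x$sequence), "nt,",
      x$source_alphabet, "input )\n")
  invisible(x)
}

#' Construct a mature miRNA library
#'
#' Validates lengths and names and deduplicates identical records. Mature
#' miRNAs are 17-22 nt; lengths outside a widened [16, 28] band are rejected
#' as malformed.
#'
#' @param name,sequence Character vectors of equal length.
#' @return A data frame of class `mirna_library` with columns `name`,
#'   `sequence` (RNA, 5'->3').
#' @export
mirna_library <- function(name, sequence) {
  stopifnot(length(name) == length(sequence))
  if (length(name) == 0L) stop("empty miRNA library")
  seqs <- character(length(sequence))
  for (i in seq_along(sequence))
    seqs[i] <- normalize_rna(sequence[i], name[i])$sequence
  len <- nchar(seqs)
  if (any(len < 16L | len > 28L))
    stop("miRNA length outside [16, 28] nt for: ",
         paste(name[len < 16L | len > 28L], collapse = ", "))
  df <- data.frame(name = name, sequence = seqs, stringsAsFactors = FALSE)
  dup <- duplicated(df)               # same name AND same sequence: collapse
  df <- df[!dup, , drop = FALSE]
  if (anyDuplicated(df$name))
    stop("duplicate miRNA name with conflicting sequence: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  rownames(df) <- NULL
  class(df) <- c("mirna_library", "data.frame")
  df
}

#' Read a FASTA file of UTR sequences or mature miRNAs
#'
#' DNA and RNA alphabets are both accepted; sequences are stored as RNA
#' (T -> U, upper case). Record ids are the FASTA header up to the first
#' whitespace, preserved verbatim.
#'
#' @param path FASTA file.
#' @param kind `"utr"` or `"mirna"`.
#' @return For `kind = "utr"`, a list of [utr_sequence()] records in file
#'   order; for `kind = "mirna"`, a [mirna_library()].
#' @export
read_fasta <- function(path, kind = c("utr", "mirna")) {
  kind <- match.arg(kind)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- unname(as.character(set))
  if (kind == "utr") {
    out <- vector("list", length(set))
    for (i in seq_along(set)) out[[i]] <- utr_sequence(ids[i], seqs[i])
    out
  } else {
    mirna_library(ids, seqs)
  }
}

derive_variant_class <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  ifelse(nr == 1L & na == 1L, "SNP",
         ifelse(na > nr, "INS", ifelse(na < nr, "DEL", "MNV")))
}

validate_variants <- function(df, utr) {
  utr_len <- nchar(utr$sequence)
  for (i in seq_len(nrow(df))) {
    pos <- df$position[i]
    ref <- df$ref[i]
    if (pos < 1L || pos > utr_len)
      stop("variant '", df$variant_id[i], "': position ", pos,
           " outside UTR [1, ", utr_len, "]")
    have <- substr(utr$sequence, pos, pos + nchar(ref) - 1L)
    if (have != ref)
      stop("variant '", df$variant_id[i], "': ref allele '", ref,
           "' does not match UTR sequence '", have, "' at position ", pos)
  }
  df$variant_class <- derive_variant_class(df$ref, df$alt)
  rownames(df) <- NULL
  df
}

#' Read a variant list (TSV or minimal VCF) against a UTR record
#'
#' TSV dialect: header columns `variant_id`, `position`, `ref`, `alt`.
#' VCF dialect: a minimal VCF 4.x subset whose `CHROM` equals the UTR
#' `record_id` and whose `POS` is in UTR-local 1-based coordinates; the
#' anchor-base indel convention maps directly onto the internal
#' (position, ref, alt) form with non-empty ref.
#'
#' Every variant is validated against the UTR sequence (positions in range,
#' ref allele matching); the variant class (`SNP`, `INS`, `DEL`, `MNV`) is
#' derived, never user-supplied.
#'
#' @param path Input file.
#' @param utr A [utr_sequence()].
#' @param dialect `"tsv"` or `"vcf"`.
#' @return Data frame with columns `variant_id`, `position`, `ref`, `alt`,
#'   `variant_class`.
#' @export
read_variants <- function(path, utr, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = "character",
                            stringsAsFactors = FALSE)
    need <- c("variant_id", "position", "ref", "alt")
    if (!all(need %in% names(df)))
      stop("variant TSV must have columns: ", paste(need, collapse = ", "))
    df <- df[need]
  } else {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    if (any(fix$CHROM != utr$record_id))
      stop("VCF CHROM '", unique(fix$CHROM[fix$CHROM != utr$record_id])[1],
           "' does not match UTR record_id '", utr$record_id, "'")
    df <- data.frame(variant_id = fix$ID, position = fix$POS,
                     ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  }
  df$position <- as.integer(df$position)
  for (col in c("ref", "alt"))
    df[[col]] <- vapply(seq_len(nrow(df)), function(i)
      normalize_rna(df[[col]][i], df$variant_id[i])$sequence, character(1))
  validate_variants(df, utr)
}

#' Read a tissue-specific miRNA whitelist
#'
#' One mature miRNA name per line; `#` starts a comment; names are
#' whitespace-trimmed, case preserved, duplicates collapsed.
#'
#' @param path Whitelist file.
#' @return Character vector of unique names. An empty whitelist produces a
#'   warning (downstream whitelist filtering then passes nothing).
#' @export
read_whitelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  names <- unique(lines[nzchar(lines)])
  if (length(names) == 0L)
    warning("empty miRNA whitelist: all sites will be filtered out")
  names
}

#' Read a population allele-frequency annotation table
#'
#' TSV with columns `variant_id` and `max_af` (maximum population allele
#' frequency, a fraction in [0, 1]). Missingness is explicit: absent
#' variants and empty values are `NA`, never silently 0.
#'
#' @param path TSV file.
#' @return Data frame with columns `variant_id`,
#'   `max_population_allele_frequency`.
#' @export
read_frequencies <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", stringsAsFactors = FALSE)
  if (!all(c("variant_id", "max_af") %in% names(df)))
    stop("frequency TSV must have columns: variant_id, max_af")
  af <- suppressWarnings(as.numeric(df$max_af))
  if (any(!is.na(af) & (af < 0 | af > 1)))
    stop("allele frequencies must lie in [0, 1]")
  data.frame(variant_id = df$variant_id,
             max_population_allele_frequency = af,
             stringsAsFactors = FALSE)
}

#' Write pipeline results
#'
#' Emits three files under `out_prefix`:
#' \describe{
#'   \item{`<prefix>_impacts.tsv`}{per-variant impact table (columns
#'     `method`, `variant_id`, `delta_n`, `delta_w`,
#'     `max_population_allele_frequency`, `candidate_flag`), grouped by
#'     method.}
#'   \item{`<prefix>_sites.json`}{all retained interaction sites keyed by
#'     variant and allele, full numeric precision (round-trips bit-exactly).}
#'   \item{`<prefix>_energy_summary.tsv`}{count, minimum and median site
#'     energy per method x allele, a compact stand-in for an energy
#'     distribution plot.}
#' }
#'
#' @param impacts Impact data frame (see [variant_impact()]).
#' @param sites Interaction-site data frame (see [duplex_mfe()]).
#' @param out_prefix Path prefix for the three output files.
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_results <- function(impacts, sites, out_prefix) {
  dir <- dirname(out_prefix)
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(impacts = paste0(out_prefix, "_impacts.tsv"),
             sites = paste0(out_prefix, "_sites.json"),
             energy = paste0(out_prefix, "_energy_summary.tsv"))

  cols <- c("method", "variant_id", "delta_n", "delta_w",
            "max_population_allele_frequency", "candidate_flag")
  imp <- impacts
  if (nrow(imp) == 0L) {
    imp <- data.frame(method = character(), variant_id = character(),
                      delta_n = integer(), delta_w = numeric(),
                      max_population_allele_frequency = numeric(),
                      candidate_flag = logical())
  } else {
    if (!"max_population_allele_frequency" %in% names(imp))
      imp$max_population_allele_frequency <- NA_real_
    imp$candidate_flag <- imp$candidate
    imp <- imp[order(imp$method), cols, drop = FALSE]
  }
  utils::write.table(imp[, cols, drop = FALSE], paths[["impacts"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)

  site_tree <- list()
  if (!is.null(sites) && nrow(sites) > 0L) {
    for (v in unique(sites$variant_id)) {
      sv <- sites[sites$variant_id == v, , drop = FALSE]
      site_tree[[v]] <- lapply(split(sv, sv$allele), function(d) {
        rownames(d) <- NULL
        d
      })
    }
  }
  json <- jsonlite::toJSON(site_tree, dataframe = "rows", digits = NA,
                           na = "null", auto_unbox = TRUE, pretty = TRUE)
  writeLines(json, paths[["sites"]])

  if (!is.null(sites) && nrow(sites) > 0L) {
    key <- interaction(sites$method, sites$allele, drop = TRUE)
    summ <- do.call(rbind, lapply(split(sites, key), function(d)
      data.frame(method = d$method[1], allele = d$allele[1],
                 n_sites = nrow(d), min_energy = min(d$energy),
                 median_energy = stats::median(d$energy))))
    summ <- summ[order(summ$method, summ$allele), , drop = FALSE]
  } else {
    summ <- data.frame(method = character(), allele = character(),
                       n_sites = integer(), min_energy = numeric(),
                       median_energy = numeric())
  }
  utils::write.table(summ, paths[["energy"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Re-read an interaction-site JSON dump written by [write_results()]
#'
#' @param path Path to a `*_sites.json` file.
#' @return Interaction-site data frame (same columns as written).
#' @export
read_sites_json <- function(path) {
  tree <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  rows <- list()
  for (v in names(tree))
    for (a in names(tree[[v]]))
      rows[[length(rows) + 1L]] <- tree[[v]][[a]]
  if (length(rows) == 0L) return(empty_sites())
  out <- do.call(rbind, rows)
  out <- out[order(match(out$variant_id, out$variant_id)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
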