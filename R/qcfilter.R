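#' Remove clonal (byte-identical) reads
#'
#' Among groups of identical sequences the first-encountered read is kept;
#' order is otherwise preserved. Clonal duplicates would otherwise inflate
#' apparent coverage without adding independent evidence.
#'
#' @param reads Tibble with columns `id`, `bases`.
#' @return A list: `kept` (tibble), `removed` (tibble).
#' @export
filter_clonal <- function(reads) {
  dup <- duplicated(reads$bases)
  list(kept = reads[!dup, ], removed = reads[dup, ])
}

# mismatch count between two equal-length strings
str_mismatches <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# trim a primer prefix/suffix matching within max_mm mismatches (no indels)
trim_primer_ends <- function(bases, prefixes, suffixes, max_mm) {
  for (p in prefixes) {
    k <- nchar(p)
    if (nchar(bases) >= k && str_mismatches(substr(bases, 1, k), p) <= max_mm) {
      bases <- substr(bases, k + 1, nchar(bases))
      break
    }
  }
  for (p in suffixes) {
    k <- nchar(p)
    n <- nchar(bases)
    if (n >= k && str_mismatches(substr(bases, n - k + 1, n), p) <= max_mm) {
      bases <- substr(bases, 1, n - k)
      break
    }
  }
  bases
}

#' Remove reads containing N and excise primer sequences
#'
#' Reads with at least one `N` are removed (on this platform `N` marks a
#' failed nucleotide incorporation, not an ambiguity code). Surviving reads
#' have a leading or trailing primer excised when it matches within
#' `max_mismatch` substitutions, leaving only the extended portion; reads
#' reduced to nothing (primer-only reads) are removed.
#'
#' @param reads Tibble with columns `id`, `bases`.
#' @param amplicons Amplicon tibble (or `NULL` to skip trimming).
#' @param max_mismatch Primer match tolerance (substitutions only).
#' @return A list: `kept` (trimmed tibble), `removed` (tibble).
#' @export
filter_n_and_trim_primers <- function(reads, amplicons = NULL,
                                      max_mismatch = 2L) {
  has_n <- grepl("N", reads$bases, fixed = TRUE)
  removed <- reads[has_n, ]
  kept <- reads[!has_n, ]
  if (!is.null(amplicons) && nrow(kept) > 0) {
    # a read in L-orientation can start with a fwd primer or a rev primer's
    # read-through; in H-orientation the roles are reverse-complemented
    prefixes <- unique(c(amplicons$fwd_primer, amplicons$rev_primer))
    suffixes <- unique(revcomp(prefixes))
    kept$bases <- vapply(
      kept$bases, trim_primer_ends, "",
      prefixes = prefixes, suffixes = suffixes, max_mm = max_mismatch,
      USE.NAMES = FALSE
    )
    empty <- nchar(kept$bases) == 0
    removed <- dplyr::bind_rows(removed, kept[empty, ])
    kept <- kept[!empty, ]
  }
  list(kept = kept, removed = removed)
}

#' Retain reads within a length window
#'
#' Bounds are inclusive: the canonical 200-300 bp window keeps reads of
#' exactly 200 or 300 bases.
#'
#' @param reads Tibble with columns `id`, `bases`.
#' @param min,max Inclusive length bounds.
#' @return A list: `kept`, `removed`.
#' @export
filter_length <- function(reads, min = 200L, max = 300L) {
  stopifnot(min <= max)
  len <- nchar(reads$bases)
  ok <- len >= min & len <= max
  list(kept = reads[ok, ], removed = reads[!ok, ])
}

#' Retain uniquely mapped reads
#'
#' Reads with no acceptable alignment, or with acceptable alignments at more
#' than one location, are discarded.
#'
#' @param alignments Alignment tibble from [align_reads()] (rows per hit,
#'   `n_hits` per read).
#' @param read_ids Ids of all reads that entered alignment; needed to count
#'   unmapped reads.
#' @return A list: `kept` (single-hit alignment rows), `removed_ids`
#'   (character vector of discarded read ids).
#' @export
filter_mapping <- function(alignments, read_ids) {
  single <- alignments[alignments$n_hits == 1L, ]
  removed <- setdiff(read_ids, single$read_id)
  list(kept = single, removed_ids = removed)
}

#' Collapse reads sharing identical start, end and strand
#'
#' Non-identical reads with identical placement are overwhelmingly amplicon
#' artifacts. Within each `(start, end, strand)` group one representative
#' is kept: the read with the fewest mismatches to the reference, ties
#' broken by the lexicographically smallest sequence (deterministic).
#' Clonal duplicates have already been removed by this stage, so groups
#' contain non-identical sequences.
#'
#' @param alignments Single-hit alignment tibble.
#' @return A list: `kept` (alignment rows), `removed_ids`.
#' @export
filter_startstop <- function(alignments) {
  if (nrow(alignments) == 0) {
    return(list(kept = alignments, removed_ids = character(0)))
  }
  kept <- alignments %>%
    dplyr::group_by(.data$start, .data$end, .data$strand) %>%
    dplyr::arrange(.data$mismatches, .data$aln_seq, .by_group = TRUE) %>%
    dplyr::slice(1L) %>%
    dplyr::ungroup()
  list(
    kept = kept,
    removed_ids = setdiff(alignments$read_id, kept$read_id)
  )
}

#' Run the five-stage read filter
#'
#' Applies, in order: (1) clonal read removal, (2) N removal with primer
#' excision, (3) length window, then alignment, then (4) unique-mapping and
#' (5) identical start/stop collapsing. Every input read is claimed by
#' exactly one filter or retained, so the report satisfies
#' `input = retained + sum(removed)`.
#'
#' @param reads Tibble with columns `id`, `bases`.
#' @param ref A [circular_reference()].
#' @param amplicons Amplicon tibble, or `NULL` to skip primer trimming.
#' @param align_par An [align_params()].
#' @param min_len,max_len Inclusive read-length bounds.
#' @param primer_max_mismatch Primer excision tolerance.
#' @return A list of class `qc_result`: `alignments` (retained single-hit
#'   alignments), `report` (tibble `filter`, `removed`, `retained_after`),
#'   `reads` (the retained reads after trimming).
#' @export
qc_run_all <- function(reads, ref, amplicons = NULL,
                       align_par = align_params(),
                       min_len = 200L, max_len = 300L,
                       primer_max_mismatch = 2L) {
  n_input <- nrow(reads)
  s1 <- filter_clonal(reads)
  s2 <- filter_n_and_trim_primers(s1$kept, amplicons, primer_max_mismatch)
  s3 <- filter_length(s2$kept, min_len, max_len)
  aln <- align_reads(s3$kept, ref, align_par)
  s4 <- filter_mapping(aln, s3$kept$id)
  s5 <- filter_startstop(s4$kept)
  removed <- c(
    clonal = nrow(s1$removed),
    contains_N = nrow(s2$removed),
    length = nrow(s3$removed),
    mapping = length(s4$removed_ids),
    startstop = length(s5$removed_ids)
  )
  retained <- n_input - cumsum(removed)
  report <- tibble::tibble(
    filter = names(removed),
    removed = as.integer(removed),
    retained_after = as.integer(retained)
  )
  out <- list(
    alignments = s5$kept,
    report = report,
    reads = s3$kept[s3$kept$id %in% s5$kept$read_id, ],
    input = n_input,
    retained = as.integer(retained[length(retained)])
  )
  class(out) <- "qc_result"
  out
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> %d reads in, %d retained (%.1f%%)\n",
              x$input, x$retained, 100 * x$retained / max(1, x$input)))
  print(x$report)
  invisible(x)
}

#' Per-filter accounting of a QC run
#'
#' @param x A `qc_result`.
#' @param ... Unused.
#' @return The report tibble (`filter`, `removed`, `retained_after`).
#' @export
tidy.qc_result <- function(x, ...) x$report

#' One-row summary of a QC run
#'
#' @param x A `qc_result`.
#' @param ... Unused.
#' @return A tibble with `input`, `retained` and `retained_fraction`.
#' @export
glance.qc_result <- function(x, ...) {
  tibble::tibble(
    input = x$input, retained = x$retained,
    retained_fraction = x$retained / max(1, x$input)
  )
}
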