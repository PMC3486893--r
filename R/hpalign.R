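#' Alignment parameters
#'
#' Scoring and search parameters for the homopolymer-aware seed-and-extend
#' aligner. The gap model grants "free" gaps inside reference homopolymer
#' runs: none for runs of length 3 or less, one for runs of length 4, two
#' for runs of length 5 or more; remaining gaps in a segment are charged the
#' standard affine penalty `gap_open + (k - 1) * gap_extend`. The affine
#' values themselves follow common BLASTN-like defaults; the scheme's shape,
#' not the exact values, is what the homopolymer correction depends on.
#'
#' @param match Match score (positive).
#' @param mismatch Mismatch penalty (positive; subtracted).
#' @param gap_open,gap_extend Affine gap penalties (positive; subtracted).
#' @param seed_len Exact-match seed length for locating candidate loci.
#' @param band Half-width of the banded dynamic program around a seed
#'   diagonal; 16 comfortably covers the longest (8 bp) mitochondrial
#'   homopolymer plus drift.
#' @param max_gap Longest single gap segment considered by the dynamic
#'   program (both the production aligner and the test oracle share this
#'   contract).
#' @param min_score_frac Acceptance threshold: alignments scoring below
#'   `min_score_frac * read_length * match` are dropped.
#' @param multi_margin Alignments at distinct loci within this many score
#'   points of the best are reported together as an ambiguous multi-map.
#' @return A list of class `align_params`.
#' @export
align_params <- function(match = 1L, mismatch = 3L, gap_open = 5L,
                         gap_extend = 2L, seed_len = 13L, band = 16L,
                         max_gap = 8L, min_score_frac = 0.6,
                         multi_margin = 5L) {
  stopifnot(match > 0, mismatch >= 0, gap_open >= 0, gap_extend >= 0,
            seed_len >= 4, band >= 1, max_gap >= 1)
  structure(list(
    match = as.integer(match), mismatch = as.integer(mismatch),
    gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
    seed_len = as.integer(seed_len), band = as.integer(band),
    max_gap = as.integer(max_gap), min_score_frac = min_score_frac,
    multi_margin = as.integer(multi_margin)
  ), class = "align_params")
}

#' Free gaps granted inside a homopolymer run
#'
#' @param h Run length(s) on the reference.
#' @return Integer vector: 0 for `h <= 3`, 1 for `h == 4`, 2 for `h >= 5`.
#' @export
hp_free_gaps <- function(h) {
  ifelse(h >= 5, 2L, ifelse(h == 4, 1L, 0L))
}

#' Penalty for gaps inside a homopolymer run
#'
#' The first [hp_free_gaps()] gaps are forgiven; the remainder are charged
#' the affine penalty `gap_open + (k - 1) * gap_extend`.
#'
#' @param run_len Reference run length `h >= 1`.
#' @param n_gaps Number of gaps `g >= 0` placed in the run.
#' @param params An [align_params()].
#' @return Non-negative penalty.
#' @export
hp_gap_cost <- function(run_len, n_gaps, params = align_params()) {
  stopifnot(run_len >= 1, n_gaps >= 0)
  k <- pmax(0L, n_gaps - hp_free_gaps(run_len))
  ifelse(k == 0, 0L, params$gap_open + (k - 1L) * params$gap_extend)
}

#' Exhaustive homopolymer-aware local alignment score (test oracle)
#'
#' Full-matrix Smith-Waterman under the same scoring contract as
#' [align_read()], with no seeding and no banding. Intended as an
#' independent oracle at test scale.
#'
#' @param seq_a Query sequence (read-like).
#' @param seq_b Subject sequence (reference-like; homopolymer runs are
#'   defined on it).
#' @param params An [align_params()].
#' @return Best local alignment score (integer).
#' @export
dp_oracle <- function(seq_a, seq_b, params = align_params()) {
  if (nchar(seq_a) * nchar(seq_b) > 1e6) {
    stop("dp_oracle is a test oracle; inputs exceed 10^6 cells")
  }
  hp_dp_score_cpp(toupper(seq_a), toupper(seq_b), params$match,
                  params$mismatch, params$gap_open, params$gap_extend,
                  params$max_gap)
}

# Exact k-mer index of the reference (doubled to expose circular k-mers).
# Environment mapping k-mer -> integer vector of 1-based start positions
# in 1..L.
ref_seed_index <- function(ref, k) {
  doubled <- paste0(ref$seq, substr(ref$seq, 1, min(k - 1, ref$length)))
  n <- ref$length
  kmers <- substring(doubled, 1:n, 1:n + k - 1)
  keep <- nchar(kmers) == k
  env <- new.env(hash = TRUE, parent = emptyenv())
  pos <- which(keep)
  sp <- split(pos, kmers[keep])
  list2env(sp, envir = env)
  env
}

# Candidate diagonals (0-based offsets: ref position = read position + diag,
# mod L) for one oriented read, from exact seed hits.
seed_diagonals <- function(bases, index, k, L, max_candidates = 5L) {
  len <- nchar(bases)
  if (len < k) return(integer(0))
  probes <- unique(c(seq(1L, len - k + 1L, by = k), len - k + 1L))
  kmers <- substring(bases, probes, probes + k - 1L)
  hits <- mget(kmers, envir = index, ifnotfound = list(integer(0)))
  diags <- unlist(lapply(seq_along(probes), function(i) {
    (hits[[i]] - probes[i]) %% L
  }), use.names = FALSE)
  if (length(diags) == 0) return(integer(0))
  tab <- sort(table(diags), decreasing = TRUE)
  cand <- as.integer(names(tab))
  # merge diagonals that are within a band of a better-supported one
  kept <- integer(0)
  for (d in cand) {
    if (length(kept) == 0L ||
        all(pmin(abs(kept - d), L - abs(kept - d)) > 8L)) {
      kept <- c(kept, d)
    }
    if (length(kept) >= max_candidates) break
  }
  kept
}

# Prebuilt alignment context: seed index plus a tripled sequence for fast
# wrap-around window extraction (windows may exceed one genome length when
# reads approach it).
align_context <- function(ref, params) {
  list(
    ref = ref, L = ref$length,
    index = ref_seed_index(ref, params$seed_len),
    tripled = paste0(ref$seq, ref$seq, ref$seq)
  )
}

# Align one oriented read sequence at one candidate diagonal.
banded_at_diagonal <- function(bases, ctx, diag, params) {
  L <- ctx$L
  len <- nchar(bases)
  win_start <- ((diag - params$band) %% L) + 1L
  win_len <- min(len + 2L * params$band, 2L * L)
  window <- substr(ctx$tripled, win_start, win_start + win_len - 1L)
  res <- hp_banded_align_cpp(bases, window, params$band, params$match,
                             params$mismatch, params$gap_open,
                             params$gap_extend, params$max_gap)
  if (res$score <= 0) return(NULL)
  ref_start <- ((win_start - 1L + res$win_start - 1L) %% L) + 1L
  ref_end <- ((win_start - 1L + res$win_end - 1L) %% L) + 1L
  list(score = res$score, ref_start = ref_start, ref_end = ref_end,
       read_start = res$read_start, read_end = res$read_end,
       ops = res$ops, mismatches = res$mismatches)
}

#' Align a single read to a circular reference
#'
#' Seed-and-extend: exact `seed_len`-mers locate candidate diagonals on both
#' strands of the (doubled, to handle circularity) reference, then a banded
#' homopolymer-aware Smith-Waterman refines each candidate. Absence of an
#' alignment is a value, not an error: the result has zero rows when no
#' locus reaches the score threshold, one row for a unique hit, and several
#' rows when distinct loci score within `multi_margin` of the best
#' (ambiguous multi-maps; downstream filtering removes such reads).
#'
#' @param id Read identifier.
#' @param bases Read sequence.
#' @param ref A [circular_reference()].
#' @param params An [align_params()].
#' @param index Unused; retained for backward compatibility of the call
#'   signature.
#' @return A tibble with columns `read_id`, `start`, `end`, `strand`,
#'   `score`, `mismatches`, `ops`, `aln_seq` (the read in reference
#'   orientation, clipped to the aligned span), `read_len`, `read_offset`
#'   (1-based start of the aligned span within the oriented read), `n_hits`.
#' @export
align_read <- function(id, bases, ref, params = align_params(), index = NULL) {
  ctx <- align_context(ref, params)
  hits <- align_read_hits(bases, ctx, params)
  hits_to_tibble(list(hits), id, toupper(bases))
}

# hit records (plain lists) for one read; no tibble allocation
align_read_hits <- function(bases, ctx, params) {
  bases <- toupper(bases)
  oriented <- c(fwd = bases, rev = revcomp(bases))
  hits <- list()
  for (strand in c("fwd", "rev")) {
    seqs <- oriented[[strand]]
    for (diag in seed_diagonals(seqs, ctx$index, params$seed_len, ctx$L)) {
      a <- banded_at_diagonal(seqs, ctx, diag, params)
      if (is.null(a)) next
      a$strand <- strand
      a$aln_seq <- substr(seqs, a$read_start, a$read_end)
      hits[[length(hits) + 1L]] <- a
    }
  }
  if (length(hits) == 0) return(list())
  scores <- vapply(hits, `[[`, 0, "score")
  min_score <- params$min_score_frac * nchar(bases) * params$match
  hits <- hits[scores >= min_score]
  if (length(hits) == 0) return(list())
  if (length(hits) > 1) {
    # deduplicate hits at the same locus/strand, keep the best score
    key <- vapply(hits, function(a) paste(a$ref_start, a$strand), "")
    hits <- lapply(split(hits, key), function(grp) {
      grp[[which.max(vapply(grp, `[[`, 0, "score"))]]
    })
    scores <- vapply(hits, `[[`, 0, "score")
    hits <- hits[scores >= max(scores) - params$multi_margin]
    hits <- hits[order(-vapply(hits, `[[`, 0, "score"))]
  }
  hits
}

# assemble hit-record lists (one element per read) into the alignment tibble
hits_to_tibble <- function(hit_lists, ids, bases) {
  n_per <- lengths(hit_lists)
  if (sum(n_per) == 0) return(empty_alignments())
  flat <- unlist(hit_lists, recursive = FALSE)
  ridx <- rep(seq_along(hit_lists), n_per)
  tibble::tibble(
    read_id = ids[ridx],
    start = vapply(flat, `[[`, 0L, "ref_start"),
    end = vapply(flat, `[[`, 0L, "ref_end"),
    strand = vapply(flat, `[[`, "", "strand"),
    score = vapply(flat, `[[`, 0L, "score"),
    mismatches = vapply(flat, `[[`, 0L, "mismatches"),
    ops = vapply(flat, `[[`, "", "ops"),
    aln_seq = vapply(flat, `[[`, "", "aln_seq"),
    read_len = nchar(bases)[ridx],
    read_offset = vapply(flat, `[[`, 0L, "read_start"),
    n_hits = rep(n_per, n_per)
  )
}

empty_alignments <- function() {
  tibble::tibble(
    read_id = character(), start = integer(), end = integer(),
    strand = character(), score = integer(), mismatches = integer(),
    ops = character(), aln_seq = character(), read_len = integer(),
    read_offset = integer(), n_hits = integer()
  )
}

#' Align a set of reads to a circular reference
#'
#' @param reads Tibble with columns `id`, `bases`.
#' @param ref A [circular_reference()].
#' @param params An [align_params()].
#' @return A tibble of alignments (see [align_read()]); reads without an
#'   acceptable locus contribute no rows, ambiguous reads contribute one row
#'   per locus with `n_hits > 1`.
#' @export
align_reads <- function(reads, ref, params = align_params()) {
  ctx <- align_context(ref, params)
  hit_lists <- lapply(reads$bases, align_read_hits, ctx = ctx, params = params)
  hits_to_tibble(hit_lists, reads$id, reads$bases)
}
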