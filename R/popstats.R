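TRANSITIONS <- c("A>G", "G>A", "C>T", "T>C")

#' Variant table from genome calls
#'
#' One record per position where the called primary allele differs from the
#' reference; uncalled (`Z`) positions are skipped. Substitutions are
#' classified as transition or transversion; deletion records carry no
#' such class. An optional user-supplied site list marks known variants
#' (database lookups are deliberately not performed: database content
#' drifts, a frozen list is reproducible).
#'
#' @param calls A `genome_calls` tibble from [call_genome()].
#' @param known_sites Optional integer vector (or tibble with column `pos`)
#'   of known variant positions.
#' @return A tibble: `pos`, `ref`, `alt`, `class`, `known`.
#' @export
variant_table <- function(calls, known_sites = NULL) {
  diff <- calls$status == "called" & calls$allele != calls$ref_base
  v <- calls[diff, c("pos", "ref_base", "allele")]
  names(v) <- c("pos", "ref", "alt")
  v <- tibble::as_tibble(v)
  v$class <- dplyr::case_when(
    v$alt == "del" ~ "deletion",
    paste0(v$ref, ">", v$alt) %in% TRANSITIONS ~ "transition",
    TRUE ~ "transversion"
  )
  known_pos <- if (is.null(known_sites)) {
    integer(0)
  } else if (is.data.frame(known_sites)) known_sites$pos else known_sites
  v$known <- v$pos %in% known_pos
  v
}

#' Transition:transversion ratio
#'
#' @param variants A variant tibble (or several, row-bound) with a `class`
#'   column.
#' @return `#transitions / #transversions`; `Inf` when there are
#'   transitions but no transversions. Errors when there are no
#'   substitutions at all.
#' @export
ts_tv_ratio <- function(variants) {
  ts <- sum(variants$class == "transition")
  tv <- sum(variants$class == "transversion")
  if (ts + tv == 0) stop("no substitutions to classify")
  if (tv == 0) return(Inf)
  ts / tv
}

#' Nucleotide diversity among consensus sequences
#'
#' Average pairwise difference per comparable site. For each pair of
#' sequences only positions called (non-`Z`) in both are compared
#' (pairwise-deletion handling of missing data); the per-pair difference
#' rate is averaged over all pairs.
#'
#' @param seqs Character vector (length >= 2) of equal-length consensus
#'   strings over `{A,C,G,T,Z}` on a shared coordinate frame (use `Z` for
#'   uncalled; called deletions may be represented by any non-`Z` symbol
#'   and then count as differences where they disagree).
#' @return The diversity estimate (a number, typically around 10^-3 for
#'   human mitochondria).
#' @export
nucleotide_diversity <- function(seqs) {
  k <- length(seqs)
  if (k < 2) stop("need at least 2 sequences")
  if (length(unique(nchar(seqs))) != 1) stop("sequences must share a coordinate frame")
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rates <- c()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- mat[i, ] != "Z" & mat[j, ] != "Z"
      S <- sum(ok)
      if (S == 0) stop("a pair of sequences shares no called positions")
      rates <- c(rates, sum(mat[i, ok] != mat[j, ok]) / S)
    }
  }
  mean(rates)
}

#' Per-region polymorphic-site frequency
#'
#' For each named region: the number of distinct polymorphic positions in
#' the region, divided by the region length, divided by the sample size.
#' A site polymorphic in several samples counts once.
#'
#' @param variants Variant tibble pooled over samples (column `pos`).
#' @param regions Tibble with columns `region`, `start`, `end` (circular,
#'   1-based inclusive).
#' @param sample_size Number of samples pooled.
#' @param L Genome length (for wrap-around regions).
#' @return A tibble: `region`, `length`, `n_sites`, `frequency`.
#' @export
region_frequency <- function(variants, regions, sample_size, L) {
  stopifnot(sample_size > 0)
  purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    len <- circular_span_length(regions$start[i], regions$end[i], L)
    if (len == 0) stop("zero-length region: ", regions$region[i])
    pos <- circular_positions(regions$start[i], regions$end[i], L)
    n_sites <- length(unique(variants$pos[variants$pos %in% pos]))
    tibble::tibble(
      region = regions$region[i], length = len, n_sites = n_sites,
      frequency = n_sites / len / sample_size
    )
  })
}

#' Normalized coverage track
#'
#' Coverage per position divided by the sample's total read count in
#' thousands, making tracks comparable across samples with different
#' yields.
#'
#' @param pileup Wide pileup tibble.
#' @param total_reads The sample's total read count (> 0).
#' @return A tibble: `pos`, `coverage`, `normalized`.
#' @export
coverage_track <- function(pileup, total_reads) {
  if (total_reads <= 0) stop("total_reads must be positive")
  tibble::tibble(
    pos = pileup$pos,
    coverage = pileup$n,
    normalized = pileup$n / (total_reads / 1000)
  )
}

#' Zero-centered strand ratio
#'
#' The forward/reverse read ratio `r` mapped to `(r - 1) / (r + 1)`,
#' computed in the algebraically equivalent form
#' `(fwd - rev) / (fwd + rev)`, which is defined when one strand count is
#' zero and ranges over `[-1, 1]`.
#'
#' @param fwd,rev Strand counts (vectorised); `fwd + rev` must be positive.
#' @return Values in `[-1, 1]`.
#' @export
centered_ratio <- function(fwd, rev) {
  if (any(fwd + rev <= 0)) stop("fwd + rev must be positive")
  (fwd - rev) / (fwd + rev)
}

#' GC fraction in a sliding circular window
#'
#' @param ref A [circular_reference()].
#' @param w Odd window width, centred on each position.
#' @return Numeric vector: per-position GC fraction.
#' @export
gc_window <- function(ref, w = 51L) {
  if (w %% 2L == 0L) stop("window width must be odd")
  L <- ref$length
  if (w > L) stop("window wider than the genome")
  gc <- as.integer(strsplit(ref$seq, "", fixed = TRUE)[[1]] %in% c("G", "C"))
  half <- (w - 1L) %/% 2L
  ext <- c(gc[(L - half + 1L):L], gc, gc[1:half])
  cs <- cumsum(c(0L, ext))
  (cs[(1:L) + w] - cs[1:L]) / w
}

#' Concordance between two call sets
#'
#' Positions called (non-`Z`) in both inputs are compared. With zero
#' discordances the resolution bound `1 / compared` is reported as an
#' upper bound on the error rate.
#'
#' @param calls_a,calls_b `genome_calls` tibbles on the same coordinate
#'   frame.
#' @return A tibble: `compared`, `discordant`, `rate`, `is_bound`.
#' @export
concordance <- function(calls_a, calls_b) {
  stopifnot(nrow(calls_a) == nrow(calls_b))
  both <- calls_a$status == "called" & calls_b$status == "called"
  compared <- sum(both)
  if (compared == 0) stop("no positions called in both samples")
  disc <- sum(calls_a$allele[both] != calls_b$allele[both])
  tibble::tibble(
    compared = compared, discordant = disc,
    rate = if (disc == 0) 1 / compared else disc / compared,
    is_bound = disc == 0
  )
}

#' Pooled concordance arithmetic over per-sample counts
#'
#' Aggregates per-sample discordance counts and compared-position counts
#' into a pooled error rate; with zero total discordances the pooled
#' resolution bound `1 / sum(compared)` is reported instead.
#'
#' @param discordances Integer vector of per-sample discordant positions.
#' @param compared Integer vector of per-sample compared positions.
#' @return A tibble: `compared`, `discordant`, `rate`, `is_bound`.
#' @export
concordance_summary <- function(discordances, compared) {
  stopifnot(length(discordances) == length(compared), all(compared > 0),
            all(discordances >= 0))
  d <- sum(discordances)
  ctot <- sum(compared)
  tibble::tibble(
    compared = ctot, discordant = d,
    rate = if (d == 0) 1 / ctot else d / ctot,
    is_bound = d == 0
  )
}

#' Plot coverage, strand-ratio and GC tracks
#'
#' @param pileup Wide pileup tibble.
#' @param ref A [circular_reference()].
#' @param total_reads Total read count for normalization (defaults to the
#'   number of distinct reads contributing to the pileup being unknown;
#'   supply the sample's read count).
#' @param w GC window width.
#' @return A ggplot with three facetted tracks along the genome.
#' @export
plot_genome_tracks <- function(pileup, ref, total_reads, w = 51L) {
  m <- pileup_matrices(pileup)
  fwd <- rowSums(m$fwd)
  rev <- rowSums(m$rev)
  ratio <- ifelse(fwd + rev > 0, (fwd - rev) / (fwd + rev), NA_real_)
  df <- dplyr::bind_rows(
    tibble::tibble(pos = pileup$pos, value = pileup$n / (total_reads / 1000),
                   track = "normalized coverage"),
    tibble::tibble(pos = pileup$pos, value = ratio,
                   track = "centered strand ratio"),
    tibble::tibble(pos = seq_len(ref$length), value = gc_window(ref, w),
                   track = "GC fraction")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "steelblue") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$track), scales = "free_y") +
    ggplot2::labs(x = "genome position", y = NULL) +
    ggplot2::theme_minimal()
}
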