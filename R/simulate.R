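#' Simulation configuration for synthetic 454-style reads
#'
#' Captures the read-generating process the pipeline is designed for:
#' read lengths approximately Normal(250, 36) truncated to a plausible
#' pyrosequencing range, per-base substitution errors, homopolymer-length
#' dependent indel errors that grow sharply for runs longer than 4, clonal
#' duplicate reads (about 15% of output), overlapping long-PCR amplicons
#' with primer sequences at their boundaries, random strand assignment, and
#' optional two-haplotype mixtures at given site fractions.
#'
#' The homopolymer indel rate per run is
#' `hp_indel_base_rate * hp_growth^max(0, h - 4)` for a run of length `h`,
#' an exponential-growth parameterisation of the observed error inflation in
#' long runs. Truncation bounds default to `[100, 400]` so the 200-300 bp
#' length filter has material both to keep and to discard.
#'
#' @param ref A [circular_reference()].
#' @param amplicons Amplicon tibble (see [read_amplicons()]); defaults to
#'   three overlapping amplicons covering the circle via
#'   [default_amplicons()].
#' @param n_reads Total reads to emit (including clones).
#' @param len_mean,len_sd,len_min,len_max Truncated-normal read length model
#'   (bases).
#' @param sub_rate Per-base substitution probability (typical pyrosequencing
#'   substitution error is around 0.5%).
#' @param hp_indel_base_rate Per-run indel probability for runs of length 4
#'   or less.
#' @param hp_growth Multiplicative growth per run base beyond 4.
#' @param clonal_fraction Fraction of emitted reads that are verbatim copies
#'   of earlier reads (same errors).
#' @param strand_fwd_prob Probability a read is reported on the L-strand.
#' @param het_sites Optional tibble with columns `pos`, `alt`, `fraction`.
#' @param seed RNG seed; output is deterministic given the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(ref, amplicons = NULL, n_reads = 2000L,
                       len_mean = 250, len_sd = 36, len_min = 100,
                       len_max = 400, sub_rate = 0.005,
                       hp_indel_base_rate = 0.002, hp_growth = 2,
                       clonal_fraction = 0.15, strand_fwd_prob = 0.5,
                       het_sites = NULL, seed = 1L) {
  stopifnot(inherits(ref, "circular_reference"), n_reads >= 1,
            len_min >= 1, len_min <= len_max,
            sub_rate >= 0, sub_rate <= 1,
            clonal_fraction >= 0, clonal_fraction <= 1,
            strand_fwd_prob >= 0, strand_fwd_prob <= 1)
  if (is.null(amplicons)) amplicons <- default_amplicons(ref)
  if (nrow(amplicons) == 0) stop("amplicon list is empty")
  if (!is.null(het_sites)) {
    stopifnot(all(c("pos", "alt", "fraction") %in% names(het_sites)))
    if (any(het_sites$pos < 1 | het_sites$pos > ref$length)) {
      stop("het site outside reference")
    }
    if (any(het_sites$fraction < 0 | het_sites$fraction > 1)) {
      stop("het site fraction outside [0,1]")
    }
  }
  structure(list(
    ref = ref, amplicons = amplicons, n_reads = as.integer(n_reads),
    len_mean = len_mean, len_sd = len_sd, len_min = len_min,
    len_max = len_max, sub_rate = sub_rate,
    hp_indel_base_rate = hp_indel_base_rate, hp_growth = hp_growth,
    clonal_fraction = clonal_fraction, strand_fwd_prob = strand_fwd_prob,
    het_sites = het_sites, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Three overlapping amplicons with reference-matching primers
#'
#' Splits the circle into `n` spans of roughly equal length, each extended
#' by `overlap` bases past the next span's start so that neighbouring
#' amplicons overlap. Primer sequences are the reference subsequences at the
#' span boundaries (`fwd_primer` on the L-strand, `rev_primer` the
#' reverse-strand oligo), so simulated reads that begin at an amplicon
#' boundary naturally carry primer bases.
#'
#' @param ref A [circular_reference()].
#' @param n Number of amplicons.
#' @param primer_len Primer length (bases).
#' @param overlap Overlap between neighbouring amplicons (bases).
#' @return An amplicon tibble.
#' @export
default_amplicons <- function(ref, n = 3L, primer_len = 22L, overlap = 60L) {
  L <- ref$length
  starts <- floor((0:(n - 1)) * L / n) + 1L
  ends_excl <- c(starts[-1], L + 1L)
  tibble::tibble(
    id = paste0("amp", seq_len(n)),
    start = starts,
    end = ((ends_excl - 1L + overlap - 1L) %% L) + 1L
  ) %>%
    dplyr::mutate(
      fwd_primer = vapply(.data$start, function(s)
        circular_subseq(ref, s, primer_len), ""),
      rev_primer = vapply(.data$end, function(e)
        revcomp(circular_subseq(ref, e - primer_len + 1L, primer_len)), "")
    ) %>%
    dplyr::select("id", "fwd_primer", "rev_primer", "start", "end")
}

#' Simulate a synthetic 454-style read set with known truth
#'
#' Each read is drawn by choosing an amplicon, sampling a start uniformly
#' within it and a length from the truncated normal (clipped at the amplicon
#' end), copying template bases with heteroplasmic alternate alleles applied
#' per site with probability equal to the site fraction, applying per-base
#' substitutions and homopolymer-run indels, reverse-complementing with
#' probability `1 - strand_fwd_prob`, and finally re-emitting verbatim
#' clones for `clonal_fraction` of the output (a deterministic count,
#' `round(clonal_fraction * n_reads)`).
#'
#' @param config A [sim_config()].
#' @return A list with elements `reads` (tibble `id`, `bases`) and `truth`
#'   (tibble with per-read provenance: `id`, `amplicon`, `start`, `end`,
#'   `strand`, `tmpl_len`, `alt_sites`, `clone_of`).
#' @export
simulate_reads <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_reads_impl(config))
}

simulate_reads_impl <- function(config) {
  ref <- config$ref
  L <- ref$length
  refchars <- strsplit(ref$seq, "", fixed = TRUE)[[1]]
  run_ids <- hp_run_ids(ref)
  run_lens <- hp_run_lengths(ref)
  amp <- config$amplicons
  het <- config$het_sites
  bases4 <- c("A", "C", "G", "T")

  n_clones <- round(config$clonal_fraction * config$n_reads)
  n_orig <- config$n_reads - n_clones

  draw_len <- function() {
    repeat {
      l <- round(rnorm(1, config$len_mean, config$len_sd))
      if (l >= config$len_min && l <= config$len_max) return(l)
    }
  }

  out_bases <- character(n_orig)
  tr_amp <- character(n_orig); tr_start <- integer(n_orig)
  tr_end <- integer(n_orig); tr_strand <- character(n_orig)
  tr_len <- integer(n_orig); tr_alt <- vector("list", n_orig)

  for (i in seq_len(n_orig)) {
    ai <- sample.int(nrow(amp), 1L)
    span_len <- circular_span_length(amp$start[ai], amp$end[ai], L)
    len <- min(draw_len(), span_len)
    # uniform over starts at which the read fits inside the amplicon product
    off <- sample.int(span_len - len + 1L, 1L)
    start <- ((amp$start[ai] - 1L + off - 1L) %% L) + 1L
    idx <- ((start - 1L + seq_len(len) - 1L) %% L) + 1L
    chars <- refchars[idx]

    alt_applied <- integer(0)
    if (!is.null(het)) {
      hit <- which(het$pos %in% idx)
      for (h in hit) {
        if (runif(1) < het$fraction[h]) {
          chars[match(het$pos[h], idx)] <- toupper(het$alt[h])
          alt_applied <- c(alt_applied, het$pos[h])
        }
      }
    }

    if (config$sub_rate > 0) {
      mut <- which(runif(len) < config$sub_rate)
      for (m in mut) chars[m] <- sample(setdiff(bases4, chars[m]), 1L)
    }

    counts <- rep(1L, len)
    if (config$hp_indel_base_rate > 0) {
      rids <- run_ids[idx]
      for (rid in unique(rids)) {
        h <- run_lens[idx[match(rid, rids)]]
        rate <- config$hp_indel_base_rate * config$hp_growth^max(0, h - 4)
        if (runif(1) < rate) {
          w <- which(rids == rid)[1L]
          counts[w] <- if (runif(1) < 0.5) 0L else 2L
        }
      }
    }
    chars <- rep(chars, counts)

    seqv <- paste(chars, collapse = "")
    strand <- if (runif(1) < config$strand_fwd_prob) "fwd" else "rev"
    if (strand == "rev") seqv <- revcomp(seqv)

    out_bases[i] <- seqv
    tr_amp[i] <- amp$id[ai]; tr_start[i] <- start
    tr_end[i] <- ((start - 1L + len - 1L) %% L) + 1L
    tr_strand[i] <- strand; tr_len[i] <- len
    tr_alt[[i]] <- alt_applied
  }

  ids <- sprintf("read%06d", seq_len(n_orig))
  clone_src <- if (n_clones > 0) sample.int(n_orig, n_clones, replace = TRUE) else integer(0)
  clone_ids <- if (n_clones > 0) sprintf("read%06d", n_orig + seq_len(n_clones)) else character(0)

  reads <- tibble::tibble(
    id = c(ids, clone_ids),
    bases = c(out_bases, out_bases[clone_src])
  )
  truth <- tibble::tibble(
    id = reads$id,
    amplicon = c(tr_amp, tr_amp[clone_src]),
    start = c(tr_start, tr_start[clone_src]),
    end = c(tr_end, tr_end[clone_src]),
    strand = c(tr_strand, tr_strand[clone_src]),
    tmpl_len = c(tr_len, tr_len[clone_src]),
    alt_sites = c(tr_alt, tr_alt[clone_src]),
    clone_of = c(rep(NA_character_, n_orig), ids[clone_src])
  )
  list(reads = reads, truth = truth)
}

#' Simulate a two-allele mixture dilution series
#'
#' Emulates a standard-reference-material style benchmark: two equal-length
#' amplicon alleles differing at exactly one site, mixed at known mass
#' fractions. For each fraction, `round(fraction * coverage)` reads are
#' full-length copies of the alternate allele and the rest of the reference
#' allele (deterministic rounding, so fraction recovery carries no binomial
#' noise at the template level); strands alternate read-by-read; per-base
#' substitution errors are applied at `sub_rate`.
#'
#' @param allele_a,allele_b The two allele sequences (equal length,
#'   differing at exactly one position).
#' @param fractions Mass fractions of `allele_b`, each in `[0, 1]`.
#' @param coverage Reads per mixture.
#' @param sub_rate Per-base substitution error probability.
#' @param seed RNG seed.
#' @return A tibble of class `mixture_series` with columns `fraction` and
#'   `reads` (list of read tibbles), and attributes `allele_a`, `allele_b`,
#'   `site` (list: `pos`, `ref`, `alt`).
#' @export
simulate_mixture_series <- function(allele_a, allele_b, fractions,
                                    coverage = 500L, sub_rate = 0.005,
                                    seed = 1L) {
  allele_a <- toupper(allele_a); allele_b <- toupper(allele_b)
  if (nchar(allele_a) != nchar(allele_b)) stop("alleles differ in length")
  ca <- strsplit(allele_a, "")[[1]]; cb <- strsplit(allele_b, "")[[1]]
  diffs <- which(ca != cb)
  if (length(diffs) != 1L) {
    stop("alleles must differ at exactly one position (found ",
         length(diffs), ")")
  }
  site <- list(pos = diffs, ref = ca[diffs], alt = cb[diffs])
  bases4 <- c("A", "C", "G", "T")
  len <- nchar(allele_a)

  sets <- withr::with_seed(seed, lapply(seq_along(fractions), function(k) {
    f <- fractions[k]
    n_alt <- round(f * coverage)
    tmpl <- c(rep(allele_b, n_alt), rep(allele_a, coverage - n_alt))
    reads <- vapply(seq_len(coverage), function(i) {
      chars <- strsplit(tmpl[i], "")[[1]]
      if (sub_rate > 0) {
        mut <- which(runif(len) < sub_rate)
        for (m in mut) chars[m] <- sample(setdiff(bases4, chars[m]), 1L)
      }
      s <- paste(chars, collapse = "")
      if (i %% 2L == 0L) s <- revcomp(s)
      s
    }, "")
    tibble::tibble(
      id = sprintf("mix%02d_read%04d", k, seq_len(coverage)),
      bases = reads
    )
  }))

  out <- tibble::tibble(fraction = fractions, reads = sets)
  attr(out, "allele_a") <- allele_a
  attr(out, "allele_b") <- allele_b
  attr(out, "site") <- site
  class(out) <- c("mixture_series", class(out))
  out
}

#' Simulate error-only pileup columns
#'
#' Independent pileup columns of fixed coverage in which the only
#' non-reference bases are random substitution errors: each base is wrong
#' with probability `error_rate`, the wrong base uniform over the other
#' three, strands assigned fairly. Used to check the false-candidate rate of
#' the Poisson secondary threshold.
#'
#' @param n_positions Number of columns.
#' @param coverage Reads per column.
#' @param error_rate Per-base substitution probability.
#' @param ref_base Reference (true) base at every column.
#' @param seed RNG seed.
#' @return A wide pileup tibble (see [build_pileup()]).
#' @export
simulate_error_pileup <- function(n_positions = 2000L, coverage = 200L,
                                  error_rate = 0.05, ref_base = "A",
                                  seed = 1L) {
  alleles <- c("A", "C", "G", "T")
  others <- setdiff(alleles, ref_base)
  withr::with_seed(seed, {
    errs <- rbinom(n_positions, coverage, error_rate)
    split1 <- rbinom(n_positions, errs, 1 / 3)
    split2 <- rbinom(n_positions, errs - split1, 1 / 2)
    cnt <- matrix(0L, nrow = n_positions, ncol = 4,
                  dimnames = list(NULL, alleles))
    cnt[, ref_base] <- coverage - errs
    cnt[, others[1]] <- split1
    cnt[, others[2]] <- split2
    cnt[, others[3]] <- errs - split1 - split2
    fwd <- matrix(rbinom(length(cnt), as.vector(cnt), 0.5),
                  nrow = n_positions, dimnames = dimnames(cnt))
    out <- tibble::tibble(pos = seq_len(n_positions))
    for (b in alleles) {
      out[[paste0(b, "_fwd")]] <- as.integer(fwd[, b])
      out[[paste0(b, "_rev")]] <- as.integer(cnt[, b] - fwd[, b])
    }
    out$del_fwd <- 0L
    out$del_rev <- 0L
    out$n <- as.integer(rowSums(cnt))
    out
  })
}
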