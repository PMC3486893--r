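#' Curate heteroplasmy candidates
#'
#' Applies the exclusion rules that separate plausible biological
#' heteroplasmy from PCR and alignment artifacts: a candidate is rejected
#' when (a) its position lies within a primer footprint (the primer base
#' accumulates in the PCR product and manufactures an artificial secondary
#' base; such sites remain reportable as plain variants), (b) either allele
#' is a deletion, or (c) the position sits at (or immediately beside) the
#' boundary of a homopolymer run of length `hp_min_run` or more, where
#' overcall/undercall errors pile up.
#'
#' @param candidates Candidate tibble from [call_secondary()].
#' @param ref A [circular_reference()].
#' @param amplicons Amplicon tibble (for primer footprints), or `NULL`.
#' @param hp_min_run Run length from which run-boundary candidates are
#'   excluded.
#' @return The candidate tibble with logical flags `in_primer`,
#'   `deletion_allele`, `hp_run_end`, plus `accepted` and `reason`.
#' @export
curate_candidates <- function(candidates, ref, amplicons = NULL,
                              hp_min_run = 4L) {
  n <- nrow(candidates)
  in_primer <- rep(FALSE, n)
  if (!is.null(amplicons) && n > 0) {
    L <- ref$length
    primer_pos <- unique(unlist(lapply(seq_len(nrow(amplicons)), function(i) {
      fp <- nchar(amplicons$fwd_primer[i])
      rp <- nchar(amplicons$rev_primer[i])
      s <- amplicons$start[i]; e <- amplicons$end[i]
      c(
        if (fp > 0) circular_positions(s, ((s - 1L + fp - 1L) %% L) + 1L, L),
        if (rp > 0) circular_positions((((e - rp) %% L)) + 1L, e, L)
      )
    })))
    in_primer <- candidates$pos %in% primer_pos
  }
  deletion_allele <- candidates$primary == "del" | candidates$secondary == "del"
  hp_run_end <- rep(FALSE, n)
  if (n > 0) {
    lens <- hp_run_lengths(ref)
    ids <- hp_run_ids(ref)
    L <- ref$length
    boundary <- integer(0)
    for (rid in unique(ids[lens >= hp_min_run])) {
      p <- which(ids == rid)
      nxt <- (p %% L) + 1L
      prv <- ((p - 2L) %% L) + 1L
      ends <- p[!(nxt %in% p)]
      starts <- p[!(prv %in% p)]
      if (length(ends) == 0) ends <- p      # run covers the whole circle
      boundary <- c(boundary, ends, starts,
                    (ends %% L) + 1L, ((starts - 2L) %% L) + 1L)
    }
    hp_run_end <- candidates$pos %in% unique(boundary)
  }
  reason <- dplyr::case_when(
    in_primer ~ "in_primer",
    deletion_allele ~ "deletion_allele",
    hp_run_end ~ "hp_run_end",
    TRUE ~ NA_character_
  )
  dplyr::mutate(
    candidates,
    in_primer = in_primer,
    deletion_allele = deletion_allele,
    hp_run_end = hp_run_end,
    accepted = is.na(reason),
    reason = reason
  )
}

#' Read-positional distribution of candidate alleles
#'
#' True heteroplasmic alleles should appear throughout reads; artifacts
#' cluster at the head or tail where base quality decays. For every
#' candidate, the read-relative coordinate (in each read's own sequencing
#' orientation) of the secondary allele is collected over its carrier
#' reads; the sample standard deviation of these coordinates and
#' head/middle/tail counts (thirds of each read's aligned length) are
#' recorded for both the primary (`c_*`) and secondary (`d_*`) alleles. A
#' candidate is flagged `suspicious` when every secondary occurrence falls
#' in the head third, or every one in the tail third; candidates whose
#' positional standard deviation reaches `sd_threshold` are additionally
#' flagged `sd_outlier`.
#'
#' @param candidates Curated candidate tibble.
#' @param alignments Single-hit alignment tibble for the sample.
#' @param ref A [circular_reference()].
#' @param sd_threshold Outlier threshold on the positional standard
#'   deviation.
#' @return The candidate tibble with columns `c_head`, `c_mid`, `c_tail`,
#'   `d_head`, `d_mid`, `d_tail`, `sd_read_pos`, `suspicious`,
#'   `sd_outlier`. `sd_read_pos` is `NA` with fewer than two carriers.
#' @export
positional_distribution <- function(candidates, alignments, ref,
                                    sd_threshold = 12) {
  L <- ref$length
  n <- nrow(candidates)
  cols <- c("c_head", "c_mid", "c_tail", "d_head", "d_mid", "d_tail")
  for (cn in cols) candidates[[cn]] <- 0L
  candidates$sd_read_pos <- NA_real_
  candidates$suspicious <- FALSE
  candidates$sd_outlier <- FALSE
  if (n == 0 || nrow(alignments) == 0) return(candidates)

  # expand alignments once into (pos, allele, seq-orientation coordinate)
  expanded <- lapply(seq_len(nrow(alignments)), function(i) {
    opsv <- strsplit(alignments$ops[i], "", fixed = TRUE)[[1]]
    refcons <- opsv != "I"
    readcons <- opsv != "D"
    rpos <- ((alignments$start[i] - 1L + cumsum(refcons) - 1L) %% L) + 1L
    qpos <- cumsum(readcons)
    chars <- strsplit(alignments$aln_seq[i], "", fixed = TRUE)[[1]]
    allele <- ifelse(opsv == "D", "del", chars[qpos])
    alen <- nchar(alignments$aln_seq[i])
    # coordinate within the aligned span, in sequencing orientation
    q_seq <- if (alignments$strand[i] == "rev") alen - qpos + 1L else qpos
    # coordinate within the full read, in sequencing orientation
    full <- alignments$read_offset[i] + qpos - 1L
    r_seq <- if (alignments$strand[i] == "rev") {
      alignments$read_len[i] - full + 1L
    } else full
    keep <- refcons
    tibble::tibble(
      pos = rpos[keep], allele = allele[keep],
      read_pos = r_seq[keep],
      third = pmin(3L, pmax(1L, ceiling(3 * q_seq[keep] / alen)))
    )
  })
  expanded <- dplyr::bind_rows(expanded)

  for (i in seq_len(n)) {
    at <- expanded[expanded$pos == candidates$pos[i], ]
    d <- at[at$allele == candidates$secondary[i], ]
    cc <- at[at$allele == candidates$primary[i], ]
    candidates$c_head[i] <- sum(cc$third == 1L)
    candidates$c_mid[i] <- sum(cc$third == 2L)
    candidates$c_tail[i] <- sum(cc$third == 3L)
    candidates$d_head[i] <- sum(d$third == 1L)
    candidates$d_mid[i] <- sum(d$third == 2L)
    candidates$d_tail[i] <- sum(d$third == 3L)
    if (nrow(d) >= 2) candidates$sd_read_pos[i] <- sd(d$read_pos)
    nd <- nrow(d)
    candidates$suspicious[i] <- nd > 0 &&
      (candidates$d_head[i] == nd || candidates$d_tail[i] == nd)
    candidates$sd_outlier[i] <- !is.na(candidates$sd_read_pos[i]) &&
      candidates$sd_read_pos[i] >= sd_threshold
  }
  candidates
}

#' Heteroplasmy level of a candidate
#'
#' @param candidate One or more candidate rows.
#' @return Level as a percentage (secondary count over total coverage),
#'   rounded to one decimal.
#' @export
estimate_level <- function(candidate) {
  round(100 * candidate$sec_count / candidate$n, 1)
}

#' Detect curated heteroplasmy in a filtered sample
#'
#' Convenience wrapper chaining pileup construction, genome calling,
#' secondary-candidate detection, curation and positional diagnostics.
#'
#' @param qc A `qc_result` from [qc_run_all()].
#' @param ref A [circular_reference()].
#' @param amplicons Amplicon tibble, or `NULL`.
#' @param params A [call_params()].
#' @return A list: `calls` (genome calls), `candidates` (curated, with
#'   positional statistics and `level_pct`).
#' @export
detect_heteroplasmy <- function(qc, ref, amplicons = NULL,
                                params = call_params()) {
  pile <- build_pileup(qc$alignments, ref)
  calls <- call_genome(pile, ref, params)
  hp <- hp_run_lengths(ref)
  cand <- call_secondary(pile, calls, hp, params)
  cand <- curate_candidates(cand, ref, amplicons)
  cand <- positional_distribution(cand, qc$alignments, ref)
  cand$level_pct <- estimate_level(cand)
  list(calls = calls, candidates = cand)
}

#' Evaluate heteroplasmy recovery on a mixture dilution series
#'
#' Runs the mapping pipeline (N and length filters, alignment, unique-
#' mapping filter, pileup, calling, secondary candidates, curation) on each
#' mixture and regresses the estimated level on the true mass fraction by
#' ordinary least squares. A mixture with no accepted candidate at the
#' known divergent site contributes an estimate of zero: the detection
#' floor of the thresholds is part of what is being measured.
#'
#' The clonal and identical-start/stop filters are deliberately not applied
#' here: every read of a fixed-endpoint amplicon mixture shares its
#' placement by construction, so those duplicate-removal filters, designed
#' for randomly fragmented shotgun reads, would collapse the data rather
#' than clean it.
#'
#' @param series A `mixture_series` from [simulate_mixture_series()].
#' @param align_par An [align_params()].
#' @param call_par A [call_params()].
#' @param min_len,max_len Read-length filter bounds.
#' @return An object of class `mixture_eval`: list with `results` (tibble
#'   `fraction`, `truth_pct`, `estimate_pct`, `detected`), `fit` (the `lm`
#'   object) and `r_squared`.
#' @export
evaluate_mixture_series <- function(series, align_par = align_params(),
                                    call_par = call_params(),
                                    min_len = 200L, max_len = 300L) {
  stopifnot(inherits(series, "mixture_series"))
  ref <- circular_reference(attr(series, "allele_a"), name = "allele_a")
  site <- attr(series, "site")
  hp <- hp_run_lengths(ref)

  estimates <- vapply(seq_len(nrow(series)), function(k) {
    reads <- series$reads[[k]]
    reads <- filter_n_and_trim_primers(reads, NULL)$kept
    reads <- filter_length(reads, min_len, max_len)$kept
    aln <- align_reads(reads, ref, align_par)
    aln <- filter_mapping(aln, reads$id)$kept
    pile <- build_pileup(aln, ref)
    calls <- call_genome(pile, ref, call_par)
    cand <- call_secondary(pile, calls, hp, call_par)
    cand <- curate_candidates(cand, ref, NULL)
    hit <- cand[cand$accepted & cand$pos == site$pos &
                  (cand$secondary == site$alt | cand$primary == site$alt), ]
    if (nrow(hit) == 0) {
      0
    } else if (hit$secondary[1] == site$alt) {
      estimate_level(hit[1, ])
    } else {
      # at mixtures near 50% the alternate allele can itself be modal;
      # the known divergent allele's level is then the primary's share
      round(100 * (hit$n[1] - hit$leftover[1]) / hit$n[1], 1)
    }
  }, 0)

  results <- tibble::tibble(
    fraction = series$fraction,
    truth_pct = 100 * series$fraction,
    estimate_pct = estimates,
    detected = estimates > 0
  )
  fit <- lm(estimate_pct ~ truth_pct, data = results)
  # computed directly so a perfect noiseless fit stays quiet
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((results$estimate_pct - mean(results$estimate_pct))^2)
  out <- list(
    results = results, fit = fit,
    r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  )
  class(out) <- "mixture_eval"
  out
}

#' @export
print.mixture_eval <- function(x, ...) {
  cat(sprintf("<mixture_eval> %d mixtures, R^2 = %.4f\n",
              nrow(x$results), x$r_squared))
  print(x$results)
  invisible(x)
}

#' Per-mixture estimates of a dilution-series evaluation
#'
#' @param x A `mixture_eval`.
#' @param ... Unused.
#' @return The per-mixture results tibble.
#' @export
tidy.mixture_eval <- function(x, ...) x$results

#' One-row summary of a dilution-series evaluation
#'
#' @param x A `mixture_eval`.
#' @param ... Unused.
#' @return A tibble with `r.squared`, regression slope and intercept, and
#'   the number of detected mixtures.
#' @export
glance.mixture_eval <- function(x, ...) {
  co <- coef(x$fit)
  tibble::tibble(
    r.squared = x$r_squared,
    intercept = unname(co[1]), slope = unname(co[2]),
    n_mixtures = nrow(x$results),
    n_detected = sum(x$results$detected)
  )
}

#' Plot estimated versus true mixture levels
#'
#' @param object A `mixture_eval`.
#' @param ... Unused.
#' @return A ggplot: estimates against truth with the identity line and
#'   the fitted regression.
#' @export
autoplot.mixture_eval <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$truth_pct, y = .data$estimate_pct)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue", linewidth = 0.6) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "true mixture level (%)", y = "estimated heteroplasmy level (%)",
      title = sprintf("Mixture series recovery (R² = %.3f)",
                      object$r_squared)
    ) +
    ggplot2::theme_minimal()
}
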