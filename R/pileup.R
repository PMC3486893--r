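PILEUP_ALLELES <- c("A", "C", "G", "T", "del")

pileup_count_cols <- function() {
  as.vector(t(outer(PILEUP_ALLELES, c("fwd", "rev"), paste, sep = "_")))
}

#' Base-calling parameters
#'
#' Thresholds of the quantitative base-calling model. A primary (consensus)
#' base is called when its fractional coverage `phi` is at least
#' `phi_primary`, it is seen on both strands (the operational reading of the
#' very wide strand-ratio bounds), and the homopolymer run containing the
#' position is no longer than `hp_max`. `phi` is taken over the
#' error-implausible coverage: non-modal alleles whose counts fall within
#' the Poisson error budget are treated as sequencing noise and excluded
#' from the denominator, so a balanced biallelic site is not silenced by a
#' handful of scattered errors. A secondary base becomes a
#' heteroplasmy candidate when its count exceeds the Poisson error threshold
#' at `confidence` (errors modelled per base at rate `lambda` over the
#' column's coverage), it holds at least `phi_secondary` of the leftover
#' (non-primary) coverage, its forward/reverse ratio lies within
#' `rho_secondary_bounds`, and the homopolymer condition holds.
#'
#' @param phi_primary Minimum fractional coverage of the modal allele.
#' @param hp_max Longest homopolymer run at which calls are still made.
#' @param lambda Assumed per-base substitution error rate (deliberately
#'   liberal relative to typical raw error rates, for conservative
#'   candidate calling).
#' @param phi_secondary Minimum fraction of leftover coverage held by the
#'   secondary allele.
#' @param rho_secondary_bounds Two-sided bounds on the secondary allele's
#'   forward/reverse count ratio.
#' @param confidence Poisson confidence level for the secondary threshold.
#' @param hp_end_z Force the 3'-terminal position of every reference run of
#'   length `hp_max + 1` or more to an uncalled `Z` (such positions carry an
#'   intrinsic base-calling ambiguity on this platform).
#' @return A list of class `call_params`.
#' @export
call_params <- function(phi_primary = 0.5, hp_max = 4L, lambda = 0.05,
                        phi_secondary = 0.8,
                        rho_secondary_bounds = c(1 / 12, 12),
                        confidence = 0.99, hp_end_z = TRUE) {
  stopifnot(phi_primary > 0, phi_primary <= 1, hp_max >= 1,
            lambda >= 0, lambda <= 1, phi_secondary > 0, phi_secondary <= 1,
            length(rho_secondary_bounds) == 2, all(rho_secondary_bounds > 0),
            confidence > 0, confidence < 1)
  structure(list(
    phi_primary = phi_primary, hp_max = as.integer(hp_max), lambda = lambda,
    phi_secondary = phi_secondary,
    rho_secondary_bounds = sort(rho_secondary_bounds),
    confidence = confidence, hp_end_z = isTRUE(hp_end_z)
  ), class = "call_params")
}

#' Build strand-resolved pileup columns from alignments
#'
#' Each aligned read contributes exactly one allele (a base or a deletion)
#' per reference position it spans. Insertions relative to the reference are
#' recorded in a side channel (attribute `insertions`), never as column
#' alleles: a mapping-based consensus cannot confidently place them.
#'
#' @param alignments Alignment tibble from [align_reads()], post-filter
#'   (single-hit reads only).
#' @param ref A [circular_reference()].
#' @return A wide tibble with one row per reference position `1..L`:
#'   `pos`, `<allele>_<strand>` counts for allele in A, C, G, T, del and
#'   strand in fwd, rev, and total coverage `n`. Attribute `insertions` is a
#'   tibble (`pos`, `strand`, `seq`) of read insertions anchored to the
#'   reference position preceding them.
#' @export
build_pileup <- function(alignments, ref) {
  L <- ref$length
  if (nrow(alignments) > 0 && any(alignments$n_hits > 1)) {
    stop("pileup expects uniquely mapped alignments; run the mapping filter first")
  }
  pos_list <- vector("list", nrow(alignments))
  allele_list <- vector("list", nrow(alignments))
  strand_vec <- character(nrow(alignments))
  ins_list <- vector("list", nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    opsv <- strsplit(alignments$ops[i], "", fixed = TRUE)[[1]]
    refcons <- opsv != "I"
    readcons <- opsv != "D"
    rpos_all <- ((alignments$start[i] - 1L + cumsum(refcons) - 1L) %% L) + 1L
    qpos <- cumsum(readcons)
    chars <- strsplit(alignments$aln_seq[i], "", fixed = TRUE)[[1]]
    allele <- ifelse(opsv == "D", "del", chars[qpos])
    pos_list[[i]] <- rpos_all[refcons]
    allele_list[[i]] <- allele[refcons]
    strand_vec[i] <- alignments$strand[i]
    if (any(!refcons)) {
      ins_idx <- which(!refcons)
      grp <- cumsum(c(TRUE, diff(ins_idx) != 1L))
      ins_list[[i]] <- tibble::tibble(
        pos = rpos_all[ins_idx][!duplicated(grp)],
        strand = alignments$strand[i],
        seq = vapply(split(allele[ins_idx], grp), paste, "", collapse = "")
      )
    }
  }
  pos <- unlist(pos_list, use.names = FALSE)
  allele <- unlist(allele_list, use.names = FALSE)
  strand <- rep(strand_vec, lengths(pos_list))
  out <- tibble::tibble(pos = seq_len(L))
  keep <- allele %in% PILEUP_ALLELES
  pos <- pos[keep]; allele <- allele[keep]; strand <- strand[keep]
  for (al in PILEUP_ALLELES) {
    for (st in c("fwd", "rev")) {
      sel <- allele == al & strand == st
      out[[paste0(al, "_", st)]] <-
        as.integer(tabulate(pos[sel], nbins = L))
    }
  }
  out$n <- as.integer(rowSums(out[, pileup_count_cols()]))
  attr(out, "insertions") <- dplyr::bind_rows(ins_list)
  out
}

# strand-resolved count matrices from a wide pileup tibble
pileup_matrices <- function(pileup) {
  fwd <- as.matrix(pileup[, paste0(PILEUP_ALLELES, "_fwd")])
  rev <- as.matrix(pileup[, paste0(PILEUP_ALLELES, "_rev")])
  colnames(fwd) <- colnames(rev) <- PILEUP_ALLELES
  list(fwd = fwd, rev = rev, tot = fwd + rev)
}

#' Poisson threshold for plausible secondary counts
#'
#' Smallest count `k*` such that the Poisson CDF with mean `lambda * N`
#' reaches `confidence`: secondary counts above `k*` are implausible as
#' accumulated substitution errors alone.
#'
#' @param N Column coverage (vectorised).
#' @param lambda Per-base substitution error rate.
#' @param confidence Confidence level.
#' @return Integer threshold(s) `k*`.
#' @export
poisson_secondary_threshold <- function(N, lambda = 0.05, confidence = 0.99) {
  stopifnot(all(N >= 0), lambda >= 0)
  as.integer(qpois(confidence, lambda * N))
}

# Vectorised primary calling over wide pileup rows.
# hp_len: per-row homopolymer run length of the reference position.
#
# phi is the modal allele's share of the error-implausible coverage: a
# non-modal allele whose count lies within the Poisson error budget k*(N)
# is sequencing noise, not a competing allele, and is excluded from the
# denominator. Wherever a competitor is real (count > k*), phi reduces to
# the plain modal/N; the correction only prevents scattered errors from
# knife-edging a balanced biallelic site just below the 0.5 majority line.
call_primary_rows <- function(pileup, hp_len, params) {
  m <- pileup_matrices(pileup)
  n <- pileup$n
  modal_idx <- max.col(m$tot, ties.method = "first")
  modal <- PILEUP_ALLELES[modal_idx]
  pick <- cbind(seq_len(nrow(pileup)), modal_idx)
  modal_cnt <- m$tot[pick]
  modal_fwd <- m$fwd[pick]
  modal_rev <- m$rev[pick]
  k_star <- poisson_secondary_threshold(n, params$lambda, params$confidence)
  real_mass <- rowSums(m$tot * (m$tot > k_star))
  nonmodal_real <- real_mass - ifelse(modal_cnt > k_star, modal_cnt, 0L)
  n_eff <- modal_cnt + pmax(nonmodal_real, 0L)
  phi <- ifelse(n > 0, modal_cnt / n_eff, NA_real_)
  rho <- ifelse(modal_rev > 0, modal_fwd / modal_rev, Inf)
  ok_cov <- n > 0
  ok_phi <- ok_cov & phi >= params$phi_primary
  ok_rho <- modal_fwd >= 1 & modal_rev >= 1
  ok_hp <- hp_len <= params$hp_max
  called <- ok_cov & ok_phi & ok_rho & ok_hp
  reasons <- character(nrow(pileup))
  reasons[!ok_cov] <- paste0(reasons[!ok_cov], "no_coverage;")
  reasons[ok_cov & !ok_phi] <- paste0(reasons[ok_cov & !ok_phi], "phi;")
  reasons[ok_cov & !ok_rho] <- paste0(reasons[ok_cov & !ok_rho], "rho;")
  reasons[!ok_hp] <- paste0(reasons[!ok_hp], "hp;")
  tibble::tibble(
    pos = pileup$pos,
    status = ifelse(called, "called", "Z"),
    allele = ifelse(called, modal, NA_character_),
    modal = modal, n = n,
    modal_count = modal_cnt, modal_fwd = modal_fwd, modal_rev = modal_rev,
    phi = phi, rho = rho, hp_len = hp_len,
    reasons = sub(";$", "", reasons)
  )
}

#' Primary calls for a set of pileup columns
#'
#' Vectorised form of [call_primary()] for arbitrary column sets (not
#' necessarily a full genome; no forced-Z rule is applied here).
#'
#' @param pileup Wide pileup tibble.
#' @param hp_len Per-row reference homopolymer run lengths (recycled).
#' @param params A [call_params()].
#' @return A tibble of per-column calls (see [call_primary()]).
#' @export
call_columns <- function(pileup, hp_len = 1L, params = call_params()) {
  call_primary_rows(pileup, rep_len(hp_len, nrow(pileup)), params)
}

#' Call the primary base for a single pileup column
#'
#' @param col A one-row wide pileup tibble (see [build_pileup()]).
#' @param hp_len Homopolymer run length of the reference at this position.
#' @param params A [call_params()].
#' @return A one-row tibble: `status` (`"called"` or `"Z"`), the called
#'   `allele`, the modal allele, `phi`, `rho`, counts, and failure
#'   `reasons` when uncalled.
#' @export
call_primary <- function(col, hp_len = 1L, params = call_params()) {
  stopifnot(nrow(col) == 1)
  call_primary_rows(col, hp_len, params)
}

# Vectorised secondary-candidate evaluation; primary must be called.
call_secondary_rows <- function(pileup, primary, hp_len, params) {
  m <- pileup_matrices(pileup)
  n <- pileup$n
  idx <- seq_len(nrow(pileup))
  modal_idx <- match(primary$modal, PILEUP_ALLELES)
  tot2 <- m$tot
  tot2[cbind(idx, modal_idx)] <- -1L
  sec_idx <- max.col(tot2, ties.method = "first")
  pick <- cbind(idx, sec_idx)
  sec_cnt <- m$tot[pick]
  sec_fwd <- m$fwd[pick]
  sec_rev <- m$rev[pick]
  leftover <- n - primary$modal_count
  k_star <- poisson_secondary_threshold(n, params$lambda, params$confidence)
  phi_sec <- ifelse(leftover > 0, sec_cnt / leftover, 0)
  rho_sec <- ifelse(sec_rev > 0, sec_fwd / sec_rev, Inf)
  ok <- primary$status == "called" &
    sec_cnt > k_star &
    phi_sec >= params$phi_secondary &
    rho_sec >= params$rho_secondary_bounds[1] &
    rho_sec <= params$rho_secondary_bounds[2] &
    hp_len <= params$hp_max
  tibble::tibble(
    pos = pileup$pos,
    primary = primary$modal,
    secondary = PILEUP_ALLELES[sec_idx],
    n = n, sec_count = sec_cnt, sec_fwd = sec_fwd, sec_rev = sec_rev,
    leftover = leftover, phi_sec = phi_sec, rho_sec = rho_sec,
    k_star = k_star, hp_len = hp_len,
    level = ifelse(n > 0, sec_cnt / n, NA_real_)
  )[ok, ]
}

#' Secondary-base (heteroplasmy) candidates from a pileup
#'
#' Evaluates the most frequent non-primary allele of every column whose
#' primary base was called, against the Poisson error threshold, the
#' leftover-coverage fraction, the strand-ratio bounds and the homopolymer
#' condition.
#'
#' @param pileup Wide pileup tibble.
#' @param primary Primary calls for the same rows (from
#'   [call_genome()] or [call_primary()]).
#' @param hp_len Per-row reference homopolymer run lengths.
#' @param params A [call_params()].
#' @return A tibble of candidate rows (zero rows when none qualify) with
#'   the secondary allele, its counts, `phi_sec`, `rho_sec`, the threshold
#'   `k_star` and the raw `level` (secondary count over total coverage).
#' @export
call_secondary <- function(pileup, primary, hp_len, params = call_params()) {
  call_secondary_rows(pileup, primary, hp_len, params)
}

# 3'-terminal position (L-strand orientation) of every circular run of
# length >= min_len
hp_run_end_positions <- function(ref, min_len = 5L) {
  lens <- hp_run_lengths(ref)
  ids <- hp_run_ids(ref)
  L <- ref$length
  ends <- integer(0)
  for (rid in unique(ids[lens >= min_len])) {
    in_run <- ids == rid
    p <- which(in_run & !in_run[(seq_len(L) %% L) + 1L])
    ends <- c(ends, p)
  }
  sort(ends)
}

#' Call a consensus genome from a pileup
#'
#' Applies the primary-call thresholds position by position over the whole
#' circle. Positions failing any threshold are reported as `Z`; in
#' addition, when `params$hp_end_z` is set, the 3'-terminal position of
#' every reference homopolymer run longer than `hp_max` is forced to `Z`.
#'
#' @param pileup Wide pileup tibble covering positions `1..L`.
#' @param ref A [circular_reference()].
#' @param params A [call_params()].
#' @return A tibble of class `genome_calls` (one row per position, as
#'   [call_primary()]), with attributes `consensus` (consensus string over
#'   `{A,C,G,T,Z}` with called deletions excised) and `ref_name`.
#' @export
call_genome <- function(pileup, ref, params = call_params()) {
  stopifnot(nrow(pileup) == ref$length)
  hp <- hp_run_lengths(ref)
  calls <- call_primary_rows(pileup, hp, params)
  calls$ref_base <- strsplit(ref$seq, "", fixed = TRUE)[[1]]
  if (params$hp_end_z) {
    forced <- hp_run_end_positions(ref, params$hp_max + 1L)
    if (length(forced)) {
      hit <- calls$pos %in% forced
      calls$status[hit] <- "Z"
      calls$allele[hit] <- NA_character_
      calls$reasons[hit] <- ifelse(
        nzchar(calls$reasons[hit]),
        paste0(calls$reasons[hit], ";hp_run_end"), "hp_run_end"
      )
    }
  }
  cons <- ifelse(calls$status == "called", calls$allele, "Z")
  consensus <- paste(cons[cons != "del"], collapse = "")
  attr(calls, "consensus") <- consensus
  attr(calls, "ref_name") <- ref$name
  class(calls) <- c("genome_calls", class(calls))
  calls
}

#' Non-modal base frequency of a pileup column
#'
#' Fraction of the column's bases that disagree with the modal allele
#' (ties broken by the fixed allele order A, C, G, T, del).
#'
#' @param col A one-row wide pileup tibble with `n > 0`.
#' @return `(N - modal count) / N`.
#' @export
nonmodal_frequency <- function(col) {
  stopifnot(nrow(col) == 1)
  if (col$n == 0) stop("column has no coverage")
  m <- pileup_matrices(col)
  (col$n - max(m$tot)) / col$n
}
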