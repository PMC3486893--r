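KASM_BASES <- c("A", "C", "G", "T")

#' Build an n-mer multiplicity database from reads
#'
#' Slides a window of `n` bases along every read, one base at a time, and
#' counts the occurrences (multiplicity `m`) of each distinct n-mer across
#' the whole read set. Windows containing `N` are skipped. `n` must be odd
#' so that every position has a centred n-mer with `(n - 1) / 2` flanks.
#'
#' @param reads Tibble with columns `id`, `bases`.
#' @param n Window length (odd, at least 3; default 27 balances uniqueness
#'   within a mitochondrial-sized genome against the chance of containing a
#'   sequencing error).
#' @return An object of class `kmer_db`: `n`, a hashed environment mapping
#'   n-mer to multiplicity, and `total` (the sum of multiplicities).
#' @export
build_kmer_db <- function(reads, n = 27L) {
  n <- as.integer(n)
  if (n < 3L) stop("n must be at least 3")
  if (n %% 2L == 0L) stop("n must be odd (a centred n-mer needs equal flanks)")
  all_kmers <- lapply(reads$bases, function(b) {
    L <- nchar(b)
    if (L < n) return(character(0))
    substring(b, 1:(L - n + 1L), n:L)
  })
  all_kmers <- unlist(all_kmers, use.names = FALSE)
  if (length(all_kmers)) {
    all_kmers <- all_kmers[!grepl("N", all_kmers, fixed = TRUE)]
  }
  env <- new.env(hash = TRUE, parent = emptyenv())
  if (length(all_kmers)) {
    tab <- table(all_kmers)
    list2env(as.list(as.integer(tab)) |>
               stats::setNames(names(tab)), envir = env)
  }
  structure(
    list(n = n, env = env, total = length(all_kmers)),
    class = "kmer_db"
  )
}

#' @export
print.kmer_db <- function(x, ...) {
  cat(sprintf("<kmer_db> n = %d, %d distinct n-mers, total multiplicity %d\n",
              x$n, length(ls(x$env)), x$total))
  invisible(x)
}

#' Multiplicity lookup
#'
#' @param db A [build_kmer_db()] database.
#' @param kmers Character vector of n-mers.
#' @return Integer multiplicities (0 for absent n-mers).
#' @export
kmer_mult <- function(db, kmers) {
  as.integer(unlist(
    mget(kmers, envir = db$env, ifnotfound = list(0L)),
    use.names = FALSE
  ))
}

#' Probability that an n-mer is error free
#'
#' Under uncorrelated per-base errors at rate `lambda`, an n-base window is
#' error free with probability `(1 - lambda)^n`; when most windows are
#' error free, majority-wins selection over n-mer multiplicities is sound.
#'
#' @param lambda Per-base error rate in `[0, 1]`.
#' @param n Window length.
#' @return `(1 - lambda)^n`.
#' @export
error_free_prob <- function(lambda, n) {
  stopifnot(lambda >= 0, lambda <= 1, n >= 1)
  (1 - lambda)^n
}

#' Validate the assumptions behind n-mer assembly
#'
#' The greedy majority-wins assembler assumes the genome contains no
#' duplicated n-mers and no palindromic n-mers (an L-strand n-mer whose
#' reverse complement also occurs). Checks a known genome and warns on
#' violations; assembly of a violating genome may stall or mis-resolve.
#'
#' @param genome_seq Circular genome sequence (string).
#' @param n Window length.
#' @return Invisibly, a tibble of checks with `ok` flags.
#' @export
check_assembly_assumptions <- function(genome_seq, n = 27L) {
  L <- nchar(genome_seq)
  doubled <- paste0(genome_seq, substr(genome_seq, 1, n - 1))
  kmers <- substring(doubled, 1:L, 1:L + n - 1L)
  dup <- anyDuplicated(kmers) > 0
  pal <- any(revcomp(kmers) %in% kmers)
  if (dup) warning("genome contains duplicated ", n, "-mers; assembly may stall or mis-resolve")
  if (pal) warning("genome contains palindromic ", n, "-mers; strand-summed multiplicities may mix loci")
  invisible(tibble::tibble(
    check = c("no_duplicate_nmers", "no_palindromic_nmers"),
    ok = c(!dup, !pal)
  ))
}

#' Find a usable assembly seed along a reference
#'
#' Probes successive reference positions (starting at position 1) until the
#' centred start condition holds: the n-mer at the position and its reverse
#' complement both have multiplicity above `min_start_m`. Local coverage
#' dips — amplicon boundaries, strand imbalance — make position 1 itself
#' occasionally unusable.
#'
#' @param db A [build_kmer_db()] database.
#' @param ref A [circular_reference()].
#' @param min_start_m Strict lower bound on each strand's multiplicity.
#' @return The first qualifying n-mer (a string).
#' @export
find_start_nmer <- function(db, ref, min_start_m = 10L) {
  n <- db$n
  doubled <- paste0(ref$seq, substr(ref$seq, 1, n - 1))
  for (p in seq_len(ref$length)) {
    km <- substr(doubled, p, p + n - 1L)
    if (kmer_mult(db, km) > min_start_m &&
          kmer_mult(db, revcomp(km)) > min_start_m) {
      return(km)
    }
  }
  stop("no reference position satisfies the assembly start condition")
}

#' Assemble a circular genome from an n-mer database
#'
#' Greedy majority-wins extension: starting from a seed n-mer whose forward
#' and reverse-complement multiplicities both exceed `min_start_m`, the
#' four candidate successor n-mers (drop the first base, append A, C, G or
#' T — or symmetrically prepend, in the retrograde direction) are scored by
#' the sum of their forward and reverse-complement multiplicities, and the
#' most abundant wins. Extension stops when the start n-mer recurs (the
#' genome is circular) and fails on a coverage gap (all four candidates
#' absent) or when no recurrence happens within a safety bound of four
#' times the expected genome length. Ties between candidates are recorded
#' as ambiguity events and broken toward the alphabetically smallest base,
#' so assembly is deterministic and auditable.
#'
#' Per-position consensus coverage is the summed two-strand multiplicity of
#' the n-mer centred on the position.
#'
#' @param db A [build_kmer_db()] database.
#' @param start_nmer Seed n-mer (for resequencing, the reference's first
#'   `n` bases; reference-free, pick a high-multiplicity n-mer).
#' @param direction `"antegrade"` (extend with increasing position) or
#'   `"retrograde"`.
#' @param min_start_m Strict lower bound each strand's start multiplicity
#'   must exceed.
#' @param max_steps Safety bound on extension steps; defaults to four times
#'   the distinct n-mer count.
#' @return An object of class `assembly_result`: `seq`, `coverage` (integer
#'   per position), `direction`, `status` (`"complete"`, `"gap"` or
#'   `"non_circular"`), `fail_pos`, `ambiguities` tibble, `n`.
#' @export
assemble_genome <- function(db, start_nmer,
                            direction = c("antegrade", "retrograde"),
                            min_start_m = 10L, max_steps = NULL) {
  direction <- match.arg(direction)
  n <- db$n
  start_nmer <- toupper(start_nmer)
  if (nchar(start_nmer) != n) stop("start_nmer must have length n = ", n)
  m_f <- kmer_mult(db, start_nmer)
  m_r <- kmer_mult(db, revcomp(start_nmer))
  if (m_f <= min_start_m || m_r <= min_start_m) {
    stop(sprintf(
      "start n-mer multiplicity must exceed %d on both strands (got %d / %d); probe successive positions for a better seed",
      min_start_m, m_f, m_r
    ))
  }
  if (is.null(max_steps)) max_steps <- 4L * max(length(ls(db$env)), n)

  added <- character(max_steps)
  n_added <- 0L
  cur <- start_nmer
  status <- "non_circular"
  fail_pos <- NA_integer_
  amb <- list()

  repeat {
    if (n_added >= max_steps) break
    if (direction == "antegrade") {
      stem <- substr(cur, 2L, n)
      cands <- paste0(stem, KASM_BASES)
    } else {
      stem <- substr(cur, 1L, n - 1L)
      cands <- paste0(KASM_BASES, stem)
    }
    mult <- kmer_mult(db, cands) + kmer_mult(db, revcomp(cands))
    top <- max(mult)
    if (top == 0L) {
      status <- "gap"
      fail_pos <- n + n_added + 1L
      break
    }
    pick <- which(mult == top)[1L]
    if (sum(mult == top) > 1L) {
      amb[[length(amb) + 1L]] <- tibble::tibble(
        step = n_added + 1L,
        bases = paste(KASM_BASES[mult == top], collapse = "/"),
        multiplicity = top
      )
    }
    n_added <- n_added + 1L
    added[n_added] <- KASM_BASES[pick]
    cur <- cands[pick]
    if (cur == start_nmer) {
      status <- "complete"
      break
    }
  }

  if (status != "complete") {
    out <- list(seq = NA_character_, coverage = integer(0),
                direction = direction, status = status, fail_pos = fail_pos,
                ambiguities = dplyr::bind_rows(amb), n = n)
    class(out) <- "assembly_result"
    return(out)
  }

  added <- added[seq_len(n_added)]
  full <- if (direction == "antegrade") {
    paste0(start_nmer, paste(added, collapse = ""))
  } else {
    paste0(paste(rev(added), collapse = ""), start_nmer)
  }
  genome <- substr(full, 1L, nchar(full) - n)
  out <- list(
    seq = genome,
    coverage = assembly_coverage(db, genome),
    direction = direction, status = "complete", fail_pos = NA_integer_,
    ambiguities = dplyr::bind_rows(amb), n = n
  )
  class(out) <- "assembly_result"
  out
}

# two-strand multiplicity of the centred n-mer at every position
assembly_coverage <- function(db, genome) {
  n <- db$n
  L <- nchar(genome)
  flank <- (n - 1L) %/% 2L
  doubled <- paste0(genome, genome)
  starts <- ((seq_len(L) - flank - 1L) %% L) + 1L
  kmers <- substring(doubled, starts, starts + n - 1L)
  kmer_mult(db, kmers) + kmer_mult(db, revcomp(kmers))
}

#' @export
print.assembly_result <- function(x, ...) {
  if (x$status == "complete") {
    cat(sprintf("<assembly_result> %s: %d bp circular, median coverage %d, %d ambiguity event(s)\n",
                x$direction, nchar(x$seq),
                as.integer(stats::median(x$coverage)), nrow(x$ambiguities)))
  } else {
    cat(sprintf("<assembly_result> %s: FAILED (%s at position %s)\n",
                x$direction, x$status, x$fail_pos))
  }
  invisible(x)
}

#' One-row summary of an assembly
#'
#' @param x An `assembly_result`.
#' @param ... Unused.
#' @return Tibble with status, length, coverage summary and ambiguity count.
#' @export
glance.assembly_result <- function(x, ...) {
  tibble::tibble(
    direction = x$direction, status = x$status,
    length = if (x$status == "complete") nchar(x$seq) else NA_integer_,
    median_coverage = if (x$status == "complete")
      stats::median(x$coverage) else NA_real_,
    n_ambiguities = nrow(x$ambiguities)
  )
}

#' Canonical rotation of a circular sequence
#'
#' The lexicographically minimal rotation; two circular sequences are
#' rotation-identical iff their canonical rotations are equal.
#'
#' @param seq Sequence string.
#' @return The canonical rotation.
#' @export
canonical_rotation <- function(seq) {
  L <- nchar(seq)
  doubled <- paste0(seq, seq)
  min(substring(doubled, 1:L, 1:L + L - 1L))
}

#' Compare antegrade and retrograde assemblies and resolve discrepancies
#'
#' Both assemblies are built from the same seed so they share a coordinate
#' frame. At each discrepancy block, each assembly's variant is supported
#' by the n-mer centred on the block in that assembly's own sequence:
#' a variant qualifies when that n-mer has multiplicity above zero on both
#' strands, and among qualifying variants the higher summed multiplicity
#' wins. Discrepancy blocks other than a substitution or a single-base
#' length difference (the homopolymer-length signature) are flagged
#' unresolved and the antegrade variant is retained.
#'
#' @param ante,retro Completed `assembly_result`s (same seed).
#' @param db The [build_kmer_db()] database both were assembled from.
#' @return A list: `consensus` (an `assembly_result`, direction
#'   `"consensus"`) and `discrepancies` (tibble with one row per block:
#'   position, both variants, supports, winner, `resolved`).
#' @export
compare_and_resolve <- function(ante, retro, db) {
  stopifnot(inherits(ante, "assembly_result"), inherits(retro, "assembly_result"))
  if (ante$status != "complete" || retro$status != "complete") {
    stop("both assemblies must be complete")
  }
  if (ante$seq == retro$seq) {
    cons <- ante
    cons$direction <- "consensus"
    return(list(consensus = cons, discrepancies = empty_discrepancies()))
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(retro$seq), Biostrings::DNAString(ante$seq),
    type = "global", gapOpening = 4, gapExtension = 1
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ncol_aln <- length(p)
  a_pos <- cumsum(s != "-")  # antegrade coordinate per column
  r_pos <- cumsum(p != "-")
  diffc <- p != s
  if (!any(diffc)) {
    cons <- ante
    cons$direction <- "consensus"
    return(list(consensus = cons, discrepancies = empty_discrepancies()))
  }
  blk <- cumsum(c(TRUE, diff(which(diffc)) != 1L))
  blocks <- split(which(diffc), blk)

  n <- db$n
  flank <- (n - 1L) %/% 2L
  centred <- function(seq, pos) {
    L <- nchar(seq)
    start <- ((pos - flank - 1L) %% L) + 1L
    paste0(substring(paste0(seq, seq), start, start + n - 1L))
  }
  support <- function(seq, pos) {
    km <- centred(seq, pos)
    c(fwd = kmer_mult(db, km), rev = kmer_mult(db, revcomp(km)))
  }

  rows <- list()
  winners <- character(length(blocks))
  for (bi in seq_along(blocks)) {
    cols <- blocks[[bi]]
    a_var <- paste(s[cols][s[cols] != "-"], collapse = "")
    r_var <- paste(p[cols][p[cols] != "-"], collapse = "")
    a_mid <- a_pos[cols[ceiling(length(cols) / 2)]]
    r_mid <- r_pos[cols[ceiling(length(cols) / 2)]]
    type <- if (nchar(a_var) == 1 && nchar(r_var) == 1) {
      "substitution"
    } else if (abs(nchar(a_var) - nchar(r_var)) == 1) {
      "hp_length"
    } else "complex"
    sup_a <- support(ante$seq, max(1L, a_mid))
    sup_r <- support(retro$seq, max(1L, r_mid))
    qa <- all(sup_a > 0); qr <- all(sup_r > 0)
    winner <- if (type == "complex") {
      "unresolved"
    } else if (qa && !qr) "antegrade"
    else if (qr && !qa) "retrograde"
    else if (qa && qr) {
      if (sum(sup_r) > sum(sup_a)) "retrograde" else "antegrade"
    } else "unresolved"
    winners[bi] <- winner
    rows[[bi]] <- tibble::tibble(
      block = bi, ante_pos = a_mid, type = type,
      ante_variant = a_var, retro_variant = r_var,
      ante_support = sum(sup_a), retro_support = sum(sup_r),
      ante_both_strands = qa, retro_both_strands = qr,
      winner = winner, resolved = winner != "unresolved"
    )
  }

  # splice winners into a consensus along the alignment columns
  take_retro <- winners == "retrograde"
  out_chars <- character(ncol_aln)
  for (j in seq_len(ncol_aln)) {
    if (!diffc[j]) {
      out_chars[j] <- s[j]
    } else {
      bi <- blk[match(j, which(diffc))]
      out_chars[j] <- if (take_retro[bi]) p[j] else s[j]
    }
  }
  cons_seq <- paste(out_chars[out_chars != "-"], collapse = "")
  cons <- list(
    seq = cons_seq,
    coverage = assembly_coverage(db, cons_seq),
    direction = "consensus", status = "complete", fail_pos = NA_integer_,
    ambiguities = dplyr::bind_rows(ante$ambiguities, retro$ambiguities),
    n = db$n
  )
  class(cons) <- "assembly_result"
  list(consensus = cons, discrepancies = dplyr::bind_rows(rows))
}

empty_discrepancies <- function() {
  tibble::tibble(
    block = integer(), ante_pos = integer(), type = character(),
    ante_variant = character(), retro_variant = character(),
    ante_support = integer(), retro_support = integer(),
    ante_both_strands = logical(), retro_both_strands = logical(),
    winner = character(), resolved = logical()
  )
}

#' Assembly-based substitution-heteroplasmy scan
#'
#' At every consensus position the central base of the centred n-mer is
#' replaced by each of the other three bases; the two-strand multiplicity
#' of the altered n-mer measures support for the alternative allele, and
#' the fraction `m_alt / (m_alt + m_ref)` estimates its level. Candidates
#' at or above the reporting floor are returned.
#'
#' @param assembly A completed `assembly_result`.
#' @param db The [build_kmer_db()] database.
#' @param floor Minimum reported fraction.
#' @return A tibble: `pos`, `ref_base`, `alt_base`, `m_ref`, `m_alt`,
#'   `fraction`.
#' @export
scan_substitution_heteroplasmy <- function(assembly, db, floor = 0.05) {
  stopifnot(inherits(assembly, "assembly_result"),
            assembly$status == "complete")
  n <- db$n
  flank <- (n - 1L) %/% 2L
  genome <- assembly$seq
  L <- nchar(genome)
  doubled <- paste0(genome, genome)
  starts <- ((seq_len(L) - flank - 1L) %% L) + 1L
  ref_kmers <- substring(doubled, starts, starts + n - 1L)
  m_ref <- kmer_mult(db, ref_kmers) + kmer_mult(db, revcomp(ref_kmers))
  ref_base <- substring(genome, seq_len(L), seq_len(L))
  rows <- list()
  for (b in KASM_BASES) {
    idx <- which(ref_base != b)
    if (!length(idx)) next
    alt_kmers <- ref_kmers[idx]
    substr(alt_kmers, flank + 1L, flank + 1L) <- b
    m_alt <- kmer_mult(db, alt_kmers) + kmer_mult(db, revcomp(alt_kmers))
    frac <- ifelse(m_alt + m_ref[idx] > 0, m_alt / (m_alt + m_ref[idx]), 0)
    keep <- frac >= floor & m_alt > 0
    if (any(keep)) {
      rows[[b]] <- tibble::tibble(
        pos = idx[keep], ref_base = ref_base[idx][keep], alt_base = b,
        m_ref = m_ref[idx][keep], m_alt = m_alt[keep],
        fraction = frac[keep]
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) out <- dplyr::arrange(out, .data$pos, .data$alt_base)
  out
}

#' Histogram of n-mer multiplicities
#'
#' The multiplicity distribution is diagnostic: a mass at `m = 1` collects
#' n-mers carrying sequencing errors, the main mode sits near the per-
#' position n-mer coverage, and a high tail marks amplicon-overlap regions.
#'
#' @param db A [build_kmer_db()] database.
#' @return A tibble: `m`, `n_kmers`.
#' @export
multiplicity_histogram <- function(db) {
  vals <- as.integer(unlist(as.list(db$env), use.names = FALSE))
  if (!length(vals)) return(tibble::tibble(m = integer(), n_kmers = integer()))
  tab <- table(vals)
  tibble::tibble(m = as.integer(names(tab)), n_kmers = as.integer(tab))
}

#' Plot the n-mer multiplicity spectrum
#'
#' @param object A `kmer_db`.
#' @param ... Unused.
#' @return A ggplot of n-mer counts per multiplicity.
#' @export
autoplot.kmer_db <- function(object, ...) {
  h <- multiplicity_histogram(object)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$m, y = .data$n_kmers)) +
    ggplot2::geom_col(width = 0.9, fill = "steelblue") +
    ggplot2::labs(x = "multiplicity m", y = "distinct n-mers",
                  title = sprintf("%d-mer multiplicity spectrum", object$n)) +
    ggplot2::theme_minimal()
}
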