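# Fixture builders shared across the suite. Everything is generated in code
# under fixed seeds; no stored data files.

BASES <- c("A", "C", "G", "T")

random_genome <- function(L, seed) {
  withr::with_seed(seed, paste(sample(BASES, L, TRUE), collapse = ""))
}

random_ref <- function(L, seed, name = "toy") {
  circular_reference(random_genome(L, seed), name = name)
}

# Two equal-length amplicon alleles differing at exactly one isolated
# (homopolymer length 1) mid-sequence position.
allele_pair <- function(len = 285L, seed = 9L) {
  withr::with_seed(seed, {
    ca <- sample(BASES, len, TRUE)
    pos <- floor(len / 2)
    while (ca[pos - 1] == ca[pos] || ca[pos + 1] == ca[pos]) pos <- pos + 1L
    cb <- ca
    cb[pos] <- setdiff(BASES, ca[pos])[1]
    list(
      a = paste(ca, collapse = ""), b = paste(cb, collapse = ""),
      pos = pos, ref = ca[pos], alt = cb[pos]
    )
  })
}

# Error-free tiling reads over a circular genome, alternating strands so
# both orientations carry multiplicity.
tiling_reads <- function(genome, read_len = 60L, step = 1L) {
  L <- nchar(genome)
  doubled <- paste0(genome, genome)
  starts <- seq(1L, L, by = step)
  bases <- substring(doubled, starts, starts + read_len - 1L)
  rev <- seq_along(bases) %% 2L == 0L
  bases[rev] <- revcomp(bases[rev])
  tibble::tibble(id = sprintf("tile%05d", seq_along(starts)), bases = bases)
}

# A one-row wide pileup column from named counts, e.g.
# pileup_col(A_fwd = 40, A_rev = 30, G_fwd = 25, G_rev = 25)
pileup_col <- function(pos = 1L, ...) {
  counts <- list(...)
  col <- tibble::tibble(pos = pos)
  for (al in c("A", "C", "G", "T", "del")) {
    for (st in c("fwd", "rev")) {
      nm <- paste0(al, "_", st)
      col[[nm]] <- if (nm %in% names(counts)) as.integer(counts[[nm]]) else 0L
    }
  }
  col$n <- as.integer(sum(unlist(counts)))
  col
}
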