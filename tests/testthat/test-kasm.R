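test_that("the n-mer database counts sliding windows exactly", {
  r30 <- tibble::tibble(id = "a", bases = random_genome(30, seed = 130))
  db <- build_kmer_db(r30, n = 27)
  expect_equal(db$total, 4L)  # 30 - 27 + 1
  expect_equal(length(ls(db$env)), 4L)

  short <- tibble::tibble(id = "s", bases = random_genome(20, seed = 131))
  expect_equal(build_kmer_db(short, n = 27)$total, 0L)

  twice <- tibble::tibble(id = c("a", "b"),
                          bases = rep(random_genome(40, seed = 132), 2))
  db2 <- build_kmer_db(twice, n = 27)
  expect_true(all(kmer_mult(db2, ls(db2$env)) == 2L))

  # N-containing windows are skipped
  withN <- tibble::tibble(id = "n", bases = paste0(
    random_genome(27, seed = 133), "N", random_genome(27, seed = 134)))
  expect_equal(build_kmer_db(withN, n = 27)$total, 2L)

  expect_error(build_kmer_db(r30, n = 26), "odd")
  expect_error(build_kmer_db(r30, n = 1), "at least 3")
})

test_that("error-free n-mer probability follows (1 - lambda)^n", {
  expect_equal(round(error_free_prob(0.005, 27), 2), 0.87)
  expect_equal(error_free_prob(0, 12), 1)
  expect_equal(error_free_prob(0.005, 54), error_free_prob(0.005, 27)^2)
})

test_that("antegrade and retrograde assemblies reproduce a toy circle", {
  genome <- random_genome(600, seed = 140)
  expect_silent(check_assembly_assumptions(genome, 27))
  reads <- tiling_reads(genome, read_len = 60L, step = 1L)
  db <- build_kmer_db(reads, n = 27)
  start <- substr(genome, 1, 27)
  ante <- assemble_genome(db, start, "antegrade")
  retro <- assemble_genome(db, start, "retrograde")
  expect_equal(ante$status, "complete")
  expect_equal(retro$status, "complete")
  expect_equal(ante$seq, genome)
  expect_equal(retro$seq, genome)
  expect_equal(canonical_rotation(ante$seq), canonical_rotation(genome))
  expect_equal(length(ante$coverage), 600L)

  # consensus coverage oracle: brute-force count of reads containing the
  # full centred n-mer span
  flank <- 13L
  L <- 600L
  for (p in c(1L, 17L, 300L, 600L)) {
    span <- ((p - flank - 1L + 0:26) %% L) + 1L
    covered <- vapply(seq_len(nrow(reads)), function(i) {
      s <- ((i - 1L) %% L) + 1L      # tiling start of read i (step 1)
      read_span <- ((s - 1L + 0:59) %% L) + 1L
      all(span %in% read_span)
    }, TRUE)
    expect_equal(ante$coverage[p], sum(covered))
  }
})

test_that("assembly fails cleanly at a coverage gap", {
  genome <- random_genome(600, seed = 141)
  half <- tiling_reads(genome, read_len = 60L, step = 1L)
  # keep only reads starting in the first half of the circle
  half <- half[1:250, ]
  db <- build_kmer_db(half, n = 27)
  # seed from the well-covered interior of the half-circle
  res <- assemble_genome(db, substr(genome, 101, 127), "antegrade")
  expect_equal(res$status, "gap")
  expect_true(is.finite(res$fail_pos))
  expect_true(is.na(res$seq))
})

test_that("assembly start condition requires both-strand multiplicity", {
  genome <- random_genome(400, seed = 142)
  fwd_only <- tibble::tibble(
    id = sprintf("f%03d", 1:400),
    bases = substring(paste0(genome, genome), 1:400, 1:400 + 59)
  )
  db <- build_kmer_db(fwd_only, n = 27)
  expect_error(assemble_genome(db, substr(genome, 1, 27)), "both strands")
  expect_error(find_start_nmer(db, circular_reference(genome)),
               "start condition")
})

test_that("seed probing walks past a thinly covered reference start", {
  genome <- random_genome(500, seed = 151)
  reads <- tiling_reads(genome, read_len = 60L, step = 1L)
  # depress (but do not zero) coverage around the origin: keep only every
  # eighth read covering position 1, so the start condition fails there
  # while every n-mer keeps some support
  covering <- vapply(seq_len(nrow(reads)), function(i) {
    s <- ((i - 1L) %% 500L) + 1L
    span <- ((s - 1L + 0:59) %% 500L) + 1L
    1L %in% span
  }, TRUE)
  idx <- which(covering)
  drop <- idx[-seq(1, length(idx), by = 8)]
  db <- build_kmer_db(reads[-drop, ], n = 27)
  m1 <- kmer_mult(db, substr(genome, 1, 27))
  expect_lte(m1, 10)
  start <- find_start_nmer(db, circular_reference(genome))
  asm <- assemble_genome(db, start, "antegrade")
  expect_equal(asm$status, "complete")
  expect_equal(canonical_rotation(asm$seq), canonical_rotation(genome))
})

test_that("a minority haplotype neither derails assembly nor escapes the scan", {
  genome <- random_genome(600, seed = 143)
  pos <- 300L
  while (substr(genome, pos - 1, pos - 1) == substr(genome, pos, pos) ||
           substr(genome, pos + 1, pos + 1) == substr(genome, pos, pos)) {
    pos <- pos + 1L
  }
  alt_genome <- genome
  substr(alt_genome, pos, pos) <-
    setdiff(BASES, substr(genome, pos, pos))[1]
  major <- tiling_reads(genome, read_len = 60L, step = 1L)
  minor <- tiling_reads(alt_genome, read_len = 60L, step = 4L)  # ~20% depth
  minor$id <- paste0("alt_", minor$id)
  db <- build_kmer_db(dplyr::bind_rows(major, minor), n = 27)
  asm <- assemble_genome(db, substr(genome, 1, 27), "antegrade")
  expect_equal(asm$status, "complete")
  expect_equal(asm$seq, genome)  # majority wins at the divergent site

  scan <- scan_substitution_heteroplasmy(asm, db, floor = 0.05)
  hit <- scan[scan$pos == pos, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$alt_base, substr(alt_genome, pos, pos))
  expect_lt(abs(hit$fraction - 0.2), 0.05)

  # an error-free single-haplotype database yields no candidates
  db1 <- build_kmer_db(major, n = 27)
  asm1 <- assemble_genome(db1, substr(genome, 1, 27), "antegrade")
  expect_equal(nrow(scan_substitution_heteroplasmy(asm1, db1, 0.05)), 0L)
})

test_that("identical assemblies compare clean; discrepancies resolve by support", {
  genome <- random_genome(600, seed = 144)
  reads <- tiling_reads(genome, read_len = 60L, step = 1L)
  db <- build_kmer_db(reads, n = 27)
  start <- substr(genome, 1, 27)
  ante <- assemble_genome(db, start, "antegrade")
  retro <- assemble_genome(db, start, "retrograde")
  res <- compare_and_resolve(ante, retro, db)
  expect_equal(nrow(res$discrepancies), 0L)
  expect_equal(res$consensus$seq, genome)

  # manufacture a one-base substitution discrepancy in the retrograde copy;
  # only the true variant has both-strand database support
  pos <- 250L
  fake <- retro
  substr(fake$seq, pos, pos) <- setdiff(BASES, substr(genome, pos, pos))[1]
  res2 <- compare_and_resolve(ante, fake, db)
  expect_equal(nrow(res2$discrepancies), 1L)
  expect_equal(res2$discrepancies$type, "substitution")
  expect_equal(res2$discrepancies$winner, "antegrade")
  expect_equal(res2$consensus$seq, genome)

  # both variants supported: the higher local multiplicity wins
  extra <- fake$seq
  boost <- substring(paste0(extra, extra), seq(pos - 40, pos + 10, by = 8),
                     seq(pos - 40, pos + 10, by = 8) + 59)
  boost <- c(boost, revcomp(boost))
  db_mixed <- build_kmer_db(dplyr::bind_rows(
    reads,
    tibble::tibble(id = sprintf("b%03d", seq_along(boost)), bases = boost)
  ), n = 27)
  res3 <- compare_and_resolve(ante, fake, db_mixed)
  expect_equal(nrow(res3$discrepancies), 1L)
  expect_true(res3$discrepancies$ante_both_strands)
  expect_true(res3$discrepancies$retro_both_strands)
  # the majority haplotype still carries more multiplicity
  expect_equal(res3$discrepancies$winner, "antegrade")
})

test_that("the assumption validator warns on repeats and palindromes", {
  seg <- random_genome(30, seed = 145)
  rep_genome <- paste0(seg, random_genome(100, seed = 146), seg,
                       random_genome(100, seed = 147))
  expect_warning(check_assembly_assumptions(rep_genome, 27), "duplicated")
  pal_genome <- paste0(random_genome(80, seed = 148), seg,
                       random_genome(40, seed = 149), revcomp(seg))
  expect_warning(check_assembly_assumptions(pal_genome, 27), "palindromic")
})

test_that("multiplicity histograms show the coverage mode and error mass", {
  genome <- random_genome(500, seed = 150)
  reads <- tiling_reads(genome, read_len = 60L, step = 1L)
  db <- build_kmer_db(reads, n = 27)
  h <- multiplicity_histogram(db)
  # uniform tiling: each circular n-mer seen 60 - 27 + 1 = 34 times,
  # split between the two strand orientations
  expect_equal(sum(h$n_kmers * h$m), db$total)
  expect_equal(max(h$n_kmers), h$n_kmers[which(h$m == 17)])

  empty <- build_kmer_db(tibble::tibble(id = "x", bases = "ACGT"), 27)
  expect_equal(nrow(multiplicity_histogram(empty)), 0L)

  # substitution errors add an m = 1 mass
  noisy <- reads
  noisy$bases <- vapply(noisy$bases, function(b) {
    i <- sample(60, 1)
    substr(b, i, i) <- sample(BASES, 1)
    b
  }, "", USE.NAMES = FALSE)
  hn <- multiplicity_histogram(build_kmer_db(noisy, n = 27))
  expect_gt(hn$n_kmers[hn$m == 1], 100)
})
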