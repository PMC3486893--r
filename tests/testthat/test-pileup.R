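test_that("pileup columns conserve aligned bases and record deletions", {
  ref <- random_ref(400, seed = 100)
  reads <- tiling_reads(ref$seq, read_len = 80L, step = 7L)
  aln <- align_reads(reads, ref)
  expect_true(all(aln$n_hits == 1))
  pile <- build_pileup(aln, ref)
  expect_equal(nrow(pile), 400L)
  # count conservation: column totals equal reference-consuming op lengths
  ref_consumed <- vapply(aln$ops, function(o) {
    sum(strsplit(o, "")[[1]] != "I")
  }, 0L, USE.NAMES = FALSE)
  expect_equal(sum(pile$n), sum(ref_consumed))

  # a read with a genuine deletion contributes a del allele
  del_read <- paste0(substr(ref$seq, 101, 150), substr(ref$seq, 152, 201))
  aln_d <- align_reads(tibble::tibble(id = "d", bases = del_read), ref)
  pile_d <- build_pileup(aln_d, ref)
  expect_equal(pile_d$del_fwd[151] + pile_d$del_rev[151], 1L)
})

test_that("one perfect forward read gives unit columns over its span", {
  ref <- random_ref(400, seed = 101)
  read <- substr(ref$seq, 1, 250)
  aln <- align_reads(tibble::tibble(id = "r", bases = read), ref)
  pile <- build_pileup(aln, ref)
  expect_equal(pile$n[1:250], rep(1L, 250))
  expect_equal(pile$n[251:400], rep(0L, 150))
  refchars <- strsplit(ref$seq, "")[[1]]
  hit <- vapply(1:250, function(p) {
    pile[[paste0(refchars[p], "_fwd")]][p]
  }, 0L)
  expect_equal(hit, rep(1L, 250))
})

test_that("primary calling applies the phi, strand and homopolymer thresholds", {
  p <- call_params()
  # phi = 70/120, both strands: called
  col <- pileup_col(A_fwd = 40, A_rev = 30, G_fwd = 25, G_rev = 25)
  bc <- call_primary(col, hp_len = 1, params = p)
  expect_equal(bc$status, "called")
  expect_equal(bc$allele, "A")
  expect_equal(bc$phi, 70 / 120)
  expect_equal(bc$rho, 40 / 30)

  # modal 59 of 120: phi below 0.5
  bc <- call_primary(pileup_col(A_fwd = 30, A_rev = 29, G_fwd = 31,
                                G_rev = 15, T_fwd = 15), hp_len = 1,
                     params = p)
  expect_equal(bc$status, "Z")
  expect_match(bc$reasons, "phi")

  # modal allele on one strand only
  bc <- call_primary(pileup_col(A_fwd = 70, G_fwd = 10, G_rev = 10),
                     hp_len = 1, params = p)
  expect_equal(bc$status, "Z")
  expect_match(bc$reasons, "rho")

  # long homopolymer context
  bc <- call_primary(pileup_col(A_fwd = 60, A_rev = 60), hp_len = 5,
                     params = p)
  expect_equal(bc$status, "Z")
  expect_match(bc$reasons, "hp")

  # no coverage
  bc <- call_primary(pileup_col(), hp_len = 1, params = p)
  expect_equal(bc$status, "Z")
  expect_match(bc$reasons, "no_coverage")
})

test_that("the Poisson secondary threshold matches direct pmf summation", {
  # independent oracle: accumulate the Poisson pmf until the confidence
  # level is reached
  k_by_sum <- function(mean, conf) {
    k <- 0
    acc <- dpois(0, mean)
    while (acc < conf) {
      k <- k + 1
      acc <- acc + dpois(k, mean)
    }
    k
  }
  expect_equal(poisson_secondary_threshold(100, 0.05, 0.99),
               k_by_sum(5, 0.99))
  expect_equal(poisson_secondary_threshold(100, 0.05, 0.99), 11L)
  expect_equal(poisson_secondary_threshold(0, 0.05, 0.99), 0L)
  expect_equal(poisson_secondary_threshold(c(50, 500), 0, 0.99), c(0L, 0L))
  # monotone in coverage and in lambda
  ks <- poisson_secondary_threshold(seq(0, 2000, by = 50), 0.05, 0.99)
  expect_true(all(diff(ks) >= 0))
  kl <- vapply(seq(0, 0.2, by = 0.01), function(l)
    poisson_secondary_threshold(300, l, 0.99), 0L)
  expect_true(all(diff(kl) >= 0))
})

test_that("secondary candidates require count, phi, strand and HP conditions", {
  p <- call_params()
  hp <- 1L
  base <- pileup_col(A_fwd = 42, A_rev = 38, G_fwd = 9, G_rev = 9,
                     T_fwd = 1, T_rev = 1)
  prim <- call_primary(base, hp, p)
  cand <- call_secondary(base, prim, hp, p)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$secondary, "G")
  expect_equal(cand$phi_sec, 0.9)
  expect_equal(cand$k_star, 11L)
  expect_equal(cand$level, 0.18)

  # secondary count at the threshold: not a candidate
  low <- pileup_col(A_fwd = 45, A_rev = 43, G_fwd = 5, G_rev = 5,
                    T_fwd = 1, T_rev = 1)
  expect_equal(nrow(call_secondary(low, call_primary(low, hp, p), hp, p)), 0L)

  # single-strand secondary: rejected by the strand ratio
  biased <- pileup_col(A_fwd = 41, A_rev = 39, G_fwd = 18, T_fwd = 1,
                       T_rev = 1)
  expect_equal(
    nrow(call_secondary(biased, call_primary(biased, hp, p), hp, p)), 0L)
})

test_that("genome calling is clean in the zero-noise limit and forces Z at long run ends", {
  ref <- random_ref(500, seed = 110)
  # scrub runs >= 5 out of the toy genome so no forced Z arises
  expect_true(max(hp_run_length(ref, 1:500)) < 5)
  reads <- tiling_reads(ref$seq, read_len = 70L, step = 3L)
  aln <- align_reads(reads, ref)
  pile <- build_pileup(aln, ref)
  calls <- call_genome(pile, ref)
  expect_equal(sum(calls$status == "Z"), 0L)
  expect_equal(attr(calls, "consensus"), ref$seq)

  # insert a single 6-base run: exactly one forced-Z position at its end
  seq6 <- paste0(substr(ref$seq, 1, 200), "GGGGGG", substr(ref$seq, 207, 500))
  ref6 <- circular_reference(seq6)
  reads6 <- tiling_reads(ref6$seq, read_len = 70L, step = 3L)
  calls6 <- call_genome(build_pileup(align_reads(reads6, ref6), ref6), ref6)
  z <- calls6[calls6$status == "Z", ]
  forced <- z[grepl("hp_run_end", z$reasons), ]
  expect_equal(nrow(forced), 1L)
  expect_equal(forced$pos, 206L)
  # the in-run positions fail the plain HP <= 4 threshold instead
  expect_true(all(calls6$status[201:206] == "Z"))
})

test_that("a fixed variant shifts the consensus at exactly one position", {
  ref <- random_ref(400, seed = 111)
  mutated <- ref$seq
  substr(mutated, 123, 123) <- setdiff(BASES, substr(ref$seq, 123, 123))[1]
  reads <- tiling_reads(mutated, read_len = 70L, step = 3L)
  aln <- align_reads(reads, ref)
  pile <- build_pileup(filter_mapping(aln, reads$id)$kept, ref)
  calls <- call_genome(pile, ref)
  diffs <- which(calls$status == "called" & calls$allele != calls$ref_base)
  expect_equal(diffs, 123L)
})

test_that("non-modal frequency follows the fixed tie order", {
  expect_equal(nonmodal_frequency(pileup_col(A_fwd = 99, G_fwd = 1)), 0.01)
  expect_equal(nonmodal_frequency(pileup_col(C_fwd = 37, C_rev = 13)), 0)
  expect_equal(nonmodal_frequency(pileup_col(A_fwd = 50, G_fwd = 50)), 0.5)
  expect_error(nonmodal_frequency(pileup_col()), "no coverage")
})

test_that("false secondary candidates are controlled at the Poisson level", {
  p <- call_params()
  pile <- simulate_error_pileup(n_positions = 1500, coverage = 200,
                                error_rate = 0.05, seed = 42)
  prim <- call_columns(pile, 1L, p)
  cand <- call_secondary(pile, prim, rep(1L, nrow(pile)), p)
  expect_lte(nrow(cand) / nrow(pile), 0.01)
})
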