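# minimal genome_calls-like tibble for statistics tests
fake_calls <- function(ref_seq, allele = NULL, status = NULL) {
  L <- nchar(ref_seq)
  refb <- strsplit(ref_seq, "")[[1]]
  if (is.null(allele)) allele <- refb
  if (is.null(status)) status <- rep("called", L)
  tibble::tibble(
    pos = seq_len(L), status = status,
    allele = ifelse(status == "called", allele, NA_character_),
    ref_base = refb
  )
}

test_that("variant tables classify substitutions and deletions", {
  ref <- "ACGTACGT"
  calls <- fake_calls(ref)
  expect_equal(nrow(variant_table(calls)), 0L)

  allele <- strsplit(ref, "")[[1]]
  allele[1] <- "G"    # A>G transition
  allele[2] <- "del"  # deletion
  allele[3] <- "C"    # G>C transversion
  status <- rep("called", 8)
  status[5] <- "Z"
  allele[5] <- "G"    # differing but uncalled: must be skipped
  v <- variant_table(fake_calls(ref, allele, status),
                     known_sites = c(1L))
  expect_equal(v$pos, c(1L, 2L, 3L))
  expect_equal(v$class, c("transition", "deletion", "transversion"))
  expect_equal(v$known, c(TRUE, FALSE, FALSE))
})

test_that("transition:transversion ratio handles boundary cases", {
  v <- tibble::tibble(class = c("transition", "transition", "transversion"))
  expect_equal(ts_tv_ratio(v), 2)
  expect_equal(ts_tv_ratio(tibble::tibble(class = "transition")), Inf)
  expect_equal(ts_tv_ratio(tibble::tibble(class = "transversion")), 0)
  expect_error(ts_tv_ratio(tibble::tibble(class = "deletion")),
               "no substitutions")
  # the classification is a partition over substitutions
  subs <- expand.grid(ref = BASES, alt = BASES, stringsAsFactors = FALSE)
  subs <- subs[subs$ref != subs$alt, ]
  cls <- variant_table(tibble::tibble(
    pos = seq_len(nrow(subs)), status = "called",
    allele = subs$alt, ref_base = subs$ref
  ))$class
  expect_equal(sum(cls == "transition"), 4L)
  expect_equal(sum(cls == "transversion"), 8L)
})

test_that("nucleotide diversity uses pairwise deletion over Z positions", {
  expect_equal(nucleotide_diversity(c("ACGTACGTAC", "ACGTACGTAC")), 0)
  two <- c("ACGTACGTAC", "ACGTACGTAG")
  expect_equal(nucleotide_diversity(two), 0.1)
  # three sequences with pairwise differences 1, 2, 3 over 100 positions
  base <- random_genome(100, seed = 160)
  s2 <- base; substr(s2, 10, 10) <- "A"; substr(s2, 10, 10) <- setdiff(BASES, substr(base, 10, 10))[1]
  s3 <- s2
  substr(s3, 30, 30) <- setdiff(BASES, c(substr(s2, 30, 30)))[1]
  substr(s3, 50, 50) <- setdiff(BASES, c(substr(s2, 50, 50)))[1]
  d <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  expect_equal(nucleotide_diversity(c(base, s2, s3)),
               mean(c(d(base, s2), d(base, s3), d(s2, s3))) / 100)
  # a Z position drops out of the pair that carries it
  zed <- paste0("Z", substr(two[1], 2, 10))
  expect_equal(nucleotide_diversity(c(zed, two[2])), 1 / 9)
  expect_error(nucleotide_diversity("ACGT"), "at least 2")
})

test_that("region frequencies count distinct sites once", {
  regions <- tibble::tibble(region = c("dloop", "coding"),
                            start = c(1100L, 81L), end = c(80L, 1099L))
  v <- tibble::tibble(pos = c(rep(10L, 5), 20L, 500L, 600L, 700L,
                              rep(1150L, 3), 1160L, 30L, 40L, 50L, 55L,
                              60L, 70L))
  rf <- region_frequency(v, regions, sample_size = 20, L = 1200)
  expect_equal(rf$length, c(181L, 1019L))
  expect_equal(rf$n_sites, c(10L, 3L))
  expect_equal(rf$frequency, c(10 / 181 / 20, 3 / 1019 / 20))
  none <- region_frequency(tibble::tibble(pos = integer(0)), regions, 20,
                           1200)
  expect_equal(none$frequency, c(0, 0))
  # worked numbers: 10 sites in a 1,122 bp region across 20 samples
  one <- region_frequency(
    tibble::tibble(pos = seq(10, 1000, length.out = 10)),
    tibble::tibble(region = "r", start = 1L, end = 1122L), 20, 2000
  )
  expect_equal(one$frequency, 10 / 1122 / 20, tolerance = 1e-12)
})

test_that("coverage normalization divides by reads per thousand", {
  pile <- pileup_col(A_fwd = 60, A_rev = 60)
  tr <- coverage_track(pile, total_reads = 10000)
  expect_equal(tr$normalized, 120 / 10)
  pile0 <- pileup_col()
  expect_equal(coverage_track(pile0, 10000)$normalized, 0)
  expect_error(coverage_track(pile, 0), "positive")
})

test_that("centered strand ratio is bounded, antisymmetric and exact", {
  expect_equal(centered_ratio(5, 5), 0)
  expect_equal(centered_ratio(3, 1), 0.5)
  expect_equal(centered_ratio(0, 5), -1)
  expect_equal(centered_ratio(5, 0), 1)
  expect_error(centered_ratio(0, 0), "positive")
  set.seed(161)
  f <- sample(0:50, 30, TRUE)
  r <- sample(1:50, 30, TRUE)
  expect_equal(centered_ratio(f, r), -centered_ratio(r, f))
  expect_true(all(abs(centered_ratio(f, r)) <= 1))
  # equivalence with the ratio form where both are defined
  expect_equal(centered_ratio(12, 4), ((12 / 4) - 1) / ((12 / 4) + 1))
})

test_that("GC windows are circular and sum-consistent", {
  allg <- circular_reference(strrep("G", 60))
  expect_equal(gc_window(allg, 5), rep(1, 60))
  at <- circular_reference(strrep("AT", 30))
  expect_equal(gc_window(at, 5), rep(0, 60))
  toy <- circular_reference("GGGGGAAAAA")
  expect_equal(gc_window(toy, 5)[3], 1)
  expect_equal(gc_window(toy, 5)[8], 0)
  expect_error(gc_window(toy, 4), "odd")
  # circular double-counting identity
  ref <- random_ref(200, seed = 162)
  w <- 51
  total_gc <- sum(strsplit(ref$seq, "")[[1]] %in% c("G", "C"))
  expect_equal(sum(gc_window(ref, w)) * w, w * total_gc)
})

test_that("concordance arithmetic reproduces pooled rates and bounds", {
  # discordant duplicates: 13 changes in 65,525 compared positions
  r <- concordance_summary(c(0, 1, 8, 4), c(16567, 16567, 16196, 16195))
  expect_equal(r$compared, 65525L)
  expect_equal(r$discordant, 13L)
  expect_equal(r$rate, 13 / 65525)
  expect_equal(round(r$rate * 1e5, 2), 19.84)
  expect_false(r$is_bound)

  # concordant duplicates: bound of 1 in 66,231
  b <- concordance_summary(c(0, 0, 0, 0), c(16568, 16567, 16527, 16569))
  expect_equal(b$compared, 66231L)
  expect_true(b$is_bound)
  expect_equal(round(b$rate * 1e5, 2), 1.51)

  # per-position comparison of call tables
  ref <- random_genome(50, seed = 163)
  ca <- fake_calls(ref)
  cb <- fake_calls(ref)
  expect_equal(concordance(ca, cb)$discordant, 0L)
  cb2 <- cb
  cb2$allele[7] <- setdiff(BASES, cb$allele[7])[1]
  cb2$status[9] <- "Z"
  r2 <- concordance(ca, cb2)
  expect_equal(r2$compared, 49L)  # the Z position drops out
  expect_equal(r2$discordant, 1L)
})
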