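# Read QC: poly-G filter, seeded subsampling, quality trimming.

test_that("poly-G pairs are removed at the 20-G threshold, both senses", {
  base <- rand_dna(100, seed = 1)
  p <- pairs_df(
    seq1 = c(base, paste0(base, strrep("G", 20)),
             paste0(base, strrep("G", 19)), base),
    seq2 = c(base, base, base, paste0(strrep("C", 20), base)))
  out <- filter_polyg(p, qc_params())
  expect_identical(out$id, c("p001", "p003"))  # order preserved
  # G-only sense keeps the C-run pair
  out2 <- filter_polyg(p, qc_params(both_senses = FALSE))
  expect_identical(out2$id, c("p001", "p003", "p004"))
  # empty stream in, empty stream out
  expect_equal(nrow(filter_polyg(p[0, ], qc_params())), 0L)
})

test_that("subsampling is seeded, uniform and keeps mates together", {
  p <- pairs_df(seq1 = replicate(1000, rand_dna(20)),
                seq2 = replicate(1000, rand_dna(20)))
  expect_identical(subsample_pairs(p, 2000, seed = 1), p)  # oversampling
  a <- subsample_pairs(p, 100, seed = 42)
  b <- subsample_pairs(p, 100, seed = 42)
  expect_identical(a, b)
  expect_equal(nrow(a), 100L)
  expect_false(is.unsorted(match(a$id, p$id)))  # original order
  # uniformity over 200 seeds: each pair selected with frequency ~ 0.1
  counts <- integer(1000)
  for (s in 1:200) {
    idx <- match(subsample_pairs(p, 100, seed = s)$id, p$id)
    counts[idx] <- counts[idx] + 1L
  }
  freq <- counts / 200
  expect_lt(abs(mean(freq) - 0.1), 1e-9)
  expect_lt(max(abs(freq - 0.1)), 5 * sqrt(0.1 * 0.9 / 200) + 0.02)
})

test_that("trimming matches a brute-force sliding-window oracle", {
  set.seed(7)
  n <- 150
  seqs <- character(n); quals <- character(n)
  for (i in seq_len(n)) {
    len <- sample(50:150, 1)
    seqs[i] <- rand_dna(len)
    q <- pmin(pmax(round(rnorm(len, mean = sample(c(8, 18, 30), 1), sd = 10)), 0), 41)
    quals[i] <- intToUtf8(q + 33L)
  }
  p <- pairs_df(seqs, seqs, quals, quals)
  tr <- trim_pairs(p, qc_params(min_len = 0))
  got <- setNames(tr$pairs$seq1, tr$pairs$id)
  for (i in seq_len(n)) {
    want <- trim_oracle(seqs[i], quals[i])
    if (nchar(want) >= 0 && p$id[i] %in% names(got))
      expect_identical(unname(got[[p$id[i]]]), want)
  }
})

test_that("trim edge rules: clean reads unchanged, leading low-Q removed", {
  clean <- pairs_df(rand_dna(150, 1), rand_dna(150, 2),
                    phred_string(c(40, 150)), phred_string(c(40, 150)))
  out <- trim_pairs(clean, qc_params())
  expect_identical(out$pairs$seq1, clean$seq1)

  s <- rand_dna(150, 3)
  lowlead <- pairs_df(s, s, paste0("#", substr(phred_string(c(40, 150)), 2, 150)),
                      phred_string(c(40, 150)))  # '#' = Q2
  out2 <- trim_pairs(lowlead, qc_params())
  expect_identical(out2$pairs$seq1, substr(s, 2, 150))

  # four consecutive Q10 bases starting at index 51 truncate to length 50
  q <- c(rep(40, 50), rep(10, 4), rep(40, 96))
  s2 <- rand_dna(150, 4)
  p3 <- pairs_df(s2, s2, intToUtf8(q + 33), phred_string(c(40, 150)))
  out3 <- trim_pairs(p3, qc_params())
  expect_identical(out3$pairs$seq1, substr(s2, 1, 50))
})

test_that("short mates drop and orphans route the surviving mate", {
  s <- rand_dna(150, 5)
  short_q <- paste0(phred_string(c(40, 30)), phred_string(c(0, 120)))
  p <- pairs_df(c(s, s), c(s, s),
                qual1 = c(short_q, phred_string(c(40, 150))),
                qual2 = c(phred_string(c(40, 150)), phred_string(c(40, 150))))
  out <- trim_pairs(p, qc_params())
  expect_equal(nrow(out$pairs), 1L)
  expect_equal(nrow(out$orphans), 1L)
  expect_equal(nchar(out$orphans$seq), 150)
  expect_error(trim_pairs(pairs_df(s, s, qual1 = "II"), qc_params()),
               "malformed")
})

test_that("trimming is idempotent and never alters surviving content", {
  set.seed(9)
  seqs <- replicate(60, rand_dna(sample(60:150, 1)))
  quals <- vapply(nchar(seqs), function(n)
    intToUtf8(pmin(pmax(round(rnorm(n, 25, 9)), 0), 41) + 33L), character(1))
  p <- pairs_df(seqs, rev(seqs), quals, rev(quals))
  once <- trim_pairs(p, qc_params())
  twice <- trim_pairs(once$pairs, qc_params())
  expect_identical(twice$pairs, once$pairs)
  expect_lte(nrow(once$pairs), nrow(p))
  # survivors are substrings of the input (content only truncated)
  for (i in seq_len(nrow(once$pairs))) {
    j <- match(once$pairs$id[i], p$id)
    expect_true(grepl(once$pairs$seq1[i], p$seq1[j], fixed = TRUE))
  }
  # survivor mates remain ID-synchronized
  full <- qc_reads(p, qc_params(sample_pairs = 40, sample_seed = 3))
  expect_true(all(full$pairs$id %in% p$id))
})
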