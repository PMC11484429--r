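# Synthetic guide/truth/read generator.

test_that("guide sets share a backbone and carry the class insertion", {
  gs1 <- make_guide_set(seed = 1, base_length = 100000, classes = c(SHORT = 0))
  expect_length(gs1, 1L)
  g <- gs1$guide_SHORT
  expect_equal(nchar(g$sequence), 100000)
  expect_null(g$class_insert_interval)
  expect_false(grepl("[^ACGT]", g$sequence))

  gs2 <- make_guide_set(seed = 1, base_length = 100000,
                        classes = c(SHORT = 0, LONG = 20000))
  gS <- gs2$guide_SHORT
  gL <- gs2$guide_LONG
  expect_equal(nchar(gL$sequence), nchar(gS$sequence) + 20000)
  iv <- gL$class_insert_interval
  expect_true(iv[1] >= 0 && iv[2] <= nchar(gL$sequence) && iv[1] < iv[2])
  # flanks outside the insert are shared verbatim
  expect_identical(substr(gL$sequence, 1, iv[1]),
                   substr(gS$sequence, 1, iv[1]))
  expect_identical(substr(gL$sequence, iv[2] + 1, nchar(gL$sequence)),
                   substr(gS$sequence, iv[1] + 1, nchar(gS$sequence)))
  # repeat annotation lies within each guide
  bed <- guide_repeat_bed(gs2)
  expect_true(all(bed$start >= 0))
  for (gid in unique(bed$guide_id)) {
    expect_true(all(bed$end[bed$guide_id == gid] <=
                      nchar(gs2[[gid]]$sequence)))
  }
  # the segdup pair is near-identical (>= 99.9%)
  sd <- bed[bed$type == "segdup" & bed$guide_id == "guide_SHORT", ]
  c1 <- substr(gS$sequence, sd$start[1] + 1, sd$end[1])
  c2 <- substr(gS$sequence, sd$start[2] + 1, sd$end[2])
  mism <- sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  expect_lte(mism / nchar(c1), 0.001)
})

test_that("the same seed reproduces a byte-identical guide set", {
  a <- make_guide_set(seed = 9, base_length = 30000, classes = c(SHORT = 0, LONG = 5000))
  b <- make_guide_set(seed = 9, base_length = 30000, classes = c(SHORT = 0, LONG = 5000))
  expect_identical(a, b)
})

test_that("guide set rejects invalid specifications", {
  expect_error(make_guide_set(1, 100000, numeric(0)), "class")
  expect_error(make_guide_set(1, 10000, c(SHORT = 0)), "20 kb")
  expect_error(make_guide_set(1, 100000, c(LONG = 60000)), "base_length/2")
})

test_that("mutate_to_truth plants exactly the ledgered variation", {
  g <- plain_guide(30000, seed = 2)
  # zero-rate identity
  t0 <- mutate_to_truth(g, 0, 0, NULL, seed = 5)
  expect_identical(t0$sequence, g$sequence)
  expect_equal(nrow(t0$ledger), 0L)

  # deletion bookkeeping
  td <- mutate_to_truth(g, 0, 0,
                        data.frame(type = "DEL", length = 500L, count = 1L),
                        seed = 3)
  expect_equal(nchar(td$sequence), nchar(g$sequence) - 500)
  expect_equal(sum(td$ledger$type == "DEL"), 1L)

  # SNV count is binomial
  g2 <- plain_guide(100000, seed = 4)
  t1 <- mutate_to_truth(g2, 1e-3, 0, NULL, seed = 7)
  n <- sum(t1$ledger$type == "SNV")
  expect_lt(abs(n - 100), 3 * sqrt(100000 * 1e-3 * (1 - 1e-3)))
  expect_true(all(t1$ledger$ref[t1$ledger$type == "SNV"] !=
                    t1$ledger$alt[t1$ledger$type == "SNV"]))
  expect_error(mutate_to_truth(g, 0.2, 0, NULL, 1), "rates")
})

test_that("ledger replay reproduces the truth for many seeds", {
  g <- plain_guide(25000, seed = 11)
  for (s in 1:6) {
    tr <- mutate_to_truth(g, 1e-3, 1e-4,
                          draw_sv_specs(5, 2, 300), seed = s)
    expect_false(is.unsorted(tr$ledger$pos, strictly = TRUE))
    expect_identical(apply_ledger(g$sequence, tr$ledger), tr$sequence)
  }
})

test_that("unplaceable SV specs raise an error", {
  g <- plain_guide(20000, seed = 3)
  big <- data.frame(type = "DEL", length = 3000L, count = 10L)
  expect_error(mutate_to_truth(g, 0, 0, big, seed = 1), "place")
})

test_that("diploid truths share the prescribed fraction of variants", {
  gs <- make_guide_set(seed = 5, base_length = 40000,
                       classes = c(SHORT = 0, LONG = 8000))
  tr <- make_diploid_truths(gs$guide_SHORT, gs$guide_LONG, snv_rate = 1e-3,
                            n_sv = 10, hom_frac = 0.5, seed = 6)
  for (h in 1:2) {
    g <- gs[[tr[[h]]$guide_id]]
    expect_identical(apply_ledger(g$sequence, tr[[h]]$ledger),
                     tr[[h]]$sequence)
  }
  expect_equal(sum(tr[[1]]$ledger$shared & tr[[1]]$ledger$type != "SNV"), 5L)
  expect_equal(sum(tr[[2]]$ledger$shared & tr[[2]]$ledger$type != "SNV"), 5L)
  # shared records carry the same alt allele on both haplotypes
  shA <- tr[[1]]$ledger[tr[[1]]$ledger$shared, ]
  shB <- tr[[2]]$ledger[tr[[2]]$ledger$shared, ]
  expect_setequal(shA$alt, shB$alt)
})

test_that("read simulation respects the pair-count and fragment model", {
  tr <- list(id = "t", sequence = rand_dna(10000, seed = 8))
  sim <- simulate_reads(tr, read_sim_params(depth_fold = 30, seed = 2))
  expect_equal(nrow(sim$pairs), 1000L)  # ceil(10000 * 30 / 300)
  expect_true(all(nchar(sim$pairs$seq1) == 150))
  expect_true(all(nchar(sim$pairs$qual2) == 150))

  # error-free reads match their source fragments exactly
  sim0 <- simulate_reads(tr, read_sim_params(per_base_error = 0, seed = 3))
  pl <- sim0$placements
  for (i in sample.int(nrow(sim0$pairs), 50)) {
    frag_start <- pl$frag_start[i]
    r1 <- if (pl$strand[i] == "+") sim0$pairs$seq1[i] else sim0$pairs$seq2[i]
    expect_identical(r1, substr(tr$sequence, frag_start + 1, frag_start + 150))
  }

  # defaults mirror the 150 bp / 30x / 426 +/- 109 protocol
  p <- read_sim_params()
  expect_equal(c(p$read_length, p$depth_fold, p$fragment_mean, p$fragment_sd),
               c(150, 30, 426, 109))
  expect_error(read_sim_params(read_length = 500), "fragment_mean")
  expect_error(simulate_reads(list(id = "x", sequence = rand_dna(300)),
                              read_sim_params()), "shorter")
})

test_that("diploid sampling is balanced and depth-consistent", {
  t1 <- list(id = "a", sequence = rand_dna(20000, seed = 1))
  t2 <- list(id = "b", sequence = rand_dna(20000, seed = 2))
  sim <- simulate_reads(list(t1, t2), read_sim_params(seed = 4))
  tab <- table(sim$placements$hap)
  expect_equal(nrow(sim$pairs), 4000L)  # 40000 * 30 / 300
  expect_lt(abs(tab[["a"]] - tab[["b"]]), 4 * sqrt(4000))
})

test_that("diploid reads from identical truths match haploid kmer content", {
  s <- rand_dna(15000, seed = 21)
  hap <- simulate_reads(list(id = "h", sequence = s),
                        read_sim_params(depth_fold = 30, per_base_error = 0,
                                        seed = 5))
  dip <- simulate_reads(list(list(id = "h1", sequence = s),
                             list(id = "h2", sequence = s)),
                        read_sim_params(depth_fold = 15, per_base_error = 0,
                                        seed = 6))
  uh <- unique_kmer_count(hap$pairs, k = 31)
  ud <- unique_kmer_count(dip$pairs, k = 31)
  # both should essentially observe every 31-mer of the source
  expect_lt(abs(uh - ud) / uh, 0.02)
})
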