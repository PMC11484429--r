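# Guide assignment, read mapping, pair binning, superblocks.

hmap <- haplotype_map(
  alleles = c("01" = "SHORT", "03" = "SHORT", "04" = "LONG", "15" = "LONG2"),
  guides = c(SHORT = "guide_SHORT", LONG = "guide_LONG",
             LONG2 = "guide_LONG2"),
  fallback_guide = "guide_REF")

test_that("BMH assignment follows the first-field genotype rules", {
  expect_identical(assign_bmh("s1", c("03", "03"), hmap)$guide_ids,
                   "guide_SHORT")                     # homozygous: one BMH
  expect_identical(assign_bmh("s2", c("03", "04"), hmap)$guide_ids,
                   c("guide_SHORT", "guide_LONG"))    # heterozygous: two
  expect_identical(assign_bmh("s3", c("08", "08"), hmap)$guide_ids,
                   "guide_REF")                       # unmatched: fallback
  expect_identical(assign_bmh("s4", c("01", "03"), hmap)$guide_ids,
                   "guide_SHORT")                     # same class: one BMH
  nofb <- hmap; nofb$fallback_guide <- NULL
  expect_error(assign_bmh("s5", c("08", "03"), nofb), "08")
  expect_error(haplotype_map(c("03" = "SHORT"), c(LONG = "x"), "fb"),
               "SHORT")
})

test_that("the minimum alignment score is the linear L,0,-0.6 function", {
  expect_equal(min_alignment_score(150), -90)
  expect_equal(min_alignment_score(100), -60)
  expect_gte(0, min_alignment_score(1))  # perfect match passes any length
  expect_error(min_alignment_score(0))
})

test_that("read mapping places exact, mismatched and foreign reads correctly", {
  g <- plain_guide(100000, seed = 31)
  set.seed(3)
  starts <- sample(1:(100000 - 150), 60)
  reads <- substring(g$sequence, starts, starts + 149)
  p <- pairs_df(reads[1:30], reads[31:60])
  pl <- map_read_pairs(p, g)
  m1 <- pl[pl$mate == 1, ]
  expect_true(all(m1$mapped))
  expect_equal(m1$pos, starts[1:30] - 1)
  expect_true(all(m1$score == 0))

  # ten mismatches score -60 >= -90: still mapped
  r <- reads[1]
  mm <- r
  pos10 <- seq(5, 50, by = 5)  # clustered so a clean seed window remains
  for (i in pos10) substr(mm, i, i) <- setdiff(c("A","C","G","T"),
                                               substr(r, i, i))[1]
  pl2 <- map_read_pairs(pairs_df(mm, reads[2]), g)
  expect_true(pl2$mapped[pl2$mate == 1])
  expect_equal(pl2$score[pl2$mate == 1], -60)

  # random non-guide 150-mers never map on a 100 kb guide
  set.seed(4)
  rnd <- replicate(500, rand_dna(150))
  pl3 <- map_read_pairs(pairs_df(rnd[1:250], rnd[251:500]), g)
  expect_equal(sum(pl3$mapped), 0L)

  expect_error(map_read_pairs(p, guide_haplotype("t", "ACGT", "X")),
               "seed")
})

test_that("pair binning partitions pairs by the either-mate rule", {
  g <- plain_guide(50000, seed = 32)
  on_guide <- substr(g$sequence, 1001, 1150)
  foreign <- rand_dna(150, seed = 33)
  p <- pairs_df(c(on_guide, foreign), c(foreign, foreign),
                ids = c("mixed", "off"))
  pl <- map_read_pairs(p, g)
  bins <- bin_pairs(pl)
  expect_identical(bins$mapped_ids, "mixed")
  expect_identical(bins$unmapped_ids, "off")
  expect_length(c(bins$mapped_ids, bins$unmapped_ids), 2L)
  # mate-level binning demotes the mixed pair
  binsM <- bin_pairs(pl, pair_level = FALSE)
  expect_length(binsM$mapped_ids, 0L)
})

test_that("blocks and superblocks follow the overlap/flank/cap rules", {
  g <- plain_guide(120000, seed = 34)
  mk <- function(id, pos) data.frame(read_id = id, mate = 1L,
                                     guide_id = g$id, pos = pos,
                                     end = pos + 150, strand = "+",
                                     score = 0L, mapped = TRUE)
  # two overlapping reads: one block, one superblock
  sb <- build_superblocks(rbind(mk("a", 100), mk("b", 150)), g)
  expect_equal(nrow(sb), 1L)
  # separated by more than the flank: two superblocks
  sb2 <- build_superblocks(rbind(mk("a", 100), mk("b", 1000)), g)
  expect_equal(nrow(sb2), 2L)
  # blocks within the flank still merge
  sb3 <- build_superblocks(rbind(mk("a", 100), mk("b", 500)), g,
                           flank = 300)
  expect_equal(nrow(sb3), 1L)
  # empty placement stream
  expect_equal(nrow(build_superblocks(mk("a", 1)[0, ], g)), 0L)
  # the 50 kb cap with flank-bp overlap between consecutive superblocks
  dense <- do.call(rbind, lapply(seq(0, 119000, by = 100), function(p)
    mk(paste0("r", p), p)))
  sb4 <- build_superblocks(dense, g, max_block = 50000, flank = 300)
  expect_gte(nrow(sb4), 3L)
  expect_true(all(diff(sb4$start) > 0))
  expect_true(all(sb4$end - sb4$start <= 50000))
  for (i in seq_len(nrow(sb4) - 1))
    expect_equal(sb4$start[i + 1], sb4$end[i] - 300)
  # cover: union of superblocks covers every placement
  expect_true(all(vapply(seq_len(nrow(dense)), function(i)
    any(dense$pos[i] < sb4$end & dense$end[i] > sb4$start), logical(1))))
})

test_that("essentially all error-free on-guide pairs bin as mapped", {
  g <- plain_guide(30000, seed = 35)
  pairs <- simple_pairs(g$sequence, depth = 10, seed = 36)
  pl <- map_read_pairs(pairs, g)
  bins <- bin_pairs(pl)
  expect_gte(length(bins$mapped_ids) / nrow(pairs), 0.999)
})
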