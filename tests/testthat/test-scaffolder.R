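# Scaffolding: anchoring, placement scores, filtering, gap closing,
# consensus emission.

test_that("anchoring scores exact, chimeric and novel contigs correctly", {
  g <- plain_guide(60000, seed = 71)
  exact <- substr(g$sequence, 10001, 15000)
  chim <- paste0(substr(g$sequence, 20001, 22500),
                 substr(g$sequence, 45001, 47500))
  novel <- rand_dna(3000, seed = 72)
  ct <- data.frame(id = c("exact", "chim", "novel"),
                   sequence = c(exact, chim, novel), mean_cov = 10,
                   source_bin = "MAPPED", stringsAsFactors = FALSE)
  # disable chimera splitting to observe the raw scores
  anc <- anchor_contigs(ct, g, min_cluster_n = 1e9L)
  pl <- anc$placements
  expect_equal(pl$location_score[pl$contig_id == "exact"], 1.0)
  expect_equal(pl$orientation_score[pl$contig_id == "exact"], 1.0)
  expect_lt(abs(pl$location_score[pl$contig_id == "chim"] - 0.5), 0.05)
  expect_false("novel" %in% pl$contig_id)  # no anchors, no placement

  # reverse-complement contigs place on the minus strand at the same spot
  ct2 <- data.frame(id = "rc", sequence = revcomp(exact), mean_cov = 10,
                    source_bin = "MAPPED", stringsAsFactors = FALSE)
  pl2 <- anchor_contigs(ct2, g)$placements
  expect_identical(pl2$strand, "-")
  expect_equal(pl2$start, 10000)
})

test_that("a collapsed-repeat chimera is split at the junction", {
  g <- plain_guide(60000, seed = 73)
  chim <- paste0(substr(g$sequence, 20001, 24000),
                 substr(g$sequence, 40001, 44000))
  ct <- data.frame(id = "chim", sequence = chim, mean_cov = 10,
                   source_bin = "MAPPED", stringsAsFactors = FALSE)
  anc <- anchor_contigs(ct, g)
  expect_equal(nrow(anc$placements), 2L)
  expect_setequal(anc$placements$contig_id, c("chim/1", "chim/2"))
  starts <- sort(anc$placements$start)
  expect_lt(abs(starts[1] - 20000), 50)
  expect_lt(abs(starts[2] - 40000), 50)
})

test_that("the placement filter implements the stated predicate exactly", {
  mk <- function(loc, orient) data.frame(
    contig_id = sprintf("c_%.2f_%.2f", loc, orient), start = 0, end = 100,
    strand = "+", offset = 0, location_score = loc,
    orientation_score = orient, qlen = 100, stringsAsFactors = FALSE)
  expect_equal(nrow(filter_placements(mk(0.05, 0.99))), 0L)  # loc < 0.1
  expect_equal(nrow(filter_placements(mk(0.2, 0.6))), 0L)    # soft rule
  expect_equal(nrow(filter_placements(mk(0.2, 0.8))), 1L)    # kept
  # full truth table against the predicate
  grid <- expand.grid(loc = c(0.05, 0.15, 0.25, 0.35, 0.8),
                      orient = c(0.5, 0.74, 0.76, 1.0))
  for (i in seq_len(nrow(grid))) {
    keep_want <- !(grid$loc[i] < 0.1 ||
                     (grid$loc[i] < 0.3 && grid$orient[i] < 0.75))
    got <- nrow(filter_placements(mk(grid$loc[i], grid$orient[i]))) == 1L
    expect_identical(got, keep_want)
  }
})

test_that("paired reads close coverable gaps exactly", {
  g <- plain_guide(30000, seed = 74)
  pairs <- simple_pairs(g$sequence, depth = 30, seed = 75)
  rp <- map_read_pairs(pairs, g)
  # two contigs with a 200 bp gap between them
  left <- substr(g$sequence, 1001, 15000)
  right <- substr(g$sequence, 15201, 29000)
  ct <- data.frame(id = c("L", "R"), sequence = c(left, right),
                   mean_cov = 30, source_bin = "MAPPED",
                   stringsAsFactors = FALSE)
  anc <- anchor_contigs(ct, g)
  pl <- filter_placements(anc$placements)
  cg <- close_gaps(pl, anc$contigs, g, pairs, rp)
  expect_equal(nrow(cg$closed), 1L)
  expect_equal(nrow(cg$placements), 1L)
  merged <- cg$contigs$sequence[cg$contigs$id == cg$placements$contig_id[1]]
  expect_identical(merged, substr(g$sequence, 1001, 29000))

  # a gap with no spanning pairs stays open
  cg2 <- close_gaps(pl, anc$contigs, g, pairs[0, ], rp[0, ])
  expect_equal(nrow(cg2$closed), 0L)
  expect_equal(nrow(cg2$placements), 2L)
})

test_that("consensus emission tiles, fills and reports unplaced records", {
  g <- plain_guide(30000, seed = 76)
  # perfect tiling: two contigs overlapping seamlessly
  c1 <- substr(g$sequence, 1, 20000)
  c2 <- substr(g$sequence, 20001, 30000)
  ct <- data.frame(id = c("c1", "c2"), sequence = c(c1, c2), mean_cov = 30,
                   source_bin = "MAPPED", stringsAsFactors = FALSE)
  anc <- anchor_contigs(ct, g)
  cons <- emit_consensus(anc$placements, anc$contigs, g)
  expect_identical(cons$consensus, g$sequence)
  expect_false(any(cons$gap_mask$type == "filled"))
  # gap_mask partitions the consensus
  gm <- cons$gap_mask
  expect_equal(gm$cons_start, c(0, head(gm$cons_end, -1)))
  expect_equal(tail(gm$cons_end, 1), nchar(cons$consensus))

  # one missing 1 kb interval under gap_policy N
  ct2 <- data.frame(id = c("c1", "c3"),
                    sequence = c(c1, substr(g$sequence, 21001, 30000)),
                    mean_cov = 30, source_bin = "MAPPED",
                    stringsAsFactors = FALSE)
  anc2 <- anchor_contigs(ct2, g)
  consN <- emit_consensus(anc2$placements, anc2$contigs, g, gap_policy = "N")
  expect_identical(substr(consN$consensus, 20001, 21000), strrep("N", 1000))
  expect_equal(nchar(consN$consensus), 30000)
  # guide policy fills the same interval in lowercase
  consG <- emit_consensus(anc2$placements, anc2$contigs, g)
  expect_identical(substr(consG$consensus, 20001, 21000),
                   tolower(substr(g$sequence, 20001, 21000)))

  # an unplaceable novel contig becomes a separate record
  ct3 <- rbind(ct, data.frame(id = "nov", sequence = rand_dna(2000, 77),
                              mean_cov = 5, source_bin = "UNMAPPED",
                              stringsAsFactors = FALSE))
  anc3 <- anchor_contigs(ct3, g)
  cons3 <- emit_consensus(anc3$placements, anc3$contigs, g)
  recs <- consensus_records(cons3)
  expect_true("unplaced_nov" %in% names(recs))
  expect_length(recs, 2L)

  # no placements at all: empty consensus with a warning
  anc4 <- anchor_contigs(ct3[3, ], g)
  expect_warning(cons4 <- emit_consensus(anc4$placements, anc4$contigs, g),
                 "no placements")
  expect_identical(cons4$consensus, "")
})

test_that("overlapping placements resolve by score then length", {
  g <- plain_guide(30000, seed = 78)
  big <- substr(g$sequence, 5001, 15000)
  small <- substr(g$sequence, 9001, 11000)
  ct <- data.frame(id = c("big", "small"), sequence = c(big, small),
                   mean_cov = 30, source_bin = "MAPPED",
                   stringsAsFactors = FALSE)
  anc <- anchor_contigs(ct, g)
  cons <- emit_consensus(anc$placements, anc$contigs, g)
  gm <- cons$gap_mask
  # both have location score 1; the longer contig claims first and the
  # fully-overlapped small one is displaced into the records
  expect_true(all(gm$contig_id[gm$type == "assembled"] == "big"))
  expect_true(any(grepl("small", cons$unplaced$id)))
  # consensus length stays within [0.5, 1.5] x guide
  expect_gte(nchar(cons$consensus), 0.5 * 30000)
  expect_lte(nchar(cons$consensus), 1.5 * 30000)
})
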