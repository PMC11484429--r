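# De Bruijn assembly, contig filtering, merging, polishing.

test_that("kmer counting is canonical and complete", {
  kc <- count_kmers("ACGTACGT", 4)
  expect_equal(sum(kc$count), 5)  # len - k + 1
  s <- rand_dna(300, seed = 41)
  expect_identical(count_kmers(s, 21), count_kmers(revcomp(s), 21))
  expect_warning(kc2 <- count_kmers(c("ACGT", "AC"), 10), "empty")
  expect_equal(nrow(kc2), 0L)
})

test_that("estimate_best_k maximizes distinct solid kmers (spectrum oracle)", {
  src <- rand_dna(1500, seed = 42)
  set.seed(43)
  starts <- sample(1:(1500 - 100), 600, replace = TRUE)
  reads <- substring(src, starts, starts + 99)
  cands <- c(15L, 21L, 31L)
  # brute-force oracle: enumerate canonical kmers per read in R
  oracle_solid <- function(k) {
    all <- unlist(lapply(reads, function(r) {
      ss <- substring(r, 1:(nchar(r) - k + 1), k:nchar(r))
      pmin(ss, revcomp(ss))
    }))
    sum(table(all) >= 3)
  }
  solid <- vapply(cands, oracle_solid, numeric(1))
  want <- max(cands[solid == max(solid)])
  expect_equal(estimate_best_k(reads, cands), want)
  expect_error(estimate_best_k(character(0), 21L), "reads")
  expect_error(estimate_best_k("ACGTACGTA", c(15L, 21L)), "exceed")
  expect_error(estimate_best_k(reads, c(16L)), "odd")
})

test_that("clean graphs of error-free reads spell the source sequence", {
  src <- rand_dna(10000, seed = 44)
  set.seed(45)
  starts <- sample(1:(10000 - 150), 2000, replace = TRUE)
  reads <- substring(src, starts, starts + 149)
  g <- build_and_clean(reads, assembly_params())
  ct <- extract_contigs(g)
  expect_equal(nrow(ct), 1L)
  hit <- grepl(ct$sequence, src, fixed = TRUE) ||
    grepl(ct$sequence, revcomp(src), fixed = TRUE)
  expect_true(hit)
  expect_gte(nchar(ct$sequence), 0.98 * nchar(src))
  expect_gt(ct$mean_cov, 0)

  # a single sequencing error at 30x is cleaned away
  reads_err <- reads
  substr(reads_err[1], 75, 75) <- setdiff(c("A", "C", "G", "T"),
                                          substr(reads_err[1], 75, 75))[1]
  ct2 <- extract_contigs(build_and_clean(reads_err, assembly_params()))
  expect_equal(nrow(ct2), 1L)
  expect_identical(ct2$sequence, ct$sequence)

  expect_error(build_and_clean(reads, assembly_params(min_kmer_cov = 500L)),
               "empty")
})

test_that("contig extraction breaks at branch points and orders output", {
  # two sources sharing an identical 2 kb middle create a degree-2 branch
  mid <- rand_dna(2000, seed = 46)
  a <- paste0(rand_dna(3000, seed = 47), mid, rand_dna(3000, seed = 48))
  b <- paste0(rand_dna(3000, seed = 49), mid, rand_dna(3000, seed = 50))
  reads <- c()
  for (s in c(a, b)) {
    set.seed(51)
    st <- sample(1:(nchar(s) - 150), 1600, replace = TRUE)
    reads <- c(reads, substring(s, st, st + 149))
  }
  ct <- extract_contigs(build_and_clean(reads, assembly_params()))
  expect_gte(nrow(ct), 3L)  # no contig spans the shared middle's branches
  expect_true(all(diff(nchar(ct$sequence)) <= 0))  # length-desc order
  for (i in seq_len(nrow(ct))) {
    ok <- any(vapply(c(a, b), function(s)
      grepl(ct$sequence[i], s, fixed = TRUE) ||
        grepl(ct$sequence[i], revcomp(s), fixed = TRUE), logical(1)))
    expect_true(ok)
  }
})

test_that("cross-haplotype contigs are removed under the 50%/90% rule", {
  alt <- plain_guide(40000, seed = 52, id = "alt")
  contigs <- data.frame(
    id = c("c_alt", "c_random", "c_partial"),
    sequence = c(substr(alt$sequence, 5001, 7000),   # exact alt substring
                 rand_dna(2000, seed = 53),          # aligns nowhere
                 paste0(substr(alt$sequence, 9001, 9800),
                        rand_dna(1200, seed = 54))), # only 40% aligned
    mean_cov = 10, source_bin = "UNMAPPED", stringsAsFactors = FALSE)
  out <- filter_cross_contigs(contigs, alt_guide = alt)
  expect_identical(out$id, c("c_random", "c_partial"))
  # with no references everything is retained
  expect_identical(filter_cross_contigs(contigs), contigs)
})

test_that("contig merging joins qualifying overlaps and collapses containment", {
  a <- rand_dna(3000, seed = 55)
  b <- rand_dna(3000, seed = 56)
  ov <- 60L
  left <- paste0(a, substr(b, 1, ov))
  ct <- data.frame(id = c("L", "R"),
                   sequence = c(left, b),
                   mean_cov = c(10, 12), source_bin = "MAPPED",
                   stringsAsFactors = FALSE)
  m <- merge_contigs(ct)
  expect_equal(nrow(m), 1L)
  expect_equal(nchar(m$sequence), nchar(left) + nchar(b) - ov)

  # disjoint contigs stay apart
  d <- data.frame(id = c("A", "B"),
                  sequence = c(rand_dna(2000, 57), rand_dna(2000, 58)),
                  mean_cov = 10, source_bin = "MAPPED",
                  stringsAsFactors = FALSE)
  expect_equal(nrow(merge_contigs(d)), 2L)

  # full containment collapses to the container
  cont <- data.frame(id = c("big", "small"),
                     sequence = c(a, substr(a, 501, 1700)),
                     mean_cov = 10, source_bin = "MAPPED",
                     stringsAsFactors = FALSE)
  mc <- merge_contigs(cont)
  expect_equal(nrow(mc), 1L)
  expect_identical(mc$sequence, a)
})

test_that("polishing follows the depth-5 / 70% majority rule", {
  src <- rand_dna(4000, seed = 59)
  pairs <- simple_pairs(src, depth = 30, frag = 400, seed = 60)
  # plant one error into the contig
  bad <- src
  substr(bad, 2000, 2000) <- setdiff(c("A", "C", "G", "T"),
                                     substr(src, 2000, 2000))[1]
  ct <- data.frame(id = "c1", sequence = bad, mean_cov = 30,
                   source_bin = "MAPPED", stringsAsFactors = FALSE)
  pol <- polish_contigs(ct, pairs)
  expect_identical(pol$contigs$sequence, src)
  expect_equal(nrow(pol$corrections), 1L)
  expect_identical(pol$corrections$type, "SUB")
  expect_equal(pol$corrections$pos, 1999)  # 0-based

  # a correct contig receives zero corrections (majority never overridden)
  pol2 <- polish_contigs(data.frame(id = "c1", sequence = src,
                                    mean_cov = 30, source_bin = "MAPPED",
                                    stringsAsFactors = FALSE), pairs)
  expect_identical(pol2$contigs$sequence, src)
  expect_equal(nrow(pol2$corrections), 0L)

  # depth below 5 never corrects
  few <- pairs[1:3, , drop = FALSE]
  pol3 <- polish_contigs(ct, few)
  expect_identical(pol3$contigs$sequence, bad)
})

test_that("assembled consensus length grows with depth up to saturation", {
  # the de novo assembled (non-guide-filled) consensus length grows with
  # coverage and plateaus once the region saturates
  src <- rand_dna(20000, seed = 61)
  g <- guide_haplotype("flat", src, "SHORT")
  tot <- vapply(c(10, 20, 30), function(d) {
    pairs <- simulate_reads(
      list(id = "t", sequence = src),
      read_sim_params(depth_fold = d, fragment_mean = 400, fragment_sd = 60,
                      seed = 62))$pairs
    res <- assemble_haplotype(pairs, g, qc = NULL)
    sum(strsplit(res$consensus$consensus, "")[[1]] %in%
          c("A", "C", "G", "T"))
  }, numeric(1))
  expect_gt(tot[2], tot[1])
  expect_gt(tot[3], tot[1])
  expect_gte(tot[3], tot[2] - 0.005 * nchar(src))  # plateau jitter
})
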