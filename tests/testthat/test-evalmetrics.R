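# Validation metrics: N50, truth alignment, error taxonomy, recovery,
# kmer diversity, PAF export.

test_that("n50 agrees with the definition and a brute-force oracle", {
  expect_equal(n50(100), 100)
  expect_equal(n50(c(4, 3, 2, 1)), 3)  # 4 < 5 <= 4 + 3
  expect_error(n50(numeric(0)), "empty")
  n50_oracle <- function(lens) {
    s <- sort(lens, decreasing = TRUE)
    half <- sum(s) / 2
    for (i in seq_along(s)) if (sum(s[1:i]) >= half) return(s[i])
  }
  set.seed(81)
  for (i in 1:1000) {
    lens <- sample.int(5000, sample(1:40, 1), replace = TRUE)
    expect_identical(n50(lens), n50_oracle(lens))
  }
})

test_that("assembly stats summarise a contig set", {
  ct <- data.frame(sequence = c(strrep("A", 400), strrep("C", 100)))
  st <- assembly_stats(ct)
  expect_equal(st$n_contigs, 2L)
  expect_equal(st$total_length, 500)
  expect_equal(st$n50, 400)
})

test_that("truth alignment handles identity, deletions and strand", {
  s <- rand_dna(10000, seed = 82)
  aln <- align_to_truth(s, s)
  expect_equal(nrow(aln$segments), 1L)
  expect_equal(aln$segments$qstart, 0)
  expect_equal(aln$segments$qend, 10000)
  expect_equal(aln$segments$nmatch, aln$segments$alnlen)
  expect_equal(nrow(aln$variants), 0L)

  # truth with a 500 bp deletion relative to the assembly:
  # two chained segments with a query-side gap, plus the INS variant
  truth_del <- paste0(substr(s, 1, 4000), substr(s, 4501, 10000))
  aln2 <- align_to_truth(s, truth_del)
  expect_equal(nrow(aln2$segments), 2L)
  qgap <- aln2$segments$qstart[2] - aln2$segments$qend[1]
  expect_lt(abs(qgap - 500), 40)
  ins <- aln2$variants[aln2$variants$type == "INS", ]
  expect_equal(sum(ins$len), 500)

  # reverse-complemented assembly: a single minus-strand segment
  aln3 <- align_to_truth(revcomp(s), s)
  expect_identical(aln3$strand, "-")
  expect_equal(nrow(aln3$segments), 1L)
  expect_error(align_to_truth("", s), "empty")
})

test_that("error taxonomy counts planted errors exactly", {
  s <- rand_dna(10000, seed = 83)
  # identical pair: all zero
  er0 <- call_errors(align_to_truth(s, s))
  expect_equal(er0$total_error_pct, 0)
  expect_equal(er0$large_false_sv_count, 0)

  # one substitution in 10 kb -> base error 0.01%
  sub <- s
  substr(sub, 5000, 5000) <- setdiff(c("A", "C", "G", "T"),
                                     substr(s, 5000, 5000))[1]
  er1 <- call_errors(align_to_truth(sub, s))
  expect_equal(er1$base_call_error_pct, 0.01)
  expect_equal(er1$sv_nonrepeat_pct + er1$sv_repeat_pct, 0)

  # a 5 bp deletion outside repeats -> SV non-repeat 0.05%
  del <- paste0(substr(s, 1, 3000), substr(s, 3006, 10000))
  er2 <- call_errors(align_to_truth(del, s))
  expect_equal(er2$sv_nonrepeat_pct, 100 * 5 / nchar(del))
  expect_equal(er2$base_call_error_pct, 0)

  # planted INDELs of many sizes are recovered at their exact lengths
  sizes <- c(1, 3, 12, 60, 250, 2000)
  pos <- seq(1000, 9000, length.out = length(sizes))
  q <- s
  for (i in rev(seq_along(sizes))) {  # right-to-left keeps coordinates
    q <- paste0(substr(q, 1, pos[i]),
                rand_dna(sizes[i], seed = 90 + i),
                substr(q, pos[i] + 1, nchar(q)))
  }
  er3 <- call_errors(align_to_truth(q, s), min_sv = 1)
  got <- sort(er3$sv_records$len)
  expect_equal(got, sort(sizes))
  expect_equal(er3$large_false_sv_count, 1L)  # only the 2 kb event
  # min_sv = 2 drops the single-bp event
  er4 <- call_errors(align_to_truth(q, s), min_sv = 2)
  expect_equal(sort(er4$sv_records$len), sort(sizes[sizes >= 2]))

  # symmetry: swapping query/target preserves the mismatch count
  sub2 <- s
  for (p in c(2000, 4000, 6000))
    substr(sub2, p, p) <- setdiff(c("A", "C", "G", "T"),
                                  substr(s, p, p))[1]
  e_fwd <- call_errors(align_to_truth(sub2, s))
  e_rev <- call_errors(align_to_truth(s, sub2))
  expect_equal(e_fwd$base_call_error_pct, e_rev$base_call_error_pct)
})

test_that("guide-filled bases are excluded from the error denominator", {
  s <- rand_dna(8000, seed = 84)
  q <- paste0(substr(s, 1, 4000), tolower(substr(s, 4001, 5000)),
              substr(s, 5001, 8000))
  er <- call_errors(align_to_truth(q, s))
  expect_equal(er$assembled_length, 7000)
  er_all <- call_errors(align_to_truth(q, s), exclude_filled = FALSE)
  expect_equal(er_all$assembled_length, 8000)
})

test_that("heterozygous-allele errors are flagged OTHER_HAP", {
  s <- rand_dna(6000, seed = 85)
  other <- s
  substr(other, 3000, 3000) <- setdiff(c("A", "C", "G", "T"),
                                       substr(s, 3000, 3000))[1]
  q <- other  # assembly carries the other haplotype's allele
  er <- call_errors(align_to_truth(q, s), other_truth = other)
  expect_equal(er$n_other_hap, 1L)
  expect_equal(er$base_call_error_pct, 100 * 1 / 6000)  # still counted
})

test_that("novel-variant recovery matches its definition", {
  g <- plain_guide(30000, seed = 86)
  tr <- mutate_to_truth(g, 1e-3, 0, draw_sv_specs(6, 2, 200), seed = 87)
  # the truth itself recovers everything
  rec1 <- recover_novel_variants(tr$sequence, tr)
  expect_equal(rec1$snv_frac, 1.0)
  expect_equal(rec1$sv_frac, 1.0)
  # the bare guide recovers nothing
  rec0 <- recover_novel_variants(g$sequence, tr)
  expect_equal(rec0$snv_frac, 0.0)
  expect_equal(rec0$sv_frac, 0.0)
  # reverting exactly one of the SNVs yields (n-1)/n
  led <- tr$ledger
  snv_rows <- which(led$type == "SNV")
  drop1 <- led[-snv_rows[1], ]
  partial <- apply_ledger(g$sequence, drop1)
  rec2 <- recover_novel_variants(partial, tr)
  expect_equal(rec2$n_recovered_snv, rec1$n_recovered_snv - 1L)
  expect_equal(rec2$sv_frac, 1.0)
  # empty ledger reports NA fractions
  t0 <- mutate_to_truth(g, 0, 0, NULL, seed = 1)
  recNA <- recover_novel_variants(g$sequence, t0)
  expect_true(is.na(recNA$snv_frac) && is.na(recNA$sv_frac))
})

test_that("unique kmer counting is canonical and distinct", {
  r <- rand_dna(150, seed = 88)
  expect_equal(unique_kmer_count(r, 150), 1)
  expect_equal(unique_kmer_count(c(r, r), 150), 1)
  r2 <- r
  substr(r2, 75, 75) <- setdiff(c("A", "C", "G", "T"), substr(r, 75, 75))[1]
  expect_equal(unique_kmer_count(c(r, r2), 150), 2)
  expect_equal(unique_kmer_count(c(r, revcomp(r)), 150), 1)
  expect_error(unique_kmer_count(r, 200), "exceeds")
})

test_that("PAF export is well-formed and round-trips", {
  s <- rand_dna(5000, seed = 89)
  aln <- align_to_truth(s, s)
  path <- tempfile(fileext = ".paf")
  out <- dotplot_export(aln, path)
  back <- read_paf(path)
  expect_equal(nrow(back), 1L)
  expect_equal(back$qstart, out$qstart)
  expect_equal(back$tend, out$tend)
  expect_equal(ncol(back), 12L)
  # empty alignment list -> empty file
  p2 <- tempfile(fileext = ".paf")
  dotplot_export(list(segments = data.frame(), query = "", target = ""), p2)
  expect_equal(nrow(read_paf(p2)), 0L)
})

test_that("the low-complexity annotator finds homopolymers and tandems", {
  s <- paste0(rand_dna(500, 90), strrep("A", 15), rand_dna(500, 91),
              strrep("CAG", 10), rand_dna(500, 92))
  iv <- annotate_low_complexity(s)
  covers <- function(st, en) any(iv$start <= st & iv$end >= en)
  expect_true(covers(500, 515))
  expect_true(covers(1015, 1045))
})
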