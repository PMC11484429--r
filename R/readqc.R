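# Read-level preprocessing: poly-G artifact removal, seeded subsampling and
# quality trimming.  Adapter removal is assumed to have happened upstream.

#' Quality-control parameters
#'
#' @param polyg_min_run minimum consecutive-G run that flags a poly-G
#'   artifact (default 20).
#' @param sample_pairs number of pairs to retain in seeded subsampling, or
#'   `Inf` for all.
#' @param sample_seed subsampling seed.
#' @param lead_trail_q leading/trailing bases with quality below this (or N)
#'   are stripped (default 3).
#' @param window_len,window_meanq sliding-window truncation: reads are cut
#'   at the first `window_len`-bp window with mean quality below
#'   `window_meanq` (defaults 4 and 15).
#' @param min_len mates shorter than this after trimming are dropped
#'   (default 40).
#' @param both_senses also flag C runs (poly-G artifacts appear as C runs on
#'   the reverse-complement mate); default TRUE.
#' @return a `qc_params` list.
#' @export
qc_params <- function(polyg_min_run = 20L, sample_pairs = Inf,
                      sample_seed = 1L, lead_trail_q = 3L, window_len = 4L,
                      window_meanq = 15, min_len = 40L, both_senses = TRUE) {
  stopifnot(polyg_min_run >= 0, lead_trail_q >= 0, window_len >= 1,
            window_meanq >= 0, min_len >= 0)
  structure(list(polyg_min_run = polyg_min_run, sample_pairs = sample_pairs,
                 sample_seed = sample_seed, lead_trail_q = lead_trail_q,
                 window_len = window_len, window_meanq = window_meanq,
                 min_len = min_len, both_senses = both_senses),
            class = "qc_params")
}

#' Remove read pairs containing poly-G runs
#'
#' A pair is removed when either mate contains a run of at least
#' `polyg_min_run` consecutive G (or, with `both_senses`, C) bases.
#' Survivor order is preserved.
#'
#' @param pairs a `read_pairs` data frame.
#' @param params a [qc_params()] object.
#' @return the filtered `read_pairs`.
#' @export
filter_polyg <- function(pairs, params = qc_params()) {
  if (nrow(pairs) == 0L) return(pairs)
  n <- params$polyg_min_run
  pat <- sprintf("G{%d,}", n)
  bad <- grepl(pat, pairs$seq1) | grepl(pat, pairs$seq2)
  if (isTRUE(params$both_senses)) {
    patc <- sprintf("C{%d,}", n)
    bad <- bad | grepl(patc, pairs$seq1) | grepl(patc, pairs$seq2)
  }
  pairs[!bad, , drop = FALSE]
}

#' Seeded subsampling of read pairs
#'
#' Draws exactly `min(n_pairs, available)` pairs uniformly without
#' replacement, keeping mates together and preserving input order.
#' Deterministic for a given seed.
#'
#' @param pairs a `read_pairs` data frame.
#' @param n_pairs number of pairs to keep.
#' @param seed integer seed.
#' @export
subsample_pairs <- function(pairs, n_pairs, seed = 1L) {
  stopifnot(n_pairs >= 0)
  if (n_pairs >= nrow(pairs)) return(pairs)
  with_seed(seed, {
    idx <- sort(sample.int(nrow(pairs), n_pairs))
    pairs[idx, , drop = FALSE]
  })
}

#' Quality-trim read pairs
#'
#' Per mate: strip leading/trailing bases with quality < `lead_trail_q` or
#' base N; truncate at the start of the first `window_len`-bp window whose
#' mean quality falls below `window_meanq`; drop mates shorter than
#' `min_len`.  Pairs where exactly one mate survives route the survivor to
#' the orphan stream.
#'
#' @param pairs a `read_pairs` data frame.
#' @param params a [qc_params()] object.
#' @return list with `pairs` (both mates surviving) and `orphans` (a data
#'   frame id/seq/qual of single survivors).
#' @export
trim_pairs <- function(pairs, params = qc_params()) {
  if (nrow(pairs) == 0L)
    return(list(pairs = pairs,
                orphans = data.frame(id = character(0), seq = character(0),
                                     qual = character(0))))
  if (any(nchar(pairs$seq1) != nchar(pairs$qual1)) ||
      any(nchar(pairs$seq2) != nchar(pairs$qual2)))
    stop("malformed FASTQ record: sequence/quality length mismatch")
  t1 <- cpp_trim(pairs$seq1, pairs$qual1, params$lead_trail_q,
                 params$window_len, params$window_meanq)
  t2 <- cpp_trim(pairs$seq2, pairs$qual2, params$lead_trail_q,
                 params$window_len, params$window_meanq)
  s1 <- substr(pairs$seq1, t1$start, t1$end)
  q1 <- substr(pairs$qual1, t1$start, t1$end)
  s2 <- substr(pairs$seq2, t2$start, t2$end)
  q2 <- substr(pairs$qual2, t2$start, t2$end)
  ok1 <- nchar(s1) >= params$min_len
  ok2 <- nchar(s2) >= params$min_len
  out <- pairs[ok1 & ok2, , drop = FALSE]
  out$seq1 <- s1[ok1 & ok2]; out$qual1 <- q1[ok1 & ok2]
  out$seq2 <- s2[ok1 & ok2]; out$qual2 <- q2[ok1 & ok2]
  orph1 <- which(ok1 & !ok2)
  orph2 <- which(!ok1 & ok2)
  orphans <- rbind(
    data.frame(id = pairs$id[orph1], seq = s1[orph1], qual = q1[orph1],
               stringsAsFactors = FALSE),
    data.frame(id = pairs$id[orph2], seq = s2[orph2], qual = q2[orph2],
               stringsAsFactors = FALSE))
  list(pairs = out, orphans = orphans)
}

#' Full read QC: poly-G filter, subsampling, trimming
#'
#' @param pairs a `read_pairs` data frame.
#' @param params a [qc_params()] object.
#' @return list with `pairs`, `orphans` and `summary` (pairs in/out per
#'   filter).
#' @export
qc_reads <- function(pairs, params = qc_params()) {
  n0 <- nrow(pairs)
  pairs <- filter_polyg(pairs, params)
  n1 <- nrow(pairs)
  if (is.finite(params$sample_pairs))
    pairs <- subsample_pairs(pairs, params$sample_pairs, params$sample_seed)
  n2 <- nrow(pairs)
  tr <- trim_pairs(pairs, params)
  summary <- data.frame(
    stage = c("input", "polyg", "subsample", "trim"),
    pairs = c(n0, n1, n2, nrow(tr$pairs)))
  list(pairs = tr$pairs, orphans = tr$orphans, summary = summary)
}
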