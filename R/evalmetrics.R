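# Validation apparatus: assembly statistics, truth-based error taxonomy,
# novel-variant recovery, kmer diversity and PAF export.

#' N50 of a set of contig lengths
#'
#' The smallest length L such that contigs of length >= L sum to at least
#' half the total.
#'
#' @param lengths numeric vector of contig lengths (non-empty).
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length list")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Assembly summary statistics
#'
#' @param x a contig data frame (with `sequence`) or a numeric vector of
#'   lengths.
#' @return data frame: n_contigs, n50, total_length.
#' @export
assembly_stats <- function(x) {
  lens <- if (is.data.frame(x)) nchar(x$sequence) else x
  data.frame(n_contigs = length(lens), n50 = n50(lens),
             total_length = sum(lens))
}

#' Number of distinct canonical kmers across reads
#'
#' @param reads character vector of read sequences (or a `read_pairs` data
#'   frame, in which case both mates are used).
#' @param k kmer length (default 150, i.e. whole-read kmers).
#' @export
unique_kmer_count <- function(reads, k = 150L) {
  if (is.data.frame(reads)) reads <- c(reads$seq1, reads$seq2)
  if (k > max(nchar(reads))) stop("k exceeds every read length")
  cpp_unique_kmer_count(reads, as.integer(k))
}

# Colinear anchor chaining: anchors are grouped into diagonal runs
# (constant diagonal within tolerance, monotone in both coordinates), and
# runs are chained by dynamic programming with a penalty proportional to
# the diagonal jump.  Genuine SVs pay their one jump once; spurious
# zigzags between near-identical repeat copies do not pay off.  Returns
# the selected anchor indices.
chain_anchors <- function(anch, k, diag_tol = 40, qgap_max = 600,
                          jump_cost = 0.05, ov_max = 1000) {
  n <- nrow(anch)
  if (n == 0L) return(integer(0))
  o <- order(anch$qpos, anch$tpos)
  q <- anch$qpos[o]; t <- anch$tpos[o]
  d <- t - q
  # greedy run assignment
  run_id <- integer(n)
  runs_d <- numeric(0)   # current diagonal of each open run
  runs_q <- numeric(0)   # last qpos
  runs_t <- numeric(0)   # last tpos
  for (i in seq_len(n)) {
    hit <- which(abs(runs_d - d[i]) <= diag_tol &
                   q[i] - runs_q <= qgap_max & q[i] > runs_q &
                   t[i] > runs_t)
    if (length(hit) > 0L) {
      r <- hit[1L]
      run_id[i] <- r
      runs_q[r] <- q[i]; runs_t[r] <- t[i]; runs_d[r] <- d[i]
    } else {
      runs_d <- c(runs_d, d[i]); runs_q <- c(runs_q, q[i])
      runs_t <- c(runs_t, t[i])
      run_id[i] <- length(runs_d)
    }
  }
  m <- length(runs_d)
  rs <- data.frame(
    qstart = tapply(q, run_id, min), qend = tapply(q, run_id, max),
    tstart = tapply(t, run_id, min), tend = tapply(t, run_id, max),
    n = tabulate(run_id, m), diag = tapply(d, run_id, stats::median))
  ro <- order(rs$qstart, rs$tstart)
  rs <- rs[ro, , drop = FALSE]
  # DP over runs
  sc <- rs$n
  par <- rep(0L, m)
  dens <- rs$n / pmax(1, rs$qend - rs$qstart + 1)
  for (i in seq_len(m)) {
    for (j in seq_len(i - 1L)) {
      # modest overlap is allowed and paid for by the anchors it forfeits
      # (chimeric pieces duplicate target content at their junctions)
      ov <- max(0, rs$qend[j] - rs$qstart[i] + k,
                rs$tend[j] - rs$tstart[i] + k)
      if (ov > ov_max) next
      s <- sc[j] + rs$n[i] - jump_cost * abs(rs$diag[i] - rs$diag[j]) -
        ov * dens[i]
      if (s > sc[i]) { sc[i] <- s; par[i] <- j }
    }
  }
  best <- which.max(sc)
  chain_runs <- integer(0)
  i <- best
  while (i > 0L) { chain_runs <- c(i, chain_runs); i <- par[i] }
  keep_runs <- ro[chain_runs]  # original run ids
  sel <- o[run_id %in% keep_runs]
  sel <- sel[order(anch$qpos[sel], anch$tpos[sel])]
  # enforce strict monotonicity in both coordinates
  ok <- logical(length(sel))
  lastq <- -1; lastt <- -1
  for (i in seq_along(sel)) {
    if (anch$qpos[sel[i]] > lastq && anch$tpos[sel[i]] > lastt) {
      ok[i] <- TRUE
      lastq <- anch$qpos[sel[i]]; lastt <- anch$tpos[sel[i]]
    }
  }
  sel[ok]
}

#' Align an assembly to a truth sequence
#'
#' Kmer-anchor chaining into colinear segments with banded global
#' alignment of the inter-anchor regions.  Segments follow the PAF
#' convention; all query/target differences are additionally reported as a
#' variant list (SUB/INS/DEL with 0-based positions and lengths).  An
#' insertion is sequence present in the assembly but absent from the truth.
#'
#' @param assembly assembly sequence (string, possibly with lowercase
#'   guide-filled stretches) or a `consensus_assembly` (its continuous
#'   consensus is used).
#' @param truth truth sequence (string or `truth_haplotype`).
#' @param k anchor kmer length (default 31).
#' @param max_occ anchor kmers occurring more often than this in the truth
#'   are skipped (default 4; modest multiplicity keeps repeat copies
#'   anchorable while the jump-penalized chain resolves the copy).
#' @param step query anchor sampling step (default 19).
#' @param seg_break indels of at least this length split segments
#'   (default 100 bp).
#' @return list of class `truth_alignment`: `segments`, `variants`,
#'   `query` (oriented query sequence, case preserved), `target`, `strand`,
#'   `nmatch`.
#' @export
align_to_truth <- function(assembly, truth, k = 31L, max_occ = 4L,
                           step = 19L, seg_break = 100L) {
  q <- if (inherits(assembly, "consensus_assembly")) assembly$consensus
       else assembly
  t <- if (inherits(truth, "truth_haplotype")) truth$sequence else truth
  if (!nzchar(q) || !nzchar(t)) stop("empty input sequence")
  qu <- toupper(q)
  tu <- toupper(t)
  anch <- cpp_anchor_map(qu, tu, as.integer(k), as.integer(max_occ),
                         as.integer(step))
  strand <- "+"
  if (nrow(anch) > 0 && sum(anch$strand < 0) > sum(anch$strand > 0)) {
    strand <- "-"
    q <- revcomp(q)
    qu <- toupper(q)
    anch <- cpp_anchor_map(qu, tu, as.integer(k), as.integer(max_occ),
                           as.integer(step))
  }
  anch <- anch[anch$strand > 0, , drop = FALSE]
  empty <- list(segments = data.frame(), variants = data.frame(),
                query = q, target = t, strand = strand, nmatch = 0)
  class(empty) <- "truth_alignment"
  if (nrow(anch) == 0L) return(empty)
  keep <- chain_anchors(anch, k)
  anch <- anch[keep, , drop = FALSE]

  variants <- list()
  segments <- list()
  add_var <- function(qpos, tpos, type, len) {
    variants[[length(variants) + 1L]] <<- data.frame(
      qpos = qpos, tpos = tpos, type = type, len = len,
      stringsAsFactors = FALSE)
  }
  seg <- list(qstart = anch$qpos[1], tstart = anch$tpos[1], nmatch = 0,
              alnlen = 0)
  qa <- anch$qpos[1]; ta <- anch$tpos[1]
  close_seg <- function(qend, tend) {
    if (qend > seg$qstart) {
      al <- max(qend - seg$qstart, tend - seg$tstart)
      segments[[length(segments) + 1L]] <<- data.frame(
        qstart = seg$qstart, qend = qend, tstart = seg$tstart, tend = tend,
        strand = strand, nmatch = min(seg$nmatch, al), alnlen = al)
    }
  }
  seg$nmatch <- k

  # leading tails
  if (anch$qpos[1] > 0 && anch$tpos[1] > 0 &&
      max(anch$qpos[1], anch$tpos[1]) <= 5000) {
    qt <- substr(qu, 1, anch$qpos[1])
    tt <- substr(tu, 1, anch$tpos[1])
    al <- cpp_banded_align(qt, tt, abs(nchar(qt) - nchar(tt)) + 30L, 6L, 5L,
                           3L, FALSE)
    if (isTRUE(al$ok)) {
      v <- cigar_to_variants(al$cigar, 0, 0)
      for (j in seq_len(nrow(v$vars)))
        add_var(v$vars$qpos[j], v$vars$tpos[j], v$vars$type[j], v$vars$len[j])
      seg$qstart <- 0; seg$tstart <- 0
      seg$nmatch <- seg$nmatch + v$matches
    }
  }

  if (nrow(anch) > 1) for (i in 2:nrow(anch)) {
    qb <- anch$qpos[i]; tb <- anch$tpos[i]
    dq <- qb - qa; dt <- tb - ta
    if (dq <= 0 || dt <= 0) next
    if (dq < k || dt < k) {
      # overlapping anchors
      if (dq == dt) { seg$nmatch <- seg$nmatch + dq; qa <- qb; ta <- tb }
      next
    }
    qg <- dq - k; tg <- dt - k
    qs <- qa + k; ts <- ta + k
    broke <- FALSE
    if (qg == 0 && tg == 0) {
      # abutting anchors
    } else if (qg == tg && substr(qu, qs + 1, qs + qg) ==
               substr(tu, ts + 1, ts + tg)) {
      seg$nmatch <- seg$nmatch + qg
    } else if (qg == 0 || tg == 0) {
      len <- max(qg, tg)
      add_var(qs, ts, if (qg > 0) "INS" else "DEL", len)
      if (len >= seg_break) broke <- TRUE
    } else {
      band <- 30L
      al <- if ((qg + 1) * (2 * band + abs(qg - tg) + 1) < 4e7)
        cpp_banded_align(substr(qu, qs + 1, qs + qg),
                         substr(tu, ts + 1, ts + tg), band, 6L, 5L, 3L,
                         FALSE)
      else list(ok = FALSE)
      if (isTRUE(al$ok)) {
        v <- cigar_to_variants(al$cigar, qs, ts)
        maxind <- 0
        for (j in seq_len(nrow(v$vars))) {
          add_var(v$vars$qpos[j], v$vars$tpos[j], v$vars$type[j],
                  v$vars$len[j])
          if (v$vars$type[j] != "SUB")
            maxind <- max(maxind, v$vars$len[j])
        }
        seg$nmatch <- seg$nmatch + v$matches
        if (maxind >= seg_break) broke <- TRUE
      } else {
        add_var(qs, ts, if (qg > tg) "INS" else "DEL", abs(qg - tg))
        broke <- TRUE
      }
    }
    if (broke) {
      close_seg(qa + k, ta + k)
      seg <- list(qstart = qb, tstart = tb, nmatch = k, alnlen = 0)
    } else {
      seg$nmatch <- seg$nmatch + k
    }
    qa <- qb; ta <- tb
  }

  # trailing tails
  qend <- qa + k; tend <- ta + k
  qt <- nchar(qu) - qend; tt <- nchar(tu) - tend
  if (qt > 0 && tt > 0 && max(qt, tt) <= 5000) {
    al <- cpp_banded_align(substr(qu, qend + 1, nchar(qu)),
                           substr(tu, tend + 1, nchar(tu)),
                           abs(qt - tt) + 30L, 6L, 5L, 3L, FALSE)
    if (isTRUE(al$ok)) {
      v <- cigar_to_variants(al$cigar, qend, tend)
      for (j in seq_len(nrow(v$vars)))
        add_var(v$vars$qpos[j], v$vars$tpos[j], v$vars$type[j], v$vars$len[j])
      seg$nmatch <- seg$nmatch + v$matches
      qend <- nchar(qu); tend <- nchar(tu)
    }
  }
  close_seg(qend, tend)

  segs <- if (length(segments)) do.call(rbind, segments) else data.frame()
  vars <- if (length(variants)) do.call(rbind, variants) else
    data.frame(qpos = numeric(0), tpos = numeric(0), type = character(0),
               len = numeric(0), stringsAsFactors = FALSE)
  res <- list(segments = segs, variants = vars, query = q, target = t,
              strand = strand,
              nmatch = if (nrow(segs)) sum(segs$nmatch) else 0)
  class(res) <- "truth_alignment"
  res
}

# cigar (=XID ops) -> variants with absolute positions; groups runs.
cigar_to_variants <- function(cig, q0, t0) {
  p <- parse_cigar(cig)
  qpos <- q0; tpos <- t0
  matches <- 0
  rows <- list()
  for (i in seq_len(nrow(p))) {
    op <- p$op[i]; len <- p$len[i]
    if (op == "=") {
      matches <- matches + len
      qpos <- qpos + len; tpos <- tpos + len
    } else if (op == "X") {
      rows[[length(rows) + 1L]] <- data.frame(qpos = qpos, tpos = tpos,
                                              type = "SUB", len = len,
                                              stringsAsFactors = FALSE)
      qpos <- qpos + len; tpos <- tpos + len
    } else if (op == "I") {
      rows[[length(rows) + 1L]] <- data.frame(qpos = qpos, tpos = tpos,
                                              type = "INS", len = len,
                                              stringsAsFactors = FALSE)
      qpos <- qpos + len
    } else if (op == "D") {
      rows[[length(rows) + 1L]] <- data.frame(qpos = qpos, tpos = tpos,
                                              type = "DEL", len = len,
                                              stringsAsFactors = FALSE)
      tpos <- tpos + len
    }
  }
  list(vars = if (length(rows)) do.call(rbind, rows) else
         data.frame(qpos = numeric(0), tpos = numeric(0),
                    type = character(0), len = numeric(0),
                    stringsAsFactors = FALSE),
       matches = matches)
}

#' Annotate low-complexity intervals of a sequence
#'
#' Homopolymer runs of at least `hp_min` bp and tandem repeats of period
#' <= `max_period` with >= `min_copies` copies, as merged 0-based
#' half-open intervals.
#'
#' @param seq DNA string.
#' @param hp_min,max_period,min_copies thresholds.
#' @export
annotate_low_complexity <- function(seq, hp_min = 10L, max_period = 6L,
                                    min_copies = 3L) {
  cpp_low_complexity(seq, as.integer(hp_min), as.integer(max_period),
                     as.integer(min_copies))
}

#' Error taxonomy of an assembly-to-truth alignment
#'
#' Substitutions count as base-call error bp; INDELs of at least `min_sv`
#' bp count their lengths as SV error bp, split into repeat-associated and
#' non-repeat by overlap with `repeat_intervals` on the truth (or with the
#' internal low-complexity annotation when absent).  Percentages divide by
#' the assembled length (by default the uppercase, i.e. non-guide-filled,
#' assembly bases).
#'
#' @param aln a [align_to_truth()] result.
#' @param min_sv minimum INDEL length counted as SV (default 1).
#' @param repeat_intervals optional data frame of 0-based half-open truth
#'   intervals (columns start, end).
#' @param exclude_filled exclude guide-filled (lowercase) assembly bases
#'   from both the error counts and the assembled length (default TRUE).
#' @param other_truth optional other-haplotype sequence: substitution
#'   errors whose local assembly context occurs in it are flagged
#'   OTHER_HAP (heterozygous-allele misattribution rather than assembly
#'   error); totals still include them.
#' @return an `error_report` list: assembled_length, base_call_error_pct,
#'   sv_nonrepeat_pct, sv_repeat_pct, total_error_pct,
#'   large_false_sv_count, n_other_hap, sv_records.
#' @export
call_errors <- function(aln, min_sv = 1L, repeat_intervals = NULL,
                        exclude_filled = TRUE, other_truth = NULL) {
  q <- aln$query
  filled_at <- function(pos) {
    # pos 0-based on the oriented query
    ch <- substr(q, pos + 1L, pos + 1L)
    ch != "" & ch == tolower(ch) & ch != toupper(ch)
  }
  assembled_length <- if (exclude_filled)
    sum(strsplit(q, "", fixed = TRUE)[[1]] %in% c("A", "C", "G", "T"))
  else nchar(q)
  v <- aln$variants
  if (nrow(v) > 0 && exclude_filled) {
    fl <- vapply(pmin(pmax(v$qpos, 0), nchar(q) - 1L), filled_at, logical(1))
    v <- v[!fl, , drop = FALSE]
  }
  base_bp <- if (nrow(v)) sum(v$len[v$type == "SUB"]) else 0
  sv <- v[v$type %in% c("INS", "DEL") & v$len >= min_sv, , drop = FALSE]
  if (is.null(repeat_intervals))
    repeat_intervals <- annotate_low_complexity(aln$target)
  rep_flag <- logical(nrow(sv))
  if (nrow(sv) > 0 && nrow(repeat_intervals) > 0) {
    for (i in seq_len(nrow(sv))) {
      s <- sv$tpos[i] - 5
      e <- sv$tpos[i] + (if (sv$type[i] == "DEL") sv$len[i] else 0) + 5
      rep_flag[i] <- any(repeat_intervals$start < e & repeat_intervals$end > s)
    }
  }
  svr_bp <- sum(sv$len[rep_flag])
  svn_bp <- sum(sv$len[!rep_flag])
  n_other <- 0L
  if (!is.null(other_truth) && nrow(v) > 0) {
    ot <- toupper(if (inherits(other_truth, "truth_haplotype"))
      other_truth$sequence else other_truth)
    subs <- v[v$type == "SUB", , drop = FALSE]
    for (i in seq_len(nrow(subs))) {
      ctx <- toupper(substr(q, subs$qpos[i] + 1L - 25L,
                            subs$qpos[i] + subs$len[i] + 25L))
      if (nchar(ctx) >= 40 &&
          (grepl(ctx, ot, fixed = TRUE) ||
           grepl(revcomp(ctx), ot, fixed = TRUE)))
        n_other <- n_other + 1L
    }
  }
  pct <- function(bp) 100 * bp / assembled_length
  structure(list(
    assembled_length = assembled_length,
    base_call_error_pct = pct(base_bp),
    sv_nonrepeat_pct = pct(svn_bp),
    sv_repeat_pct = pct(svr_bp),
    total_error_pct = pct(base_bp + svn_bp + svr_bp),
    large_false_sv_count = sum(sv$len > 1000),
    n_other_hap = n_other,
    sv_records = if (nrow(sv)) cbind(sv, repeat_flag = rep_flag) else sv),
    class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf(
    "<error_report> %d bp assembled | base %.4f%% | SV non-repeat %.4f%% | SV repeat %.4f%% | total %.4f%% | >1kb false SVs: %d\n",
    x$assembled_length, x$base_call_error_pct, x$sv_nonrepeat_pct,
    x$sv_repeat_pct, x$total_error_pct, x$large_false_sv_count))
  invisible(x)
}

#' Fraction of ledger novel variants present in the assembly
#'
#' For each ledger variant the truth-side context (alt allele with
#' `flank`-bp flanks) is searched in the assembly records (continuous
#' consensus plus unplaced contigs, both strands); the variant is recovered
#' when the context is found.  Fractions are computed separately for SNVs
#' and INS/DEL records; `NA` when a class has no records.
#'
#' @param assembly a `consensus_assembly`, or a character vector of
#'   assembly records.
#' @param truth a `truth_haplotype` (its ledger defines the novel variants).
#' @param flank context flank width (default 25 bp).
#' @return a `variant_recovery` list: n_novel_snv, n_recovered_snv,
#'   snv_frac, n_novel_sv, n_recovered_sv, sv_frac, per_variant.
#' @export
recover_novel_variants <- function(assembly, truth, flank = 25L) {
  recs <- if (inherits(assembly, "consensus_assembly"))
    consensus_records(assembly) else assembly
  recs <- toupper(recs)
  led <- truth$ledger
  if (is.null(led) || nrow(led) == 0L) {
    return(structure(list(n_novel_snv = 0L, n_recovered_snv = 0L,
                          snv_frac = NA_real_, n_novel_sv = 0L,
                          n_recovered_sv = 0L, sv_frac = NA_real_,
                          per_variant = data.frame()),
                     class = "variant_recovery"))
  }
  tseq <- toupper(truth$sequence)
  shift <- 0L
  hit <- logical(nrow(led))
  tpos <- numeric(nrow(led))
  for (i in seq_len(nrow(led))) {
    tp <- led$pos[i] + shift
    tpos[i] <- tp
    alt_len <- nchar(led$alt[i])
    ctx <- substr(tseq, max(1L, tp + 1L - flank), tp + alt_len + flank)
    hit[i] <- any(vapply(recs, function(r)
      grepl(ctx, r, fixed = TRUE), logical(1))) ||
      any(vapply(recs, function(r)
        grepl(revcomp(ctx), r, fixed = TRUE), logical(1)))
    shift <- shift + alt_len - nchar(led$ref[i])
  }
  is_snv <- led$type == "SNV"
  res <- list(
    n_novel_snv = sum(is_snv), n_recovered_snv = sum(hit[is_snv]),
    snv_frac = if (any(is_snv)) mean(hit[is_snv]) else NA_real_,
    n_novel_sv = sum(!is_snv), n_recovered_sv = sum(hit[!is_snv]),
    sv_frac = if (any(!is_snv)) mean(hit[!is_snv]) else NA_real_,
    per_variant = cbind(led, truth_pos = tpos, recovered = hit))
  structure(res, class = "variant_recovery")
}

#' @export
print.variant_recovery <- function(x, ...) {
  cat(sprintf(
    "<variant_recovery> SNV %d/%d (%.1f%%) | SV %d/%d (%.1f%%)\n",
    x$n_recovered_snv, x$n_novel_snv, 100 * x$snv_frac,
    x$n_recovered_sv, x$n_novel_sv, 100 * x$sv_frac))
  invisible(x)
}

#' Export an assembly-to-truth alignment as PAF for dot plots
#'
#' @param aln a [align_to_truth()] result.
#' @param path output path.
#' @param qname,tname record names.
#' @return invisibly, the segments data frame written.
#' @export
dotplot_export <- function(aln, path, qname = "assembly", tname = "truth") {
  segs <- aln$segments
  if (is.null(segs) || nrow(segs) == 0L) {
    write_paf(data.frame(), path)
    return(invisible(data.frame()))
  }
  out <- data.frame(qname = qname, qlen = nchar(aln$query),
                    qstart = segs$qstart, qend = segs$qend,
                    strand = segs$strand, tname = tname,
                    tlen = nchar(aln$target), tstart = segs$tstart,
                    tend = segs$tend, nmatch = segs$nmatch,
                    alnlen = segs$alnlen, mapq = 60L,
                    stringsAsFactors = FALSE)
  write_paf(out, path)
  invisible(out)
}
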