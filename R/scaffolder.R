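# Ordering and orienting supercontigs against the assigned guide, placement
# score filtering, paired-read gap closing, and consensus emission.

# Cluster anchors of one contig against the guide.  Returns a data frame of
# clusters: strand, d (offset of the oriented contig on the guide), qmin,
# qmax, tmin, tmax, n (anchor count).
anchor_clusters <- function(anch, k, qlen, tol = 500) {
  out <- list()
  for (s in unique(anch$strand)) {
    a <- anch[anch$strand == s, , drop = FALSE]
    d <- if (s > 0) a$tpos - a$qpos else a$tpos + a$qpos + k - qlen
    o <- order(d)
    d <- d[o]; a <- a[o, , drop = FALSE]
    grp <- cumsum(c(TRUE, diff(d) > tol))
    for (g in unique(grp)) {
      sel <- grp == g
      aa <- a[sel, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        strand = s, d = stats::median(d[sel]), qmin = min(aa$qpos),
        qmax = max(aa$qpos), tmin = min(aa$tpos), tmax = max(aa$tpos),
        n = sum(sel))
    }
  }
  do.call(rbind, out)
}

# Group diagonal clusters into location clusters (overlapping guide
# intervals, any strand).
location_clusters <- function(cl, k) {
  cl$ts <- cl$tmin
  cl$te <- cl$tmax + k
  o <- order(cl$ts)
  cl <- cl[o, , drop = FALSE]
  grp <- cumsum(c(TRUE, cl$ts[-1] > cummax(cl$te[-nrow(cl)])))
  cl$loc <- grp
  cl
}

#' Anchor contigs on the guide and compute placement scores
#'
#' Each contig's exact-kmer anchors to the guide are clustered by diagonal.
#' The location score is the fraction of anchored bases supporting the best
#' location cluster; the orientation score is the majority-strand fraction
#' within that cluster.  Contigs without anchors get no placement.  A
#' contig whose anchors form two strong location clusters separated by more
#' than `split_min` bp on the guide is split at the cluster boundary before
#' placement (collapsed-repeat chimera correction); `split_min` is set
#' above the expected small-SV scale so allele-bearing contigs are never
#' split.
#'
#' @param contigs contig data frame.
#' @param guide a [guide_haplotype()].
#' @param k anchor kmer length (default 21).
#' @param max_occ skip guide kmers occurring more often than this.
#' @param split_min minimum diagonal separation for chimera splitting
#'   (default 700 bp, above the expected novel-SV scale so heterozygous
#'   allele contigs are never split).
#' @param min_cluster_n minimum absolute unique-anchor count of the
#'   secondary cluster to trigger a split (default 25).
#' @return list with `placements` (contig_id, start, end, strand, offset,
#'   location_score, orientation_score, qlen) and `contigs` (possibly with
#'   split pieces replacing chimeric originals).
#' @export
anchor_contigs <- function(contigs, guide, k = 21L, max_occ = 8L,
                           split_min = 700, min_cluster_n = 25L) {
  work <- contigs
  placements <- list()
  final <- list()
  glen <- nchar(guide$sequence)
  guard <- 0L
  while (nrow(work) > 0 && guard < 20L) {
    guard <- guard + 1L
    anch <- cpp_anchor_map(work$sequence, guide$sequence, as.integer(k),
                           as.integer(max_occ), 1L)
    # guide-unique anchors drive chimera detection: repeat-ambiguous
    # anchors attach to every copy and blur the junction
    anchu <- cpp_anchor_map(work$sequence, guide$sequence, as.integer(k),
                            1L, 1L)
    next_work <- list()
    for (i in seq_len(nrow(work))) {
      a <- anch[anch$query == i, , drop = FALSE]
      qlen <- nchar(work$sequence[i])
      if (nrow(a) == 0L) { final[[length(final) + 1L]] <- work[i, ]; next }
      # chimera split check on unique anchors: two strong diagonal
      # clusters, far apart on the guide, covering disjoint query ranges
      ua <- anchu[anchu$query == i, , drop = FALSE]
      if (nrow(ua) >= 2L * min_cluster_n) {
        ucl <- anchor_clusters(ua, k, qlen)
        ucl <- ucl[order(-ucl$n), , drop = FALSE]
        if (nrow(ucl) >= 2L) {
          c1 <- ucl[1L, ]; c2 <- ucl[2L, ]
          if (c2$n >= min_cluster_n && abs(c1$d - c2$d) > split_min) {
            # best separating cut between the two diagonal clusters
            du <- if (all(ua$strand > 0)) ua$tpos - ua$qpos
                  else ifelse(ua$strand > 0, ua$tpos - ua$qpos,
                              ua$tpos + ua$qpos + k - qlen)
            in1 <- abs(du - c1$d) <= 40
            in2 <- abs(du - c2$d) <= 40
            uu <- data.frame(qpos = ua$qpos, in1 = in1, in2 = in2)
            uu <- uu[uu$in1 | uu$in2, , drop = FALSE]
            uu <- uu[order(uu$qpos), , drop = FALSE]
            pre1 <- cumsum(uu$in1); pre2 <- cumsum(uu$in2)
            tot1 <- sum(uu$in1); tot2 <- sum(uu$in2)
            sep12 <- pre1 + (tot2 - pre2)   # cluster 1 left of cut
            sep21 <- pre2 + (tot1 - pre1)   # cluster 2 left of cut
            cut <- if (max(sep12) >= max(sep21))
              uu$qpos[which.max(sep12)] + k else
              uu$qpos[which.max(sep21)] + k
            cut <- as.integer(cut)
            if (cut > 0L && cut < qlen) {
              p1 <- work[i, ]; p2 <- work[i, ]
              p1$sequence <- substr(work$sequence[i], 1L, cut)
              p2$sequence <- substr(work$sequence[i], cut + 1L, qlen)
              p1$id <- paste0(work$id[i], "/1")
              p2$id <- paste0(work$id[i], "/2")
              next_work[[length(next_work) + 1L]] <- p1
              next_work[[length(next_work) + 1L]] <- p2
              next
            }
          }
        }
      }
      cl <- anchor_clusters(a, k, qlen)
      cl <- location_clusters(cl, k)
      w <- tapply(cl$n, cl$loc, sum)
      total <- sum(cl$n)
      best_loc <- as.integer(names(w)[which.max(w)])
      cb <- cl[cl$loc == best_loc, , drop = FALSE]
      loc_score <- sum(cb$n) / total
      strands <- tapply(cb$n, cb$strand, sum)
      maj_strand <- as.integer(names(strands)[which.max(strands)])
      orient_score <- max(strands) / sum(cb$n)
      cm <- cb[cb$strand == maj_strand, , drop = FALSE]
      d <- round(stats::median(rep(cm$d, cm$n)))
      start <- max(0, d)
      end <- min(glen, d + qlen)
      final[[length(final) + 1L]] <- work[i, ]
      placements[[length(placements) + 1L]] <- data.frame(
        contig_id = work$id[i], start = start, end = end,
        strand = if (maj_strand > 0) "+" else "-", offset = d,
        location_score = loc_score, orientation_score = orient_score,
        qlen = qlen, stringsAsFactors = FALSE)
    }
    work <- if (length(next_work)) do.call(rbind, next_work) else
      work[0, , drop = FALSE]
  }
  contigs_out <- do.call(rbind, final)
  rownames(contigs_out) <- NULL
  pl <- if (length(placements)) do.call(rbind, placements) else
    data.frame(contig_id = character(0), start = numeric(0),
               end = numeric(0), strand = character(0), offset = numeric(0),
               location_score = numeric(0), orientation_score = numeric(0),
               qlen = numeric(0), stringsAsFactors = FALSE)
  list(placements = pl, contigs = contigs_out)
}

#' Filter placements on location and orientation scores
#'
#' Drops a placement iff location score < 0.1, or location score < 0.3 and
#' orientation score < 0.75; survivors are unchanged.
#'
#' @param placements placement data frame from [anchor_contigs()].
#' @param loc_hard,loc_soft,orient_min the three thresholds.
#' @export
filter_placements <- function(placements, loc_hard = 0.1, loc_soft = 0.3,
                              orient_min = 0.75) {
  drop <- placements$location_score < loc_hard |
    (placements$location_score < loc_soft &
       placements$orientation_score < orient_min)
  placements[!drop, , drop = FALSE]
}

oriented_seq <- function(contigs, id, strand) {
  s <- contigs$sequence[match(id, contigs$id)]
  if (strand == "-") revcomp(s) else s
}

#' Close inter-contig gaps with paired reads
#'
#' For each gap between consecutive placed contigs, pairs with a mate
#' anchored in either flank contribute both mates to a local de Bruijn
#' mini-assembly (k = 31); when a local contig bridges both flanks with at
#' least `min_overlap` bp exact junctions and a bridge length compatible
#' with the guide gap (within `max(200, 0.3 * gap)`; collapsed-repeat
#' bridges fail this check), the gap is replaced by the assembled
#' sequence.
#'
#' @param placements filtered placements, `start`-sorted or not.
#' @param contigs contig data frame.
#' @param guide the guide haplotype.
#' @param pairs QC-surviving `read_pairs`.
#' @param read_placements per-mate guide placements ([map_read_pairs()]).
#' @param k local assembly kmer size (default 31).
#' @param flank guide flank width for read recruitment (default 600).
#' @param max_gap largest gap attempted (default 10 kb).
#' @param min_overlap minimum junction overlap (default 40 bp).
#' @return list with updated `placements` and `contigs`, plus `closed`
#'   (data frame of bridged gaps).
#' @export
close_gaps <- function(placements, contigs, guide, pairs, read_placements,
                       k = 31L, flank = 600L, max_gap = 10000L,
                       min_overlap = 40L) {
  pl <- placements[order(placements$start), , drop = FALSE]
  closed <- list()
  i <- 1L
  while (i < nrow(pl)) {
    gap <- pl$start[i + 1L] - pl$end[i]
    if (gap < 1 || gap > max_gap) { i <- i + 1L; next }
    lo <- pl$end[i] - flank
    hi <- pl$start[i + 1L] + flank
    rp <- read_placements[read_placements$mapped &
                            !is.na(read_placements$pos) &
                            read_placements$pos < hi &
                            read_placements$end > lo, , drop = FALSE]
    ids <- unique(rp$read_id)
    if (length(ids) == 0L) { i <- i + 1L; next }
    sel <- pairs$id %in% ids
    reads <- c(pairs$seq1[sel], pairs$seq2[sel])
    asm <- tryCatch(
      cpp_assemble(reads, as.integer(k), 2L, 2L * k, 0.95, 10L),
      error = function(e) NULL)
    if (is.null(asm)) { i <- i + 1L; next }
    lseq <- oriented_seq(contigs, pl$contig_id[i], pl$strand[i])
    rseq <- oriented_seq(contigs, pl$contig_id[i + 1L], pl$strand[i + 1L])
    tail_l <- substr(lseq, nchar(lseq) - min_overlap + 1L, nchar(lseq))
    head_r <- substr(rseq, 1L, min_overlap)
    bridged <- FALSE
    for (cand0 in asm$sequence) {
      for (cand in c(cand0, revcomp(cand0))) {
        pL <- regexpr(tail_l, cand, fixed = TRUE)[1]
        pR <- regexpr(head_r, cand, fixed = TRUE)[1]
        if (pL > 0 && pR > 0 && pR >= pL + min_overlap) {
          bridge <- substr(cand, pL + min_overlap, pR - 1L)
          if (abs(nchar(bridge) - gap) > max(200, 0.3 * gap)) next
          merged_seq <- paste0(lseq, bridge, rseq)
          mid <- paste0(pl$contig_id[i], "+", pl$contig_id[i + 1L])
          contigs <- contigs[!(contigs$id %in%
                                 pl$contig_id[c(i, i + 1L)]), , drop = FALSE]
          contigs <- rbind(contigs, data.frame(
            id = mid, sequence = merged_seq,
            mean_cov = NA_real_, source_bin = "GAPCLOSED",
            stringsAsFactors = FALSE))
          newrow <- pl[i, ]
          newrow$contig_id <- mid
          newrow$end <- pl$end[i + 1L]
          newrow$strand <- "+"
          newrow$qlen <- nchar(merged_seq)
          newrow$location_score <- min(pl$location_score[i:(i + 1L)])
          newrow$orientation_score <- min(pl$orientation_score[i:(i + 1L)])
          pl <- rbind(pl[seq_len(i - 1L), , drop = FALSE], newrow,
                      pl[-seq_len(i + 1L), , drop = FALSE])
          closed[[length(closed) + 1L]] <- data.frame(
            guide_start = lo + flank, guide_end = hi - flank,
            bridge_len = nchar(bridge))
          bridged <- TRUE
          break
        }
      }
      if (bridged) break
    }
    if (!bridged) i <- i + 1L
  }
  list(placements = pl, contigs = contigs,
       closed = if (length(closed)) do.call(rbind, closed) else
         data.frame(guide_start = numeric(0), guide_end = numeric(0),
                    bridge_len = numeric(0)))
}

#' Emit the guide-ordered consensus haplotype
#'
#' Contigs are concatenated in guide order; overlapping placements are
#' resolved by higher location score, then longer contig, then id, with the
#' losing contig trimmed (a fully displaced contig becomes an unplaced
#' record); remaining gaps are filled per `gap_policy`: "guide" fills with
#' lowercase guide bases, "N" with N runs sized to the guide gap.  Contigs
#' without (surviving) placements are appended as separate records, as are
#' the displaced portions (>= 100 bp) of partially trimmed placements --
#' typically the locally losing haplotype allele of a heterozygous
#' individual, which thereby remains discoverable in the output.
#'
#' @param placements filtered placements.
#' @param contigs contig data frame (superset of placed contigs).
#' @param guide the guide haplotype.
#' @param gap_policy "guide" or "N".
#' @return a `consensus_assembly`: list(guide_id, consensus, unplaced,
#'   gap_mask).  `gap_mask` intervals partition the consensus into
#'   assembled (uppercase) and filled stretches.
#' @export
emit_consensus <- function(placements, contigs, guide,
                           gap_policy = c("guide", "N")) {
  gap_policy <- match.arg(gap_policy)
  glen <- nchar(guide$sequence)
  unplaced_ids <- setdiff(contigs$id, placements$contig_id)
  if (nrow(placements) == 0L) {
    warning("no placements at all; consensus is empty")
    return(structure(list(guide_id = guide$id, consensus = "",
                          unplaced = contigs,
                          gap_mask = data.frame()),
                     class = "consensus_assembly"))
  }
  # claim guide intervals in priority order
  pr <- placements[order(-placements$location_score, -placements$qlen,
                         placements$contig_id), , drop = FALSE]
  claimed <- data.frame(start = numeric(0), end = numeric(0))
  pieces <- list()
  displaced <- character(0)
  alt_records <- list()
  for (i in seq_len(nrow(pr))) {
    s <- pr$start[i]; e <- pr$end[i]
    if (e <= s) { displaced <- c(displaced, pr$contig_id[i]); next }
    # subtract claimed intervals; a placement may contribute several free
    # sub-intervals (e.g. a long chain interrupted by a small
    # higher-priority allele piece)
    subs <- data.frame(start = s, end = e)
    if (nrow(claimed) > 0) {
      ov <- claimed[claimed$end > s & claimed$start < e, , drop = FALSE]
      if (nrow(ov) > 0) {
        bounds <- sort(unique(c(s, e, pmax(pmin(c(ov$start, ov$end), e), s))))
        subs <- data.frame(start = bounds[-length(bounds)], end = bounds[-1])
        free <- vapply(seq_len(nrow(subs)), function(j) {
          mid <- (subs$start[j] + subs$end[j]) / 2
          !any(claimed$start <= mid & claimed$end > mid)
        }, logical(1))
        subs <- subs[free & subs$end - subs$start >= 10, , drop = FALSE]
      }
    }
    if (nrow(subs) == 0L) {
      displaced <- c(displaced, pr$contig_id[i])
      next
    }
    # displaced portions of this placement (>= 100 bp) become alternate
    # records so the losing allele stays discoverable
    lost <- list()
    prev_end <- s
    for (j in seq_len(nrow(subs))) {
      if (subs$start[j] - prev_end >= 100)
        lost[[length(lost) + 1L]] <- c(prev_end, subs$start[j])
      prev_end <- subs$end[j]
    }
    if (e - prev_end >= 100) lost[[length(lost) + 1L]] <- c(prev_end, e)
    for (lv in lost) {
      sq <- oriented_seq(contigs, pr$contig_id[i], pr$strand[i])
      qs <- max(0, round(lv[1] - pr$offset[i]))
      qe <- min(nchar(sq), round(lv[2] - pr$offset[i]))
      if (qe - qs >= 100)
        alt_records[[length(alt_records) + 1L]] <- data.frame(
          id = sprintf("%s|alt:%d-%d", pr$contig_id[i], qs, qe),
          sequence = substr(sq, qs + 1, qe), mean_cov = NA_real_,
          source_bin = "ALT", stringsAsFactors = FALSE)
    }
    for (j in seq_len(nrow(subs))) {
      claimed <- rbind(claimed,
                       data.frame(start = subs$start[j], end = subs$end[j]))
      pieces[[length(pieces) + 1L]] <- data.frame(
        contig_id = pr$contig_id[i], start = subs$start[j],
        end = subs$end[j], strand = pr$strand[i], offset = pr$offset[i],
        stringsAsFactors = FALSE)
    }
  }
  pieces <- do.call(rbind, pieces)
  pieces <- pieces[order(pieces$start), , drop = FALSE]

  # local anchor diagonals per placed contig (oriented), for snapping
  # claim-junction cuts: a single global offset misplaces cuts beyond
  # internal indels
  piece_ids <- unique(pieces$contig_id)
  oseqs <- vapply(seq_along(piece_ids), function(j) {
    st <- pieces$strand[match(piece_ids[j], pieces$contig_id)]
    oriented_seq(contigs, piece_ids[j], st)
  }, character(1))
  loc_anch <- cpp_anchor_map(oseqs, guide$sequence, 21L, 4L, 1L)
  loc_anch <- loc_anch[loc_anch$strand > 0, , drop = FALSE]
  local_cut <- function(cid, gpos, global_off) {
    j <- match(cid, piece_ids)
    a <- loc_anch[loc_anch$query == j, , drop = FALSE]
    if (nrow(a) == 0L) return(gpos - global_off)
    dg <- a$tpos - a$qpos
    a <- a[abs(dg - global_off) <= 500, , drop = FALSE]
    dg <- dg[abs(dg - global_off) <= 500]
    if (length(dg) == 0L) return(gpos - global_off)
    i <- which.min(abs(a$tpos - gpos))
    gpos - dg[i]
  }

  parts <- character(0)
  mask <- list()
  cons_pos <- 0
  cur <- 0
  add_mask <- function(type, n, gs, ge, cid = NA_character_) {
    mask[[length(mask) + 1L]] <<- data.frame(
      cons_start = cons_pos, cons_end = cons_pos + n, type = type,
      guide_start = gs, guide_end = ge, contig_id = cid,
      stringsAsFactors = FALSE)
    cons_pos <<- cons_pos + n
  }
  fill <- function(gs, ge) {
    n <- ge - gs
    if (n <= 0) return()
    sq <- if (gap_policy == "guide")
      tolower(substr(guide$sequence, gs + 1, ge))
    else paste(rep("N", n), collapse = "")
    parts <<- c(parts, sq)
    add_mask("filled", n, gs, ge)
  }
  for (i in seq_len(nrow(pieces))) {
    p <- pieces[i, ]
    if (p$start > cur) fill(cur, p$start)
    sq <- oriented_seq(contigs, p$contig_id, p$strand)
    qlen <- nchar(sq)
    qs <- max(0, round(local_cut(p$contig_id, p$start, p$offset)))
    qe <- min(qlen, round(local_cut(p$contig_id, p$end, p$offset)))
    if (qe <= qs) { cur <- max(cur, p$end); next }
    sub <- toupper(substr(sq, qs + 1, qe))
    parts <- c(parts, sub)
    add_mask("assembled", nchar(sub), p$start, p$end, p$contig_id)
    cur <- p$end
  }
  if (cur < glen) fill(cur, glen)
  consensus <- paste(parts, collapse = "")
  unplaced <- contigs[contigs$id %in% c(unplaced_ids, displaced), ,
                      drop = FALSE]
  if (length(alt_records) > 0)
    unplaced <- rbind(unplaced[, c("id", "sequence", "mean_cov",
                                   "source_bin")],
                      do.call(rbind, alt_records))
  res <- structure(list(guide_id = guide$id, consensus = consensus,
                        unplaced = unplaced,
                        gap_mask = do.call(rbind, mask)),
                   class = "consensus_assembly")
  if (nchar(consensus) < 0.5 * glen || nchar(consensus) > 1.5 * glen)
    warning("consensus length outside [0.5, 1.5] x guide length")
  res
}

#' @export
print.consensus_assembly <- function(x, ...) {
  filled <- if (!is.null(x$gap_mask) && nrow(x$gap_mask) > 0)
    sum(x$gap_mask$cons_end[x$gap_mask$type == "filled"] -
          x$gap_mask$cons_start[x$gap_mask$type == "filled"]) else 0
  cat(sprintf(
    "<consensus_assembly> guide %s: %d bp consensus (%d filled), %d unplaced records\n",
    x$guide_id, nchar(x$consensus), as.integer(filled), nrow(x$unplaced)))
  invisible(x)
}

#' All sequence records of a consensus assembly
#'
#' The continuous consensus plus the unplaced contig records, as written to
#' the output FASTA.
#' @param x a `consensus_assembly`.
#' @export
consensus_records <- function(x) {
  recs <- setNames(x$consensus, paste0(x$guide_id, "_consensus"))
  if (!is.null(x$unplaced) && nrow(x$unplaced) > 0)
    recs <- c(recs, setNames(x$unplaced$sequence,
                             paste0("unplaced_", x$unplaced$id)))
  recs
}

#' Write a consensus assembly to FASTA
#' @param x a `consensus_assembly`.
#' @param path output path.
#' @export
write_consensus_fasta <- function(x, path) {
  write_fasta(consensus_records(x), path)
}
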