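# De Bruijn assembly of read bins, graph cleaning, cross-haplotype contig
# filtering, overlap merging into supercontigs, and pileup polishing.

#' Assembly parameters
#'
#' @param k odd kmer size in \[15, 127\] (default 51).
#' @param min_kmer_cov minimum kmer multiplicity kept in the graph.
#' @param tip_len_max dead-end paths shorter than this are clipped
#'   (default `2 * k`).
#' @param bubble_identity simple bubbles at least this similar are popped,
#'   keeping the higher-coverage path (default 0.95).
#' @param min_contig_len contigs shorter than this are dropped.  Default
#'   `floor(1.5 * k)`: low enough that single-junction allele fragments
#'   (nominal length `2(k-1)` bp, occasionally shorter by chance matches at
#'   the junction) survive into the output, high enough to drop sub-kmer
#'   noise.
#' @param max_rounds cleaning iteration cap.
#' @return an `assembly_params` list.
#' @export
assembly_params <- function(k = 51L, min_kmer_cov = 3L, tip_len_max = 2L * k,
                            bubble_identity = 0.95,
                            min_contig_len = floor(1.5 * k),
                            max_rounds = 20L) {
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 15L || k > 63L)
    stop("k must be odd and within [15, 63]")
  if (min_kmer_cov < 1L) stop("min_kmer_cov must be >= 1")
  structure(list(k = k, min_kmer_cov = as.integer(min_kmer_cov),
                 tip_len_max = as.integer(tip_len_max),
                 bubble_identity = bubble_identity,
                 min_contig_len = as.integer(min_contig_len),
                 max_rounds = as.integer(max_rounds)),
            class = "assembly_params")
}

#' Count canonical kmers in a read set
#'
#' Strand-collapsed kmer multiset; the total count equals the sum over
#' reads of `max(0, length - k + 1)` (N-free windows).
#'
#' @param reads character vector of read sequences.
#' @param k kmer size (<= 63).
#' @return data frame with columns `kmer` and `count`.
#' @export
count_kmers <- function(reads, k) {
  if (k > max(nchar(reads)))
    warning("k exceeds every read length; empty kmer multiset")
  x <- cpp_kmer_counts(reads, as.integer(k))
  data.frame(kmer = x$kmer, count = x$count, stringsAsFactors = FALSE)
}

#' Estimate the best assembly kmer size from candidates
#'
#' Returns the candidate maximizing the number of distinct "solid" kmers
#' (multiplicity >= `min_cov`), a simplified analogue of spectrum-based
#' kmer-size estimators; ties resolve to the larger k (larger k keeps
#' assembly time linear in read count).
#'
#' @param reads character vector of read sequences.
#' @param k_candidates odd candidate kmer sizes.
#' @param min_cov solidity threshold (default 3).
#' @export
estimate_best_k <- function(reads, k_candidates, min_cov = 3L) {
  if (length(reads) == 0L) stop("no reads")
  if (length(k_candidates) < 1L) stop("at least one candidate is required")
  if (any(k_candidates %% 2L == 0L)) stop("candidates must be odd")
  if (all(k_candidates > max(nchar(reads))))
    stop("all candidates exceed the read length")
  solid <- vapply(k_candidates, function(k)
    cpp_distinct_solid(reads, as.integer(k), as.integer(min_cov)),
    numeric(1))
  best <- max(solid)
  as.integer(max(k_candidates[solid == best]))
}

#' Build and clean the de Bruijn kmer graph
#'
#' Kmers below `min_kmer_cov` are removed; short dead-end paths (tips) are
#' clipped iteratively; simple bubbles at least `bubble_identity` similar
#' are popped keeping the higher-coverage path.
#'
#' @param reads character vector of read sequences.
#' @param params an [assembly_params()] object.
#' @return a `kmer_graph` object (cleaned unitigs plus parameters).
#' @export
build_and_clean <- function(reads, params = assembly_params()) {
  res <- cpp_assemble(reads, params$k, params$min_kmer_cov,
                      params$tip_len_max, params$bubble_identity,
                      params$max_rounds)
  structure(list(sequence = res$sequence, mean_cov = res$mean_cov,
                 params = params),
            class = "kmer_graph")
}

#' @export
print.kmer_graph <- function(x, ...) {
  cat(sprintf("<kmer_graph> k=%d, %d unitigs, %.0f bp\n", x$params$k,
              length(x$sequence), sum(nchar(x$sequence))))
  invisible(x)
}

#' Extract contigs from a cleaned kmer graph
#'
#' One contig per maximal unbranched path, canonical strand, ordered by
#' length (desc) then sequence; contigs shorter than `min_contig_len` are
#' dropped; `mean_cov` is the mean kmer multiplicity along the path.
#'
#' @param graph a [build_and_clean()] result.
#' @param params assembly parameters (defaults to the graph's).
#' @param source_bin label recorded on the contigs ("MAPPED:<superblock>" or
#'   "UNMAPPED").
#' @param prefix contig id prefix.
#' @return contig data frame: id, sequence, mean_cov, source_bin.
#' @export
extract_contigs <- function(graph, params = graph$params,
                            source_bin = "MAPPED", prefix = "contig") {
  keep <- nchar(graph$sequence) >= params$min_contig_len
  seqs <- graph$sequence[keep]
  covs <- graph$mean_cov[keep]
  if (length(seqs) == 0L)
    return(data.frame(id = character(0), sequence = character(0),
                      mean_cov = numeric(0), source_bin = character(0),
                      stringsAsFactors = FALSE))
  data.frame(id = sprintf("%s%04d", prefix, seq_along(seqs)),
             sequence = seqs, mean_cov = covs, source_bin = source_bin,
             stringsAsFactors = FALSE)
}

#' Assemble one read bin into contigs
#'
#' Convenience wrapper: [build_and_clean()] then [extract_contigs()].
#' @inheritParams build_and_clean
#' @inheritParams extract_contigs
#' @export
assemble_bin <- function(reads, params = assembly_params(),
                         source_bin = "MAPPED", prefix = "contig") {
  extract_contigs(build_and_clean(reads, params), params, source_bin, prefix)
}

parse_cigar <- function(cig) {
  if (is.null(cig) || !nzchar(cig))
    return(data.frame(len = integer(0), op = character(0)))
  len <- as.integer(regmatches(cig, gregexpr("[0-9]+", cig))[[1]])
  op <- regmatches(cig, gregexpr("[=XIDM]", cig))[[1]]
  data.frame(len = len, op = op, stringsAsFactors = FALSE)
}

cigar_stats <- function(cig) {
  p <- parse_cigar(cig)
  list(matches = sum(p$len[p$op == "="]),
       alnlen = sum(p$len),
       qlen = sum(p$len[p$op %in% c("=", "X", "I")]),
       tlen = sum(p$len[p$op %in% c("=", "X", "D")]),
       indel_bp = sum(p$len[p$op %in% c("I", "D")]))
}

# Best anchor cluster of query-vs-target anchors for one query.
# Returns NULL or list(strand, d (offset of query start on target),
# qmin, qmax, tmin, tmax, n).
best_anchor_cluster <- function(anch, k, qlen, tol = 100) {
  if (nrow(anch) == 0L) return(NULL)
  best <- NULL
  for (s in unique(anch$strand)) {
    a <- anch[anch$strand == s, , drop = FALSE]
    # '+': offset of query start on target; '-': offset of rc(query) start
    d <- if (s > 0) a$tpos - a$qpos else a$tpos + a$qpos + k - qlen
    o <- order(d)
    d <- d[o]; a <- a[o, , drop = FALSE]
    grp <- cumsum(c(TRUE, diff(d) > tol))
    for (g in unique(grp)) {
      sel <- grp == g
      if (is.null(best) || sum(sel) > best$n) {
        aa <- a[sel, , drop = FALSE]
        best <- list(strand = s, d = stats::median(d[sel]),
                     qmin = min(aa$qpos), qmax = max(aa$qpos),
                     tmin = min(aa$tpos), tmax = max(aa$tpos),
                     n = sum(sel))
      }
    }
  }
  best
}

#' Remove unmapped-bin contigs that belong to the alternative haplotype or
#' a decoy
#'
#' A contig is removed when at least `min_frac` of its length aligns to the
#' alternative guide or to a decoy sequence at `min_ident` identity or
#' better.
#'
#' @param contigs contig data frame (from the unmapped bin).
#' @param alt_guide alternative [guide_haplotype()] or `NULL`.
#' @param decoy named character vector of decoy sequences or `NULL`.
#' @param min_frac minimum aligned length fraction (default 0.5).
#' @param min_ident minimum identity (default 0.9).
#' @return the retained contigs.
#' @export
filter_cross_contigs <- function(contigs, alt_guide = NULL, decoy = NULL,
                                 min_frac = 0.5, min_ident = 0.9) {
  if (nrow(contigs) == 0L) return(contigs)
  refs <- character(0)
  if (!is.null(alt_guide)) refs <- c(refs, alt_guide$sequence)
  if (!is.null(decoy)) refs <- c(refs, unname(decoy))
  if (length(refs) == 0L) return(contigs)
  drop <- rep(FALSE, nrow(contigs))
  for (r in refs) {
    anch <- cpp_anchor_map(contigs$sequence, r, 15L, 32L, 1L)
    for (i in which(!drop)) {
      a <- anch[anch$query == i, , drop = FALSE]
      qlen <- nchar(contigs$sequence[i])
      cl <- best_anchor_cluster(a, 15L, qlen)
      if (is.null(cl)) next
      span <- cl$qmax - cl$qmin + 15L
      if (span < min_frac * qlen) next
      qseq <- contigs$sequence[i]
      if (cl$strand < 0) {
        qseq <- revcomp(qseq)
        qs <- qlen - (cl$qmax + 15L); qe <- qlen - cl$qmin
      } else {
        qs <- cl$qmin; qe <- cl$qmax + 15L
      }
      ts <- max(0, cl$tmin); te <- min(nchar(r), cl$tmax + 15L)
      al <- cpp_banded_align(substr(qseq, qs + 1L, qe),
                             substr(r, ts + 1L, te), 50L, 6L, 5L, 3L, FALSE)
      if (!isTRUE(al$ok)) next
      st <- cigar_stats(al$cigar)
      if (st$qlen >= min_frac * qlen && st$matches / st$alnlen >= min_ident)
        drop[i] <- TRUE
    }
  }
  contigs[!drop, , drop = FALSE]
}

# Verified overlap/containment between two oriented sequences.
# Returns NULL, or list(kind = "contain"/"join", ...).
verify_relation <- function(qseq, tseq, cl, k, min_overlap, min_identity) {
  qlen <- nchar(qseq); tlen <- nchar(tseq)
  orient <- if (cl$strand < 0) "-" else "+"
  if (orient == "-") qseq <- revcomp(qseq)
  d <- round(cl$d)  # offset of the (oriented) query start on the target
  pad <- 25L
  if (d >= -pad && d + qlen <= tlen + pad) {
    # containment candidate: q inside t
    ts <- max(0L, d); te <- min(tlen, d + qlen)
    al <- cpp_banded_align(qseq, substr(tseq, ts + 1L, te), 40L, 6L, 5L, 3L,
                           FALSE)
    if (isTRUE(al$ok)) {
      st <- cigar_stats(al$cigar)
      # gap-aware: a piece carrying a divergent indel allele is NOT a
      # redundant copy and must survive
      if (st$matches >= min_identity * qlen && st$indel_bp <= 2L)
        return(list(kind = "contain"))
    }
    return(NULL)
  }
  if (d <= pad && d + qlen >= tlen - pad && qlen > tlen) {
    # reverse containment: t inside q
    qs <- max(0L, -d); qe <- min(qlen, -d + tlen)
    al <- cpp_banded_align(tseq, substr(qseq, qs + 1L, qe), 40L, 6L, 5L, 3L,
                           FALSE)
    if (isTRUE(al$ok)) {
      st <- cigar_stats(al$cigar)
      if (st$matches >= min_identity * tlen && st$indel_bp <= 2L)
        return(list(kind = "contain_t"))
    }
    return(NULL)
  }
  if (d > 0 && d < tlen) {
    ov <- tlen - d            # t suffix overlaps q prefix: t then q
    if (ov >= min_overlap && ov <= qlen) {
      al <- cpp_banded_align(substr(qseq, 1L, ov),
                             substr(tseq, d + 1L, tlen), 30L, 6L, 5L, 3L,
                             FALSE)
      if (isTRUE(al$ok)) {
        st <- cigar_stats(al$cigar)
        if (st$matches / st$alnlen >= min_identity)
          return(list(kind = "join", left = "t", ov = ov, orient = orient,
                      ident = st$matches / st$alnlen))
      }
    }
    return(NULL)
  }
  if (d < 0) {
    ov <- qlen + d            # q suffix overlaps t prefix: q then t
    if (ov >= min_overlap && ov <= tlen) {
      al <- cpp_banded_align(substr(qseq, qlen - ov + 1L, qlen),
                             substr(tseq, 1L, ov), 30L, 6L, 5L, 3L, FALSE)
      if (isTRUE(al$ok)) {
        st <- cigar_stats(al$cigar)
        if (st$matches / st$alnlen >= min_identity)
          return(list(kind = "join", left = "q", ov = ov, orient = orient,
                      ident = st$matches / st$alnlen))
      }
    }
  }
  NULL
}

#' Merge overlapping contigs into non-redundant supercontigs
#'
#' Greedy overlap-layout merge: suffix-prefix overlaps of at least
#' `min_overlap` bp at `min_identity` or better are joined longest first;
#' contigs near-identically contained in another collapse to the container;
#' the output has no remaining qualifying overlaps.
#'
#' @param contigs contig data frame.
#' @param min_overlap minimum end overlap in bp (default 40).
#' @param min_identity minimum overlap identity (default 0.99).
#' @return supercontig data frame (id, sequence, mean_cov, source_bin).
#' @export
merge_contigs <- function(contigs, min_overlap = 40L, min_identity = 0.99) {
  n <- nrow(contigs)
  if (n <= 1L) return(contigs)
  k <- 31L
  seqs <- contigs$sequence
  covs <- contigs$mean_cov
  bins <- contigs$source_bin
  alive <- rep(TRUE, n)

  # pass 1: relations from pairwise anchors (target = i, queries = all)
  rels <- list()
  for (i in seq_len(n)) {
    anch <- cpp_anchor_map(seqs, seqs[i], k, 8L, 1L)
    anch <- anch[anch$query != i, , drop = FALSE]
    for (j in unique(anch$query)) {
      if (j < i) next  # each unordered pair once (i as target)
      a <- anch[anch$query == j, , drop = FALSE]
      cl <- best_anchor_cluster(a, k, nchar(seqs[j]))
      if (is.null(cl) || cl$n < 2) next
      rel <- verify_relation(seqs[j], seqs[i], cl, k, min_overlap,
                             min_identity)
      if (!is.null(rel)) {
        rel$t <- i; rel$q <- j
        rels[[length(rels) + 1L]] <- rel
      }
    }
  }

  # containments: drop the contained contig (the shorter of the pair)
  for (rel in rels) {
    if (!alive[rel$q] || !alive[rel$t]) next
    if (rel$kind == "contain") alive[rel$q] <- FALSE
    if (rel$kind == "contain_t") alive[rel$t] <- FALSE
  }

  # end-joins: greedy by overlap length; each contig end used once
  joins <- Filter(function(r) r$kind == "join" && alive[r$q] && alive[r$t],
                  rels)
  if (length(joins) > 0) {
    ordj <- order(-vapply(joins, `[[`, numeric(1), "ov"),
                  -vapply(joins, `[[`, numeric(1), "ident"))
    joins <- joins[ordj]
  }
  # ends: for contig c in its own orientation: "L" and "R"
  used <- matrix(FALSE, n, 2, dimnames = list(NULL, c("L", "R")))
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  edges <- list()
  for (e in joins) {
    # orient +: join t.R -> q.L ; orient -: q is reverse-complemented,
    # so its joining end flips
    if (e$left == "t") {
      ta <- e$t; ea <- "R"
      tb <- e$q; eb <- if (e$orient == "+") "L" else "R"
    } else {
      ta <- e$q; ea <- if (e$orient == "+") "R" else "L"
      tb <- e$t; eb <- "L"
    }
    if (!alive[ta] || !alive[tb]) next
    if (used[ta, ea] || used[tb, eb]) next
    if (find(ta) == find(tb)) next  # would close a cycle
    used[ta, ea] <- TRUE
    used[tb, eb] <- TRUE
    parent[find(ta)] <- find(tb)
    edges[[length(edges) + 1L]] <- list(a = ta, ea = ea, b = tb, eb = eb,
                                        ov = e$ov)
  }

  # build chains
  adj <- vector("list", n)
  for (e in edges) {
    adj[[e$a]] <- c(adj[[e$a]], list(e))
    adj[[e$b]] <- c(adj[[e$b]], list(e))
  }
  visited <- rep(FALSE, n)
  out <- list()
  for (s in seq_len(n)) {
    if (!alive[s] || visited[s]) next
    if (length(adj[[s]]) >= 2L) next  # start from chain ends only
    # walk the chain
    chain <- list()
    cur <- s
    enter_end <- if (length(adj[[s]]) == 0L) NA_character_ else {
      e <- adj[[s]][[1L]]
      # the end NOT used by the single edge is the entry
      uend <- if (e$a == s) e$ea else e$eb
      if (uend == "L") "R" else "L"
    }
    prev_edge <- NULL
    repeat {
      visited[cur] <- TRUE
      orient <- if (is.na(enter_end) || enter_end == "L") "+" else "-"
      chain[[length(chain) + 1L]] <- list(idx = cur, orient = orient,
                                          ov_in = if (is.null(prev_edge)) 0L
                                                  else prev_edge$ov)
      exit_end <- if (orient == "+") "R" else "L"
      nxt <- NULL
      for (e in adj[[cur]]) {
        if (identical(e, prev_edge)) next
        uend <- if (e$a == cur) e$ea else e$eb
        if (uend == exit_end) { nxt <- e; break }
      }
      if (is.null(nxt)) break
      prev_edge <- nxt
      nxt_idx <- if (nxt$a == cur) nxt$b else nxt$a
      enter_end <- if (nxt$a == cur) nxt$eb else nxt$ea
      cur <- nxt_idx
    }
    # concatenate
    segs <- character(0)
    covw <- 0; lenw <- 0
    binset <- character(0)
    for (ci in seq_along(chain)) {
      el <- chain[[ci]]
      sq <- seqs[el$idx]
      if (el$orient == "-") sq <- revcomp(sq)
      if (el$ov_in > 0) sq <- substr(sq, el$ov_in + 1L, nchar(sq))
      segs <- c(segs, sq)
      covw <- covw + covs[el$idx] * nchar(seqs[el$idx])
      lenw <- lenw + nchar(seqs[el$idx])
      binset <- union(binset, bins[el$idx])
    }
    out[[length(out) + 1L]] <- data.frame(
      sequence = paste(segs, collapse = ""), mean_cov = covw / lenw,
      source_bin = paste(sort(binset), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(-nchar(res$sequence), res$sequence), , drop = FALSE]
  data.frame(id = sprintf("supercontig%04d", seq_len(nrow(res))),
             sequence = res$sequence, mean_cov = res$mean_cov,
             source_bin = res$source_bin, stringsAsFactors = FALSE)
}

#' Polish contigs with a read pileup
#'
#' Reads are realigned to the contigs; a column is rewritten to the
#' majority allele when depth >= `min_depth` and the majority fraction is
#' >= `min_frac`; small insertions and deletions are corrected under the
#' same rule.  A column already matching the pileup majority is never
#' changed.
#'
#' @param contigs contig data frame.
#' @param pairs the individual's QC-surviving `read_pairs`.
#' @param min_depth minimum pileup depth (default 5).
#' @param min_frac minimum majority fraction (default 0.7).
#' @param k_seed,band mapper parameters.
#' @return list with `contigs` (polished) and `corrections` (report).
#' @export
polish_contigs <- function(contigs, pairs, min_depth = 5L, min_frac = 0.7,
                           k_seed = 21L, band = 40L) {
  if (nrow(contigs) == 0L)
    return(list(contigs = contigs,
                corrections = data.frame(contig = character(0))))
  reads <- c(pairs$seq1, pairs$seq2)
  res <- cpp_polish(contigs$sequence, reads, k_seed, 3L, band, 6L, 5L, 3L,
                    -0.6, 64L, as.integer(min_depth), min_frac)
  out <- contigs
  out$sequence <- res$sequence
  corr <- res$corrections
  if (nrow(corr) > 0) corr$contig <- contigs$id[corr$contig]
  list(contigs = out, corrections = corr)
}
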