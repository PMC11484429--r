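# Synthetic guide haplotypes, diploid truth haplotypes with variant ledgers,
# and Illumina-like paired reads.  The generator emulates the validation
# inputs of the assembly method: a set of guide haplotypes that differ by a
# large class-II-like insertion block, diploid individuals carrying novel
# SNVs/INDELs relative to their guides, and 150 bp paired reads at 30-60x
# with fragment length 426 +/- 109.

#' Construct a guide haplotype object
#'
#' @param id guide identifier.
#' @param sequence DNA string (A/C/G/T).
#' @param dr_class structural class label (e.g. "SHORT", "LONG", "FALLBACK").
#' @param class_insert_interval 0-based half-open interval of the
#'   class-defining insertion block, or `NULL` when the class has none.
#' @return an object of class `guide_haplotype`.
#' @export
guide_haplotype <- function(id, sequence, dr_class,
                            class_insert_interval = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nchar(sequence) > 0L)
  if (grepl("[^ACGT]", sequence))
    stop("guide sequence must contain only A/C/G/T")
  if (!is.null(class_insert_interval)) {
    stopifnot(length(class_insert_interval) == 2L,
              class_insert_interval[1] >= 0,
              class_insert_interval[2] <= nchar(sequence),
              class_insert_interval[1] < class_insert_interval[2])
  }
  structure(list(id = id, sequence = sequence, dr_class = dr_class,
                 class_insert_interval = class_insert_interval),
            class = "guide_haplotype")
}

#' @export
print.guide_haplotype <- function(x, ...) {
  cat(sprintf("<guide_haplotype> %s [%s], %d bp", x$id, x$dr_class,
              nchar(x$sequence)))
  if (!is.null(x$class_insert_interval))
    cat(sprintf(", class insert [%d,%d)", x$class_insert_interval[1],
                x$class_insert_interval[2]))
  cat("\n")
  invisible(x)
}

# Place n non-overlapping intervals of the given lengths inside [lo, hi),
# with a small buffer, by rejection sampling.  Returns 0-based starts.
place_intervals <- function(lens, lo, hi, occupied = NULL, buffer = 2L,
                            max_tries = 2000L) {
  starts <- integer(0)
  occ <- occupied
  for (len in lens) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      s <- sample.int(hi - lo - len, 1L) + lo - 1L
      e <- s + len
      ok <- TRUE
      if (!is.null(occ) && nrow(occ) > 0) {
        ok <- all(e + buffer <= occ$start | s >= occ$end + buffer)
      }
      if (ok) {
        occ <- rbind(occ, data.frame(start = s, end = e))
        starts <- c(starts, s)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place a feature interval without overlap")
  }
  list(starts = starts, occupied = occ)
}

# Write repeat-bearing features into a character vector `ch` (1-based
# indexing); returns list(ch, bed rows).
embed_repeats <- function(ch, lo, hi, n_homopolymer = 5L, n_str = 5L,
                          n_dispersed = 3L, dispersed_len = 300L,
                          dispersed_divergence = 0.03, segdup_len = 4000L,
                          segdup_divergence = 0.001) {
  bed <- data.frame(start = integer(0), end = integer(0),
                    type = character(0), stringsAsFactors = FALSE)
  occ <- NULL

  add_bed <- function(s, e, ty) {
    bed <<- rbind(bed, data.frame(start = s, end = e, type = ty,
                                  stringsAsFactors = FALSE))
  }

  # near-identical tandem segmental duplication (C4A/C4B analogue)
  if (segdup_len > 0) {
    pl <- place_intervals(2L * segdup_len, lo, hi, occ)
    occ <- pl$occupied
    s <- pl$starts[1]
    copy1 <- ch[(s + 1):(s + segdup_len)]
    nsub <- max(1L, round(segdup_len * segdup_divergence))
    idx <- sample.int(segdup_len, nsub)
    copy2 <- copy1
    for (i in idx) copy2[i] <- sample(setdiff(DNA_BASES, copy1[i]), 1L)
    ch[(s + segdup_len + 1):(s + 2L * segdup_len)] <- copy2
    add_bed(s, s + segdup_len, "segdup")
    add_bed(s + segdup_len, s + 2L * segdup_len, "segdup")
  }

  # dispersed repeat family
  if (n_dispersed >= 2L) {
    pl <- place_intervals(rep(dispersed_len, n_dispersed), lo, hi, occ)
    occ <- pl$occupied
    src <- pl$starts[1]
    elem <- ch[(src + 1):(src + dispersed_len)]
    add_bed(src, src + dispersed_len, "dispersed")
    for (j in 2:n_dispersed) {
      s <- pl$starts[j]
      cp <- elem
      nsub <- max(1L, round(dispersed_len * dispersed_divergence))
      for (i in sample.int(dispersed_len, nsub))
        cp[i] <- sample(setdiff(DNA_BASES, elem[i]), 1L)
      ch[(s + 1):(s + dispersed_len)] <- cp
      add_bed(s, s + dispersed_len, "dispersed")
    }
  }

  # short tandem repeats
  for (j in seq_len(n_str)) {
    p <- sample(2:6, 1L)
    copies <- sample(8:20, 1L)
    len <- p * copies
    pl <- place_intervals(len, lo, hi, occ)
    occ <- pl$occupied
    s <- pl$starts[1]
    unit <- sample(DNA_BASES, p, replace = TRUE)
    ch[(s + 1):(s + len)] <- rep(unit, copies)
    add_bed(s, s + len, "tandem")
  }

  # homopolymer tracts
  for (j in seq_len(n_homopolymer)) {
    len <- sample(15:25, 1L)
    pl <- place_intervals(len, lo, hi, occ)
    occ <- pl$occupied
    s <- pl$starts[1]
    ch[(s + 1):(s + len)] <- sample(DNA_BASES, 1L)
    add_bed(s, s + len, "homopolymer")
  }
  list(ch = ch, bed = bed)
}

#' Generate a set of guide haplotypes sharing a common backbone
#'
#' All guides share one randomly generated backbone containing configurable
#' repeat tracts (homopolymers, short tandem repeats, a dispersed repeat
#' family) and one near-identical tandem segmental duplication pair that
#' emulates the C4A/C4B locus.  Classes with a positive insertion length
#' additionally carry a class-defining insertion block at a common locus,
#' emulating the extra sequence content that distinguishes the long HLA
#' class II structural haplotypes.  Per-guide point divergence from the
#' backbone is optional (`class_divergence`, default 0).
#'
#' @param seed integer seed; the same seed yields a byte-identical set.
#' @param base_length backbone length in bp (>= 20 kb).
#' @param classes named numeric vector of class insertion lengths, e.g.
#'   `c(SHORT = 0, LONG = 20000)`.
#' @param class_divergence per-bp substitution rate of guide-private point
#'   divergence from the backbone (default 0).
#' @param insert_pos_frac fractional backbone position of the insertion locus.
#' @param segdup_len length of each segmental-duplication copy (0 disables).
#' @param segdup_divergence divergence between the two copies (default 0.001,
#'   i.e. 99.9% identity).
#' @return an object of class `guide_set`: a named list of
#'   [guide_haplotype()] objects with attributes `repeat_bed` (a data frame
#'   of per-guide repeat intervals, 0-based half-open) and `insert_pos`
#'   (backbone coordinate of the insertion locus).
#' @export
make_guide_set <- function(seed, base_length, classes,
                           class_divergence = 0,
                           insert_pos_frac = 0.6,
                           segdup_len = 4000L, segdup_divergence = 0.001) {
  if (length(classes) < 1L) stop("at least one class spec is required")
  if (base_length < 20000) stop("base_length must be >= 20 kb")
  if (any(classes < 0) || base_length <= 0)
    stop("lengths must be non-negative")
  if (any(classes >= base_length / 2))
    stop("class insertion lengths must be < base_length/2")
  if (is.null(names(classes)) || any(!nzchar(names(classes))))
    stop("classes must be a named vector of insertion lengths")

  with_seed(seed, {
    ch <- sample(DNA_BASES, base_length, replace = TRUE)
    margin <- max(1000L, segdup_len %/% 4L)
    emb <- embed_repeats(ch, lo = margin, hi = base_length - margin,
                         segdup_len = segdup_len,
                         segdup_divergence = segdup_divergence)
    ch <- emb$ch
    backbone <- paste(ch, collapse = "")
    bed_bb <- emb$bed
    ipos <- floor(base_length * insert_pos_frac)
    # keep the insertion locus clear of backbone features
    while (nrow(bed_bb) > 0 &&
           any(ipos > bed_bb$start - 200 & ipos < bed_bb$end + 200)) {
      ipos <- ipos + 250L
    }

    guides <- list()
    bed_all <- data.frame()
    for (cls in names(classes)) {
      ins_len <- as.integer(classes[[cls]])
      gid <- paste0("guide_", cls)
      if (ins_len > 0) {
        ins_ch <- sample(DNA_BASES, ins_len, replace = TRUE)
        ins_emb <- embed_repeats(ins_ch, lo = 200L, hi = ins_len - 200L,
                                 n_homopolymer = 2L, n_str = 2L,
                                 n_dispersed = 0L, segdup_len = 0L)
        ins_seq <- paste(ins_emb$ch, collapse = "")
        seq <- paste0(substr(backbone, 1, ipos), ins_seq,
                      substr(backbone, ipos + 1, base_length))
        interval <- c(ipos, ipos + ins_len)
        bed_g <- bed_bb
        shift <- bed_g$start >= ipos
        bed_g$start[shift] <- bed_g$start[shift] + ins_len
        bed_g$end[shift] <- bed_g$end[shift] + ins_len
        bed_ins <- ins_emb$bed
        if (nrow(bed_ins) > 0) {
          bed_ins$start <- bed_ins$start + ipos
          bed_ins$end <- bed_ins$end + ipos
        }
        bed_g <- rbind(bed_g, bed_ins)
      } else {
        seq <- backbone
        interval <- NULL
        bed_g <- bed_bb
      }
      div_pos <- integer(0)
      if (class_divergence > 0) {
        n_div <- rbinom(1L, nchar(seq), class_divergence)
        if (n_div > 0) {
          div_pos <- sort(sample.int(nchar(seq), n_div))
          seq <- substitute_bases(seq, div_pos)
        }
      }
      g <- guide_haplotype(gid, seq, cls, interval)
      attr(g, "private_div") <- div_pos - 1L
      guides[[gid]] <- g
      if (nrow(bed_g) > 0) {
        bed_g <- data.frame(guide_id = gid, bed_g[order(bed_g$start), ],
                            stringsAsFactors = FALSE)
        bed_all <- rbind(bed_all, bed_g)
      }
    }
    structure(guides, class = "guide_set", repeat_bed = bed_all,
              insert_pos = ipos, backbone_length = base_length)
  })
}

#' Repeat annotation of a guide set
#'
#' @param guides a [make_guide_set()] result.
#' @return data frame of 0-based half-open repeat intervals per guide.
#' @export
guide_repeat_bed <- function(guides) attr(guides, "repeat_bed")

#' Apply a variant ledger to a guide sequence
#'
#' Replays ordered ledger records (SNV/INS/DEL, 0-based guide positions)
#' onto the guide, reproducing the truth sequence exactly.  An INS record at
#' position p inserts `alt` before guide base p; a DEL removes `ref`
#' starting at p; an SNV replaces the single base at p.
#'
#' @param guide a [guide_haplotype()] or a DNA string.
#' @param ledger data frame with columns `pos` (0-based), `type`
#'   ("SNV"/"INS"/"DEL"), `ref`, `alt`.
#' @return the mutated sequence (character scalar).
#' @export
apply_ledger <- function(guide, ledger) {
  seq <- if (inherits(guide, "guide_haplotype")) guide$sequence else guide
  if (is.null(ledger) || nrow(ledger) == 0L) return(seq)
  if (is.unsorted(ledger$pos, strictly = TRUE))
    stop("ledger positions must be strictly increasing")
  out <- character(0)
  cur <- 0L  # 0-based cursor on guide
  for (i in seq_len(nrow(ledger))) {
    p <- ledger$pos[i]
    ty <- ledger$type[i]
    if (p < cur) stop("overlapping ledger records")
    if (p > cur) out <- c(out, substr(seq, cur + 1L, p))
    if (ty == "SNV") {
      ref <- substr(seq, p + 1L, p + 1L)
      if (ref != ledger$ref[i]) stop("ledger ref mismatch at pos ", p)
      if (ledger$ref[i] == ledger$alt[i]) stop("SNV ref == alt at pos ", p)
      out <- c(out, ledger$alt[i])
      cur <- p + 1L
    } else if (ty == "DEL") {
      len <- nchar(ledger$ref[i])
      if (substr(seq, p + 1L, p + len) != ledger$ref[i])
        stop("ledger ref mismatch at pos ", p)
      cur <- p + len
    } else if (ty == "INS") {
      out <- c(out, ledger$alt[i])
      cur <- p
    } else stop("unknown ledger record type: ", ty)
  }
  if (cur < nchar(seq)) out <- c(out, substr(seq, cur + 1L, nchar(seq)))
  paste(out, collapse = "")
}

#' Draw structural-variant specifications with a realistic size spectrum
#'
#' Indel/SV lengths are heavily skewed towards small events in real data;
#' lengths are drawn as `min_len + Geometric` with the given mean, truncated
#' at `max_len`, and types alternate INS/DEL with equal probability.
#'
#' @param n number of SV records.
#' @param min_len,max_len inclusive length bounds.
#' @param mean_len target mean length of the untruncated distribution.
#' @return data frame with columns `type`, `length`, `count` (= 1).
#' @export
draw_sv_specs <- function(n, min_len = 2L, max_len = 500L, mean_len = 28) {
  len <- min_len + stats::rgeom(n, prob = 1 / (mean_len - min_len + 1))
  len <- pmin(len, max_len)
  data.frame(type = sample(c("INS", "DEL"), n, replace = TRUE),
             length = as.integer(len), count = 1L,
             stringsAsFactors = FALSE)
}

# Sample variant records on a sequence of length L, avoiding occupied
# footprints.  Returns list(ledger rows, occupied).  Positions 0-based.
sample_variants <- function(seq, n_snv, sv_specs, margin, occupied = NULL) {
  L <- nchar(seq)
  occ <- occupied
  rows <- list()
  if (!is.null(sv_specs) && nrow(sv_specs) > 0) {
    for (i in seq_len(nrow(sv_specs))) {
      for (cnt in seq_len(sv_specs$count[i])) {
        len <- sv_specs$length[i]
        ty <- sv_specs$type[i]
        foot <- if (ty == "DEL") len else 1L
        pl <- tryCatch(
          place_intervals(foot, margin, L - margin - foot, occ, buffer = 4L),
          error = function(e) stop("could not place SV specs without overlap",
                                   call. = FALSE))
        occ <- pl$occupied
        p <- pl$starts[1]
        if (ty == "DEL") {
          rows[[length(rows) + 1L]] <- data.frame(
            pos = p, type = "DEL", ref = substr(seq, p + 1L, p + len),
            alt = "", stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            pos = p, type = "INS", ref = "", alt = random_dna(len),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (n_snv > 0) {
    pl <- place_intervals(rep(1L, n_snv), margin, L - margin - 1L, occ,
                          buffer = 2L)
    occ <- pl$occupied
    for (p in pl$starts) {
      ref <- substr(seq, p + 1L, p + 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        pos = p, type = "SNV", ref = ref,
        alt = sample(setdiff(DNA_BASES, ref), 1L), stringsAsFactors = FALSE)
    }
  }
  ledger <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pos = integer(0), type = character(0), ref = character(0),
               alt = character(0), stringsAsFactors = FALSE)
  list(ledger = ledger[order(ledger$pos), , drop = FALSE], occupied = occ)
}

#' Derive a truth haplotype from a guide by planting novel variants
#'
#' Introduces SNVs at `snv_rate` per bp, small indels at `indel_rate`
#' (lengths 1 + Geometric(0.5), capped at 10 bp), and the structural
#' variants listed in `sv_specs`.  Variant placement excludes the first and
#' last `margin` bases so every novel variant is coverable by reads, and no
#' variant is placed inside another variant's footprint.  The returned
#' ledger replays exactly onto the guide.
#'
#' @param guide a [guide_haplotype()].
#' @param snv_rate,indel_rate per-bp rates in \[0, 0.05\].
#' @param sv_specs `NULL` or a data frame with columns `type` ("INS"/"DEL"),
#'   `length`, `count` (see [draw_sv_specs()]).
#' @param seed integer seed.
#' @param margin exclusion zone at the sequence ends (default 150 bp).
#' @param id identifier of the truth haplotype.
#' @return object of class `truth_haplotype`: list with `id`, `guide_id`,
#'   `sequence` and `ledger` (columns `pos`, `type`, `ref`, `alt`).
#' @export
mutate_to_truth <- function(guide, snv_rate, indel_rate = 0, sv_specs = NULL,
                            seed = 1L, margin = 150L,
                            id = paste0(guide$id, "_truth")) {
  stopifnot(inherits(guide, "guide_haplotype"))
  if (snv_rate < 0 || snv_rate > 0.05 || indel_rate < 0 || indel_rate > 0.05)
    stop("rates must lie in [0, 0.05]")
  with_seed(seed, {
    L <- nchar(guide$sequence)
    n_snv <- rbinom(1L, L, snv_rate)
    specs <- sv_specs
    n_ind <- rbinom(1L, L, indel_rate)
    if (n_ind > 0) {
      ind <- data.frame(type = sample(c("INS", "DEL"), n_ind, replace = TRUE),
                        length = pmin(1L + stats::rgeom(n_ind, 0.5), 10L),
                        count = 1L, stringsAsFactors = FALSE)
      specs <- rbind(specs, ind)
    }
    sv <- sample_variants(guide$sequence, n_snv, specs, margin)
    seq <- apply_ledger(guide$sequence, sv$ledger)
    structure(list(id = id, guide_id = guide$id, sequence = seq,
                   ledger = sv$ledger),
              class = "truth_haplotype")
  })
}

#' @export
print.truth_haplotype <- function(x, ...) {
  cat(sprintf("<truth_haplotype> %s (guide %s), %d bp, %d ledger records\n",
              x$id, x$guide_id, nchar(x$sequence), nrow(x$ledger)))
  invisible(x)
}

#' Generate the two truth haplotypes of a diploid individual
#'
#' Emulates a diploid individual whose haplotypes carry novel variation
#' relative to their (class-matched) guides.  A fraction `hom_frac` of the
#' variant sites is shared by both haplotypes (homozygous novel variation,
#' placed on the common backbone), the remainder is haplotype-private
#' (heterozygous).  For a guide-unrelated individual the neutral-coalescent
#' expectation of the shared fraction is 1/2, the default.
#'
#' @param guide_a,guide_b guides from one [make_guide_set()] (they must
#'   share the backbone).
#' @param snv_rate total per-bp novel SNV rate of each haplotype vs its guide.
#' @param n_sv number of SV records per haplotype (see [draw_sv_specs()]).
#' @param hom_frac fraction of variant sites shared by both haplotypes.
#' @param sv_len_range,sv_len_mean SV length distribution parameters.
#' @param seed integer seed.
#' @param margin end exclusion zone in bp.
#' @return list of two `truth_haplotype` objects; each ledger carries an
#'   extra logical column `shared`.
#' @export
make_diploid_truths <- function(guide_a, guide_b, snv_rate = 1e-3,
                                n_sv = 20L, hom_frac = 0.5,
                                sv_len_range = c(2L, 500L), sv_len_mean = 28,
                                seed = 1L, margin = 150L) {
  stopifnot(inherits(guide_a, "guide_haplotype"),
            inherits(guide_b, "guide_haplotype"))
  with_seed(seed, {
    iv_a <- guide_a$class_insert_interval %||% c(0L, 0L)
    iv_b <- guide_b$class_insert_interval %||% c(0L, 0L)
    ins_a <- iv_a[2] - iv_a[1]
    ins_b <- iv_b[2] - iv_b[1]
    Lbb <- nchar(guide_a$sequence) - ins_a
    if (nchar(guide_b$sequence) - ins_b != Lbb)
      stop("guides do not share a backbone")
    # backbone coord -> guide coord
    to_a <- function(p) ifelse(p < iv_a[1], p, p + ins_a)
    to_b <- function(p) {
      # positions at/after the (common) insert locus shift by the insert
      ip <- if (ins_b > 0) iv_b[1] else if (ins_a > 0) iv_a[1] else Lbb + 1
      ifelse(p < ip, p, p + ins_b)
    }
    if (ins_a > 0 && ins_b > 0 && iv_a[1] != iv_b[1])
      stop("guides with inserts at different loci are not supported")

    n_shared_sv <- round(hom_frac * n_sv)
    n_uniq_sv <- n_sv - n_shared_sv
    n_shared_snv <- rbinom(1L, Lbb, snv_rate * hom_frac)

    shared_specs <- if (n_shared_sv > 0)
      draw_sv_specs(n_shared_sv, sv_len_range[1], sv_len_range[2],
                    sv_len_mean) else NULL
    # place shared variants on backbone coordinates (clear of the insert
    # locus and of the end margins of both guides)
    occ_bb <- data.frame(start = c(-1L, Lbb), end = c(margin, Lbb + 1L))
    ipos <- if (ins_a > 0) iv_a[1] else if (ins_b > 0) iv_b[1] else NA
    if (!is.na(ipos))
      occ_bb <- rbind(occ_bb, data.frame(start = ipos - 600L, end = ipos + 600L))
    bb_seq <- if (ins_a == 0) guide_a$sequence else
      paste0(substr(guide_a$sequence, 1, iv_a[1]),
             substr(guide_a$sequence, iv_a[2] + 1, nchar(guide_a$sequence)))
    shared <- sample_variants(bb_seq, n_shared_snv, shared_specs,
                              margin, occ_bb)

    build_hap <- function(guide, to_g, lab) {
      Lg <- nchar(guide$sequence)
      n_uniq_snv <- rbinom(1L, Lg, snv_rate * (1 - hom_frac))
      uniq_specs <- if (n_uniq_sv > 0)
        draw_sv_specs(n_uniq_sv, sv_len_range[1], sv_len_range[2],
                      sv_len_mean) else NULL
      # occupied footprints: shared variants lifted to guide coords
      occ <- NULL
      led_sh <- shared$ledger
      if (nrow(led_sh) > 0) {
        gp <- to_g(led_sh$pos)
        foot <- ifelse(led_sh$type == "DEL", nchar(led_sh$ref), 1L)
        occ <- data.frame(start = gp, end = gp + foot)
      }
      uq <- sample_variants(guide$sequence, n_uniq_snv, uniq_specs, margin,
                            occ)
      led_uq <- uq$ledger
      led <- rbind(
        if (nrow(led_sh) > 0)
          cbind(transform(led_sh, pos = to_g(led_sh$pos)), shared = TRUE)
        else NULL,
        if (nrow(led_uq) > 0) cbind(led_uq, shared = FALSE) else NULL)
      if (is.null(led))
        led <- data.frame(pos = integer(0), type = character(0),
                          ref = character(0), alt = character(0),
                          shared = logical(0))
      led <- led[order(led$pos), , drop = FALSE]
      rownames(led) <- NULL
      seq <- apply_ledger(guide$sequence, led)
      structure(list(id = paste0(guide$id, "_hap", lab),
                     guide_id = guide$id, sequence = seq, ledger = led),
                class = "truth_haplotype")
    }
    list(build_hap(guide_a, to_a, "A"), build_hap(guide_b, to_b, "B"))
  })
}

#' Read-simulation parameters
#'
#' Defaults mirror Illumina HiSeqX-like whole-genome sequencing of the
#' validation experiments: 150 bp paired reads, 30-fold coverage, fragment
#' length 426 +/- 109.  Qualities follow a truncated-normal phred model
#' (mean `quality_mean`, sd `quality_sd`, clamped to \[2, 41\]).
#'
#' @param read_length read length in bp.
#' @param depth_fold target fold coverage of the (combined) truth sequence.
#' @param fragment_mean,fragment_sd fragment length distribution in bp.
#' @param per_base_error substitution error probability per sequenced base.
#' @param quality_mean,quality_sd phred quality model.
#' @param seed integer seed.
#' @return a `read_sim_params` list.
#' @export
read_sim_params <- function(read_length = 150L, depth_fold = 30,
                            fragment_mean = 426L, fragment_sd = 109L,
                            per_base_error = 0.002, quality_mean = 35,
                            quality_sd = 5, seed = 1L) {
  if (read_length > fragment_mean)
    stop("read_length must be <= fragment_mean")
  if (depth_fold <= 0) stop("depth_fold must be positive")
  if (per_base_error < 0 || per_base_error >= 0.1)
    stop("per_base_error must lie in [0, 0.1)")
  structure(list(read_length = as.integer(read_length),
                 depth_fold = depth_fold,
                 fragment_mean = as.integer(fragment_mean),
                 fragment_sd = fragment_sd,
                 per_base_error = per_base_error,
                 quality_mean = quality_mean, quality_sd = quality_sd,
                 seed = as.integer(seed)),
            class = "read_sim_params")
}

make_qual_strings <- function(n, len, mean, sd) {
  q <- round(rnorm(n * len, mean, sd))
  q <- pmin(pmax(q, 2), 41)
  m <- matrix(rawToChar(as.raw(q + 33L), multiple = TRUE), nrow = n)
  do.call(paste0, asplit(m, 2))
}

add_read_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  len <- nchar(seqs[1])
  ne <- rbinom(length(seqs), len, rate)
  idx <- which(ne > 0)
  for (i in idx) seqs[i] <- substitute_bases(seqs[i], sample.int(len, ne[i]))
  seqs
}

#' Simulate Illumina-like paired reads from one or two truth haplotypes
#'
#' Haploid mode (one truth) or diploid mode (two truths sampled with equal
#' probability).  Fragment lengths are Gaussian, truncated to
#' \[read_length, 2 x fragment_mean\]; R1/R2 are the two fragment ends on
#' opposite strands; per-base substitution errors are applied at
#' `per_base_error`.  The number of pairs is
#' `ceiling(total_truth_length * depth_fold / (2 * read_length))`.
#'
#' @param truths a `truth_haplotype` (or any list with `id`/`sequence`), or
#'   a list of one or two of them.
#' @param params a [read_sim_params()] object.
#' @return list with `pairs` (a `read_pairs` data frame: id, seq1, qual1,
#'   seq2, qual2) and `placements` (read id, source haplotype, 0-based
#'   fragment start, strand).
#' @export
simulate_reads <- function(truths, params = read_sim_params()) {
  if (inherits(truths, "truth_haplotype") || !is.null(truths$sequence))
    truths <- list(truths)
  if (length(truths) < 1L || length(truths) > 2L)
    stop("one (haploid) or two (diploid) truth haplotypes are required")
  lens <- vapply(truths, function(t) nchar(t$sequence), numeric(1))
  if (any(lens < params$fragment_mean))
    stop("truth sequence shorter than fragment_mean")
  rl <- params$read_length
  n_pairs <- as.integer(ceiling(sum(lens) * params$depth_fold / (2 * rl)))

  with_seed(params$seed, {
    hap <- if (length(truths) == 2L)
      sample.int(2L, n_pairs, replace = TRUE) else rep(1L, n_pairs)
    frag <- round(rnorm(n_pairs, params$fragment_mean, params$fragment_sd))
    bad <- which(frag < rl | frag > 2L * params$fragment_mean)
    while (length(bad) > 0) {
      frag[bad] <- round(rnorm(length(bad), params$fragment_mean,
                               params$fragment_sd))
      bad <- bad[frag[bad] < rl | frag[bad] > 2L * params$fragment_mean]
    }
    hl <- lens[hap]
    start0 <- floor(runif(n_pairs) * (hl - frag + 1))  # 0-based
    seqs <- character(n_pairs)
    for (h in seq_along(truths)) {
      sel <- hap == h
      seqs[sel] <- substring(truths[[h]]$sequence, start0[sel] + 1L,
                             start0[sel] + frag[sel])
    }
    r1 <- substr(seqs, 1L, rl)
    r2 <- revcomp(substring(seqs, frag - rl + 1L, frag))
    flip <- runif(n_pairs) < 0.5
    tmp <- r1[flip]; r1[flip] <- r2[flip]; r2[flip] <- tmp
    r1 <- add_read_errors(r1, params$per_base_error)
    r2 <- add_read_errors(r2, params$per_base_error)
    q1 <- make_qual_strings(n_pairs, rl, params$quality_mean, params$quality_sd)
    q2 <- make_qual_strings(n_pairs, rl, params$quality_mean, params$quality_sd)
    ids <- sprintf("pair%07d", seq_len(n_pairs))
    pairs <- data.frame(id = ids, seq1 = r1, qual1 = q1, seq2 = r2,
                        qual2 = q2, stringsAsFactors = FALSE)
    class(pairs) <- c("read_pairs", "data.frame")
    placements <- data.frame(
      read_id = ids,
      hap = vapply(truths, `[[`, character(1), "id")[hap],
      frag_start = start0, strand = ifelse(flip, "-", "+"),
      stringsAsFactors = FALSE)
    list(pairs = pairs, placements = placements)
  })
}
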