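# Guide-haplotype assignment from HLA-DRB1 first-field genotypes, read
# alignment to assigned guides, mapped/unmapped pair binning, and
# block/superblock construction over the mapped bin.

#' Allele-to-guide haplotype map
#'
#' @param alleles named character vector mapping first-field DRB1 alleles to
#'   structural class labels, e.g. `c("03" = "SHORT", "04" = "LONG")`.
#' @param guides named character vector mapping class labels to guide ids.
#' @param fallback_guide guide id used for alleles absent from `alleles`
#'   (the method assigns the reference genome to unmatched classes such as
#'   DR8).
#' @return a `haplotype_map` object.
#' @export
haplotype_map <- function(alleles, guides, fallback_guide) {
  missing_cls <- setdiff(unique(alleles), names(guides))
  if (length(missing_cls) > 0)
    stop("classes without a guide: ", paste(missing_cls, collapse = ", "))
  if (missing(fallback_guide) || is.null(fallback_guide))
    stop("a fallback guide is required")
  structure(list(alleles = alleles, guides = guides,
                 fallback_guide = fallback_guide),
            class = "haplotype_map")
}

#' Read a haplotype map from TSV files
#'
#' `alleles_path` has columns allele, class; `guides_path` has columns
#' class, guide_id; the row with class "FALLBACK" names the fallback guide.
#' @param alleles_path,guides_path TSV paths.
#' @export
read_haplotype_map <- function(alleles_path, guides_path) {
  a <- read.delim(alleles_path, stringsAsFactors = FALSE,
                  colClasses = "character")
  g <- read.delim(guides_path, stringsAsFactors = FALSE,
                  colClasses = "character")
  fb <- g$guide_id[g$class == "FALLBACK"]
  if (length(fb) == 0) stop("no FALLBACK row in the guide map")
  haplotype_map(setNames(a$class, a$allele),
                setNames(g$guide_id, g$class)[g$class != "FALLBACK"], fb[1])
}

#' Assign best-matched guide haplotypes from a first-field genotype
#'
#' Homozygous genotypes (or two alleles of the same structural class) yield
#' one guide; heterozygous classes yield two.  Alleles absent from the map
#' fall back to the fallback guide; an unknown allele with no fallback is an
#' error naming the allele.
#'
#' @param sample_id sample identifier.
#' @param genotype character vector of the two first-field alleles.
#' @param map a [haplotype_map()].
#' @return a `bmh_assignment`: list(sample_id, guide_ids) with 1 or 2 guides.
#' @export
assign_bmh <- function(sample_id, genotype, map) {
  stopifnot(length(genotype) == 2L)
  resolve <- function(allele) {
    if (allele %in% names(map$alleles)) {
      cls <- map$alleles[[allele]]
      gid <- map$guides[[cls]]
      if (is.null(gid)) stop("class without a guide: ", cls)
      gid
    } else if (!is.null(map$fallback_guide)) {
      map$fallback_guide
    } else {
      stop("unknown allele with no fallback: ", allele)
    }
  }
  gids <- unique(vapply(as.character(genotype), resolve, character(1),
                        USE.NAMES = FALSE))
  structure(list(sample_id = sample_id, guide_ids = gids),
            class = "bmh_assignment")
}

#' Read a genotype table (sample_id, allele1, allele2)
#' @param path TSV path.
#' @export
read_genotypes <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c("character", "character", "character"))
}

#' Minimum alignment score for a mapped read
#'
#' The linear end-to-end threshold `intercept + slope * read_length`
#' (defaults 0 and -0.6, i.e. -90 for a 150 bp read).
#'
#' @param read_length read length in bp.
#' @param intercept,slope linear score function coefficients.
#' @export
min_alignment_score <- function(read_length, intercept = 0, slope = -0.6) {
  stopifnot(all(read_length > 0))
  intercept + slope * read_length
}

#' Map read pairs to a guide haplotype
#'
#' Exact-kmer seeding (seed length `k_seed`), best-diagonal chaining, and
#' banded end-to-end extension with penalties mismatch 6, gap open 5, gap
#' extend 3.  A mate maps when its score reaches
#' [min_alignment_score()] of its length.
#'
#' @param pairs a `read_pairs` data frame.
#' @param guide a [guide_haplotype()].
#' @param k_seed seed kmer length (default 21).
#' @param band extension band half-width.
#' @param slope score threshold slope (default -0.6).
#' @return data frame with one row per mate: read_id, mate (1/2), guide_id,
#'   pos (0-based), end, strand, score, mapped.
#' @export
map_read_pairs <- function(pairs, guide, k_seed = 21L, band = 40L,
                           slope = -0.6) {
  if (nchar(guide$sequence) < k_seed)
    stop("guide shorter than the seed length")
  one <- function(seqs, mate) {
    m <- cpp_map_reads(seqs, guide$sequence, k_seed, 3L, band, 6L, 5L, 3L,
                       slope, 64L)
    data.frame(read_id = pairs$id, mate = mate, guide_id = guide$id,
               pos = m$pos, end = m$end,
               strand = ifelse(is.na(m$strand), NA,
                               ifelse(m$strand > 0, "+", "-")),
               score = m$score, mapped = m$mapped, stringsAsFactors = FALSE)
  }
  rbind(one(pairs$seq1, 1L), one(pairs$seq2, 2L))
}

#' Partition read pairs into mapped and unmapped bins
#'
#' A pair is binned "mapped" when either mate maps (flag `pair_level`);
#' with `pair_level = FALSE` each mate is binned individually.
#'
#' @param placements output of [map_read_pairs()].
#' @param pair_level bin whole pairs (default TRUE).
#' @return list with `mapped_ids` and `unmapped_ids` (read ids).
#' @export
bin_pairs <- function(placements, pair_level = TRUE) {
  if (pair_level) {
    mp <- tapply(placements$mapped, placements$read_id, any)
  } else {
    mp <- tapply(placements$mapped, placements$read_id, all)
  }
  ids <- names(mp)
  list(mapped_ids = ids[mp], unmapped_ids = ids[!mp])
}

#' Group mapped placements into blocks and merge them into superblocks
#'
#' Blocks are maximal runs of transitively overlapping mapped placements on
#' the guide; blocks separated by at most `flank` bp merge; merged regions
#' are capped at `max_block` with `flank`-bp overlap between consecutive
#' superblocks.
#'
#' @param placements mapped-mate placements (rows of [map_read_pairs()] with
#'   `mapped = TRUE`).
#' @param guide the guide haplotype.
#' @param max_block superblock size cap in bp (default 50 kb).
#' @param flank inter-superblock overlap in bp (default 300).
#' @return data frame: guide_id, start, end (0-based half-open) plus a
#'   list-column `read_ids` of member pair ids.
#' @export
build_superblocks <- function(placements, guide, max_block = 50000L,
                              flank = 300L) {
  pl <- placements[placements$mapped & !is.na(placements$pos), , drop = FALSE]
  if (nrow(pl) == 0L)
    return(data.frame(guide_id = character(0), start = numeric(0),
                      end = numeric(0)))
  pl <- pl[order(pl$pos), , drop = FALSE]
  # blocks: transitive interval overlap
  newblk <- c(TRUE, pl$pos[-1] > cummax(pl$end[-nrow(pl)]))
  blk <- cumsum(newblk)
  bstart <- tapply(pl$pos, blk, min)
  bend <- tapply(pl$end, blk, max)
  # merge blocks within `flank`
  keepnew <- c(TRUE, bstart[-1] > bend[-length(bend)] + flank)
  grp <- cumsum(keepnew)
  gstart <- as.numeric(tapply(bstart, grp, min))
  gend <- as.numeric(tapply(bend, grp, max))
  # cap at max_block with flank overlap
  sb <- list()
  for (i in seq_along(gstart)) {
    s <- gstart[i]
    repeat {
      e <- min(s + max_block, gend[i])
      sb[[length(sb) + 1L]] <- c(s, e)
      if (e >= gend[i]) break
      s <- e - flank
    }
  }
  sbdf <- data.frame(guide_id = guide$id,
                     start = vapply(sb, `[`, numeric(1), 1),
                     end = vapply(sb, `[`, numeric(1), 2))
  sbdf$read_ids <- lapply(seq_len(nrow(sbdf)), function(i) {
    sel <- pl$pos < sbdf$end[i] & pl$end > sbdf$start[i]
    unique(pl$read_id[sel])
  })
  sbdf
}
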