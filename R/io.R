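# File-format boundaries: FASTA/FASTQ through Biostrings, simple tabular
# formats (ledger TSV, BED, PAF) through base R.

#' Write paired reads to a pair of FASTQ files
#'
#' @param pairs a `read_pairs` data frame (id, seq1, qual1, seq2, qual2).
#' @param file1,file2 output paths (".gz" suffix compresses).
#' @return invisibly, the two paths.
#' @export
write_fastq_pairs <- function(pairs, file1, file2) {
  w <- function(seqs, quals, ids, path) {
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(seqs, ids)),
      Biostrings::PhredQuality(quals))
    withCallingHandlers(
      Biostrings::writeQualityScaledXStringSet(
        x, path, compress = grepl("\\.gz$", path)),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }
  w(pairs$seq1, pairs$qual1, paste0(pairs$id, "/1"), file1)
  w(pairs$seq2, pairs$qual2, paste0(pairs$id, "/2"), file2)
  invisible(c(file1, file2))
}

#' Read paired FASTQ files into a `read_pairs` data frame
#'
#' Mates must be synchronized; a mate-ID mismatch is a hard error.
#'
#' @param file1,file2 FASTQ paths (plain or gzip).
#' @return a `read_pairs` data frame.
#' @export
read_fastq_pairs <- function(file1, file2) {
  rd <- function(f) withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(f),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  r1 <- rd(file1)
  r2 <- rd(file2)
  if (length(r1) != length(r2))
    stop("desynchronized mates: different read counts")
  strip <- function(x) sub("[/ ].*$", "", x)
  id1 <- strip(names(r1))
  id2 <- strip(names(r2))
  if (!identical(id1, id2))
    stop("desynchronized mates: read ID mismatch")
  pairs <- data.frame(
    id = id1,
    seq1 = as.character(r1), qual1 = as.character(Biostrings::quality(r1)),
    seq2 = as.character(r2), qual2 = as.character(Biostrings::quality(r2)),
    stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  class(pairs) <- c("read_pairs", "data.frame")
  pairs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector (or data frame with `id`/`sequence`).
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$sequence, seqs$id)
  x <- Biostrings::BStringSet(seqs)  # BString keeps lowercase gap-fill masks
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write a variant ledger as TSV
#'
#' Columns: guide_id, pos0, type, ref, alt.
#' @param truth a `truth_haplotype` (or a ledger data frame plus `guide_id`).
#' @param path output path.
#' @param guide_id guide identifier when `truth` is a bare ledger.
#' @export
write_ledger <- function(truth, path, guide_id = NULL) {
  led <- if (inherits(truth, "truth_haplotype")) truth$ledger else truth
  gid <- if (inherits(truth, "truth_haplotype")) truth$guide_id else guide_id
  out <- data.frame(guide_id = gid, pos0 = led$pos, type = led$type,
                    ref = led$ref, alt = led$alt, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a variant ledger TSV
#' @param path ledger path (columns guide_id, pos0, type, ref, alt).
#' @return ledger data frame with columns pos, type, ref, alt, guide_id.
#' @export
read_ledger <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  x$ref[is.na(x$ref)] <- ""
  x$alt[is.na(x$alt)] <- ""
  data.frame(pos = x$pos0, type = x$type, ref = x$ref, alt = x$alt,
             guide_id = x$guide_id, stringsAsFactors = FALSE)
}

#' Write 0-based half-open intervals as BED
#' @param df data frame with columns chrom (or guide_id), start, end and
#'   optionally a name/type column.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  chrom <- df$chrom %||% df$guide_id
  name <- df$type %||% df$name %||% "."
  out <- data.frame(chrom, df$start, df$end, name)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write alignment segments as PAF
#'
#' Standard 12-column PAF suitable for dot-plot rendering.
#'
#' @param segments data frame with columns qname, qlen, qstart, qend,
#'   strand, tname, tlen, tstart, tend, nmatch, alnlen (mapq optional).
#' @param path output path.
#' @export
write_paf <- function(segments, path) {
  if (nrow(segments) == 0) {
    file.create(path)
    return(invisible(path))
  }
  out <- data.frame(segments$qname, segments$qlen, segments$qstart,
                    segments$qend, segments$strand, segments$tname,
                    segments$tlen, segments$tstart, segments$tend,
                    segments$nmatch, segments$alnlen,
                    segments$mapq %||% 60L)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a PAF file
#' @param path PAF path.
#' @return data frame with the 12 standard columns.
#' @export
read_paf <- function(path) {
  cols <- c("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
            "tstart", "tend", "nmatch", "alnlen", "mapq")
  if (file.size(path) == 0)
    return(setNames(data.frame(character(0), numeric(0), numeric(0),
                               numeric(0), character(0), character(0),
                               numeric(0), numeric(0), numeric(0),
                               numeric(0), numeric(0), numeric(0),
                               stringsAsFactors = FALSE), cols))
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)[, 1:12]
  setNames(x, cols)
}

#' Write contigs as FASTA with coverage in the headers
#' @param contigs contig data frame (id, sequence, mean_cov, source_bin).
#' @param path output path.
#' @export
write_contig_fasta <- function(contigs, path) {
  ids <- sprintf("%s cov=%.1f bin=%s", contigs$id, contigs$mean_cov,
                 contigs$source_bin)
  write_fasta(setNames(contigs$sequence, ids), path)
}
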