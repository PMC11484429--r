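# End-to-end per-guide pipeline: QC -> binning -> superblock assembly ->
# cross-contig filtering -> merging -> polishing -> scaffolding -> consensus.

#' Assemble one haplotype against its guide
#'
#' Runs the full per-guide pipeline on a set of read pairs: quality
#' control, alignment to the guide and pair binning, superblock
#' construction and per-superblock de Bruijn assembly of mapped reads,
#' separate assembly of unmapped reads with cross-haplotype contig
#' filtering, overlap merging into supercontigs, pileup polishing, and
#' score-filtered scaffolding to the guide with gap closing.
#'
#' @param pairs a `read_pairs` data frame.
#' @param guide the assigned [guide_haplotype()].
#' @param alt_guide the heterozygous individual's other guide (or `NULL`).
#' @param decoy optional named character vector of decoy sequences for
#'   off-target filtering.
#' @param qc a [qc_params()] object, or `NULL` to skip QC.
#' @param asm an [assembly_params()] object.
#' @param gap_policy consensus gap fill: "guide" or "N".
#' @param max_block,flank superblock sizing (bp).
#' @param gap_close run paired-read gap closing (default TRUE).
#' @return list: `consensus` (a `consensus_assembly`), `contigs` (polished
#'   supercontigs), `placements`, `read_placements`, `binning`, `stats`,
#'   `qc_summary`, `corrections`, `closed_gaps`.
#' @export
assemble_haplotype <- function(pairs, guide, alt_guide = NULL, decoy = NULL,
                               qc = qc_params(), asm = assembly_params(),
                               gap_policy = "guide", max_block = 50000L,
                               flank = 300L, gap_close = TRUE) {
  qc_summary <- NULL
  if (!is.null(qc)) {
    q <- qc_reads(pairs, qc)
    pairs <- q$pairs
    qc_summary <- q$summary
  }
  if (nrow(pairs) == 0L) stop("no read pairs survive QC")

  rp <- map_read_pairs(pairs, guide)
  bins <- bin_pairs(rp)
  mapped_pl <- rp[rp$mapped & rp$read_id %in% bins$mapped_ids, , drop = FALSE]
  sb <- build_superblocks(mapped_pl, guide, max_block, flank)

  contigs <- list()
  for (i in seq_len(nrow(sb))) {
    ids <- sb$read_ids[[i]]
    sel <- pairs$id %in% ids
    reads <- c(pairs$seq1[sel], pairs$seq2[sel])
    ct <- tryCatch(
      assemble_bin(reads, asm, source_bin = sprintf("MAPPED:sb%02d", i),
                   prefix = sprintf("sb%02d_c", i)),
      error = function(e) NULL)
    if (!is.null(ct) && nrow(ct) > 0) contigs[[length(contigs) + 1L]] <- ct
  }
  if (length(bins$unmapped_ids) > 0) {
    sel <- pairs$id %in% bins$unmapped_ids
    reads <- c(pairs$seq1[sel], pairs$seq2[sel])
    un <- tryCatch(
      assemble_bin(reads, asm, source_bin = "UNMAPPED", prefix = "un_c"),
      error = function(e) NULL)
    if (!is.null(un) && nrow(un) > 0) {
      un <- filter_cross_contigs(un, alt_guide, decoy)
      if (nrow(un) > 0) contigs[[length(contigs) + 1L]] <- un
    }
  }
  if (length(contigs) == 0L) stop("assembly produced no contigs")
  contigs <- do.call(rbind, contigs)
  contigs$id <- make.unique(contigs$id)

  sup <- merge_contigs(contigs)
  pol <- polish_contigs(sup, pairs)
  sup <- pol$contigs

  anc <- anchor_contigs(sup, guide)
  pl <- filter_placements(anc$placements)
  sup2 <- anc$contigs
  closed <- NULL
  if (isTRUE(gap_close) && nrow(pl) > 1) {
    cg <- close_gaps(pl, sup2, guide, pairs, rp)
    pl <- cg$placements
    sup2 <- cg$contigs
    closed <- cg$closed
  }
  cons <- emit_consensus(pl, sup2, guide, gap_policy)

  list(consensus = cons, contigs = sup2, placements = pl,
       read_placements = rp,
       binning = data.frame(mapped = length(bins$mapped_ids),
                            unmapped = length(bins$unmapped_ids)),
       stats = assembly_stats(sup2), qc_summary = qc_summary,
       corrections = pol$corrections, closed_gaps = closed)
}

#' Run the per-guide pipeline for one individual
#'
#' Assigns guide haplotypes from the genotype and runs
#' [assemble_haplotype()] once per assigned guide; for heterozygous
#' individuals each run uses the other guide as the alternative for
#' cross-contig filtering.
#'
#' @param pairs a `read_pairs` data frame.
#' @param sample_id sample identifier.
#' @param genotype the two first-field alleles.
#' @param map a [haplotype_map()].
#' @param guides a [make_guide_set()] result (or named list of guides).
#' @param ... passed to [assemble_haplotype()].
#' @return named list of per-guide results (see [assemble_haplotype()]).
#' @export
run_individual <- function(pairs, sample_id, genotype, map, guides, ...) {
  bmh <- assign_bmh(sample_id, genotype, map)
  out <- list()
  for (gid in bmh$guide_ids) {
    g <- guides[[gid]]
    if (is.null(g)) stop("assigned guide not in the guide set: ", gid)
    alt <- if (length(bmh$guide_ids) == 2L)
      guides[[setdiff(bmh$guide_ids, gid)]] else NULL
    out[[gid]] <- assemble_haplotype(pairs, g, alt_guide = alt, ...)
  }
  out
}

#' Read a key=value control file
#'
#' Plain-text `key=value` lines (comments with `#`); values are returned as
#' a named character vector.
#' @param path control file path.
#' @export
read_control <- function(path) {
  ln <- readLines(path)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln[grepl("=", ln)])
  kv <- strsplit(ln, "=", fixed = TRUE)
  setNames(trimws(vapply(kv, `[`, character(1), 2)),
           trimws(vapply(kv, `[`, character(1), 1)))
}

#' Run the full workflow from a control file
#'
#' Chains simulate (optional) -> qc -> bin -> assemble -> scaffold ->
#' evaluate from one `key=value` control file.  Recognized keys: fastq1,
#' fastq2 (or sim_seed/sim_length to simulate), guides_fasta, genotypes,
#' sample_id, allele_map, guide_map, out_dir, k, min_cov, sample_pairs,
#' seed, gap_policy, truth_fasta, ledger.
#'
#' @param path control file path.
#' @return invisibly, the per-guide results.
#' @export
run_all <- function(path) {
  cv <- read_control(path)
  ctl <- function(key, default = NULL) {
    if (key %in% names(cv)) cv[[key]] else default
  }
  out_dir <- ctl("out_dir", ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(ctl("fastq1"))) {
    pairs <- read_fastq_pairs(ctl("fastq1"), ctl("fastq2"))
  } else stop("control file must provide fastq1/fastq2")

  gseqs <- read_fasta(ctl("guides_fasta"))
  classes <- sub("^guide_", "", names(gseqs))
  guides <- lapply(seq_along(gseqs), function(i)
    guide_haplotype(names(gseqs)[i], toupper(gseqs[[i]]), classes[i]))
  names(guides) <- names(gseqs)

  map <- read_haplotype_map(ctl("allele_map"), ctl("guide_map"))
  gt <- read_genotypes(ctl("genotypes"))
  sid <- ctl("sample_id", gt$sample_id[1])
  row <- gt[gt$sample_id == sid, ]
  if (nrow(row) == 0) stop("sample not in genotype table: ", sid)

  asm <- assembly_params(k = as.integer(ctl("k", "51")),
                         min_kmer_cov = as.integer(ctl("min_cov", "3")))
  qcp <- qc_params(sample_pairs = as.numeric(ctl("sample_pairs", Inf)),
                   sample_seed = as.integer(ctl("seed", "1")))
  res <- run_individual(pairs, sid, c(row$allele1[1], row$allele2[1]), map,
                        guides, qc = qcp, asm = asm,
                        gap_policy = ctl("gap_policy", "guide"))
  for (gid in names(res)) {
    write_consensus_fasta(res[[gid]]$consensus,
                          file.path(out_dir, paste0(sid, "_", gid, ".fasta")))
    write.table(res[[gid]]$stats,
                file.path(out_dir, paste0(sid, "_", gid, "_stats.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(res)
}
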