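---
title: "Haplotype-guided de novo assembly of the MHC: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-guided de novo assembly of the MHC: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The major histocompatibility complex (MHC, ~5 Mb on 6p21.31) is the most
polymorphic region of the human genome.  Short-read analyses that merely
align reads to a single reference miss much of its novel heterozygosity and
large structural variation, in particular the HLA class II
structural haplotypes (DR2/DR3/DR4/DR8 and relatives), which differ by long
insertion blocks between the *HLA-DRB* paralogs, and the near-identical
*C4A*/*C4B* duplication.  `mhcasm` implements a reference-informed, de novo
short-read assembly strategy for this situation: reads are binned against
one or two *guide haplotypes* chosen from the individual's *HLA-DRB1*
first-field genotype, assembled de novo per region, and the resulting
contigs are ordered and oriented back onto the guide to emit one continuous
pseudo-haploid consensus per guide, with everything unplaceable kept as
separate records.  The guide steers read binning and scaffolding only; all
base-level sequence comes from the de Bruijn assembly, so variation absent
from the guide is recoverable.

The package also contains the validation apparatus (truth-based error
taxonomy, novel-variant recovery, assembly statistics) and a synthetic
diploid-region/read simulator, so that the whole pipeline is exercisable
and testable without any external data.

## Pipeline

For one individual and one assigned guide:

1. **Read QC** (`qc_reads`): pairs containing a run of >= 20 consecutive G
   (or C, the artifact's appearance on the opposite sense) are dropped;
   optional seeded subsampling; per-mate trimming that strips
   leading/trailing bases below Q3 or N, truncates at the first 4-bp window
   with mean quality < 15, and drops mates shorter than 40 bp (single
   survivors go to an orphan stream).  Adapters are assumed removed
   upstream.
2. **Binning** (`map_read_pairs`, `bin_pairs`): each mate is aligned to the
   guide by an internal seed-chain-extend mapper (exact 21-mer seeds,
   best-diagonal voting, banded end-to-end extension with mismatch 6, gap
   open 5, gap extend 3).  A mate maps when its score reaches the linear
   threshold `0 - 0.6 * length` (-90 for 150 bp).  A pair is binned
   *mapped* when either mate maps; heterozygous individuals are processed
   once per guide.
3. **Superblocks** (`build_superblocks`): transitively overlapping mapped
   placements form blocks; blocks separated by at most the flank (300 bp)
   merge; merged regions are capped at 50 kb with 300 bp overlap between
   consecutive superblocks so each is assembled independently at desk
   scale and their contigs re-join through the shared flank.
4. **De Bruijn assembly** (`build_and_clean`, `extract_contigs`): canonical
   kmers at k = 51, multiplicity < 3 removed, iterative clipping of
   dead-end paths shorter than 2k, and popping of simple bubbles whose two
   paths are >= 95% identical (higher mean coverage wins).  Contigs are
   maximal unbranched paths.  Unmapped-bin reads are assembled separately
   and their contigs are removed if at least half their length aligns at
   >= 90% identity to the alternative guide or a decoy
   (`filter_cross_contigs`).
5. **Merging** (`merge_contigs`): greedy overlap-layout joining of
   suffix-prefix overlaps >= 40 bp at >= 99% identity, longest first;
   near-identical containments collapse to the container.
6. **Polishing** (`polish_contigs`): reads are realigned to the contigs; a
   pileup column is rewritten to its majority allele when depth >= 5 and
   the majority fraction is >= 0.7, including small indel corrections.  A
   column matching the majority is never changed.
7. **Scaffolding** (`anchor_contigs`, `filter_placements`, `close_gaps`,
   `emit_consensus`): contigs are anchored to the guide by exact 21-mers
   clustered by diagonal.  The *location score* is the fraction of
   anchored bases in the best location cluster, the *orientation score*
   the majority-strand fraction within it; placements with location < 0.1,
   or location < 0.3 and orientation < 0.75, are dropped.  Gaps between
   consecutive placements are re-assembled locally (k = 31) from pairs
   anchored in the flanks and closed when a bridge with >= 40 bp exact
   junctions and a plausible length exists.  The consensus is the
   guide-ordered concatenation of placed contigs, with remaining gaps
   filled by lowercase guide sequence (or N runs); unplaced contigs are
   emitted as separate records.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `read_length`, `depth_fold` | 150 bp, 30x | simulated protocol |
| `fragment_mean`, `fragment_sd` | 426, 109 bp | fragment length model |
| `per_base_error` | 0.002 | substitution error per sequenced base |
| `polyg_min_run` | 20 | poly-G artifact run length |
| `lead_trail_q`, `window_len`, `window_meanq`, `min_len` | 3, 4, 15, 40 | trimming |
| `k_seed` | 21 | mapper/anchor seed length |
| score threshold | `0 - 0.6 L` | end-to-end mapping cutoff |
| `max_block`, `flank` | 50 kb, 300 bp | superblock sizing |
| `k` | 51 | assembly kmer size (odd, 15-63) |
| `min_kmer_cov` | 3 | solid-kmer floor |
| `tip_len_max` | `2k` | tip clipping bound |
| `bubble_identity` | 0.95 | bubble popping similarity |
| `min_contig_len` | `floor(1.5k)` | contig length floor (see below) |
| `min_overlap`, `min_identity` | 40 bp, 0.99 | contig merging |
| polish `min_depth`, `min_frac` | 5, 0.7 | pileup correction rule |
| `split_min`, `min_cluster_n` | 700 bp, 25 | chimera splitting |
| `min_sv` | 1 | smallest INDEL counted as SV error |

The assembly kmer size default of 51 reflects the regime where assembly
time grows linearly with read count while mapped-read spectra remain
informative; `estimate_best_k` provides a simplified spectrum-based
estimate (the candidate maximizing distinct solid kmers, ties to the
larger k) for users who want to tune it per data set.

**Contig length floor.**  The shortest informative fragments in a
heterozygous assembly are single-junction allele paths -- for example the
junction allele of a heterozygous deletion -- whose nominal spelled length
is `2(k-1)` bp and which can come out one or two bases shorter when an
allele base coincides with the guide continuation.  The floor is therefore
set at `floor(1.5 k)` (76 bp at k = 51): comfortably below `2(k-1)`, above
single-kmer noise.  Dropping these fragments would silently erase the
minor allele of every heterozygous deletion.

## The synthetic data generator

`make_guide_set` builds a backbone of i.i.d. uniform bases carrying:
homopolymer tracts (15-25 bp), short tandem repeats (period 2-6, 8-20
copies), a dispersed 300-bp repeat family at 3% divergence, and one tandem
segmental-duplication pair at 99.9% identity (4 kb per copy by default)
emulating *C4A*/*C4B*.  Classes with positive insertion length add a
class-defining block at a common locus, emulating the extra sequence
content of the long HLA class II haplotypes; flanks outside the block are
shared verbatim between the class guides (per-guide point divergence is
available but off by default).

`mutate_to_truth` derives a truth haplotype by planting SNVs and indels at
given rates plus explicit SV records; every difference is recorded in a
ledger that replays exactly onto the guide (a tested invariant).  Variants
avoid each other's footprints and the outermost `read_length` bases, so
each is coverable by reads.  SV lengths from `draw_sv_specs` follow
`min + Geometric` with mean ~28 bp truncated at 500 bp, reflecting the
heavy small-indel skew of real indel spectra; uniform lengths over
2-500 bp would be unrealistic and would dominate error percentages with
rare large events.

`make_diploid_truths` emulates a diploid individual: a fraction
`hom_frac` of variant sites is shared by both haplotypes (homozygous novel
variation, placed on the common backbone), the rest is haplotype-private.
The default is 1/2: for three haplotypes (guide plus the individual's
two), exchangeability under the neutral coalescent makes the two singleton
site patterns -- mutation on the guide's lineage (seen as homozygous novel
variation) versus mutation on one truth lineage (heterozygous) -- equally
frequent.

`simulate_reads` draws Gaussian fragments truncated to
`[read_length, 2 x fragment_mean]`, emits both ends as a 150-bp pair on
opposite strands, applies i.i.d. substitution errors, and models qualities
as truncated-normal phred scores (mean 35, sd 5, clamped to [2, 41]) -- a
deliberately simple, seedable stand-in for instrument-specific profiles,
sufficient to exercise the QC stage.  What is *not* modelled: PCR/optical
duplicates, GC bias, indel sequencing errors, quality-error coupling,
target-capture probe dropout, and real MHC gene content.  Consequently,
passing tests demonstrate the algorithmic behaviour of the pipeline under
controlled conditions, not its performance on any particular instrument's
data.

## Numerical and design choices

* **Truth alignment** (`align_to_truth`) chains exact 31-mer anchors as
  diagonal runs joined by dynamic programming with a penalty of
  `0.05 * |diagonal jump|` and tolerance for modest run overlap (paid for
  by the anchors it forfeits).  A plain longest-increasing-subsequence
  chain is not used: between near-identical segmental-duplication copies
  it zigzags across diagonals and fabricates compensating insertion/
  deletion pairs.  A genuine SV pays its jump once and wins; a zigzag does
  not.  Inter-anchor gaps are resolved by banded global alignment (band
  30 plus the length difference); indels >= 100 bp split PAF segments but
  are still reported as variants.
* **Chimera splitting before placement**: a contig whose *guide-unique*
  anchors form two diagonal clusters separated by more than 700 bp (with
  >= 25 anchors in the minor cluster) is cut at the best separating query
  position and the pieces are re-anchored.  This is the same correction a
  reference scaffolder applies to misjoined queries; without it, a
  collapsed repeat that joins two distant loci injects multi-kb false
  indels into the consensus.  The 700 bp floor is above the simulated SV
  ceiling (500 bp), so heterozygous allele contigs are never split.
* **Containment during merging** additionally requires <= 2 bp of total
  indel difference, so a junction-allele fragment spanning the other
  allele's indel is not treated as a redundant copy.
* **Consensus junctions** are cut at the nearest local anchor diagonal
  rather than at a single global contig offset; beyond an internal indel
  the global offset is stale and produces compensating indel pairs at the
  junctions.
* **Displaced placements become records**: when two near-duplicate contigs
  (typically the two haplotypes of one region) compete, the loser's
  displaced spans (>= 100 bp) are appended to the unplaced records
  instead of being discarded.  The continuous consensus stays single-
  haplotype per position, but the locally losing allele remains
  discoverable -- this is the channel through which heterozygous SV
  alleles are recovered, and it mirrors reference scaffolders that emit
  every input sequence either placed or unplaced.
* **Gap closing** accepts a bridge only if its length matches the guide
  gap within `max(200 bp, 30%)`; local reassembly inside a collapsed
  repeat otherwise produces plausible-looking but chimeric bridges.
* **Gap fill policy**: the consensus is described with respect to the
  guide, so gaps default to lowercase guide bases ("guide"); an `"N"`
  policy is available for reference-bias-sensitive uses.  Error
  percentages exclude guide-filled bases from both numerator and
  denominator by default (flag-controllable), since filled bases are not
  assembled sequence.
* **SV error floor**: the error taxonomy counts INDELs >= 1 bp by default
  (`min_sv = 1`), matching the reported tables; a 2 bp floor is available
  as a flag.
* **Determinism**: contigs are emitted in canonical strand and sorted by
  length then sequence; bubble popping and merging break ties by coverage,
  then length, then lexicographic order; all stochastic stages take
  explicit seeds and restore the caller's RNG state.

## Problem sizes

The bundled tests and the acceptance script run entirely on synthetic
regions: unit fixtures of 10-60 kb, and scaled-down validation analogues
on a 150 kb region (plus a 20 kb class insertion for the heterozygote)
at 30-60x, averaged over three seeds.  These sizes keep a full validation
sweep in the low minutes on one CPU while preserving every structural
feature the method must confront (class insertion, segmental duplication,
repeat tracts, heterozygous SNV/SV variation).

## Known limitations

* Heterozygous **SNV** alleles sit in simple bubbles that the cleaning
  stage pops deterministically, so the minor allele of an isolated het
  SNV is erased from the graph; diploid SNV recovery is therefore
  markedly lower than haploid recovery.  Het indel alleles survive (their
  bubbles fail the 95% identity rule) and are recovered through the
  consensus or the record channel.  Formal phasing of the two per-guide
  consensi is out of scope.
* The near-identical segmental duplication collapses or breaks rather
  than being resolved -- the expected limitation of short-read de Bruijn
  assembly; its copies surface as guide-filled stretches, mosaic alleles,
  and occasional repeat-associated errors, and copy-number calling is
  delegated to dedicated tools.
* Possible recombination between class haplotypes is ignored in guide
  assignment, and a pair whose mates map to discordant loci is binned at
  the better mate.
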