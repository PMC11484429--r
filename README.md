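# mhcasm

Haplotype-guided, reference-informed **de novo assembly of the MHC region
from short reads**, with a built-in validation framework and a synthetic
diploid-region/read simulator.

The ~5 Mb major histocompatibility complex (MHC) is the most polymorphic
region of the human genome.  Its large HLA class II structural haplotypes
(long insertion blocks between the *HLA-DRB* paralogs) and the
near-identical *C4A*/*C4B* duplication defeat plain reference alignment,
while fully de novo assembly of diploid short-read data fragments at
heterozygous structure.  `mhcasm` implements the middle road for
population-scale short-read cohorts:

1. assign each individual one or two **guide haplotypes** from the
   *HLA-DRB1* first-field genotype (homozygous → one guide, heterozygous
   → two; unmatched classes fall back to a reference guide);
2. **bin** read pairs by end-to-end alignment to each guide (seed-chain-
   extend mapper; a mate maps when its score ≥ `0 − 0.6·L`, i.e. −90 for
   150 bp reads; a pair is mapped if either mate maps);
3. group mapped reads into **superblocks** (≤ 50 kb, 300 bp overlap) and
   assemble each with a **de Bruijn graph** at *k* = 51 (solid-kmer floor
   3, tip clipping < 2k, bubble popping at ≥ 95% identity); unmapped
   reads are assembled separately and contigs that belong to the
   alternative haplotype or a decoy are removed;
4. **merge** overlapping contigs into supercontigs (≥ 40 bp overlaps at
   ≥ 99% identity), **polish** them with a read pileup (majority ≥ 70% at
   depth ≥ 5), and
5. **scaffold** against the guide: contigs are ordered/oriented by kmer
   anchors, kept only if their *location score* ≥ 0.1 and not
   (location < 0.3 and *orientation score* < 0.75), gaps are closed with
   paired reads, and one continuous consensus haplotype is emitted per
   guide — gaps filled with lowercase guide bases (or N), every
   unplaceable contig kept as a separate FASTA record.

Validation tools measure what the paper-style analysis needs: assembly
statistics (N50, contig count, total length), a truth-based **error
taxonomy** (base-call %, repeat and non-repeat SV % of assembled length,
false SVs > 1 kb), **novel-variant recovery** against a variant ledger,
unique-kmer diversity, and PAF export for dot plots.

The simulator (`make_guide_set`, `make_diploid_truths`, `simulate_reads`)
generates class-structured guide sets (shared backbone, class-defining
insertion, repeat tracts, a 99.9%-identical segmental-duplication pair),
diploid truth haplotypes with exact variant ledgers, and 150 bp paired
reads (fragments 426 ± 109 bp, configurable error model) — so every stage
of the pipeline is testable without external data.

## Worked example

A 150 kb synthetic region, SHORT/LONG class heterozygote (20 kb class
insertion), 30× diploid reads, assembled against the SHORT guide and
validated against the SHORT truth haplotype:

```r
library(mhcasm)

guides <- make_guide_set(seed = 1, base_length = 150000,
                         classes = c(SHORT = 0, LONG = 20000))
truths <- make_diploid_truths(guides$guide_SHORT, guides$guide_LONG,
                              snv_rate = 1e-3, n_sv = 20, seed = 1)
sim <- simulate_reads(truths, read_sim_params(depth_fold = 30, seed = 1))
nrow(sim$pairs)
#> [1] 31955

res <- assemble_haplotype(sim$pairs, guides$guide_SHORT,
                          alt_guide = guides$guide_LONG)
res$consensus
#> <consensus_assembly> guide guide_SHORT: 149438 bp consensus (1820 filled), 9 unplaced records
res$stats
#>   n_contigs   n50 total_length
#> 1        15 33551       207099

aln <- align_to_truth(res$consensus, truths[[1]])
call_errors(aln)
#> <error_report> 147618 bp assembled | base 0.1199% | SV non-repeat 0.2832% | SV repeat 0.1335% | total 0.5365% | >1kb false SVs: 0
recover_novel_variants(res$consensus, truths[[1]])
#> <variant_recovery> SNV 122/150 (81.3%) | SV 18/20 (90.0%)
```

Reading the output: the consensus is one continuous sequence in guide
coordinates, 149,438 bp of which 1,820 bp could not be assembled and were
filled from the guide (lowercase); nine unplaced records carry novel or
locally displaced sequence (including the other haplotype's alleles where
the two haplotypes competed).  Against the ground truth, 0.12% of
assembled bases are substitution errors and 0.42% sit in small false
indels — mostly the other haplotype's alleles at heterozygous sites, the
expected cost of a single pseudo-haploid consensus — with no false
structural variant over 1 kb.  Eighteen of the twenty planted novel
structural variants and 81% of the (half heterozygous) novel SNVs are
present in the output records.

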