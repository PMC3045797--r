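# spliceLoop

Simulation and analysis of heteroduplex-trapped, alternative-splicing
(AS) enriched cDNA libraries.

## The problem

AS-enriched libraries capture splicing differences physically: denatured
double-stranded cDNA re-anneals, and two splice variants of the same gene
hybridize through their shared exons into a **heteroduplex** whose
variant-discordant region forms a single-stranded loop. Random
biotinylated 25-mers anneal to the loops, so streptavidin beads enrich
DpnII restriction fragments that straddle an AS event. The sequenced tags
(ASSETs — *alternative splicing sequence-enriched tags*) land on splicing
differences without prior knowledge of the variants.

`spliceLoop` is for people building or analyzing such libraries (or
evaluating the protocol in silico): it re-enacts the protocol at sequence
level with per-read ground truth, and implements the full downstream
pipeline.

## What it computes

* **Simulator** — log-normal variant abundances; heteroduplex loops as
  the symmetric difference of two exon chains; exonuclease trimming of
  unpaired ends; DpnII digestion restricted to double-stranded GATC;
  25-nt loop capture with a 5% noise floor; shifted-Poisson PCR
  duplication (mean 6.6 reads/fragment); FASTQ + truth manifest.
* **Read processing** — windowed quality trimming (20-nt windows, ≥ 15
  bases at Phred ≥ 20, longest run kept), vector trimming, greedy overlap
  clustering into contigs/singlets with majority consensus, and the
  redundancy statistic `100 × (reads − consensus)/reads`.
* **Alignment filtering** — PSL/BED12 ingestion, best-hit selection by
  (matches, identity, coverage), the inclusive identity ≥ 93% / coverage
  ≥ 55% filter, multi-exon vs intronless split, positional profiles along
  reference transcripts.
* **Event classification** — single-linkage clustering of tags with
  reference transcripts by exonic overlap; pairwise exon/intron boundary
  comparison inside the window delimited by the two outermost exonic
  overlaps; four event types with strand-normalized donor/acceptor roles:

  | type | rule | size |
  |---|---|---|
  | `alt_5ss` | shared acceptor, shifted donor | donor shift (nt) |
  | `alt_3ss` | shared donor, shifted acceptor | acceptor shift (nt) |
  | `intron_retention` | intron strictly inside the other chain's exon | intron length |
  | `exon_skipping` | exons strictly inside the other chain's intron, flanking boundaries matching | summed exon length |

* **Coding consequences** — in-frame stop scan from an annotated ATG,
  distance from the stop to the last exon–exon junction, and the strict
  50-nt nonsense-mediated-decay (NMD) rule.
* **Expression balance** — reference-gene normalization, per-sample
  asset/variant balance, signed cross-sample fold (`r` if `r ≥ 1`, else
  `−1/r`), `|fold| ≥ 2` differential calls, and ligation-probe design
  against variant-specific exon junctions.

## Worked example

```r
library(spliceLoop)

# simulate a 12-gene library (one planted AS event per gene) and run the
# whole pipeline
res <- runPipeline(pipelineConfig(seed = 7, nGenes = 12), outDir = "out")
```

The run prints its summary to `out/summary.txt`:

```
seed: 7
reads in: 148, surviving QC: 135
consensus sequences: 19 (19 contigs, 0 singlets)
redundancy: 85.93%
aligned assets kept: 19 (15 multi-exon, 4 intronless)
AS events: 11
  exon_skipping: 3 (27.3%)
  intron_retention: 3 (27.3%)
  alt_5ss: 3 (27.3%)
  alt_3ss: 2 (18.2%)
planted-event recall: 0.917
```

Reading it: 148 simulated reads collapse to 19 consensus tags (a
redundancy of 85.93%, the deliberate consequence of the mean-6.6 PCR
duplication model); 15 multi-exon tags classified against the reference
variants recover 11 of the 12 planted events (one loop fragment was lost
to the 5% capture noise), each with the correct type.

Single operations work standalone:

```r
redundancy(946, 144)      # 84.78  (% of sequencing spent on duplicates)
signedFold(20.0, 95.7)    # -4.8   (case/control balance fold, signed)
nmdCandidate(96)          # TRUE   (stop 96 nt upstream of last junction)
```

A command-line wrapper is installed at
`system.file("scripts", "run_pipeline.R", package = "spliceLoop")`.

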