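---
title: "spliceLoop: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spliceLoop: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceLoop)
```

# The problem

Alternative-splicing (AS) enriched cDNA libraries exploit a physical trick:
when double-stranded cDNA from a transcript population is denatured and
re-annealed, two different splice variants of the same gene hybridize
through their shared exons and form a *heteroduplex* whose
variant-discordant region bulges out as a single-stranded loop. Random
biotinylated 25-mers anneal to those loops, so streptavidin capture enriches
restriction fragments that straddle a splicing difference. Sequencing the
captured fragments yields partial cDNA tags — ASSETs (alternative splicing
sequence-enriched tags) — concentrated around AS events, without prior
knowledge of the variants.

`spliceLoop` provides (i) a sequence-level simulator of that protocol with a
per-read ground-truth manifest, and (ii) the downstream analysis pipeline:
windowed quality trimming, greedy overlap clustering into consensus tags,
identity/coverage filtering of spliced placements, exon/intron boundary
comparison that classifies AS events into four types, coding-consequence
characterization (premature termination codons and the 50-nt NMD rule), and
reference-gene-normalized expression balance with signed fold changes.

# The simulator

## What it models

* **Abundances.** Per-variant copy numbers are log-normal
  (`abundanceMeanlog`, `abundanceSdlog`; defaults `log(50)` and 1). The
  spread creates the skewed variant balances that make one duplex strand
  dominate in real libraries.
* **Heteroduplex formation.** For each ordered variant pair (A, B) of a
  gene, the two spliced sequences are paired through their shared genomic
  positions. Positions of A absent from B are single-stranded loops;
  unpaired terminal overhangs are removed, abstracting the
  exonuclease-VII step to "keep the region between the outermost shared
  base pairs".
* **Restriction digestion.** DpnII cuts 5' of GATC. Inside a duplex, only
  sites whose four bases are double-stranded (shared by both variants) are
  cut: a restriction enzyme requires double-stranded substrate, so loops
  are never cut. The pure-string `dpniiDigest()` operation, by contrast,
  cuts every GATC — it models digestion of an ordinary homoduplex.
* **Capture.** A fragment whose longest loop reaches `minLoop` (default
  25 nt, the annealing length of the biotinylated 25-mer; the protocol
  itself fixes no threshold, so it is a tunable) is captured with
  probability `1 - captureNoise`; loop-less fragments leak in with
  probability `captureNoise` (default 0.05).
* **PCR redundancy.** Each captured fragment yields
  `1 + Poisson(pcrRedundancy - 1)` reads — the simplest one-parameter
  duplication model with a controllable mean. The default mean of 6.6
  reads per distinct fragment corresponds to a library-level redundancy
  statistic near 85% (`1 - 1/6.6`), the regime reported for Sanger-scale
  AS-enriched libraries.
* **Errors.** Substitutions at `readErrorRate` (default 1e-3) with Phred
  qualities drawn from a clipped normal (mean 30, sd 3). Reads are emitted
  5'→3' of one duplex strand per clone, reflecting the single-strand
  adaptor-ligation artifact of the protocol.

All randomness flows from `SimulationParams@seed`; stages derive their
streams from it, so reruns are byte-identical.

## The planted gene set

`simulateGeneSet()` defines the study conditions: 50 two-variant genes
(5–8 exons of 90–200 nt, introns of 120–300 nt), alternating strands, one
planted AS event per gene cycling through exon skipping, intron retention,
and alternative 5'/3' splice sites (shifts of 30–120 nt, so every loop
exceeds the 25-nt capture threshold). Every junction carries canonical
GT/AG dinucleotides written strand-aware into the genome, and every
transcript starts with ATG.

Two deliberate generator choices:

* One GATC is planted mid-exon (on top of natural background occurrences,
  about one per 256 nt) so duplex fragments typically extend a junction
  beyond the loop on each side — matching the 100–700 nt multi-exon tags
  the protocol produces. For intron-retention genes the two exons being
  merged are kept GATC-free; otherwise the retention fragment would be cut
  inside the merged exon, come out single-block, and be excluded from
  classification as intronless.
* No 3'-bias is applied to the amplification steps: positional profiles of
  the captured tags along their transcripts are flat by construction,
  which is what `relativePositionProfile()` measures.

What the simulator does **not** emulate: hybridization thermodynamics,
chimeras, cloning-vector insertions, indel sequencing errors, and genome
context outside the simulated loci. Passing end-to-end tests therefore
demonstrate correctness of the pipeline's logic under controlled
conditions, not robustness to every artifact of real Sanger data.

# Read processing

Quality trimming keeps the longest run of consecutive 20-nt windows
containing at least 15 bases at Phred ≥ 20 (windows advance 1 nt); reads
below 50 nt after trimming are discarded. When several good runs exist the
single longest is kept — the conventional phred/lucy-style choice.

Clustering replaces black-box EST assembly with a specified greedy
algorithm: reads seed clusters longest-first; a read joins the cluster
whose consensus gives its best overlap of ≥ 40 nt at ≥ 95% identity
(overlap alignment; identity = matches / aligned columns), and the
consensus is recomputed by per-column majority with ties broken toward the
lexicographically smallest base. A shared-k-mer prefilter (21-mers sampled
every 10 nt) limits alignments to plausible clusters; it affects speed,
not the decision rule. The stacking step assumes substitution-dominated
errors — appropriate for the simulator and for quality-trimmed Sanger
reads, approximate for indel-rich data.

The redundancy statistic is `100 * (reads - consensus) / reads`, reported
to two decimals.

# Alignment filtering

Spliced placements arrive as PSL or BED12 + metrics, or from
`alignToModels()`, a transcript-guided placement that matches each
consensus against candidate spliced sequences (substitution-only) and
projects the matched interval through the exon map — a consumer of
transcript models, not a genome-scale aligner. Identity is
`100 * matches / aligned bases` (query gaps excluded, the PSL convention)
and coverage is `100 * aligned bases / consensus length` (the consensus,
not the genomic span, is the denominator). Best hits maximize (matches,
identity, coverage) lexicographically with a deterministic (chrom, start)
tie-break; the filter keeps identity ≥ 93 and coverage ≥ 55, both
inclusive. Chains with ≥ 2 blocks are multi-exon; single-block tags are
intronless and are excluded from event classification because they carry
no splice-site orientation.

# Event classification

Assets and reference transcripts are clustered single-linkage by ≥ 1 nt of
exonic overlap on the same chromosome and strand. Within a cluster, each
multi-exon asset is compared to each reference inside the *comparison
window* — from the start of the 5'-most to the end of the 3'-most exonic
overlap of the two chains; only introns fully inside the window are
compared. After strand normalization (the donor is always the
transcription-5' side of an intron):

* identical introns → no event;
* shared acceptor, shifted donor → `alt_5ss`, size = donor shift;
* shared donor, shifted acceptor → `alt_3ss`, size = acceptor shift;
* an intron of one chain strictly inside a single exon of the other →
  `intron_retention`, size = intron length;
* complete exons of one chain strictly inside a single intron of the
  other, that intron's two ends matching the flanking introns' outer
  boundaries → `exon_skipping`, size = summed skipped exon length. The
  two intron pairs explained by a skipping event are suppressed from the
  alt-site comparisons, so a skipped exon is not double-counted as an
  alt-5' plus an alt-3' event.

Containment is strict for both skipping and retention: a skipped exon or
retained intron sharing a boundary with its host degrades to an alt-site
call. This single rule prevents double counting and gives every boundary
configuration exactly one label. The minimum alt-site shift is 1 nt — no
lower-bound filter is applied. Event lists are deduplicated by (type,
coordinates) within a cluster by default (`dedup = FALSE` retains one
record per asset–reference pair, for the alternative bookkeeping in which
a difference seen against several references counts several times).
Mutually exclusive exons, alternative first/last exons and alternative
polyadenylation are outside the four-type scheme and are not classified.

# Coding consequences

`findStop()` scans codon-by-codon from an annotated ATG in transcript
space; `ptcDistance()` is the offset from the stop codon's end to the last
exon–exon junction (positive = upstream); `nmdCandidate()` applies the
canonical 50-nt rule, strictly (`distance > 50`, tunable). Start codons
are taken from annotation projected onto the variant; de novo ORF scanning
is deliberately out of scope. A retained *last* intron always places its
new stop downstream of the final junction, so such variants are never
flagged — the geometry, not a special case, produces that answer.

# Expression balance

Peak concentrations are normalized by a per-sample reference-gene factor
(supplied by the user; the factors are never published alongside such
tables). The balance is asset/variant within a sample; the cross-sample
fold is `r = case/control` reported as `r` when `r ≥ 1` and `-1/r`
otherwise. The signed convention is inferred from the negative entries
such tables print; the plain ratio text description alone would not
produce them. Reported values round half-away-from-zero at one decimal;
differential calls use `|fold| ≥ 2`, inclusive. `balanceTable()` computes
folds from the one-decimal balances, matching how printed tables chain
their columns. Ligation probes for variant-specific assays concatenate the
forward-primer site (19 nt), the 38-nt stuffer, and a 20-nt upstream arm
(left probe), and a 20-nt downstream arm plus the reverse-primer site
(23 nt, right probe, 5'-phosphorylated): the default amplicon is
19 + 38 + 2×20 + 23 = 120 nt.

# Numerical and design notes

* Coordinates are 1-based closed `IRanges` throughout, converted at the
  BED12 boundary. Boundary equality tests are exact integer comparisons
  within one convention, which is all the classifier needs.
* Transcripts with introns shorter than 4 nt are rejected on load: they
  cannot carry splice dinucleotides.
* 5'/3' in event names always refers to transcription orientation;
  classification happens after strand normalization, and mirroring a case
  to the minus strand leaves the labels invariant (tested).
* Rounding for reports is half-away-from-zero with a 1e-9 epsilon guard
  against binary representation of decimal halves.
* Problem sizes used by the test suite — 50 genes end-to-end, 1000 random
  chain pairs against the brute-force classifier oracle, 10-gene runs for
  the PCR-redundancy monotonicity check — were chosen as the smallest
  scales at which the stochastic acceptance bands (recall ≥ 0.9,
  redundancy within 80–90%) are comfortably stable under the fixed seeds.

# Known limitations

* The greedy clusterer is not an overlap-layout-consensus assembler; deep
  or repetitive read sets may fragment across clusters.
* `alignToModels()` requires the true transcript (or a close model) to be
  among the candidates; it cannot discover unannotated loci.
* Recall in the end-to-end simulation is capped by capture: each planted
  event rides on a single loop fragment, so the 5% capture-noise floor
  translates directly into a few-percent event loss.
* The published corpus-scale figures of the original study (214 tags, 164
  clusters, 138 events and their type split, ontology enrichments) depend
  on unreleased sequences and 2007-era databases; the package checks the
  arithmetic and algorithms behind them, not those numbers themselves.
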