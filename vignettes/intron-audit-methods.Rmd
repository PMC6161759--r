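---
title: "Auditing very small introns: models, parameters and design choices"
author: "intronAudit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing very small introns: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronAudit)
```

## The problem

Genome annotations predict introns from sequence models and transcript
evidence, and both can err. Predicted introns of a few tens of base pairs
are particularly suspect: canonical spliceosomal introns carry a GT donor
and an AG acceptor and appear to have a lower size limit somewhere below
100 bp, so an annotated 10- or 20-bp "microintron" is more likely a gene
model artifact -- a tandem-repeat-confused alignment, a mis-placed
boundary inside a larger real intron, or a pseudogene with no transcript
at all -- than a genuine splicing event.

The experimental audit this package models works gene by gene: amplify a
cDNA fragment that spans both the suspect intron *and* a second, larger
**control intron**, then sequence the product. If the control intron is
absent from the product, the template was spliced mRNA, and the suspect
intron's own presence or absence in that same read settles its status. If
the product matches genomic sequence end to end, nothing can be concluded
(the template may have been genomic DNA), which is recorded as
*unable to judge*.

`intronAudit` implements every computational step of that audit:

1. **Census** (`readGenome`, `readAnnotation`, `deriveIntrons`,
   `intronCensus`): derive per-isoform introns from FASTA + GFF3 and
   tally their size distribution.
2. **Screen** (`selectCandidates`, `applyExclusions`,
   `flagRepeatContext`, `diffAnnotations`): pick introns at or below a
   size threshold and exclude the unverifiable ones.
3. **Design** (`designPrimers`, `inSilicoPcr`): two-intron primer pairs
   whose genomic and spliced product sizes differ by the summed spanned
   intron lengths -- the discrimination signal.
4. **Verdict** (`splicedAlign`, `refineBoundaries`, `classifyAmplicon`,
   `verifyPanel`): align each sequenced amplicon to its locus with
   intron-sized gaps and call the outcome.
5. **Report** (`summarizePanel`, `consistencyReport`): panel tallies and
   arithmetic checks over published survey counts.
6. **Simulate** (`simulateGenome`, `simulateAmplicons`): synthetic
   genomes with planted annotation errors and known truth, so steps 1-5
   are testable end to end with no downloads.

## Coordinates, counting and bins

Internally every interval is a 1-based closed `IRanges`/`GRanges`, the
R/Bioconductor convention; `rtracklayer` handles the GFF3 boundary, so
file coordinates are 1-based inclusive on both sides of I/O. Intron
intervals are always reported on the forward genomic strand; ordinals,
donors and acceptors always follow transcript orientation
(reverse-complemented for minus-strand isoforms). Intron IDs are
`<isoform>-<ordinal>`.

Introns are counted **per isoform occurrence** by default, matching the
per-isoform ID scheme used in annotation releases; `uniqueLoci = TRUE`
collapses identical genomic intervals for locus-level counting. The
default census bins are the irregular decades used in small-intron
surveys -- below 30, exactly 30, 31-39, 40-49, 50-59, then 60-70, 71-80,
81-89, 90-99. Bins are defined by inclusive lower edges (each bin ends
where the next begins), which is why the 60 bin runs to 70: published
binnings in this area are themselves inconsistent about where 70 bp
falls, and lower-edge bins keep the partition total without a gap.

Donor/acceptor dinucleotides containing N are flagged non-canonical
rather than rejected; N bases are legal genome content.

## Screening rules

A candidate is excluded as `NO_CONTROL_INTRON` only when *no* isoform of
its gene offers a second intron: the control-intron requirement is about
what can be co-amplified from the gene, so any isoform that provides a
second intron rescues the candidate. `NO_PRIMER_SITE` marks candidates
whose neighbouring exons cannot host an acceptable pair under the design
constraints (decided by actually running the designer).
`AMBIGUOUS_PRODUCT` is reserved for candidates whose product turned out
to be indistinguishable downstream; it is assigned from verification
results, not predicted.

The repeat flag scans the candidate interval plus 30 bp of flank on each
side for a perfect tandem repeat of period 1-10 with at least 3 exact
copies, reporting the best tract (most copies, then smallest period,
then leftmost). The defaults are chosen so that a hexamer tract of the
CAACAG type -- the classic repeat context that induces microintron
mispredictions -- trips the flag; all three thresholds are arguments.

Candidates are rank-ordered by descending gene expression in reports
because the audit works through high-expression genes first: those are
the genes whose cDNA is actually obtainable.

## Primer design

Defaults: primer length 18-25 nt, Wallace-rule Tm (2(A+T) + 4(G+C))
between 50 and 65 degrees C, GC 40-60%, pair Tm difference at most 5,
spliced product 120-1000 bp. These are conventional ranges for
Sanger-sequencable RT-PCR products; primer optimality is not the point
of the audit, so there is no nearest-neighbour thermodynamics and only a
minimal 3' check (a perfect 4-bp 3' dimer rejects the pair).

The control intron is the annotated intron adjacent to the candidate --
downstream in transcript orientation when one exists, otherwise
upstream, so first and last introns get the only control available to
them. The scan is fully deterministic: forward windows advance 5' to 3'
through the exon upstream of the earliest spanned intron, reverse
windows retreat 3' to 5' through the exon downstream of the last
spanned intron (their range pre-bounded by the product-length
constraint), and the first feasible pair wins. Determinism makes designs
reproducible and testable; nothing is stochastic anywhere in the design
path.

## Spliced alignment and verdicts

`splicedAlign` decomposes an amplicon against its locus into collinear
blocks separated by locus-only gaps. Exact k-mer anchors (k = 15 by
default) are merged into maximal exact diagonal segments, chained by a
small dynamic program that maximises matched amplicon bases, and the
regions between chained segments are resolved: unplaced amplicon bases
attach to the flanking blocks at the split maximising matches (leftmost
on ties), locus gaps shorter than `minSpliceGap` are absorbed as small
deletions, amplicon-only bases as small insertions. Every reported gap
is then put into a deterministic *leftmost normal form* (shifted as far
left as sequence allows), which makes results comparable against
exhaustive enumeration.

Three numerical choices deserve explanation:

* **`minSpliceGap` = 8 bp.** The smallest predicted candidate a panel
  plausibly tests is around 8 bp, so a gap that small must still count
  as splicing evidence; anything smaller is treated as an alignment
  indel. Lowering the threshold can only convert indels into gaps,
  never the reverse, so relaxing it never destroys splicing evidence.
* **Anchor ladder 15 / 11 / 8.** A short edge block carrying a
  substitution can contain no exact 15-mer at all, in which case its
  splice gap would be silently absorbed into an edge extension. If the
  alignment that comes back is noisier than the tolerated substitution
  rate (`maxMismatchRate`, default 5%), the aligner retries with
  shorter anchors and keeps the cleanest result.
* **GT..AG prior in `refineBoundaries`.** When block ends repeat the
  gap edges, several gap placements reconstruct the amplicon equally
  well; the refiner enumerates them and keeps the placement whose gap
  is canonical in transcript orientation (GT..AG; CT..AC on the forward
  strand of a minus-strand gene), leftmost among canonical, leftmost
  overall if none. When the amplicon itself is supplied, placements are
  compared by shift *cost* (change in mismatch count) -- for exact
  alignments zero-cost shifts are exactly the sequence-preserving ones
  -- and a canonical placement costing at most one extra mismatch is
  preferred. That last rule matters when a sequencing error lands on a
  splice junction: the error can make a one-off gap placement look
  exactly as good as the true one, and the splice-site prior is the
  only evidence left to break the tie.

`classifyAmplicon` then applies the decision tree: no gap at all means
the product is indistinguishable from genomic DNA
(`GDNA_UNABLE_TO_JUDGE`); gaps that never touch the candidate interval
mean the candidate is retained in the mature transcript
(`CDNA_NOT_AN_INTRON`); a gap equal to the predicted interval confirms
it (`CDNA_CONFIRMED`); a gap overlapping but exceeding it re-annotates
the intron (`CDNA_LARGER`, with the gap as the actual interval; the
never-expected smaller case is labelled `CDNA_SMALLER`). Gaps matching
no annotated intron and clear of the candidate are reported as extra
splicing. Orientation is resolved by aligning both strands and keeping
more matched bases, forward on exact ties.

## The synthetic generator

`simulateGenome` plants six scenario kinds with known expected verdicts:
true small introns (confirmed), false microintrons inside real exons
(not an intron), repeat-induced false microintrons (not an intron, with
the repeat flag), boundary shifts annotated strictly inside a larger
true intron (larger than predicted), extra unannotated introns
(confirmed plus extra splicing), and expression-0 pseudogenes (unable to
judge, because their only obtainable product is genomic).

Background sequence is i.i.d. uniform ACGT; true introns are forced to
GT..AG; there is no branch-point or splice-site-strength model, no
chromatogram noise and no heterozygosity. Passing the planted-truth
loop therefore shows the pipeline's logic and coordinate handling are
right under substitution noise -- it does not show robustness to the
full messiness of real Sanger traces or real genomes, which share
little of this generator's simplicity. True intron lengths are drawn
from a discrete law over 59-500 bp peaked at 85 bp (a normal bump of sd
10 mixed 80:20 with a uniform tail): small plant introns are strongly
modal in the 80s, and 59 bp is the smallest size the audit ever
verified a true intron at, hence the support's lower edge. Planted
candidate introns default to that same 59 bp. Exons are 120-300 bp and
genes sit on one chromosome separated by 200-400 bp spacers, sizes at
which every default design constraint is satisfiable. A single integer
seed drives one RNG stream consumed in documented order (scenario
assignment, then per-gene sequence, placement, expression), so a seed
and a configuration reproduce output byte for byte.

Scenario proportions are converted to gene counts deterministically
(cumulative rounding), not sampled, so a 50-gene default mix always
contains every scenario kind.

## What the test and acceptance runs compute

The suite checks the aligner against a brute-force single-gap
enumerator (100 random cases, blocks at least 25 bp, gaps at least
20 bp, up to 1% substitutions), boundary refinement against exhaustive
shift enumeration, repeat flagging against an exhaustive
period-times-phase scanner, the census of a 150-gene / 5-exon genome
against its configured law by chi-square, and the full
generate-screen-design-simulate-verify loop on a 50-gene genome at 0%
and 0.5% substitution error. The published-table material enters only
as fixture data: a transcribed verification table and the printed
survey counts, over which `consistencyReport` re-derives every
percentage (half-up rounding to the printed decimals, with the
genome-wide total obtained by inverting the sub-100 bp anchor
percentage and clearly labelled as derived). Genome-scale release
counts are deliberately not recomputed from raw annotation here; that
would require the frozen public releases themselves.

## Limitations

* The aligner's contract is desk-scale: amplicons of hundreds of bases
  against loci of a few kilobases. It is not a general spliced aligner
  and has no affine-gap model; sub-`minSpliceGap` indels are absorbed,
  not placed optimally.
* `CDNA_CONFIRMED` requires exact interval equality after refinement;
  a placement ambiguity that survives the GT..AG prior is reported as
  re-annotation, not silently accepted.
* Homolog counts and expression are consumed from TSVs, never computed;
  pseudogene status is only ever evidenced as "low expression plus
  genomic product", not called.
* No trans-splicing, no CDS/UTR semantics, no organellar intron types,
  no multi-product PCR artifacts beyond what `inSilicoPcr` reports.
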