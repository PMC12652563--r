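---
title: "Authentic start-codon harmonization and NMD feature annotation"
author: "OrfHarmony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Authentic start-codon harmonization and NMD feature annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OrfHarmony)
```

## The problem

Most genome annotation pipelines assign each transcript the longest open
reading frame (ORF) it can host. When alternative splicing introduces a
premature termination codon (PTC) early in the coding region, the longest
ORF of that isoform typically restarts at an internal methionine codon
downstream of the splicing event. The resulting annotation shows a normal
stop codon and an ordinary 3' UTR — but a ribosome scanning the transcript
has no way of knowing that a downstream splice event shortened the frame;
it initiates at the same start codon it uses on the unspliced isoform.
The longest-ORF convention therefore hides exactly the transcripts that
nonsense-mediated decay (NMD) surveillance degrades, and it produces
protein sequences (N-terminally truncated instead of C-terminally
truncated) that are never made.

`OrfHarmony` implements the alternative: pick, per gene, the **authentic
start codon** — operationalized as the start whose own-transcript ORF
encodes the longest protein across all isoforms of the gene — and impose
that genomic start position on every isoform ("Revised" annotation). The
conventional per-isoform longest ORF ("Reference" annotation) is kept as
a first-class mode so the two can be compared.

## The harmonization procedure

For each transcript the candidate ORFs are all ATG occurrences on the
sense strand, each extended to the first in-frame stop codon
(TAA/TAG/TGA) or, when none occurs, to the last complete codon before
the 3' end (a *stopless* ORF). Per gene:

1. compute each isoform's longest ORF (ties: stop-terminated preferred,
   then the 5'-most start);
2. map each winning start to genomic coordinates; the authentic start is
   the candidate whose own-transcript protein is longest gene-wide
   (ties: 5'-most genomic position in transcription direction, then
   lexicographic transcript id);
3. for every isoform, if the authentic genomic position falls in an
   exon and its spliced sequence reads ATG there, the Revised ORF runs
   from that ATG to the first in-frame stop (status `HARMONIZED`);
   otherwise the isoform keeps its own longest ORF
   (`FALLBACK_OWN_LONGEST`) or is `NONCODING`.

Two properties follow and are enforced by tests: the Revised protein is
never longer than the Reference protein of the same isoform (with
equality exactly when the starts coincide), and all harmonized isoforms
of a gene share one genomic start position.

The Kozak context is deliberately **not** used in start selection; it is
computed afterwards as a diagnostic (the fraction of starts matching
`RNNATGGV`, R = A/G, V = A/C/G, with the ATG literal and positions
−3/+4/+5 constrained — the standard register of the consensus).

### Fallback behaviour

What to do with an isoform from which the authentic start has been
spliced out (e.g. a skipped first exon), or where the position no longer
reads ATG, is a genuinely open design point. We keep the isoform's own
longest ORF and flag it `FALLBACK_OWN_LONGEST`, so downstream statistics
can include or exclude these isoforms explicitly; silently dropping them
would bias the comparison universe, and forcing `NONCODING` would
discard real coding potential. We also impose only "maps to an exonic
ATG" on harmonized isoforms, not cross-isoform frame compatibility —
the ORF is re-scanned in the isoform's own spliced frame.

## NMD feature classification

For an ORF ending at transcript coordinate `stopEnd` (last base of the
stop codon, 1-based) in a transcript with exon junctions at coordinates
`j` (a junction at `j` sits between bases `j` and `j+1`; `j` equals the
cumulative length of the preceding exons):

* downstream junctions are those with `j >= stopEnd`; the distance to
  the last one is `max(j) - stopEnd`;
* the stop is classified `PTC_dEJ` when at least one downstream junction
  lies **at least 50 nt** past it (the exon-junction-complex rule;
  threshold inclusive at 50, exposed as `dejThreshold`), else `NORMAL`;
* a junction exactly at `stopEnd` counts as downstream with distance 0,
  so it can never trigger a call at the default threshold;
* stopless ORFs are `NO_STOP` and absent ORFs `NONCODING`; neither
  enters NORMAL/PTC_dEJ tallies in any downstream statistic.

5' UTR length is `start − 1`, 3' UTR length `splicedLength − stopEnd`
(0 for stopless ORFs). The per-transcript record (stop class, UTR
lengths, dEJ distance and count, Kozak match, protein) is the feature
table written by `writeFeatureTable()`, with the protein in the final
`Translation` column.

Coordinates are 1-based inclusive throughout, the native convention of
the GRanges/Biostrings containers the package is built on; GTF I/O needs
no conversion, and the junction arithmetic above is identical to the
equivalent 0-based half-open formulation.

## Comparison and enrichment statistics

Comparing two annotation sets uses a like-for-like universe: transcripts
present with a classifiable stop (`NORMAL`/`PTC_dEJ`) in both. Over that
universe the package computes the stop-class transition table, the
changed-start set (ORF start differs), and Kozak match rates restricted
to the changed set.

Given a differential transcript expression table (id, corrected p-value,
log2 fold change — e.g. from an NMD-deficient mutant vs wild type), a
transcript is `UP` when `qval < 0.05` and `log2fc > 1`, `DOWN` when
`qval < 0.05` and `log2fc < −1` (strict inequalities; thresholds
tunable). Because loss of NMD has broad indirect (trans) effects, raw up
counts overstate direct targets; the package therefore uses the up/down
ratio within each stop class and summarises NMD-target enrichment as

$$
\text{enrichment factor} =
\frac{\mathrm{up}_{PTC}/\mathrm{down}_{PTC}}
     {\mathrm{up}_{normal}/\mathrm{down}_{normal}},
$$

with a two-sided Fisher exact test on the (up, down) × (PTC, normal)
table. The factor is reported as undefined (flagged, not an error) when
a denominator count is zero. 3' UTR lengths of up-regulated transcripts
under the two annotations are compared with a **paired** two-sided
Wilcoxon signed-rank test — the same transcripts are measured under both
annotations, so the paired variant is the natural choice; a
`paired = FALSE` switch gives the rank-sum variant. Statistics always
use all values; outlier handling is a plotting concern only.

## The synthetic fixture generator

Real inputs at study scale (a plant genome, a reference transcriptome,
RNA-seq-derived DE tables) are too large to ship, so every claim the
package tests is exercised on generated data with *constructed* ground
truth. `generateFixture()` emits a genome FASTA, a GTF and a truth table
for `nGenes` loci. Each gene has a canonical 3-exon isoform (5' UTR of
9–30 nt, coding body of 47–67 codons split 10–15 / 25–35 / 10–20 across
exons, 3' UTR of 30–80 nt, introns of 17–40 nt) and, per an event drawn
from `eventWeights`, at most one alternative isoform:

* `INTRON_RETENTION` — the first intron is retained; translation from
  the authentic start terminates inside it, leaving the downstream
  exon–exon junction ≥ 50 nt past the new stop (a planted `PTC_dEJ`),
  while the longest-ORF annotation restarts at a planted weak-context
  internal ATG and still reports `NORMAL`;
* `ALT_ACCEPTOR` — an upstream acceptor includes a 14-nt stop-bearing
  intron tail, with the same Reference/Revised contrast;
* `EXON_SKIP` — the first exon (carrying the authentic start) is
  skipped, exercising the fallback path;
* `NONE` — single-isoform gene (Revised must equal Reference).

Two construction rules make the truth table derivable by arithmetic
rather than by re-running the annotator: designed ORF bodies and UTRs
use T-free alphabets, so no start or stop codon can arise anywhere
except where planted, in any frame; and planted introns embed
`TAGCTAGCTAG`, which terminates translation within 11 nt in all three
frames, so retained-intron stops are position-predictable regardless of
phase. Canonical starts receive a strong Kozak context (`GCCATGGC...`)
with probability `pKozak` (default 0.5, giving both outcomes weight in
rate tests); planted internal ATGs always get a weak context (`CCC`
upstream, `C` at +4). A fraction `fracMinus` (default 0.3) of genes is
reverse-complemented onto the minus strand to keep strand handling
honest.

`generateDeTable()` plants differential expression over the truth: a
transcript is up-regulated with probability `pUpPtc` or `pUpNormal`
according to its planted stop class and down-regulated with a
class-independent probability `pDown` (emulating class-blind indirect
effects), and p-values/fold changes are drawn consistently with those
statuses. The planted enrichment factor is `pUpPtc / pUpNormal`.

### What the fixtures do and do not show

The generator emulates the *logic* of alternative splicing coupled to
NMD — isoform structure, junction placement, start-context composition —
not the statistics of a real transcriptome: exon and UTR lengths are
uniform rather than long-tailed, splice sites are not sequence-realistic
(the reader does not model them), expression is reduced to a trinary
status, and there are no overlapping genes, no single-exon PTC escapes,
and no noise in the annotation itself. Passing the truth-recovery tests
therefore demonstrates correctness of the coordinate arithmetic,
harmonization rule and classification rule, not performance on real
data; on real annotations the interesting failure modes are upstream
(transcript-model quality), which the package takes as given.

## Numerical and scale choices

* `minProteinLen` (default 30 aa) filters ORF *candidates* during
  discovery and harmonization — a conventional main-ORF focus that
  suppresses spurious micro-ORFs; already-harmonized ORFs are never
  re-filtered, so a truncated 1-aa Revised protein is reported, not
  dropped. The threshold is exposed everywhere.
* Genes whose isoforms span multiple chromosomes or strands (annotation
  errors) are processed per (gene, chromosome, strand) group with a
  warning rather than rejected.
* Ambiguity: codons containing N translate to `X` and are never starts
  or stops — conservative on uncertain sequence.
* Test and acceptance problem sizes — 200-gene truth-recovery fixtures
  (3 seeds), a 2000-gene enrichment-recovery fixture (3 DE replicates
  per planted factor, recovery judged on the replicate mean, whose
  relative sampling error is ~7% at these counts), 500 random
  transcripts against the brute-force ORF oracle, 10,000 random Kozak
  windows — were chosen so each estimate's sampling error is comfortably
  inside the asserted tolerance while the whole suite runs in a few
  minutes on one core.

## Known limitations

Only ATG initiation and the three canonical stops are modelled: upstream
ORFs, non-AUG starts, ribosomal frameshifting and selenocysteine
recoding are out of scope, as are long-3'UTR-only NMD calling (no
accepted length cutoff exists; lengths are reported, not thresholded)
and mechanisms of NMD escape such as nuclear detention of
intron-retained transcripts. Quantification and differential testing are
consumed as a finished table, never re-run. The enrichment factor is a
descriptive ratio of ratios; it deliberately does not model indirect
effects beyond assuming they are stop-class-blind.

## A minimal session

```{r example}
fxdir <- file.path(tempdir(), "fx")
fx <- generateFixture(nGenes = 50, seed = 9, dir = fxdir)
models <- readTranscriptModels(fx$gtfFile)
genome <- readGenome(fx$genomeFile)
seqs <- splicedSequences(models, genome)

reference <- annotateReference(models, seqs = seqs)
revised <- annotateRevised(models, seqs = seqs)
featRef <- nmdFeatures(reference, models, seqs = seqs)
featRev <- nmdFeatures(revised, models, seqs = seqs)

transitionTable(featRef, featRev)$counts

changed <- changedStartSet(featRef, featRev)
kozakRate(revised, seqs, ids = changed)$fraction

de <- classifyDe(generateDeTable(fx$truth, seed = 10))
enrichmentReport(de, featRev)
```
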