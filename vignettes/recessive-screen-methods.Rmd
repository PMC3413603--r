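---
title: "Methods: candidate-gene screening under a recessive model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: candidate-gene screening under a recessive model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recscreen)
```

## The problem this package addresses

When a single animal presents with a phenotype matching a known Mendelian
disease group — here, early-onset cerebellar ataxia in a dog, with Purkinje
cell degeneration — one productive strategy is to sequence mRNA from the
affected tissue and restrict the variant search to the orthologues of genes
already implicated in the same phenotype in another species. Under an
autosomal recessive model a short cascade of exclusions (no variant; variant
non-coding; variant heterozygous; variant synonymous; missense tolerated
across species) can reduce a few dozen candidates to a single gene carrying
a homozygous loss-of-function change, which is then validated by pedigree
segregation, population screening and expression analysis.

`recscreen` re-implements that whole workflow at desk scale on fully
synthetic data. Every stage is real, testable code: the synthetic-data
generator is a first-class module whose defaults encode the study
conditions the pipeline must reproduce, and the analysis stages (mapping,
pileup, calling, annotation, cascade, consequence prediction, pedigree and
qPCR analysis) are implemented against those data.

## The synthetic scenario

A `scenario_spec()` fixes the study conditions:

* 27 candidate genes, each on its own contig, with 3–6 exons (90–240 bp,
  `GT..AG` introns), a CDS starting at `ATG` with a single terminal stop,
  and 5'/3' UTRs;
* paired-end 51 bp reads sampled from the spliced transcripts at a mean
  depth of 30, with constant Q35 qualities and a substitution error rate of
  0 by default (callers are exercised on clean signal; an error-rate
  parameter exists for robustness experiments);
* a category plan assigning each gene its planted-variant class. The
  default 27-gene plan is: 11 genes with no variant, 3 with a UTR variant
  only, 4 with a heterozygous coding missense SNV, 2 with a homozygous
  synonymous SNV, 3 with a homozygous missense SNV whose alternate residue
  is conserved across an ortholog panel, 1 with the causal variant, and 3
  genes that are incompletely covered and carry nothing;
* the causal variant is a homozygous 8 bp exonic deletion engineered inside
  a constructed tandem repeat — the 8 bases immediately 5' of the deleted
  bases are an identical copy, mimicking a deletion by homologous
  recombination — with a linked homozygous SNV exactly 18 bp downstream of
  the deleted sequence.

Three design choices deserve comment.

**Non-coding means UTR.** mRNA-seq reads only cover transcribed sequence,
so the "non-coding variants only" category is planted in UTRs. Intronic
planting is supported by the data model but not used in the default plan:
an intronic variant would be invisible to RNA reads and detection could
never equal the planted truth.

**Zygosity of the excluded classes.** The synonymous and
tolerated-missense classes are planted homozygous. If they were
heterozygous, the cascade's heterozygote-exclusion step (which fires
earlier) would absorb them and the 4/2/3 split of the excluded classes
could not exist. The heterozygous class is planted as missense so that its
exclusion is attributable to zygosity alone.

**Guaranteed coverage.** At 30× with uniform random fragment starts, the
first and last transcript bases are left uncovered with high probability —
which would contradict the scenario's own premise that 24 genes have
complete exonic coverage. The generator therefore lays a deterministic
tiling of abutting read pairs (overlapping steps) under the random layer,
so that a fully covered gene has every exonic base covered by construction,
while incompletely covered genes get a zero-coverage exonic window at
least one read length wide (fragments touching the window are discarded).
Heterozygous sites receive their allele per fragment — drawn 50/50 in the
random layer, alternating deterministically in the tiling layer — so hom
sites have allele fraction exactly 1 and het fractions converge to 0.5.

What the generator deliberately does **not** emulate: realistic error and
quality profiles, RNA degradation, 3' bias, and expression differences
between genes (depth is uniform apart from the coverage plan). Passing
tests therefore demonstrate the correctness of the algorithms on clean,
structurally faithful data; they say nothing about robustness to the noise
floor of a real sequencing run.

## The toy spliced mapper

Reads are placed against an exact k-mer index (k = 20) of the annotated
spliced transcripts and the resulting alignments are projected to genomic
coordinates, introducing `N` CIGAR operations at exon junctions. Working in
transcript space is the direct implementation of the decision to resolve
intron gaps *only* against the annotated gene models (no de novo junction
discovery), and it makes junction-spanning reads unproblematic: they are
contiguous in the space where seeding happens.

Each read is anchored by its two end seeds. Concordant seeds give an
ungapped placement (accepted at ≤ 3 mismatches); discordant spacing within
±50 bp implies an indel, verified by an exact prefix/suffix split. When
only one end seed anchors uniquely — which is the norm for reads whose
other end overlaps a planted allele, e.g. every deletion-spanning read also
carrying the linked SNV — the read is *rescued*: aligned with affine gaps
(`Biostrings::pairwiseAlignment`) against the local transcript window and
accepted only under a strict cap (≤ 3 mismatches, at most one gap event of
≤ 50 bp, and at least 8 matching bases flanking any gap). Without the
rescue path, end-anchored exact seeding alone would systematically unmap
alt-carrying reads, biasing het allele fractions below the calling band
and hiding the causal deletion entirely.

Two numerical choices matter here:

* **Scoring.** Match +1, mismatch −6, gap opening 5, gap extension 0.5.
  Inside a tandem repeat an 8 bp deletion competes with a shifted,
  gapless register that differs by only a couple of bases; a mild mismatch
  penalty would make the wrong register cheaper (this is exactly what
  production short-read aligners do, which is why indels in repeats are
  hard). The steep mismatch/shallow gap scoring makes the gapped alignment
  win whenever it is genuinely better.
* **Canonical gap placement.** All equivalent placements of an indel
  inside a repeat are shifted to the leftmost position at alignment time,
  so every read reports the same anchor and the pileup accumulates one
  event rather than several fractured ones.

Reads with ambiguous (multi-hit) seeds are flagged unmapped rather than
placed randomly, keeping the pipeline deterministic. Reads whose planted
alleles corrupt both end seeds (a ~6-position window for the
deletion + linked-SNV configuration) go unmapped; at 30× this costs a few
percent of depth near the event and nothing elsewhere, and the mapped
fraction of a scenario run stays above 0.95.

## Pileup, variant detection and normalization

The pileup records per-column allele multisets. Deleted bases are recorded
as `-` markers at every deleted position (they count toward depth — a base
spanned by a deletion-carrying read *is* covered, which is why the
coverage census over the causal gene still reports completeness) plus a
single anchored deletion event.

Calling thresholds follow conventional pileup heuristics and are
configurable: minimum depth 3, heterozygous allele-fraction band
[0.2, 0.8), homozygous threshold 0.8. Indel events are left-normalized
(the standard shift-left-while-the-context-repeats algorithm; idempotent)
and merged before thresholding.

One subtlety is specific to indels in repeats. A read that ends *inside*
the repeat is reference-consistent yet uninformative: it neither supports
nor contradicts the deletion. Counting such reads as reference support
deflates the allele fraction of a true homozygote below the homozygous
threshold. A read only contradicts a deletion if it shows a base at every
deleted column, so the reference-supporting depth is taken as the minimum
reference-base depth across the deleted columns, and the fraction is
support / (support + that minimum). Relatedly, the occasional read that
aligns gaplessly in a shifted repeat register deposits stray alt bases
inside the deleted interval; since a homozygously deleted interval has no
sequence left to carry an SNV, SNV calls inside a called homozygous
deletion are suppressed.

## The exclusion cascade

Genes are classified in a fixed order: no variants → `no_polymorphisms`;
all variants outside the CDS → `noncoding_only`; all CDS variants
heterozygous → `excluded_heterozygous` (a recessive causal variant must be
homozygous in the affected); all CDS variants synonymous →
`excluded_synonymous`; every non-synonymous CDS variant a missense whose
alternate residue is observed in the ortholog panel at that codon →
`excluded_nonsynonymous_tolerated`; anything else → `candidate_causal`.
The classification is a pure function of the variant annotations, so it is
invariant to input order, and the categories partition the gene set.

The conservation rule had to be made operational: the source reasoning
covers both "the alternate residue is the conserved one" and "both residues
occur naturally". Both are subsumed by *alternate residue observed in ≥ 1
panel sequence at that codon*; the panel and the rule are configurable, and
the simulated panels write the alternate residue into all five orthologs
for the tolerated class (the conserved-alternate situation) while
protecting every other planted codon at the reference residue.

Incompletely covered genes are reported with their coverage status but are
not excluded by it — their category reflects detected variants only. When
the screen's category counts are compared against a study that classifies
only its fully covered genes, the comparison is made over
coverage-complete genes (`category_counts(reports, complete_only = TRUE)`).

## Protein consequence prediction

`apply_and_translate()` applies CDS variants jointly and translates to the
first stop. Joint application matters: a frameshift may run into a stop
codon of the shifted frame that a *downstream* SNV destroys, lengthening
the aberrant run — the layered situation the screen's worked example
exhibits, where the linked SNV extends the aberrant run before premature
termination. The report carries the identity

wild-type length = (first aberrant residue − 1) + aberrant run + truncation

for frameshifts that terminate early, and emits two notations: the
anchor-insertion dialect (`p.G1952insRDR…*` — last wild-type residue, then
the full aberrant peptide, `*` marking termination) and standard HGVS
frameshift form (`p.R1953fsTer28`). The dialect parser/emitter is an exact
round trip; the translation core is the package's own codon stepper and is
tested against `Biostrings::translate` as an independent oracle.

In-silico PCR is exact-match only (no mismatch tolerance or melting-
temperature model): forward primer and reverse-complemented reverse primer
located on the template, product size spanning both primers inclusively; a
deletion allele shifts the product size accordingly (268 bp vs 260 bp for
the genotyping amplicon design).

## Pedigree and population analysis

Fragment-analysis peaks are assigned to the nearest expected allele size
within ±1.0 bp (capillary size noise is ~0.15 bp and the allele-size
difference is 8 bp, so the window is generous yet unambiguous);
unassignable peaks yield `missing` with a diagnostic, and more than two
assigned alleles is treated as a contamination signal.

Segregation under the recessive model counts as discordant any affected
individual not `del/del` and any `del/del` individual not affected;
individuals of unknown affection or missing genotype are never discordant
(the rule must be explicit for synthetic pedigrees). Mendelian errors are
parent–offspring allele impossibilities assessed where the trio is fully
genotyped. The built-in `study_pedigree()` reproduces the screening
family: both parents heterozygous, fourteen full siblings in two litters —
three affected, of which two genotyped `del/del` — seven unaffected
heterozygotes, three unaffected wild-type homozygotes, two offspring
ungenotyped (the counts printed by the study imply exactly two, one
affected and one unaffected), plus seven paternal half-siblings planted as
3 het / 4 wild type.

The 3-affected-of-14 litter ratio is assessed with a two-sided exact
binomial test at p = 0.25, using the minimum-likelihood convention (sum of
the probabilities of all outcomes no more likely than the observed one);
this is `stats::binom.test`'s convention, and the test suite verifies it
against full pmf enumeration for all n ≤ 30. "Consistent with recessive
inheritance" means p ≥ 0.05.

## Efficiency-corrected qPCR

Standard curves regress Ct on log2(relative quantity) over a seven-point
2× dilution series; with slope *m*, efficiency is E = 2^(−1/m) − 1 (a
helper converts the −3.32-per-decade log10 convention). Relative
expression uses the efficiency-corrected ratio with ΔCt = Ct(control) −
Ct(case):

ratio = (1+E_target)^ΔCt_target / combine_ref (1+E_ref)^ΔCt_ref

The combination rule over multiple reference genes is not dictated by the
source material; the geometric mean of the per-reference corrected ratios
is the standard multi-reference convention and is the default, with
arithmetic averaging of reference ΔCts available as `combine = "mean_dct"`
(the two agree closely at these efficiencies). Replicates are aggregated
by mean Ct. A ratio below 1 is reported as an N-fold reduction, N =
1/ratio. The ratio is scale-invariant under a constant Ct shift, reduces
to the classic 2^−ΔΔCt for a single reference at E = 1, and inverts under
case/control swap — all tested as invariants. The plate simulator follows
Ct = Ct0 − log(q)/log(1+E) plus Gaussian noise, and parameter recovery of
a 68-fold knockdown at the published assay efficiencies (99.3%, 94.3%,
100.3%) is within 10% at noise sd 0.1.

## Problem sizes, runtime and degenerate inputs

The full 27-gene scenario (≈ 13,000 read pairs) runs the complete pipeline
in roughly 10–15 s on one CPU; the property suites run the detection-
equals-truth check over 20 seeds on 3-gene scenarios, which exercise the
identical code paths (the causal gene, a heterozygous and a homozygous SNV
class) at a fraction of the cost. These sizes are the package's chosen
test conditions, not limits of the method.

Degenerate inputs are named errors at the module boundary: gene models
without exons, unsorted alignments entering the pileup, read lengths
exceeding the shortest exon, indels that cannot be left-anchored at a
contig start, overlapping CDS variants, degenerate dilution series,
out-of-range expected fractions, cyclic pedigrees, and unanchored indel
records in VCF output.

## Known limitations

* All gene models are plus-strand and one gene per contig; the coordinate
  machinery does not handle minus-strand transcripts.
* The mapper is exact-seeded and desk-scale: no mismatch-tolerant seeding,
  no mate rescue, no quality recalibration, no BAM.
* Variant calling is threshold-based, without genotype likelihoods or
  strand-bias modelling; population-frequency filters are out of scope.
* The conservation rule is a deliberate operationalization of a verbal
  criterion; with real ortholog alignments the panel and threshold should
  be chosen per study.
* In-silico PCR ignores primer thermodynamics entirely.
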