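---
title: "Methods: knowledge-driven variant triage with varitriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: knowledge-driven variant triage with varitriage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varitriage)
```

`varitriage` models the standard clinical interpretation workflow for rare
Mendelian disease: a patient's (or trio's) variant calls are cleaned,
annotated against a knowledgebase, classified under the ACMG/AMP framework,
prioritized by phenotype relevance, filtered through inheritance models, and
summarized in a versioned report. This vignette documents the procedures,
the tunable parameters and the design decisions, and states precisely what
the synthetic test data do and do not demonstrate.

## Ingest and normalization

VCF input is parsed tolerantly: individual malformed lines are skipped and
counted in the sanitation log, and the parse fails only when more than half
of the data lines are unusable (clinical VCF dialects vary widely, and a
single corrupt line should not void a case) or when no sample columns are
present. Records on non-canonical contigs are dropped; pre-existing
annotation INFO keys are stripped so a previously annotated file is reduced
to raw calls; required header definitions (DP, DP4) are injected when
absent.

Coordinates are 1-based inclusive internally; BED region files (0-based
half-open) are converted exactly once at read time, so a variant at position
*p* is retained iff `start < p <= end` for some interval. Chromosome names
are normalized to the prefix-free form ("1", "X", "MT") everywhere, which
removes an entire class of silent join misses against knowledge tables.

Multi-allelic sites are decomposed into one biallelic record per alternate
allele; each sample's genotype is re-expressed relative to that allele
(carrying it once is HET, on every chromosome copy HOM_ALT; haploid calls
carrying the allele are treated as homozygous, the hemizygous convention),
per-allele supporting reads come from the AD vector, and the shared site
depth is preserved. Allele pairs are then trimmed of shared suffix,
left-aligned through repeat context, and trimmed of shared prefix; the
operation is idempotent and verified in tests by checking that the
normalized representation reconstructs the identical alternate haplotype.
The fixed ingest order is sanitize, region-filter, split, normalize.

## Annotation

A minimal transcript-aware consequence caller operates on the packaged
transcript models. CDS SNVs are translated through the standard codon table
honoring strand (synonymous / missense / stop_gained / start_lost, with a
protein-level change string such as `p.E50*`); CDS indels are classified by
length difference mod 3; intronic positions within 2 bp of a junction are
canonical splice-site calls (donor at the transcription-wise 5' end of the
intron), 3–8 bp splice_region; exonic positions outside the CDS are UTR.
Effects map to fixed severity tiers (HIGH for null effects, MODERATE for
missense/in-frame, LOW for synonymous/splice-region, MODIFIER otherwise).
Per-transcript calls are merged to one worst call per variant, ties broken
by a fixed effect order and then transcript id, making merging
permutation-invariant. The caller is validated against an independent
oracle that re-extracts and translates the mutated CDS with Biostrings for
every CDS SNV of the fixture genome.

Control allele frequencies are a pure lookup keyed by the normalized
variant; the filterable quantity is `max_af`, the maximum over the emulated
sources (per-source values are retained for display), with 0 for a variant
absent everywhere. Prediction-tool verdicts are condensed by majority rule:
"damaging" ("tolerated") requires more than half of the non-unknown
verdicts and at least two of them; a single verdict is reported as "mixed"
rather than a consensus, and all-unknown stays "unknown".

## ACMG/AMP classification

Twelve criteria that are automatable from local tables are assigned:

* PVS1 — null effect (stop, frameshift, canonical splice, start loss) in a
  gene whose flag table records loss of function as the disease mechanism;
* PS1 / PM5 — identical amino-acid change / different change at the same
  residue as a pathogenic assertion;
* PM2 — `max_af` below 1e-5 (the numeric proxy for "absent from controls",
  configurable);
* PM4 — in-frame length change;
* PP3 / BP4 — prediction consensus damaging / tolerated;
* PP5 / BP6 — reported (likely) pathogenic / benign assertion for the exact
  variant without a conflicting assertion;
* BA1 — `max_af` ≥ 0.05 (stand-alone benign);
* BS1 — `max_af` at or above the per-gene disease frequency cutoff but
  below the BA1 threshold;
* BP7 — synonymous with no splice-region call on any transcript.

Criteria whose annotation block is missing (e.g. no frequency data) are
withheld rather than guessed. Segregation, functional and confirmed-de-novo
criteria are deliberately not automated; they are analyst judgments.

Combination follows the 2015 rule table over strength counts. Contradiction
is handled at the evidence level: whenever pathogenic-side and benign-side
criteria co-occur the variant is uncertain_significance. This is stricter
than implementations that ignore stray opposite-side evidence, but it is
conservative (it can only move variants toward VUS, never across the
pathogenic/benign divide), it makes the combiner provably monotone — adding
a pathogenic-side criterion never moves the class toward benign, which the
test suite checks over all 4096 criterion subsets against an independently
written rule-table oracle — and it matches the intuition that a
high-frequency null variant should not be auto-classified in either
direction.

## Phenotype prioritization

Gene documents are sectioned text (summaries, disorders, phenotypes,
publications, pathways, function). Matching is whole-word, case-insensitive
phrase matching with no stemming or ontology expansion — reproducibility is
preferred over recall at this scale. The direct score is

> direct(g) = (matched terms / query terms) · Σ_s w_s · log2(1 + c_s)

with default weights disorders 3.0, phenotypes 3.0, summaries 2.0, function
1.5, pathways 1.0, publications 1.0. The log saturation keeps a single
keyword-stuffed section from dominating; the matched-term fraction rewards
genes that cover more of the clinical picture; under AND semantics a
document missing any term scores zero. The exact scoring function of
production phenotype rankers is unpublished, so this package defines its
own and treats it as the specification: it is monotone in every hit count
(tested property) and section-weighted, which is all downstream ranking
relies on.

Indirect ("guilt by association") scoring is a single hop through the
gene-link graph with damping 0.5: `max_n w_link · 0.5 · direct(n)`. One hop
keeps scores interpretable and bounded by half of the best neighbor. A
gene's total is `max(direct, indirect)`; totals are zero exactly when there
is no hit and no scoring neighbor. Ranking is by total, then matched-term
count, then symbol — fully deterministic. Evidence snippets ("minicards")
carry the matched span delimited by `[[` `]]` inside a clipped character
window; stripping the markers always yields a verbatim substring of the
source section, so report evidence can be audited against the
knowledgebase.

## Genetic models

All models run as explicit filter cascades whose every step logs name,
parameters and input/output counts; the logs telescope (step k's output is
step k+1's input) and are reproduced verbatim in the report's methods
section. Reliability defaults: quality ≥ 20, proband depth ≥ 8, alternate
fraction ≥ 0.2; missing metrics fail closed. The frequency gate is the
protocol's cutoff (default 0.1%); the effect gate excludes LOW and MODIFIER
tiers.

* **Dominant HET** — proband heterozygous plus the three gates. In trios,
  candidates with both parents homozygous reference are annotated (not
  required) de novo; parental depth below 10 downgrades the flag to
  `de_novo_unconfirmed`, preventing false de novos from allele dropout.
* **Recessive HOM** — proband homozygous alternate (hemizygous male X calls
  count as homozygous); the Mendelian expectation of two heterozygous
  parents is checked and violations are flagged, not dropped.
* **Compound HET** — genes with ≥ 2 passing heterozygous variants. With a
  trio, in-trans evidence uses transmitted-allele logic only (no read-backed
  phasing): at least one variant carried only by the mother and one only by
  the father. Singletons emit the group flagged `phase_unknown`. The
  implementation is checked against exhaustive enumeration of parental
  genotype configurations.
* **Incidental findings** — panel genes with a pathogenic or likely
  pathogenic ACMG class, reported regardless of phenotype score.

Candidate tables are sorted by phenotype score descending.

## Structural variants

Events (DEL/DUP/INV/INS) are mapped to genes and regulatory elements by
≥ 1 bp overlap; insertions count as 1-bp intervals at their start, and
inversions are treated as full-span overlaps — a documented simplification,
since an inversion may disrupt only at its breakpoints. The combined element
score is the plain product of element confidence, element–gene association
confidence and the target's phenotype total: monotone in each factor, zero
when any is absent, and able to rank a distal high-scoring target above the
element's host gene. Events are ranked by best entity score, ties broken by
smaller span then coordinate.

## Case store and account statistics

Cases persist as newline-delimited JSON plus a recomputable allele-count
sidecar — diffable and serverless. In-house allele frequency counts diploid
alleles over all stored cases (hemizygous entries count one allele), always
excluding the case under analysis to avoid self-counting; sharing groups
pool counts across member stores. Per-phenotype-class resolution statistics
assign a case to every class whose keyword list intersects the case's own
keywords (exact, case-insensitive — classes may overlap), count a case as
resolved when any selected variant carries a High or Med relevance mark, and
report percentages rounded to one decimal.

## The synthetic data generator

The generator emulates a small rare-disease service: a two-chromosome toy
genome with twelve three-exon genes (alternating strands, valid ORFs), an
exome BED, and knowledge tables in which five causal genes carry their
scenario's keywords in disease-facing sections while decoy genes carry
partial matches. Cases are trios with ~150 common background variants whose
control frequencies are drawn from a Beta(2, 1) spectrum floored at 0.005 —
so every background variant is separable from a planted causal variant by
the default 0.1% cutoff by construction — and Mendelian-consistent
genotypes built by explicit allele transmission. Each scenario plants its
causal record with the prescribed genotype pattern: a de novo stop-gain, a
recessive homozygous missense with heterozygous parents, a maternal-plus-
paternal compound-het pair, a pathogenic panel variant, and a deletion
hitting an enhancer whose distal target (several kilobases away — a
reduced-distance emulation of long-range regulation) is the causal gene.
Identical seeds reproduce every file byte for byte.

What passing tests show: the pipeline's mechanics — filtering, inheritance
logic, scoring, ranking, reporting — are correct on inputs whose ground
truth is known exactly, across 20 seeds per scenario. What they do not
show: performance on real data. The generator has no sequencing error
model, no linkage structure, no population stratification, no transcript
isoform diversity, and a knowledgebase thousands of times smaller than
production gene compendia; real diagnostic yield cannot be inferred from
planted-truth recovery.

## Numerical and degenerate-input choices

Rounding only at presentation (percentages to one decimal); all internal
scores kept in double precision. Ties are always broken deterministically
(fixed effect order, lexicographic symbols, smaller SV span first) so every
ranking is permutation-invariant. Degenerate inputs have defined behavior:
header-only VCFs yield empty sets, empty keyword queries are a setup error,
empty incidental panels warn and return nothing, classes with zero cases
report a blank percentage, and zero-selection reports still carry their full
methods and version sections.

## Problem sizes

The shipped test suite runs the brute-force oracles at the sizes stated in
their tests (all 4096 ACMG subsets, 3^4 prediction vectors, ~200 random
compound-het configurations, 50 random interval instances, every fixture
CDS SNV — about 10,800 calls) and the end-to-end recovery check over the
five scenarios for 20 seeds each; these sizes were chosen as the smallest
at which the checks are exhaustive or statistically meaningful for a
desk-scale package.

## Known limitations

No liftover, phasing from reads, mosaicism, ROH or somatic subtraction; the
tumor, carrier and screening protocol types are configuration only. The
consequence caller handles the fixture transcript vocabulary, not the full
richness of real annotation (no selenoproteins, no non-canonical splice
motifs, no UTR regulatory effects). ACMG automation covers twelve criteria;
the remainder are analyst-assigned. Indirect phenotype scoring is one hop.
These boundaries are deliberate: every retained behavior is specified,
deterministic and tested.
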