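# varitriage

Knowledge-driven clinical variant triage for rare-disease genome analysis,
at desk scale.

Clinical genetics labs face the same task for every sequenced patient: out of
tens of thousands of called variants, find the one or two that explain the
phenotype. `varitriage` implements that workflow end to end as a testable R
package: VCF sanitization and normalization, transcript-aware consequence
calling, automated ACMG/AMP 2015 evidence assignment, phenotype-keyword gene
prioritization over a sectioned gene knowledgebase, inheritance-model filter
cascades for singleton and trio exomes, structural-variant scoring through
regulatory elements, a persistent case store with in-house allele
frequencies, and versioned JSON/Markdown reports. Every knowledgebase input
(reference, transcripts, control frequencies, assertions, predictions, gene
documents, enhancer maps) is emulated by a built-in synthetic fixture
generator, so the whole pipeline runs and is verified offline.

It is aimed at method developers and analysts who want an inspectable,
reproducible model of a clinical interpretation pipeline — not a clinical
device.

## The scoring and classification core

**ACMG/AMP classification.** Twelve automatable evidence criteria are
assigned from local annotation (PVS1, PS1, PM2, PM4, PM5, PP3, PP5, BA1,
BS1, BP4, BP6, BP7) and combined with the 2015 guideline rule table into the
five classes {pathogenic, likely pathogenic, VUS, likely benign, benign}.
Any co-occurrence of pathogenic-side and benign-side evidence is treated as
contradictory and yields VUS.

**Phenotype score.** For gene *g* and keyword query *Q*, per-section
whole-word hit counts *c_s* are combined as

    direct(g) = (|matched terms| / |Q|) * sum_s  w_s * log2(1 + c_s)

with section weights *w* (disorders 3, phenotypes 3, summaries 2, function
1.5, pathways 1, publications 1). A one-hop indirect ("guilt by
association") score `max_n  w_link * 0.5 * direct(n)` runs over linked
genes; a gene's total is the larger of the two.

**Structural variants.** Events are mapped to overlapping genes and
regulatory elements; an element's score through a target gene is the plain
product `element_confidence * association_confidence * total(target)`, and
events are ranked by their best entity score — so a distal high-scoring
target can outrank the element's host gene.

## Worked example

Generate a synthetic trio exome with a planted de novo stop-gain and run the
trio protocol:

```r
library(varitriage)
dir <- file.path(tempdir(), "demo")
kb <- make_fixture_bundle(dir, sim_config(seed = 42))
case <- simulate_case(kb, "de_novo_dominant", sim_config(seed = 42),
                      file.path(dir, "case"))
protocol <- default_protocol(analysis_type = "trio-exome",
                             keywords = scenario_keywords("de_novo_dominant"),
                             gene_panel = kb$gene_panel)
res <- run_case(case$vcf, kb, protocol, ped = case$ped)
res$models$dominant_het$candidates[, c("key", "gene_symbol", "effect",
  "aa_change", "acmg_class", "acmg_criteria", "phenotype_score", "de_novo")]
#>          key gene_symbol      effect aa_change        acmg_class acmg_criteria
#> 1 1:1128:G:T       TOYG1 stop_gained    p.E50* likely_pathogenic      PVS1,PM2
#>   phenotype_score de_novo
#> 1              12 de_novo
res$models$dominant_het$log
#>          name                         params n_in n_out
#> 1    genotype             zyg_proband == HET  137    48
#> 2 reliability       reliability_pass == TRUE   48    48
#> 3   frequency                 max_af < 0.001   48     1
#> 4      effect severity_tier in HIGH,MODERATE    1     1
```

Of 137 ingested variants, 48 are heterozygous in the proband, one survives
the 0.1% control-frequency cutoff, and that candidate is the planted
stop-gain: absent from controls (PM2), a null variant in a
loss-of-function gene (PVS1), hence likely pathogenic, flagged de novo
because both parents are homozygous reference at adequate depth, and ranked
first by its phenotype score (12.0 against the query "seizures,
developmental delay"). The per-step filter counts feed the report's methods
section verbatim.

A command-line wrapper ships in `exec/varitriage`
(`varitriage ingest|fixtures|analyze|stats`).

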