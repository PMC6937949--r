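# End-to-end case analysis: ingest -> annotate -> ACMG -> phenotype scores ->
# genetic models (-> SV ranking), plus the planted-truth recovery check used
# to validate the whole pipeline against the fixture generator.

#' Run a full case analysis
#'
#' @param vcf VCF path (or lines).
#' @param kb Loaded knowledgebase ([load_knowledgebase()]).
#' @param protocol A `protocol`; its keywords drive phenotype scoring.
#' @param ped Optional PED path or data.frame (trio analysis).
#' @param sv Optional SV call table path (enables the SV module).
#' @param store Optional `case_store` for in-house frequencies.
#' @param case_id Current case id (excluded from in-house counts).
#' @return list: variant_set, annotated table, phenotype score table, model
#'   results, SV ranking (or NULL), minicards, protocol, pedigree.
#' @export
run_case <- function(vcf, kb, protocol, ped = NULL, sv = NULL, store = NULL,
                     case_id = NULL) {
  if (length(protocol$gene_panel) == 0) {
    protocol$gene_panel <- kb$gene_panel %||% character()
  }
  vs <- ingest_vcf(vcf, kb$regions, kb$reference)
  av <- annotate_variants(vs, kb)
  av <- classify_variants(av, kb)

  query <- keyword_query(protocol$keywords, protocol$keyword_operator)
  pheno <- score_phenotypes(kb$gene_docs, kb$links, query)
  m <- match(av$gene_symbol, pheno$gene_symbol)
  av$phenotype_score <- ifelse(is.na(m), 0, pheno$total[m])
  av$matched_phenotype_count <- ifelse(is.na(m), 0L, pheno$matched_count[m])

  av <- attach_inhouse(av, store, exclude_case = case_id)

  pedigree <- if (!is.null(ped)) read_pedigree(ped) else NULL
  av <- attach_trio_genotypes(av, vs, pedigree, protocol$reliability)
  models <- run_genetic_models(av, protocol, pedigree)

  svs <- if (!is.null(sv)) {
    analyze_svs(sv, kb$transcripts, kb$elements, pheno)
  } else NULL

  hit_genes <- pheno$gene_symbol[pheno$matched_count > 0]
  minicards <- lapply(stats::setNames(nm = hit_genes), function(g) {
    build_minicard(kb$gene_docs[kb$gene_docs$gene_symbol == g, , drop = FALSE],
                   query)
  })

  list(variant_set = vs, annotated = av, phenotype = pheno, models = models,
       svs = svs, minicards = minicards, protocol = protocol,
       pedigree = pedigree)
}

#' Check recovery of a planted truth
#'
#' Generates a fixture bundle and one simulated case for the scenario, runs
#' the full pipeline under the scenario's keyword query, and reports whether
#' the planted causal variant (or SV event) ranks first in its genetic-model
#' tab.
#'
#' @param scenario One of the five fixture scenarios.
#' @param seed Seed for both the fixture bundle and the case.
#' @param kb Optional pre-built knowledgebase to reuse (its seed must match
#'   the bundle you want); when NULL a bundle is generated in a temporary
#'   directory.
#' @return TRUE when the planted truth is the top-ranked candidate.
#' @export
recover_planted_truth <- function(scenario, seed = 1, kb = NULL) {
  config <- sim_config(seed = seed)
  if (is.null(kb)) {
    dir <- tempfile(sprintf("fixture%d_", seed))
    on.exit(unlink(dir, recursive = TRUE), add = TRUE)
    kb <- make_fixture_bundle(dir, config)
  }
  case <- simulate_case(kb, scenario, config,
                        dir = tempfile(sprintf("case_%s_", scenario)))
  on.exit(unlink(case$dir, recursive = TRUE), add = TRUE)
  protocol <- default_protocol(analysis_type = "trio-exome",
                               keywords = case$truth$keywords,
                               gene_panel = kb$gene_panel)
  res <- run_case(case$vcf, kb, protocol, ped = case$ped, sv = case$sv)
  truth_keys <- vapply(case$truth$variants, function(v) {
    variant_key(v$chrom, v$pos, v$ref, v$alt)
  }, character(1))
  switch(scenario,
    de_novo_dominant = {
      cand <- res$models$dominant_het$candidates
      nrow(cand) > 0 && cand$key[1] %in% truth_keys
    },
    recessive_hom = {
      cand <- res$models$recessive_hom$candidates
      nrow(cand) > 0 && cand$key[1] %in% truth_keys
    },
    compound_het = {
      grp <- res$models$compound_het$groups
      nrow(grp) > 0 && grp$gene_symbol[1] == case$truth$causal_gene &&
        grp$status[1] == "in_trans"
    },
    incidental = {
      cand <- res$models$incidental$candidates
      nrow(cand) > 0 && cand$key[1] %in% truth_keys
    },
    enhancer_sv = {
      ev <- res$svs$events
      tr <- case$truth$sv
      nrow(ev) > 0 && ev$chrom[1] == tr$chrom && ev$start[1] == tr$start &&
        ev$end[1] == tr$end
    })
}
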