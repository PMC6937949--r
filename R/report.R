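# Report assembly: versioned per-case clinical report (JSON + Markdown from
# one intermediate structure) and the full per-model variant table export.

#' Build a version manifest
#'
#' Records the package version, every knowledge table used in the run (name,
#' version string, checksum), the protocol name and hash, the run timestamp
#' and the random seed, enabling tracking and reproducibility of a report.
#'
#' @param knowledge Knowledgebase list ([load_knowledgebase()]); its
#'   `manifest` entry lists the tables.
#' @param protocol A `protocol`.
#' @param timestamp Run timestamp string (pass a fixed value for
#'   byte-identical reports).
#' @param seed Random seed used in the run, if any.
#' @return A list describing the versions.
#' @export
version_manifest <- function(knowledge, protocol,
                             timestamp = "1970-01-01T00:00:00Z", seed = NULL) {
  tables <- knowledge$manifest %||%
    empty_df(list(name = character(), version = character(),
                  checksum = character()))
  list(
    engine = list(name = "varitriage",
                  version = as.character(utils::packageVersion("varitriage"))),
    tables = tables[, c("name", "version", "checksum")],
    protocol = list(name = protocol$name,
                    hash = content_checksum(yaml::as.yaml(unclass(protocol)))),
    timestamp = timestamp,
    seed = seed
  )
}

report_variant_block <- function(av_row, selection, snippets) {
  list(
    variant_key = av_row$key,
    gene_symbol = av_row$gene_symbol,
    effect = av_row$effect,
    aa_change = av_row$aa_change,
    severity_tier = av_row$severity_tier,
    max_af = av_row$max_af,
    acmg_class = av_row$acmg_class,
    acmg_criteria = av_row$acmg_criteria,
    phenotype_score = av_row$phenotype_score,
    matched_phenotype_count = av_row$matched_phenotype_count,
    relevance = selection$relevance,
    pathogenicity = selection$pathogenicity,
    note = selection$note,
    evidence = snippets
  )
}

#' Render a clinical report
#'
#' Assembles the per-case report: patient metadata, keywords, per-model
#' sections with the analyst-selected variants (annotation summary, ACMG
#' class and criteria, phenotype score, evidence snippets, note), the
#' incidental-findings section, a methods section reproducing every applied
#' filter with parameters and input/output counts, and the version manifest.
#' JSON and Markdown are generated from the same intermediate structure;
#' identical inputs give byte-identical output. A selection referencing a
#' variant absent from the analysis is a hard error.
#'
#' @param case_meta list with at least case_id; free patient/sample fields
#'   are carried through.
#' @param analysis Result of [run_case()] (needs `annotated`, `models`,
#'   `protocol`, and optionally `minicards`).
#' @param selections data.frame: variant_key, model, relevance,
#'   pathogenicity, note.
#' @param manifest A [version_manifest()].
#' @param format "json" or "markdown".
#' @return A single character string (the document).
#' @export
render_report <- function(case_meta, analysis, selections, manifest,
                          format = c("json", "markdown")) {
  format <- match.arg(format)
  av <- analysis$annotated
  missing <- setdiff(selections$variant_key, av$key)
  if (length(missing)) {
    stopf("selection references variant(s) absent from the analysis: %s",
          paste(missing, collapse = ", "))
  }
  models <- analysis$models
  sections <- list()
  for (m in names(models)) {
    sel_m <- selections[selections$model == m, , drop = FALSE]
    blocks <- lapply(seq_len(nrow(sel_m)), function(k) {
      row <- av[av$key == sel_m$variant_key[k], , drop = FALSE][1, ]
      snip <- analysis$minicards[[row$gene_symbol]] %||% list()
      report_variant_block(row, sel_m[k, ], snip)
    })
    sections[[m]] <- list(model = m, n_candidates = nrow(models[[m]]$candidates),
                          selected = blocks)
  }
  methods <- lapply(names(models), function(m) {
    list(model = m, filters = models[[m]]$log)
  })
  doc <- list(
    case = case_meta,
    keywords = analysis$protocol$keywords,
    sections = sections,
    methods = methods,
    versions = manifest
  )
  if (format == "json") {
    as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                  pretty = TRUE, null = "null"))
  } else {
    render_markdown(doc)
  }
}

render_markdown <- function(doc) {
  out <- c(sprintf("# Clinical variant report — case %s", doc$case$case_id),
           "")
  meta <- doc$case[setdiff(names(doc$case), "case_id")]
  for (nm in names(meta)) out <- c(out, sprintf("- %s: %s", nm, meta[[nm]]))
  out <- c(out, sprintf("- phenotype keywords: %s",
                        paste(doc$keywords, collapse = "; ")), "")
  for (sec in doc$sections) {
    out <- c(out, sprintf("## Model: %s", sec$model),
             sprintf("%d candidate variant(s); %d selected.",
                     sec$n_candidates, length(sec$selected)), "")
    for (b in sec$selected) {
      out <- c(out,
        sprintf("### %s (%s)", b$variant_key, b$gene_symbol),
        sprintf("- effect: %s %s", b$effect,
                if (nzchar(b$aa_change %||% "")) b$aa_change else ""),
        sprintf("- ACMG: %s [%s]", b$acmg_class, b$acmg_criteria),
        sprintf("- phenotype score: %.3f (matched terms: %s)",
                b$phenotype_score %||% 0, b$matched_phenotype_count %||% 0),
        sprintf("- max control AF: %s", format(b$max_af)),
        sprintf("- analyst: relevance=%s pathogenicity=%s note=%s",
                b$relevance, b$pathogenicity, b$note))
      if (length(b$evidence)) {
        out <- c(out, "- evidence:")
        ev <- b$evidence
        for (k in seq_len(nrow(ev))) {
          out <- c(out, sprintf("    - [%s] %s", ev$section[k], ev$snippet[k]))
        }
      }
      out <- c(out, "")
    }
  }
  out <- c(out, "## Methods")
  for (m in doc$methods) {
    out <- c(out, sprintf("### Filters — %s", m$model))
    lg <- m$filters
    for (k in seq_len(nrow(lg))) {
      out <- c(out, sprintf("- %s (%s): %d -> %d", lg$name[k], lg$params[k],
                            lg$n_in[k], lg$n_out[k]))
    }
  }
  out <- c(out, "", "## Versions",
           sprintf("- engine: %s %s", doc$versions$engine$name,
                   doc$versions$engine$version),
           sprintf("- protocol: %s (%s)", doc$versions$protocol$name,
                   doc$versions$protocol$hash),
           sprintf("- run: %s", doc$versions$timestamp))
  tb <- doc$versions$tables
  for (k in seq_len(nrow(tb))) {
    out <- c(out, sprintf("- table %s %s (%s)", tb$name[k], tb$version[k],
                          tb$checksum[k]))
  }
  paste(out, collapse = "\n")
}

#' Parse a JSON report back into its structure
#'
#' @param json Report string produced by [render_report()] with
#'   `format = "json"`.
#' @return The report list.
#' @export
parse_report <- function(json) {
  jsonlite::fromJSON(json, simplifyVector = TRUE, simplifyDataFrame = TRUE)
}

#' Export per-model variant tables
#'
#' One TSV per genetic model listing every surviving variant with all
#' annotation columns; the row count equals the model's survivor count.
#'
#' @param models Result of [run_genetic_models()].
#' @param dir Output directory.
#' @return Named character vector of written paths.
#' @export
export_variant_tables <- function(models, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (m in names(models)) {
    p <- file.path(dir, paste0("variants_", m, ".tsv"))
    write_tsv(models[[m]]$candidates, p)
    paths[m] <- p
  }
  paths
}
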