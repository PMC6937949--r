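# Protocol-driven filter cascades and inheritance-model logic: dominant HET,
# recessive homozygote, recessive compound heterozygote, and incidental
# findings, each emitting a per-step filter log for the report's methods
# section.

#' Read a PED pedigree file
#'
#' Whitespace-delimited PED (family, individual, father, mother, sex,
#' phenotype). Returns the trio if one is present: the affected individual
#' with both parents in the file.
#'
#' @param x Path to a PED file or an equivalent data.frame.
#' @return list(proband_id, mother_id, father_id, affected) or NULL when the
#'   file describes a singleton.
#' @export
read_pedigree <- function(x) {
  df <- if (is.character(x)) {
    utils::read.table(x, header = FALSE, stringsAsFactors = FALSE,
                      col.names = c("family", "id", "father", "mother",
                                    "sex", "phenotype"))
  } else as.data.frame(x)
  kid <- df[df$father != "0" & df$mother != "0", , drop = FALSE]
  if (nrow(kid) == 0) return(NULL)
  kid <- kid[1, ]
  if (!(kid$father %in% df$id) || !(kid$mother %in% df$id)) {
    stopf("pedigree names parents absent from the file")
  }
  list(proband_id = kid$id, mother_id = kid$mother, father_id = kid$father,
       affected = kid$phenotype == 2)
}

#' Default analysis protocol
#'
#' The standard rare-disease exome protocol: the four genetic-model tabs
#' (dominant HET, recessive homozygote, compound heterozygote, incidental
#' findings), a 0.1% allele-frequency cutoff, the default reliability
#' thresholds and the HIGH/MODERATE severity gate.
#'
#' @param name Protocol name.
#' @param analysis_type One of the supported protocol types.
#' @param keywords Character vector of phenotype keywords.
#' @param af_cutoff Control allele-frequency cutoff (fraction).
#' @param models Genetic-model tabs to run.
#' @param severity_gate Severity tiers considered to have a predicted effect.
#' @param reliability list(min_qual, min_depth, min_alt_fraction).
#' @param gene_panel Character vector of incidental-findings panel genes.
#' @param keyword_operator "OR" or "AND".
#' @return A list of class `protocol`.
#' @export
default_protocol <- function(name = "rare-disease-exome",
                             analysis_type = c("single-exome", "trio-exome",
                                               "tumor-biopsy", "carrier",
                                               "health-screen", "pgx"),
                             keywords = character(),
                             af_cutoff = 0.001,
                             models = c("dominant_het", "recessive_hom",
                                        "compound_het", "incidental"),
                             severity_gate = c("HIGH", "MODERATE"),
                             reliability = list(min_qual = 20, min_depth = 8,
                                                min_alt_fraction = 0.2),
                             gene_panel = character(),
                             keyword_operator = "OR") {
  stopifnot(af_cutoff >= 0, af_cutoff <= 1, length(models) >= 1)
  structure(list(name = name, analysis_type = match.arg(analysis_type),
                 keywords = keywords, keyword_operator = keyword_operator,
                 af_cutoff = af_cutoff, models = models,
                 severity_gate = severity_gate, reliability = reliability,
                 gene_panel = gene_panel, report_template = "default"),
            class = "protocol")
}

#' Read a protocol from YAML
#'
#' @param path YAML file with any subset of the [default_protocol()] fields.
#' @return A `protocol` list.
#' @export
read_protocol <- function(path) {
  y <- yaml::read_yaml(path)
  p <- default_protocol()
  for (nm in intersect(names(y), names(p))) p[[nm]] <- y[[nm]]
  if (!is.null(y$keywords) && is.list(y$keywords)) {
    p$keywords <- unlist(y$keywords$terms %||% y$keywords)
    p$keyword_operator <- y$keywords$operator %||% p$keyword_operator
  }
  stopifnot(p$af_cutoff >= 0, p$af_cutoff <= 1, length(p$models) >= 1)
  p
}

#' Write a protocol to YAML
#'
#' @param protocol A `protocol` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(protocol, path) {
  yaml::write_yaml(unclass(protocol), path)
  invisible(path)
}

#' Variant reliability filter
#'
#' Pass iff combined quality, proband depth and alternative-read fraction all
#' clear their thresholds. Missing metrics fail with reason
#' "missing_metrics".
#'
#' @param qual,depth,alt_fraction Vectors of proband call metrics.
#' @param thresholds list(min_qual, min_depth, min_alt_fraction).
#' @return data.frame(pass, reason).
#' @export
reliability_filter <- function(qual, depth, alt_fraction,
                               thresholds = list(min_qual = 20, min_depth = 8,
                                                 min_alt_fraction = 0.2)) {
  missing <- is.na(qual) | is.na(depth) | is.na(alt_fraction)
  pass <- !missing &
    qual >= thresholds$min_qual &
    depth >= thresholds$min_depth &
    alt_fraction >= thresholds$min_alt_fraction
  reason <- ifelse(missing, "missing_metrics",
                   ifelse(pass, "", "below_threshold"))
  data.frame(pass = pass, reason = reason, stringsAsFactors = FALSE)
}

#' Apply a filter cascade
#'
#' Filters are ordered column predicates; each step records its name,
#' parameters and input/output counts, so survivors are monotonically
#' non-increasing and step counts telescope. A filter naming a missing
#' column is a hard error.
#'
#' @param df Annotated variant data.frame.
#' @param cascade list of filter specs: list(name, column, op, value) with op
#'   one of `==`, `!=`, `<`, `<=`, `>`, `>=`, `in`.
#' @return list(variants, log) where log has columns name, params, n_in,
#'   n_out.
#' @export
apply_cascade <- function(df, cascade) {
  log <- empty_df(list(name = character(), params = character(),
                       n_in = integer(), n_out = integer()))
  for (f in cascade) {
    if (!f$column %in% names(df)) {
      stopf("filter '%s' references missing column '%s'", f$name, f$column)
    }
    n_in <- nrow(df)
    x <- df[[f$column]]
    keep <- switch(f$op,
      "==" = x == f$value,
      "!=" = x != f$value,
      "<"  = x < f$value,
      "<=" = x <= f$value,
      ">"  = x > f$value,
      ">=" = x >= f$value,
      "in" = x %in% f$value,
      stopf("unknown filter op '%s'", f$op))
    keep[is.na(keep)] <- FALSE
    df <- df[keep, , drop = FALSE]
    log <- rbind(log, data.frame(
      name = f$name,
      params = sprintf("%s %s %s", f$column, f$op,
                       paste(f$value, collapse = ",")),
      n_in = n_in, n_out = nrow(df), stringsAsFactors = FALSE))
  }
  rownames(df) <- NULL
  list(variants = df, log = log)
}

#' Attach per-role trio genotype columns
#'
#' Adds zygosity/depth/alt_fraction columns for the proband (and parents when
#' a pedigree is given) plus the `reliability_pass` column used by the model
#' cascades.
#'
#' @param av Annotated variant table.
#' @param vs The originating `variant_set` (for genotypes).
#' @param pedigree A trio from [read_pedigree()], or NULL; a NULL pedigree
#'   uses the first sample as proband.
#' @param reliability Thresholds for [reliability_filter()].
#' @return The augmented table.
#' @export
attach_trio_genotypes <- function(av, vs, pedigree = NULL,
                                  reliability = list(min_qual = 20,
                                                     min_depth = 8,
                                                     min_alt_fraction = 0.2)) {
  roles <- list(proband = pedigree$proband_id %||% vs$samples[1])
  if (!is.null(pedigree)) {
    roles$mother <- pedigree$mother_id
    roles$father <- pedigree$father_id
  }
  g <- vs$genotypes
  for (role in names(roles)) {
    gr <- g[g$sample_id == roles[[role]], , drop = FALSE]
    m <- match(av$uid, gr$uid)
    av[[paste0("zyg_", role)]] <- gr$zygosity[m]
    av[[paste0("depth_", role)]] <- gr$depth[m]
    av[[paste0("altfrac_", role)]] <- gr$alt_fraction[m]
  }
  rf <- reliability_filter(av$qual, av$depth_proband, av$altfrac_proband,
                           reliability)
  av$reliability_pass <- rf$pass
  av
}

model_base_cascade <- function(zygosity, protocol) {
  list(
    list(name = "genotype", column = "zyg_proband", op = "==",
         value = zygosity),
    list(name = "reliability", column = "reliability_pass", op = "==",
         value = TRUE),
    list(name = "frequency", column = "max_af", op = "<",
         value = protocol$af_cutoff),
    list(name = "effect", column = "severity_tier", op = "in",
         value = protocol$severity_gate)
  )
}

parent_carries <- function(zyg) !is.na(zyg) & zyg %in% c("HET", "HOM_ALT")
parent_homref <- function(zyg) !is.na(zyg) & zyg == "HOM_REF"

#' Dominant heterozygous model
#'
#' The four default dominant filters: proband HET only, reliability pass,
#' rare (max_af below the protocol cutoff), and a predicted effect
#' (severity gate). With a trio, candidates whose parents are both
#' homozygous-reference are flagged de novo; parental depth below
#' `min_parent_depth` downgrades the flag to de_novo_unconfirmed.
#'
#' @param av Annotated table with trio genotype columns.
#' @param protocol A `protocol`.
#' @param pedigree Trio or NULL.
#' @param min_parent_depth Depth each parent needs for a confirmed de novo.
#' @return list(candidates, log); candidates sorted by phenotype score.
#' @export
model_dominant_het <- function(av, protocol, pedigree = NULL,
                               min_parent_depth = 10) {
  res <- apply_cascade(av, model_base_cascade("HET", protocol))
  cand <- res$variants
  cand$de_novo <- rep(NA_character_, nrow(cand))
  if (!is.null(pedigree) && nrow(cand) > 0) {
    both_ref <- parent_homref(cand$zyg_mother) & parent_homref(cand$zyg_father)
    deep <- !is.na(cand$depth_mother) & cand$depth_mother >= min_parent_depth &
      !is.na(cand$depth_father) & cand$depth_father >= min_parent_depth
    cand$de_novo <- ifelse(both_ref & deep, "de_novo",
                           ifelse(both_ref, "de_novo_unconfirmed", ""))
  }
  list(candidates = sort_by_phenotype(cand), log = res$log)
}

#' Recessive homozygous model
#'
#' Proband homozygous-alternative (hemizygous male X calls count as
#' homozygous), reliability, rarity and severity gates. With a trio, the
#' Mendelian expectation is both parents heterozygous; violations are flagged
#' mendelian_inconsistent but kept.
#'
#' @inheritParams model_dominant_het
#' @return list(candidates, log).
#' @export
model_recessive_hom <- function(av, protocol, pedigree = NULL) {
  res <- apply_cascade(av, model_base_cascade("HOM_ALT", protocol))
  cand <- res$variants
  cand$trio_consistency <- rep(NA_character_, nrow(cand))
  if (!is.null(pedigree) && nrow(cand) > 0) {
    consistent <- !is.na(cand$zyg_mother) & cand$zyg_mother == "HET" &
      !is.na(cand$zyg_father) & cand$zyg_father == "HET"
    cand$trio_consistency <- ifelse(consistent, "consistent",
                                    "mendelian_inconsistent")
  }
  list(candidates = sort_by_phenotype(cand), log = res$log)
}

variant_parent_origin <- function(zyg_mother, zyg_father) {
  m <- parent_carries(zyg_mother)
  f <- parent_carries(zyg_father)
  mr <- parent_homref(zyg_mother)
  fr <- parent_homref(zyg_father)
  ifelse(m & fr, "maternal_only",
         ifelse(f & mr, "paternal_only",
                ifelse(m & f, "both_parents",
                       ifelse(mr & fr, "neither_parent", "unknown"))))
}

#' Recessive compound-heterozygous model
#'
#' Genes carrying at least two passing heterozygous variants in the proband.
#' With a trio, in-trans evidence is required by transmitted-allele logic:
#' at least one variant carried only by the mother and one only by the
#' father. Without parents the gene group is emitted flagged phase_unknown.
#'
#' @inheritParams model_dominant_het
#' @return list(groups, candidates, log): gene groups with status
#'   (in_trans / cis_or_unresolved / phase_unknown), the variants of
#'   qualifying groups, and the cascade log.
#' @export
model_compound_het <- function(av, protocol, pedigree = NULL) {
  res <- apply_cascade(av, model_base_cascade("HET", protocol))
  pass <- res$variants
  pass <- pass[!is.na(pass$gene_symbol), , drop = FALSE]
  groups <- empty_df(list(gene_symbol = character(), n_variants = integer(),
                          status = character(), phenotype_score = numeric()))
  keep_keys <- character()
  for (g in unique(pass$gene_symbol)) {
    vg <- pass[pass$gene_symbol == g, , drop = FALSE]
    if (nrow(vg) < 2) next
    if (is.null(pedigree)) {
      status <- "phase_unknown"
    } else {
      origin <- variant_parent_origin(vg$zyg_mother, vg$zyg_father)
      status <- if (any(origin == "maternal_only") &&
                    any(origin == "paternal_only")) "in_trans"
        else "cis_or_unresolved"
    }
    if (status %in% c("in_trans", "phase_unknown")) {
      groups <- rbind(groups, data.frame(
        gene_symbol = g, n_variants = nrow(vg), status = status,
        phenotype_score = max(c(vg$phenotype_score, 0), na.rm = TRUE),
        stringsAsFactors = FALSE))
      keep_keys <- c(keep_keys, vg$key)
    }
  }
  groups <- groups[order(-groups$phenotype_score, groups$gene_symbol), ,
                   drop = FALSE]
  rownames(groups) <- NULL
  cand <- pass[pass$key %in% keep_keys, , drop = FALSE]
  list(groups = groups, candidates = sort_by_phenotype(cand), log = res$log)
}

#' Incidental findings model
#'
#' Variants in the incidental-findings gene panel classified pathogenic or
#' likely pathogenic, reported regardless of phenotype score. An empty panel
#' yields an empty result with a warning.
#'
#' @param av Annotated, ACMG-classified table.
#' @param panel Character vector of panel gene symbols.
#' @return list(candidates, log).
#' @export
incidental_findings <- function(av, panel) {
  if (length(panel) == 0) {
    warnf("incidental findings requested with an empty gene panel")
    return(list(candidates = av[0, , drop = FALSE],
                log = log_row("incidental_panel", 0L)))
  }
  res <- apply_cascade(av, list(
    list(name = "panel", column = "gene_symbol", op = "in", value = panel),
    list(name = "classification", column = "acmg_class", op = "in",
         value = c("pathogenic", "likely_pathogenic"))
  ))
  list(candidates = sort_by_phenotype(res$variants), log = res$log)
}

sort_by_phenotype <- function(df) {
  if (nrow(df) == 0) return(df)
  score <- ifelse(is.na(df$phenotype_score), 0, df$phenotype_score)
  out <- df[order(-score, df$gene_symbol, df$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run every genetic-model tab of a protocol
#'
#' @param av Annotated, classified, phenotype-scored variant table with trio
#'   genotype columns.
#' @param protocol A `protocol`.
#' @param pedigree Trio or NULL.
#' @return Named list of model results (each list(candidates, log, ...)).
#' @export
run_genetic_models <- function(av, protocol, pedigree = NULL) {
  out <- list()
  for (m in protocol$models) {
    out[[m]] <- switch(m,
      dominant_het = model_dominant_het(av, protocol, pedigree),
      recessive_hom = model_recessive_hom(av, protocol, pedigree),
      compound_het = model_compound_het(av, protocol, pedigree),
      incidental = incidental_findings(av, protocol$gene_panel),
      stopf("unknown genetic model '%s'", m))
  }
  out
}
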