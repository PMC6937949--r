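# ACMG/AMP 2015 evidence assignment and five-class combination.
#
# Only the criteria automatable from local annotation are implemented:
# PVS1, PS1, PM2, PM4, PM5, PP3, PP5, BA1, BS1, BP4, BP6, BP7. Criteria that
# require segregation, functional or confirmed-de-novo evidence are left to
# analyst judgment and are out of scope here.

ACMG_CODES <- c("PVS1", "PS1", "PM2", "PM4", "PM5", "PP3", "PP5",
                "BA1", "BS1", "BP4", "BP6", "BP7")

ACMG_CLASSES <- c("pathogenic", "likely_pathogenic", "uncertain_significance",
                  "likely_benign", "benign")

#' Default strength of an ACMG criterion code
#'
#' Mapped from the guideline prefix: PVS very_strong, PS strong, PM moderate,
#' PP supporting, BA stand_alone, BS strong, BP supporting.
#'
#' @param code Character vector of criterion codes.
#' @return Character vector of strengths.
#' @export
criterion_strength <- function(code) {
  pre <- sub("[0-9]+$", "", code)
  map <- c(PVS = "very_strong", PS = "strong", PM = "moderate",
           PP = "supporting", BA = "stand_alone", BS = "strong",
           BP = "supporting")
  unname(map[pre])
}

crit_row <- function(code, rationale) {
  data.frame(code = code, strength = criterion_strength(code),
             rationale = rationale, stringsAsFactors = FALSE)
}

#' Assign automatable ACMG criteria to an annotated variant
#'
#' Rule set (each criterion fires only when the annotation block it needs is
#' present; otherwise it is silently withheld):
#' \itemize{
#'   \item PVS1: HIGH-tier null effect (stop/frameshift/canonical splice/
#'     start-loss) in a gene with an established loss-of-function mechanism.
#'   \item PS1: same amino-acid change as a pathogenic assertion in the gene.
#'   \item PM5: different amino-acid change at a residue carrying a pathogenic
#'     assertion.
#'   \item PM2: absent from controls (max_af < `pm2_af`, default 1e-5).
#'   \item PM4: in-frame indel.
#'   \item PP3 / BP4: prediction consensus damaging / tolerated.
#'   \item PP5 / BP6: reported (likely) pathogenic / (likely) benign assertion
#'     for this variant without a conflicting assertion on the other side.
#'   \item BA1: max_af >= 0.05.
#'   \item BS1: max_af at or above the gene's disease frequency cutoff but
#'     below the BA1 threshold.
#'   \item BP7: synonymous variant with no splice_region call on any
#'     transcript.
#' }
#'
#' @param v One row of an annotated variant table ([annotate_variants()]).
#' @param assertions Assertion table ([load_assertions()]).
#' @param gene_flags Per-gene flags ([load_gene_flags()]).
#' @param pm2_af Frequency proxy for "absent from controls".
#' @param ba1_af Stand-alone benign frequency threshold.
#' @return data.frame of criteria: code, strength, rationale.
#' @export
assign_criteria <- function(v, assertions, gene_flags,
                            pm2_af = 1e-5, ba1_af = 0.05) {
  out <- crit_row(character(), character())
  gene <- v$gene_symbol
  has_gene <- !is.na(gene)
  has_freq <- !is.null(v$max_af) && !is.na(v$max_af)
  flags <- if (has_gene) gene_flags[gene_flags$gene_symbol == gene, ] else
    gene_flags[0, ]

  if (has_gene && !is.na(v$severity_tier) && v$severity_tier == "HIGH" &&
      v$effect %in% NULL_EFFECTS && nrow(flags) == 1 &&
      flags$lof_mechanism == 1) {
    out <- rbind(out, crit_row("PVS1", sprintf(
      "%s in loss-of-function gene %s", v$effect, gene)))
  }

  if (has_gene && !is.na(v$aa_change) && nzchar(v$aa_change)) {
    ga <- assertions[assertions$gene_symbol == gene &
                       assertions$significance == "pathogenic" &
                       !is.na(assertions$aa_change) &
                       nzchar(assertions$aa_change), , drop = FALSE]
    res_of <- function(x) sub("^p\\.([A-Za-z*]+[0-9]+).*$", "\\1",
                              sub("[A-Za-z*]+$", "", x))
    if (any(ga$aa_change == v$aa_change)) {
      out <- rbind(out, crit_row("PS1", sprintf(
        "pathogenic assertion with identical change %s", v$aa_change)))
    } else if (any(res_of(ga$aa_change) == res_of(v$aa_change))) {
      out <- rbind(out, crit_row("PM5", sprintf(
        "pathogenic assertion at the same residue as %s", v$aa_change)))
    }
  }

  if (has_freq && v$max_af < pm2_af) {
    out <- rbind(out, crit_row("PM2", sprintf(
      "max control AF %.3g below %.0e", v$max_af, pm2_af)))
  }
  if (!is.na(v$effect) && v$effect == "inframe_indel") {
    out <- rbind(out, crit_row("PM4", "in-frame protein length change"))
  }
  if (!is.null(v$consensus_severity) && !is.na(v$consensus_severity)) {
    if (v$consensus_severity == "damaging") {
      out <- rbind(out, crit_row("PP3", "prediction consensus damaging"))
    } else if (v$consensus_severity == "tolerated") {
      out <- rbind(out, crit_row("BP4", "prediction consensus tolerated"))
    }
  }

  sig <- assertions$significance[assertions$key == v$key]
  path_rep <- any(sig %in% c("pathogenic", "likely_pathogenic"))
  ben_rep <- any(sig %in% c("benign", "likely_benign"))
  if (path_rep && !ben_rep) {
    out <- rbind(out, crit_row("PP5", "reported pathogenic without conflict"))
  }
  if (ben_rep && !path_rep) {
    out <- rbind(out, crit_row("BP6", "reported benign without conflict"))
  }

  if (has_freq && v$max_af >= ba1_af) {
    out <- rbind(out, crit_row("BA1", sprintf(
      "max control AF %.3g at or above %.2f", v$max_af, ba1_af)))
  }
  if (has_freq && has_gene && nrow(flags) == 1 &&
      !is.na(flags$disease_af_cutoff) &&
      v$max_af >= flags$disease_af_cutoff && v$max_af < ba1_af) {
    out <- rbind(out, crit_row("BS1", sprintf(
      "max control AF %.3g above disease cutoff %.3g", v$max_af,
      flags$disease_af_cutoff)))
  }
  if (!is.na(v$effect) && v$effect == "synonymous" &&
      !grepl("splice_region", v$all_effects %||% "")) {
    out <- rbind(out, crit_row("BP7", "synonymous with no splice impact"))
  }
  out
}

#' Combine ACMG criteria into a five-class pathogenicity call
#'
#' Implements the 2015 guideline combining table over criterion strength
#' counts. Evidence on both the pathogenic and the benign side is treated as
#' contradictory and yields uncertain_significance, as does an empty or
#' rule-less criteria set.
#'
#' @param codes Character vector of criterion codes (order-irrelevant).
#' @return One of pathogenic, likely_pathogenic, uncertain_significance,
#'   likely_benign, benign.
#' @export
combine_criteria <- function(codes) {
  codes <- as.character(codes)
  unknown <- setdiff(codes, ACMG_CODES)
  if (length(unknown)) {
    stopf("unknown ACMG criterion code(s): %s", paste(unknown, collapse = ", "))
  }
  strength <- criterion_strength(codes)
  pvs <- sum(strength == "very_strong")
  ps <- sum(strength == "strong" & startsWith(codes, "P"))
  pm <- sum(strength == "moderate")
  pp <- sum(strength == "supporting" & startsWith(codes, "PP"))
  ba <- sum(strength == "stand_alone")
  bs <- sum(strength == "strong" & startsWith(codes, "B"))
  bp <- sum(strength == "supporting" & startsWith(codes, "BP"))

  has_path <- (pvs + ps + pm + pp) > 0
  has_benign <- (ba + bs + bp) > 0
  if (has_path && has_benign) return("uncertain_significance")

  pathogenic <-
    (pvs >= 1 && (ps >= 1 || pm >= 2 || (pm == 1 && pp == 1) || pp >= 2)) ||
    ps >= 2 ||
    (ps == 1 && (pm >= 3 || (pm == 2 && pp >= 2) || (pm == 1 && pp >= 4)))
  if (pathogenic) return("pathogenic")
  likely_path <-
    (pvs >= 1 && pm >= 1) ||
    (ps == 1 && pm >= 1 && pm <= 2) ||
    (ps == 1 && pp >= 2) ||
    pm >= 3 ||
    (pm == 2 && pp >= 2) ||
    (pm == 1 && pp >= 4)
  if (likely_path) return("likely_pathogenic")

  if (ba >= 1 || bs >= 2) return("benign")
  if ((bs == 1 && bp >= 1) || bp >= 2) return("likely_benign")
  "uncertain_significance"
}

#' Classify every variant of an annotated table
#'
#' Runs [assign_criteria()] and [combine_criteria()] per variant and fills the
#' `acmg_class` and `acmg_criteria` columns (criteria comma-joined).
#'
#' @param av Annotated variant table.
#' @param knowledge Knowledgebase list with `assertions` and `gene_flags`.
#' @param pm2_af,ba1_af Thresholds passed to [assign_criteria()].
#' @return The table with ACMG columns filled.
#' @export
classify_variants <- function(av, knowledge, pm2_af = 1e-5, ba1_af = 0.05) {
  for (j in seq_len(nrow(av))) {
    crit <- assign_criteria(av[j, ], knowledge$assertions,
                            knowledge$gene_flags, pm2_af, ba1_af)
    av$acmg_criteria[j] <- paste(crit$code, collapse = ",")
    av$acmg_class[j] <- combine_criteria(crit$code)
  }
  av
}
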