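# Case store: persisted analyzed cases with analyst marks, in-house and
# sharing-group allele frequencies, prior interpretations, and account
# resolution statistics. Serialized as newline-delimited JSON (one case per
# line) plus a recomputable allele-count sidecar TSV; no database server.

#' Construct a case record
#'
#' @param case_id Unique case identifier within a store.
#' @param protocol Protocol name used for the analysis.
#' @param keywords Character vector of the phenotype keywords of the case.
#' @param date Analysis date (ISO string).
#' @param selections data.frame of analyst-selected variants: variant_key,
#'   gene_symbol, relevance (High/Med/Low), pathogenicity, note.
#' @param genotypes data.frame of the case's genotype summary for frequency
#'   counting: variant_key, zygosity (HET/HOM_ALT/HEMI).
#' @return A list of class `case_record`.
#' @export
case_record <- function(case_id, protocol = "rare-disease-exome",
                        keywords = character(), date = "1970-01-01",
                        selections = NULL, genotypes = NULL) {
  sel_proto <- list(variant_key = character(), gene_symbol = character(),
                    relevance = character(), pathogenicity = character(),
                    note = character())
  gt_proto <- list(variant_key = character(), zygosity = character())
  selections <- if (is.null(selections)) empty_df(sel_proto) else
    as.data.frame(selections, stringsAsFactors = FALSE)
  genotypes <- if (is.null(genotypes)) empty_df(gt_proto) else
    as.data.frame(genotypes, stringsAsFactors = FALSE)
  bad <- setdiff(unique(selections$relevance), c("High", "Med", "Low"))
  if (length(bad)) stopf("unknown relevance mark(s): %s",
                         paste(bad, collapse = ", "))
  structure(list(case_id = case_id, protocol = protocol,
                 keywords = as.character(keywords), date = date,
                 selections = selections, genotypes = genotypes),
            class = "case_record")
}

#' Create an empty case store
#'
#' @return A list of class `case_store`.
#' @export
case_store <- function() {
  structure(list(cases = list()), class = "case_store")
}

#' Add a case to a store
#'
#' @param store A `case_store`.
#' @param case A `case_record`; its case_id must be new to the store.
#' @return The updated store.
#' @export
store_add_case <- function(store, case) {
  stopifnot(inherits(store, "case_store"), inherits(case, "case_record"))
  if (case$case_id %in% names(store$cases)) {
    stopf("case id '%s' already present in store", case$case_id)
  }
  store$cases[[case$case_id]] <- case
  store
}

#' Write a store to disk
#'
#' Layout: `cases.ndjson` (one JSON object per case per line) and
#' `allele_counts.tsv`, a recomputable sidecar with pooled alt-allele and
#' total-allele counts per variant key.
#'
#' @param store A `case_store`.
#' @param dir Directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_store <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lines <- vapply(store$cases, function(cs) {
    jsonlite::toJSON(unclass(cs), auto_unbox = TRUE, digits = NA, null = "null")
  }, character(1))
  writeLines(lines, file.path(dir, "cases.ndjson"))
  keys <- sort(unique(unlist(lapply(store$cases,
                                    function(cs) cs$genotypes$variant_key))))
  counts <- do.call(rbind, lapply(keys, function(k) {
    ac <- allele_counts(k, store$cases)
    data.frame(variant_key = k, alt_alleles = ac$alt, total_alleles = ac$total,
               stringsAsFactors = FALSE)
  })) %||% empty_df(list(variant_key = character(), alt_alleles = integer(),
                         total_alleles = integer()))
  write_tsv(counts, file.path(dir, "allele_counts.tsv"))
  invisible(dir)
}

#' Read a store from disk
#'
#' @param dir Directory written by [write_store()].
#' @return A `case_store`.
#' @export
read_store <- function(dir) {
  path <- file.path(dir, "cases.ndjson")
  store <- case_store()
  if (!file.exists(path)) return(store)
  for (line in readLines(path, warn = FALSE)) {
    x <- jsonlite::fromJSON(line)
    sel <- as.data.frame(x$selections, stringsAsFactors = FALSE)
    gt <- as.data.frame(x$genotypes, stringsAsFactors = FALSE)
    store <- store_add_case(store, case_record(
      x$case_id, x$protocol, unlist(x$keywords), x$date,
      if (nrow(sel)) sel else NULL, if (nrow(gt)) gt else NULL))
  }
  store
}

# alt/total allele counts at a key over a list of cases; diploid convention,
# HEMI counts one allele of one.
allele_counts <- function(key, cases) {
  alt <- 0L
  total <- 0L
  for (cs in cases) {
    g <- cs$genotypes
    row <- g[g$variant_key == key, , drop = FALSE]
    if (nrow(row) > 0 && row$zygosity[1] == "HEMI") {
      total <- total + 1L
      alt <- alt + 1L
    } else {
      total <- total + 2L
      if (nrow(row) > 0) {
        alt <- alt + switch(row$zygosity[1], HET = 1L, HOM_ALT = 2L, 0L)
      }
    }
  }
  list(alt = alt, total = total)
}

#' In-house allele frequency
#'
#' Allele frequency of a variant over all stored diploid genotypes, the
#' current case always excluded to avoid self-counting. Cases without the key
#' contribute two reference alleles; an unseen key yields 0.
#'
#' @param key Variant key.
#' @param store A `case_store`.
#' @param exclude_case Case id of the analysis in progress (or NULL).
#' @return Frequency in [0,1].
#' @export
inhouse_af <- function(key, store, exclude_case = NULL) {
  cases <- store$cases[setdiff(names(store$cases), exclude_case)]
  ac <- allele_counts(key, cases)
  if (ac$total == 0) return(0)
  ac$alt / ac$total
}

#' Sharing-group allele frequency
#'
#' Pools allele counts across the member stores of a sharing group; with a
#' single member this equals [inhouse_af()].
#'
#' @param key Variant key.
#' @param stores List of `case_store` objects (>= 1).
#' @param exclude_case Case id excluded from every member store.
#' @return Frequency in [0,1].
#' @export
sharing_af <- function(key, stores, exclude_case = NULL) {
  stopifnot(length(stores) >= 1)
  alt <- 0L
  total <- 0L
  for (st in stores) {
    cases <- st$cases[setdiff(names(st$cases), exclude_case)]
    ac <- allele_counts(key, cases)
    alt <- alt + ac$alt
    total <- total + ac$total
  }
  if (total == 0) return(0)
  alt / total
}

#' Prior interpretations of a variant or gene
#'
#' All analyst marks recorded for the given variant key (or any variant of
#' the given gene) across stored cases, newest first.
#'
#' @param store A `case_store`.
#' @param variant_key Variant key, or NULL.
#' @param gene Gene symbol, or NULL (exactly one of the two must be given).
#' @return data.frame: case_id, date, variant_key, gene_symbol, relevance,
#'   pathogenicity, note.
#' @export
prior_interpretations <- function(store, variant_key = NULL, gene = NULL) {
  if (is.null(variant_key) == is.null(gene)) {
    stopf("give exactly one of variant_key or gene")
  }
  rows <- lapply(store$cases, function(cs) {
    sel <- cs$selections
    hit <- if (!is.null(variant_key)) sel$variant_key == variant_key else
      sel$gene_symbol == gene
    sel <- sel[hit, , drop = FALSE]
    if (nrow(sel) == 0) return(NULL)
    data.frame(case_id = cs$case_id, date = cs$date, sel,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    empty_df(list(case_id = character(), date = character(),
                  variant_key = character(), gene_symbol = character(),
                  relevance = character(), pathogenicity = character(),
                  note = character()))
  out <- out[order(out$date, decreasing = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-phenotype-class resolution statistics
#'
#' A case belongs to every class whose keyword list intersects the case's own
#' keywords (exact match, case-insensitive), so classes may overlap. A case
#' counts as resolved when at least one selected variant carries a High or
#' Med relevance mark. Percentages are rounded to one decimal; a class with
#' no cases reports NA.
#'
#' @param store A `case_store`.
#' @param class_defs Named list: class name -> character vector of keywords.
#' @return data.frame: class, keywords, total_cases, resolved_cases,
#'   percent_resolved.
#' @export
class_resolution_stats <- function(store, class_defs) {
  out <- empty_df(list(class = character(), keywords = character(),
                       total_cases = integer(), resolved_cases = integer(),
                       percent_resolved = numeric()))
  resolved_case <- vapply(store$cases, function(cs) {
    any(cs$selections$relevance %in% c("High", "Med"))
  }, logical(1))
  case_kw <- lapply(store$cases, function(cs) tolower(cs$keywords))
  for (cls in names(class_defs)) {
    kw <- tolower(class_defs[[cls]])
    member <- vapply(case_kw, function(x) length(intersect(x, kw)) > 0,
                     logical(1))
    total <- sum(member)
    res <- sum(member & resolved_case)
    out <- rbind(out, data.frame(
      class = cls, keywords = paste(class_defs[[cls]], collapse = ", "),
      total_cases = total, resolved_cases = res,
      percent_resolved = if (total == 0) NA_real_ else
        round(100 * res / total, 1),
      stringsAsFactors = FALSE))
  }
  out
}

#' Attach in-house and sharing frequencies to an annotated table
#'
#' Fills inhouse_af, sharing_af and prior_interpretations (count of prior
#' variant-level marks) from a store and an optional sharing group.
#'
#' @param av Annotated variant table.
#' @param store A `case_store` (or NULL to skip).
#' @param sharing_stores Optional list of stores forming the sharing group.
#' @param exclude_case Current case id.
#' @return The augmented table.
#' @export
attach_inhouse <- function(av, store, sharing_stores = NULL,
                           exclude_case = NULL) {
  if (is.null(store)) return(av)
  av$inhouse_af <- vapply(av$key, inhouse_af, numeric(1), store = store,
                          exclude_case = exclude_case)
  av$prior_interpretations <- vapply(av$key, function(k) {
    nrow(prior_interpretations(store, variant_key = k))
  }, integer(1))
  if (!is.null(sharing_stores)) {
    av$sharing_af <- vapply(av$key, sharing_af, numeric(1),
                            stores = sharing_stores,
                            exclude_case = exclude_case)
  }
  av
}
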