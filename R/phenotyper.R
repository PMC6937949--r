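# Phenotype-keyword gene prioritization over a sectioned local gene-document
# knowledgebase, with direct and one-hop indirect ("guilt by association")
# scoring and highlighted evidence snippets (minicards).

GENE_DOC_SECTIONS <- c("summaries", "disorders", "phenotypes", "publications",
                       "pathways", "function")

#' Default section weights
#'
#' Disease-facing sections (disorders, phenotypes) weigh most; curated
#' summaries next; function, pathways and publications progressively less.
#'
#' @return Named numeric vector of positive weights.
#' @export
default_section_weights <- function() {
  c(disorders = 3.0, phenotypes = 3.0, summaries = 2.0,
    `function` = 1.5, pathways = 1.0, publications = 1.0)
}

#' Load gene documents
#'
#' TSV with columns gene_symbol, section, text; section names come from the
#' closed vocabulary (summaries, disorders, phenotypes, publications,
#' pathways, function).
#'
#' @param x Path or data.frame.
#' @return Validated data.frame.
#' @export
load_gene_docs <- function(x) {
  df <- if (is.character(x)) {
    read_tsv_strict(x, c("gene_symbol", "section", "text"))
  } else as.data.frame(x)
  bad <- setdiff(unique(df$section), GENE_DOC_SECTIONS)
  if (length(bad)) stopf("unknown gene-doc section(s): %s",
                         paste(bad, collapse = ", "))
  df
}

#' Load gene-to-gene links
#'
#' TSV with gene_a, gene_b, link_type (shared_pathway or interaction) and
#' weight in (0,1]. Links are symmetric; self-links are rejected.
#'
#' @param x Path or data.frame.
#' @return Validated data.frame.
#' @export
load_gene_links <- function(x) {
  df <- if (is.character(x)) {
    read_tsv_strict(x, c("gene_a", "gene_b", "link_type", "weight"))
  } else as.data.frame(x)
  if (any(df$gene_a == df$gene_b)) stopf("self-links are not allowed")
  if (any(df$weight <= 0 | df$weight > 1)) {
    stopf("link weights must lie in (0,1]")
  }
  df
}

#' Build a keyword query
#'
#' @param terms Character vector of phrase terms (>= 1).
#' @param operator "OR" (any term) or "AND" (every term must occur somewhere
#'   in the document).
#' @param ignore_case Case-insensitive matching (default TRUE).
#' @return A list of class `keyword_query`.
#' @export
keyword_query <- function(terms, operator = c("OR", "AND"),
                          ignore_case = TRUE) {
  terms <- terms[nzchar(trimws(terms))]
  if (length(terms) == 0) stopf("a keyword query needs at least one term")
  structure(list(terms = trimws(terms), operator = match.arg(operator),
                 ignore_case = ignore_case),
            class = "keyword_query")
}

term_regex <- function(term) {
  paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", term), "\\b")
}

#' Search a gene document for query terms
#'
#' Whole-word, case-insensitive phrase matching per section. Under AND
#' semantics a document missing any term scores zero hits overall.
#'
#' @param doc data.frame of sections for one gene (columns section, text).
#' @param query A [keyword_query()].
#' @return list with `counts` (named per-section totals), `matched_terms`,
#'   and `hits` (data.frame section/term/start/end, character offsets).
#' @export
search_gene <- function(doc, query) {
  stopifnot(inherits(query, "keyword_query"))
  hits <- empty_df(list(section = character(), term = character(),
                        start = integer(), end = integer()))
  for (j in seq_len(nrow(doc))) {
    text <- doc$text[j]
    for (term in query$terms) {
      m <- gregexpr(term_regex(term), text, ignore.case = query$ignore_case,
                    perl = TRUE)[[1]]
      if (m[1] == -1) next
      hits <- rbind(hits, data.frame(
        section = doc$section[j], term = term, start = as.integer(m),
        end = as.integer(m) + attr(m, "match.length") - 1L,
        stringsAsFactors = FALSE))
    }
  }
  matched <- unique(hits$term)
  if (query$operator == "AND" && length(matched) < length(query$terms)) {
    hits <- hits[0, , drop = FALSE]
    matched <- character()
  }
  counts <- vapply(unique(doc$section), function(s) sum(hits$section == s),
                   integer(1))
  counts <- counts[counts > 0]
  list(counts = counts, matched_terms = matched, hits = hits)
}

#' Direct phenotype score from section hit counts
#'
#' `sum_s weight(s) * log2(1 + count(s))`, scaled by the fraction of query
#' terms matched (OR semantics; under AND either all terms matched or the
#' search already yielded zero hits).
#'
#' @param counts Named per-section hit counts.
#' @param weights Named section weights ([default_section_weights()]).
#' @param n_matched,n_terms Matched and total query term counts.
#' @return Non-negative numeric score.
#' @export
score_direct <- function(counts, weights = default_section_weights(),
                         n_matched = 1, n_terms = 1) {
  if (length(counts) == 0 || n_matched == 0) return(0)
  w <- weights[names(counts)]
  if (any(is.na(w))) stopf("no weight for section(s): %s",
                           paste(names(counts)[is.na(w)], collapse = ", "))
  sum(w * log2(1 + counts)) * (n_matched / n_terms)
}

#' Indirect (guilt-by-association) score
#'
#' One hop only: the best neighbor contribution
#' `link_weight * damping * direct_score(neighbor)`, damping fixed at 0.5.
#' Ties are broken by lexicographic neighbor symbol for determinism.
#'
#' @param gene Gene symbol.
#' @param links Link table ([load_gene_links()]).
#' @param direct_scores Named numeric vector of direct scores for all genes.
#' @param damping Attenuation per hop.
#' @return list(score, via_gene).
#' @export
score_indirect <- function(gene, links, direct_scores, damping = 0.5) {
  nb <- c(links$gene_b[links$gene_a == gene], links$gene_a[links$gene_b == gene])
  wt <- c(links$weight[links$gene_a == gene], links$weight[links$gene_b == gene])
  if (length(nb) == 0) return(list(score = 0, via_gene = NA_character_))
  contrib <- wt * damping * ifelse(is.na(direct_scores[nb]), 0,
                                   direct_scores[nb])
  o <- order(-contrib, nb)
  best <- o[1]
  if (contrib[best] <= 0) return(list(score = 0, via_gene = NA_character_))
  list(score = unname(contrib[best]), via_gene = nb[best])
}

#' Score all genes of a knowledgebase against a phenotype query
#'
#' Computes direct scores for every documented gene, then one-hop indirect
#' scores through the link graph; a gene's total is the larger of the two.
#'
#' @param gene_docs Gene documents ([load_gene_docs()]).
#' @param links Gene links ([load_gene_links()]); may be NULL.
#' @param query A [keyword_query()].
#' @param weights Section weights.
#' @param damping Indirect damping factor.
#' @return data.frame: gene_symbol, direct_score, indirect_score, total,
#'   matched_terms (comma-joined), matched_count, mode, via_gene.
#' @export
score_phenotypes <- function(gene_docs, links, query,
                             weights = default_section_weights(),
                             damping = 0.5) {
  genes <- sort(unique(c(gene_docs$gene_symbol,
                         links$gene_a %||% character(),
                         links$gene_b %||% character())))
  direct <- stats::setNames(numeric(length(genes)), genes)
  matched <- stats::setNames(vector("list", length(genes)), genes)
  for (g in genes) {
    doc <- gene_docs[gene_docs$gene_symbol == g, , drop = FALSE]
    if (nrow(doc) == 0) { matched[[g]] <- character(); next }
    sr <- search_gene(doc, query)
    direct[g] <- score_direct(sr$counts, weights,
                              length(sr$matched_terms), length(query$terms))
    matched[[g]] <- sr$matched_terms
  }
  out <- data.frame(gene_symbol = genes, direct_score = unname(direct),
                    indirect_score = 0, total = 0,
                    matched_terms = vapply(matched, paste, character(1),
                                           collapse = ","),
                    matched_count = vapply(matched, length, integer(1)),
                    mode = "none", via_gene = NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(links) && nrow(links) > 0) {
    for (j in seq_len(nrow(out))) {
      ind <- score_indirect(out$gene_symbol[j], links, direct, damping)
      out$indirect_score[j] <- ind$score
      out$via_gene[j] <- ind$via_gene
    }
  }
  out$total <- pmax(out$direct_score, out$indirect_score)
  out$mode <- ifelse(out$total == 0, "none",
                     ifelse(out$direct_score >= out$indirect_score,
                            "direct", "indirect"))
  rownames(out) <- NULL
  out
}

#' Build evidence snippets (minicards) for a gene
#'
#' One snippet per hit up to `cap` per section, ordered by position; the
#' matched span is delimited by `[[` and `]]` markers inside a character
#' window clipped at the text bounds, so that stripping the markers always
#' reproduces a verbatim substring of the section.
#'
#' @param doc data.frame of sections for one gene.
#' @param query A [keyword_query()].
#' @param window Context characters kept on each side of the match.
#' @param cap Maximum snippets per section.
#' @return data.frame: gene_symbol, section, term, snippet, source_pointer.
#' @export
build_minicard <- function(doc, query, window = 60, cap = 3) {
  sr <- search_gene(doc, query)
  hits <- sr$hits
  out <- empty_df(list(gene_symbol = character(), section = character(),
                       term = character(), snippet = character(),
                       source_pointer = character()))
  gene <- doc$gene_symbol[1] %||% NA_character_
  for (s in unique(hits$section)) {
    h <- hits[hits$section == s, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    h <- utils::head(h, cap)
    text <- doc$text[doc$section == s][1]
    for (k in seq_len(nrow(h))) {
      a <- h$start[k]; b <- h$end[k]
      lo <- max(1L, a - window)
      hi <- min(nchar(text), b + window)
      snippet <- paste0(substr(text, lo, a - 1L), "[[", substr(text, a, b),
                        "]]", substr(text, b + 1L, hi))
      out <- rbind(out, data.frame(
        gene_symbol = gene, section = s, term = h$term[k], snippet = snippet,
        source_pointer = paste0(gene, "#", s), stringsAsFactors = FALSE))
    }
  }
  out
}

#' Rank phenotype scores
#'
#' Descending total score; ties broken by matched-term count (descending),
#' then gene symbol. Stable and permutation-invariant.
#'
#' @param scores data.frame from [score_phenotypes()].
#' @return The reordered data.frame.
#' @export
rank_genes <- function(scores) {
  o <- order(-scores$total, -scores$matched_count, scores$gene_symbol)
  out <- scores[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}
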