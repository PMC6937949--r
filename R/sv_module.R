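# Structural-variant module: map SV events to genes and regulatory elements,
# score affected entities by combining element confidence, element-gene
# association confidence and the gene phenotype score, and rank events.

SV_TYPES <- c("DEL", "DUP", "INV", "INS")

#' Read a structural-variant call table
#'
#' Tab-delimited with columns chrom, start, end (1-based inclusive), sv_type
#' (DEL/DUP/INV/INS) and optional copy_number.
#'
#' @param x Path or data.frame.
#' @return Validated data.frame with event_id and length columns.
#' @export
read_sv_table <- function(x) {
  df <- if (is.character(x)) {
    read_tsv_strict(x, c("chrom", "start", "end", "sv_type"))
  } else as.data.frame(x)
  bad <- setdiff(unique(df$sv_type), SV_TYPES)
  if (length(bad)) stopf("unknown SV type(s): %s", paste(bad, collapse = ", "))
  if (any(df$start > df$end)) stopf("SV intervals must satisfy start <= end")
  df$chrom <- normalize_chrom(df$chrom)
  if (is.null(df$copy_number)) df$copy_number <- NA_integer_
  df$length <- df$end - df$start + 1L
  df$event_id <- sprintf("SV%03d", seq_len(nrow(df)))
  df
}

#' Load a regulatory-element map
#'
#' BED-like TSV with chrom, start, end (1-based inclusive here), element_id,
#' element_confidence in (0,1], and `targets` as semicolon-joined
#' gene:association_confidence pairs (e.g. "TOYG9:0.5;TOYG10:0.9").
#'
#' @param x Path or data.frame.
#' @return list(elements, targets): the element intervals and the unrolled
#'   element-gene association table.
#' @export
load_elements <- function(x) {
  df <- if (is.character(x)) {
    read_tsv_strict(x, c("chrom", "start", "end", "element_id",
                         "element_confidence", "targets"))
  } else as.data.frame(x)
  if (any(df$element_confidence <= 0 | df$element_confidence > 1)) {
    stopf("element confidences must lie in (0,1]")
  }
  df$chrom <- normalize_chrom(df$chrom)
  tlist <- lapply(seq_len(nrow(df)), function(j) {
    pairs <- strsplit(df$targets[j], ";", fixed = TRUE)[[1]]
    parts <- strsplit(pairs, ":", fixed = TRUE)
    data.frame(element_id = df$element_id[j],
               gene_symbol = vapply(parts, `[[`, character(1), 1),
               association_confidence =
                 as.numeric(vapply(parts, `[[`, character(1), 2)),
               stringsAsFactors = FALSE)
  })
  targets <- do.call(rbind, tlist) %||%
    empty_df(list(element_id = character(), gene_symbol = character(),
                  association_confidence = numeric()))
  if (nrow(targets) == 0 && nrow(df) > 0) stopf("elements must have targets")
  if (any(targets$association_confidence <= 0 |
          targets$association_confidence > 1)) {
    stopf("association confidences must lie in (0,1]")
  }
  list(elements = df, targets = targets)
}

#' Gene intervals from transcript models
#'
#' Collapses transcripts to one spanning interval per gene symbol.
#'
#' @param transcripts Transcript table ([load_transcripts()]).
#' @return data.frame gene_symbol/chrom/start/end.
#' @export
gene_intervals <- function(transcripts) {
  spans <- lapply(split(transcripts, transcripts$gene_symbol), function(tx) {
    ex <- do.call(rbind, lapply(seq_len(nrow(tx)), function(j) {
      exon_matrix(tx[j, ])
    }))
    data.frame(gene_symbol = tx$gene_symbol[1], chrom = tx$chrom[1],
               start = min(ex[, 1]), end = max(ex[, 2]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, spans)
  rownames(out) <- NULL
  out
}

sv_granges <- function(svs) {
  start <- svs$start
  end <- ifelse(svs$sv_type == "INS", svs$start, svs$end)
  GenomicRanges::GRanges(svs$chrom, IRanges::IRanges(start, end))
}

#' Map SV events to genes and regulatory elements
#'
#' An entity is affected when its interval intersects the event span by at
#' least one base; insertions are treated as 1-bp intervals at their start.
#' Each affected gene or element is listed once per event.
#'
#' @param svs SV table ([read_sv_table()]).
#' @param genes Gene interval table ([gene_intervals()]).
#' @param elements Element map ([load_elements()]).
#' @return data.frame: event_id, kind (gene/element), id.
#' @export
map_events <- function(svs, genes, elements) {
  out <- empty_df(list(event_id = character(), kind = character(),
                       id = character()))
  if (nrow(svs) == 0) return(out)
  q <- sv_granges(svs)
  if (!is.null(genes) && nrow(genes) > 0) {
    gg <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start, genes$end))
    h <- suppressWarnings(GenomicRanges::findOverlaps(q, gg))
    if (length(h)) {
      out <- rbind(out, unique(data.frame(
        event_id = svs$event_id[S4Vectors::queryHits(h)], kind = "gene",
        id = genes$gene_symbol[S4Vectors::subjectHits(h)],
        stringsAsFactors = FALSE)))
    }
  }
  el <- elements$elements
  if (!is.null(el) && nrow(el) > 0) {
    eg <- GenomicRanges::GRanges(el$chrom,
                                 IRanges::IRanges(el$start, el$end))
    h <- suppressWarnings(GenomicRanges::findOverlaps(q, eg))
    if (length(h)) {
      out <- rbind(out, unique(data.frame(
        event_id = svs$event_id[S4Vectors::queryHits(h)], kind = "element",
        id = el$element_id[S4Vectors::subjectHits(h)],
        stringsAsFactors = FALSE)))
    }
  }
  rownames(out) <- NULL
  out
}

#' Combined element score
#'
#' The prioritization score of a regulatory element through one target gene:
#' the plain product of element confidence, element-gene association
#' confidence and the target gene's phenotype score. Monotone in each factor
#' and zero whenever any factor is absent.
#'
#' @param element_confidence,association_confidence Confidences in (0,1].
#' @param phenotype_total The target gene's total phenotype score.
#' @return Non-negative numeric score.
#' @export
combined_element_score <- function(element_confidence, association_confidence,
                                   phenotype_total) {
  element_confidence * association_confidence * phenotype_total
}

#' Score affected entities of mapped SV events
#'
#' Gene entities take their gene's phenotype total; element entities take the
#' maximum [combined_element_score()] over their targets, recording the
#' maximizing target as via_target (ties broken by gene symbol).
#'
#' @param entities Mapping from [map_events()].
#' @param elements Element map ([load_elements()]).
#' @param pheno_scores Phenotype score table ([score_phenotypes()]).
#' @return The entity table with score and via_target columns.
#' @export
score_entities <- function(entities, elements, pheno_scores) {
  totals <- stats::setNames(pheno_scores$total, pheno_scores$gene_symbol)
  gene_total <- function(g) {
    v <- totals[g]
    ifelse(is.na(v), 0, v)
  }
  entities$score <- 0
  entities$via_target <- NA_character_
  for (j in seq_len(nrow(entities))) {
    if (entities$kind[j] == "gene") {
      entities$score[j] <- gene_total(entities$id[j])
    } else {
      tg <- elements$targets[elements$targets$element_id == entities$id[j], ,
                             drop = FALSE]
      ec <- elements$elements$element_confidence[
        elements$elements$element_id == entities$id[j]][1]
      if (nrow(tg) == 0) next
      sc <- combined_element_score(ec, tg$association_confidence,
                                   gene_total(tg$gene_symbol))
      o <- order(-sc, tg$gene_symbol)
      entities$score[j] <- sc[o[1]]
      if (sc[o[1]] > 0) entities$via_target[j] <- tg$gene_symbol[o[1]]
    }
  }
  entities
}

#' Rank SV events by their best entity score
#'
#' Events are ordered by descending maximum entity score, ties broken by
#' smaller event length, then chromosome and start. Per-event entity lists
#' are sorted by descending score.
#'
#' @param svs SV table.
#' @param entities Scored entity table ([score_entities()]).
#' @return list(events, entities): ranked events (with max_score) and the
#'   reordered entity table.
#' @export
rank_sv_events <- function(svs, entities) {
  max_score <- vapply(svs$event_id, function(e) {
    s <- entities$score[entities$event_id == e]
    if (length(s) == 0) 0 else max(s)
  }, numeric(1))
  svs$max_score <- unname(max_score)
  o <- order(-svs$max_score, svs$length, svs$chrom, svs$start)
  svs <- svs[o, , drop = FALSE]
  rownames(svs) <- NULL
  entities <- entities[order(match(entities$event_id, svs$event_id),
                             -entities$score, entities$id), , drop = FALSE]
  rownames(entities) <- NULL
  list(events = svs, entities = entities)
}

#' Analyze structural variants end to end
#'
#' Maps, scores and ranks SV events against the transcript-derived gene
#' intervals, the regulatory-element map and a phenotype score table.
#'
#' @param svs SV table or path.
#' @param transcripts Transcript table.
#' @param elements Element map ([load_elements()] result or path).
#' @param pheno_scores Phenotype scores ([score_phenotypes()]).
#' @return list(events, entities) as in [rank_sv_events()].
#' @export
analyze_svs <- function(svs, transcripts, elements, pheno_scores) {
  if (is.character(svs)) svs <- read_sv_table(svs)
  if (is.character(elements)) elements <- load_elements(elements)
  genes <- gene_intervals(transcripts)
  entities <- map_events(svs, genes, elements)
  entities <- score_entities(entities, elements, pheno_scores)
  rank_sv_events(svs, entities)
}
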