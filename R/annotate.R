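# Annotation: transcript-aware consequence calling, per-transcript call
# merging, control-population frequency joins, clinical assertions and
# prediction-tool consensus. This is a deliberately minimal consequence
# caller operating on packaged toy transcript models; it covers SNV codon
# effects, frame-preserving/-shifting indels, splice-site proximity, UTR,
# intronic and intergenic calls.

EFFECT_ORDER <- c("stop_gained", "frameshift", "splice_acceptor",
                  "splice_donor", "start_lost", "missense", "inframe_indel",
                  "synonymous", "splice_region", "utr", "intronic",
                  "intergenic")

EFFECT_TIER <- c(stop_gained = "HIGH", frameshift = "HIGH",
                 splice_acceptor = "HIGH", splice_donor = "HIGH",
                 start_lost = "HIGH", missense = "MODERATE",
                 inframe_indel = "MODERATE", synonymous = "LOW",
                 splice_region = "LOW", utr = "MODIFIER",
                 intronic = "MODIFIER", intergenic = "MODIFIER")

NULL_EFFECTS <- c("stop_gained", "frameshift", "splice_acceptor",
                  "splice_donor", "start_lost")

#' Effect severity tier
#'
#' Fixed effect-to-tier mapping: premature stops, frameshifts, canonical
#' splice-site (+/- 2 bp) and start-loss variants are HIGH; missense and
#' in-frame indels MODERATE; synonymous and splice-region LOW; everything
#' else MODIFIER.
#'
#' @param effect Character vector of effect labels.
#' @return Character vector of tiers.
#' @export
severity_tier <- function(effect) {
  unname(EFFECT_TIER[effect])
}

#' Load transcript models
#'
#' Reads a transcript table (TSV with columns transcript_id, gene_symbol,
#' chrom, strand, exon_starts, exon_ends, cds_start, cds_end; exon columns are
#' comma-joined 1-based inclusive coordinates) and validates structural
#' consistency: exons sorted and non-overlapping, CDS bounds inside the exon
#' span. Inconsistent models are a hard error at load time.
#'
#' @param x Path to the TSV or an equivalent data.frame.
#' @return The validated transcript data.frame.
#' @export
load_transcripts <- function(x) {
  df <- if (is.character(x)) {
    read_tsv_strict(x, c("transcript_id", "gene_symbol", "chrom", "strand",
                         "exon_starts", "exon_ends", "cds_start", "cds_end"))
  } else {
    as.data.frame(x)
  }
  df$chrom <- normalize_chrom(df$chrom)
  for (j in seq_len(nrow(df))) {
    ex <- exon_matrix(df[j, ])
    if (any(diff(ex[, 1]) <= 0) || any(ex[, 2] < ex[, 1])) {
      stopf("transcript %s: exons must be sorted, non-overlapping",
            df$transcript_id[j])
    }
    if (nrow(ex) > 1 && any(ex[-1, 1] <= ex[-nrow(ex), 2])) {
      stopf("transcript %s: overlapping exons", df$transcript_id[j])
    }
    if (df$cds_start[j] < min(ex[, 1]) || df$cds_end[j] > max(ex[, 2]) ||
        df$cds_start[j] > df$cds_end[j]) {
      stopf("transcript %s: inconsistent CDS bounds", df$transcript_id[j])
    }
  }
  df
}

exon_matrix <- function(tx) {
  s <- as.integer(strsplit(as.character(tx$exon_starts), ",")[[1]])
  e <- as.integer(strsplit(as.character(tx$exon_ends), ",")[[1]])
  if (length(s) != length(e)) stopf("exon start/end count mismatch")
  cbind(start = s, end = e)
}

#' Build a transcript index for consequence calling
#'
#' Precomputes, per transcript, the exon matrix, the ascending genomic
#' positions of CDS bases and the sense-strand CDS sequence, so that repeated
#' consequence calls are cheap.
#'
#' @param transcripts Validated transcript data.frame ([load_transcripts()]).
#' @param reference A `DNAStringSet`.
#' @return A list of class `transcript_index`.
#' @export
build_transcript_index <- function(transcripts, reference) {
  idx <- lapply(seq_len(nrow(transcripts)), function(j) {
    tx <- transcripts[j, ]
    ex <- exon_matrix(tx)
    cds_pos <- unlist(lapply(seq_len(nrow(ex)), function(i) {
      lo <- max(ex[i, 1], tx$cds_start)
      hi <- min(ex[i, 2], tx$cds_end)
      if (lo <= hi) seq.int(lo, hi) else integer()
    }))
    bases <- strsplit(ref_seq(reference, tx$chrom, min(ex[, 1]), max(ex[, 2])),
                      "")[[1]]
    cds_fwd <- paste(bases[cds_pos - min(ex[, 1]) + 1L], collapse = "")
    cds_seq <- if (tx$strand == "-") revcomp(cds_fwd) else cds_fwd
    list(transcript_id = tx$transcript_id, gene_symbol = tx$gene_symbol,
         chrom = tx$chrom, strand = tx$strand, exons = ex,
         cds_start = tx$cds_start, cds_end = tx$cds_end,
         tx_start = min(ex[, 1]), tx_end = max(ex[, 2]),
         cds_pos = cds_pos, cds_seq = cds_seq)
  })
  names(idx) <- transcripts$transcript_id
  structure(idx, class = "transcript_index")
}

codon_aa <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[toupper(codon)]]
  if (is.null(aa)) NA_character_ else aa
}

consequence_call <- function(transcript_id, gene_symbol, effect, aa_change = "") {
  list(transcript_id = transcript_id, gene_symbol = gene_symbol,
       effect = effect, severity_tier = unname(EFFECT_TIER[[effect]]),
       aa_change = aa_change)
}

#' Call the functional consequence of a variant
#'
#' For every transcript overlapping the variant, classifies the effect:
#' CDS SNVs are translated through the standard codon table honoring strand
#' (synonymous / missense / stop_gained / start_lost with a protein HGVS-like
#' `aa_change`); CDS indels are classified by length difference mod 3
#' (inframe_indel / frameshift); intronic positions within 2 bp of an
#' exon-intron junction are splice_donor/splice_acceptor (strand-aware),
#' within 3-8 bp splice_region; exonic positions outside the CDS are utr.
#' A variant overlapping no transcript yields a single intergenic call.
#'
#' @param chrom,pos,ref,alt A normalized biallelic variant.
#' @param tx_index A [build_transcript_index()] result.
#' @return data.frame of calls: transcript_id, gene_symbol, effect,
#'   severity_tier, aa_change.
#' @export
call_consequence <- function(chrom, pos, ref, alt, tx_index) {
  chrom <- normalize_chrom(chrom)
  span_end <- pos + nchar(ref) - 1L
  calls <- list()
  for (tx in tx_index) {
    if (tx$chrom != chrom || span_end < tx$tx_start || pos > tx$tx_end) next
    calls[[length(calls) + 1L]] <- consequence_one(tx, pos, ref, alt)
  }
  if (length(calls) == 0) {
    calls <- list(consequence_call(NA_character_, NA_character_, "intergenic"))
  }
  do.call(rbind, lapply(calls, function(x) {
    data.frame(x, stringsAsFactors = FALSE)
  }))
}

consequence_one <- function(tx, pos, ref, alt) {
  is_snv <- nchar(ref) == 1 && nchar(alt) == 1
  # effective position: for anchored indels the first changed base
  pos_eff <- if (is_snv) pos else min(pos + 1L, tx$tx_end)
  ex <- tx$exons
  in_exon <- which(ex[, 1] <= pos_eff & pos_eff <= ex[, 2])

  if (length(in_exon) == 0) {
    # intronic: distance to flanking exon junctions
    n <- nrow(ex)
    for (i in seq_len(n - 1)) {
      istart <- ex[i, 2] + 1L
      iend <- ex[i + 1, 1] - 1L
      if (pos_eff < istart || pos_eff > iend) next
      d5 <- pos_eff - istart   # distance into intron from upstream exon (+)
      d3 <- iend - pos_eff
      plus <- tx$strand == "+"
      if (d5 <= 1L) {
        return(consequence_call(tx$transcript_id, tx$gene_symbol,
                                if (plus) "splice_donor" else "splice_acceptor"))
      }
      if (d3 <= 1L) {
        return(consequence_call(tx$transcript_id, tx$gene_symbol,
                                if (plus) "splice_acceptor" else "splice_donor"))
      }
      if (min(d5, d3) <= 7L) {
        return(consequence_call(tx$transcript_id, tx$gene_symbol, "splice_region"))
      }
      return(consequence_call(tx$transcript_id, tx$gene_symbol, "intronic"))
    }
    return(consequence_call(tx$transcript_id, tx$gene_symbol, "intronic"))
  }

  in_cds <- pos_eff >= tx$cds_start && pos_eff <= tx$cds_end
  if (!in_cds) {
    return(consequence_call(tx$transcript_id, tx$gene_symbol, "utr"))
  }
  if (!is_snv) {
    delta <- abs(nchar(ref) - nchar(alt))
    eff <- if (delta %% 3L == 0L && delta > 0L) "inframe_indel"
      else if (delta > 0L) "frameshift"
      else "missense"   # length-preserving multi-base substitution
    return(consequence_call(tx$transcript_id, tx$gene_symbol, eff))
  }

  off_fwd <- match(pos, tx$cds_pos)
  if (is.na(off_fwd)) {
    return(consequence_call(tx$transcript_id, tx$gene_symbol, "utr"))
  }
  n_cds <- length(tx$cds_pos)
  minus <- tx$strand == "-"
  off <- if (minus) n_cds - off_fwd + 1L else off_fwd
  ref_s <- if (minus) comp_base(ref) else ref
  alt_s <- if (minus) comp_base(alt) else alt
  codon_i <- (off - 1L) %/% 3L + 1L
  within <- off - (codon_i - 1L) * 3L
  codon <- substr(tx$cds_seq, (codon_i - 1L) * 3L + 1L, codon_i * 3L)
  if (substr(codon, within, within) != toupper(ref_s)) {
    stopf("transcript %s disagrees with reference at CDS offset %d",
          tx$transcript_id, off)
  }
  alt_codon <- codon
  substr(alt_codon, within, within) <- toupper(alt_s)
  ref_aa <- codon_aa(codon)
  alt_aa <- codon_aa(alt_codon)
  aa_change <- sprintf("p.%s%d%s", ref_aa, codon_i, alt_aa)
  effect <- if (identical(ref_aa, alt_aa)) "synonymous"
    else if (identical(alt_aa, "*")) "stop_gained"
    else if (codon_i == 1L) "start_lost"
    else "missense"
  consequence_call(tx$transcript_id, tx$gene_symbol, effect,
                   if (effect == "synonymous") aa_change else aa_change)
}

#' Merge per-transcript consequence calls
#'
#' Returns the single worst call: highest severity tier, ties broken by the
#' fixed effect order, then lexicographic transcript id. Deterministic and
#' permutation-invariant.
#'
#' @param calls data.frame from [call_consequence()] (>= 1 row).
#' @return A one-row data.frame.
#' @export
merge_transcript_calls <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0) {
    stopf("merge_transcript_calls: empty call set")
  }
  o <- order(match(calls$effect, EFFECT_ORDER),
             ifelse(is.na(calls$transcript_id), "~", calls$transcript_id))
  calls[o[1], , drop = FALSE]
}

#' Load a control-population frequency table
#'
#' TSV keyed by chrom/pos/ref/alt with one numeric column per emulated control
#' source. Any allele frequency outside [0,1] is a load-time error.
#'
#' @param x Path or data.frame.
#' @return The validated table with normalized chrom and a `key` column.
#' @export
load_frequency_table <- function(x) {
  df <- if (is.character(x)) {
    read_tsv_strict(x, c("chrom", "pos", "ref", "alt"))
  } else as.data.frame(x)
  src <- setdiff(names(df), c("chrom", "pos", "ref", "alt", "key"))
  for (s in src) {
    v <- df[[s]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stopf("frequency column '%s' has values outside [0,1]", s)
    }
  }
  df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  attr(df, "sources") <- src
  df
}

#' Attach control frequencies to variants
#'
#' Pure lookup by normalized variant key. A variant absent from every source
#' gets max_af = 0 (the "absent from controls" convention); a present variant
#' gets the maximum over non-missing sources.
#'
#' @param keys Character vector of variant keys.
#' @param freq_table A [load_frequency_table()] result.
#' @return data.frame with `key`, one column per source, and `max_af`.
#' @export
attach_frequencies <- function(keys, freq_table) {
  src <- attr(freq_table, "sources") %||%
    setdiff(names(freq_table), c("chrom", "pos", "ref", "alt", "key"))
  m <- match(keys, freq_table$key)
  out <- data.frame(key = keys, stringsAsFactors = FALSE)
  for (s in src) out[[s]] <- freq_table[[s]][m]
  vals <- as.matrix(out[, src, drop = FALSE])
  max_af <- apply(vals, 1, function(v) {
    if (all(is.na(v))) 0 else max(v, na.rm = TRUE)
  })
  out$max_af <- if (length(keys)) as.numeric(max_af) else numeric()
  out
}

ASSERTION_SIGNIFICANCE <- c("pathogenic", "likely_pathogenic", "uncertain",
                            "likely_benign", "benign")

#' Load a clinical assertion table
#'
#' ClinVar/COSMIC/CiVIC-like assertions: TSV with source, chrom, pos, ref,
#' alt, gene_symbol, aa_change, condition, significance (closed vocabulary).
#'
#' @param x Path or data.frame.
#' @return Validated data.frame with a `key` column.
#' @export
load_assertions <- function(x) {
  df <- if (is.character(x)) {
    read_tsv_strict(x, c("source", "chrom", "pos", "ref", "alt", "gene_symbol",
                         "aa_change", "condition", "significance"))
  } else as.data.frame(x)
  bad <- setdiff(unique(df$significance), ASSERTION_SIGNIFICANCE)
  if (length(bad)) stopf("unknown assertion significance: %s",
                         paste(bad, collapse = ", "))
  df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  df
}

#' Load a prediction-tool verdict table
#'
#' TSV keyed by variant with one column per emulated tool (e.g. sift_like,
#' polyphen_like, mutationtaster_like, gerp_like), each verdict one of
#' damaging / tolerated / unknown.
#'
#' @param x Path or data.frame.
#' @return Validated data.frame with a `key` column.
#' @export
load_predictions <- function(x) {
  df <- if (is.character(x)) {
    read_tsv_strict(x, c("chrom", "pos", "ref", "alt"))
  } else as.data.frame(x)
  tools <- setdiff(names(df), c("chrom", "pos", "ref", "alt", "key"))
  for (t in tools) {
    bad <- setdiff(unique(df[[t]]), c("damaging", "tolerated", "unknown", NA))
    if (length(bad)) stopf("unknown verdict in '%s': %s", t,
                           paste(bad, collapse = ", "))
  }
  df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  attr(df, "tools") <- tools
  df
}

#' Consensus over prediction-tool verdicts
#'
#' Majority rule over non-unknown verdicts: "damaging" when more than half of
#' the non-unknown verdicts are damaging and at least two non-unknown verdicts
#' are present; "tolerated" symmetrically; "unknown" when every verdict is
#' unknown (or none given); "mixed" otherwise.
#'
#' @param verdicts Character vector of per-tool verdicts.
#' @return One of "damaging", "tolerated", "mixed", "unknown".
#' @export
severity_consensus <- function(verdicts) {
  v <- verdicts[!is.na(verdicts) & verdicts != "unknown"]
  if (length(v) == 0) return("unknown")
  d <- sum(v == "damaging")
  t <- sum(v == "tolerated")
  n <- length(v)
  if (n >= 2 && d / n > 0.5) return("damaging")
  if (n >= 2 && t / n > 0.5) return("tolerated")
  "mixed"
}

#' Load per-gene knowledge flags
#'
#' TSV with gene_symbol, lof_mechanism (0/1: loss of function is an
#' established disease mechanism) and disease_af_cutoff (maximum credible
#' population frequency for the gene's disease, used by the BS1 criterion).
#'
#' @param x Path or data.frame.
#' @return Validated data.frame.
#' @export
load_gene_flags <- function(x) {
  df <- if (is.character(x)) {
    read_tsv_strict(x, c("gene_symbol", "lof_mechanism", "disease_af_cutoff"))
  } else as.data.frame(x)
  df
}

#' Annotate a normalized variant set
#'
#' Produces the annotated variant table: one row per biallelic variant with
#' gene/effect (worst merged call), control frequencies, assertion and
#' prediction summaries. ACMG class, phenotype score and in-house fields are
#' filled by their own modules.
#'
#' @param vs A normalized `variant_set`.
#' @param knowledge A knowledgebase list as returned by
#'   [load_knowledgebase()], or a list with elements `tx_index`, `frequencies`,
#'   `assertions`, `predictions`.
#' @return data.frame of annotated variants.
#' @export
annotate_variants <- function(vs, knowledge) {
  recs <- vs$records
  n <- nrow(recs)
  eff <- vector("list", n)
  all_eff <- character(n)
  for (j in seq_len(n)) {
    calls <- call_consequence(recs$chrom[j], recs$pos[j], recs$ref[j],
                              recs$alt[j], knowledge$tx_index)
    all_eff[j] <- paste(sort(unique(calls$effect)), collapse = ",")
    eff[[j]] <- merge_transcript_calls(calls)
  }
  worst <- do.call(rbind, eff)
  out <- data.frame(
    uid = recs$uid, chrom = recs$chrom, pos = recs$pos, ref = recs$ref,
    alt = recs$alt, qual = recs$qual,
    key = recs$key %||% variant_key(recs$chrom, recs$pos, recs$ref, recs$alt),
    gene_symbol = worst$gene_symbol, effect = worst$effect,
    severity_tier = worst$severity_tier, aa_change = worst$aa_change,
    transcript_id = worst$transcript_id, all_effects = all_eff,
    stringsAsFactors = FALSE
  )
  fr <- attach_frequencies(out$key, knowledge$frequencies)
  out$max_af <- fr$max_af
  src <- setdiff(names(fr), c("key", "max_af"))
  for (s in src) out[[paste0("af_", s)]] <- fr[[s]]

  asr <- knowledge$assertions
  out$n_assertions <- vapply(out$key, function(k) sum(asr$key == k), integer(1))
  out$assertion_significance <- vapply(out$key, function(k) {
    paste(sort(unique(asr$significance[asr$key == k])), collapse = ",")
  }, character(1))

  pred <- knowledge$predictions
  tools <- attr(pred, "tools") %||%
    setdiff(names(pred), c("chrom", "pos", "ref", "alt", "key"))
  m <- match(out$key, pred$key)
  out$consensus_severity <- vapply(seq_len(n), function(j) {
    if (is.na(m[j])) return("unknown")
    severity_consensus(unlist(pred[m[j], tools], use.names = FALSE))
  }, character(1))

  out$acmg_class <- NA_character_
  out$acmg_criteria <- NA_character_
  out$phenotype_score <- NA_real_
  out$matched_phenotype_count <- NA_integer_
  out$inhouse_af <- NA_real_
  out$sharing_af <- NA_real_
  out$prior_interpretations <- NA_integer_
  out
}

#' Write annotated variants back to VCF INFO fields
#'
#' Emits the variant set with annotation carried in reserved-prefix INFO keys
#' (VT_GENE, VT_EFFECT, VT_AA, VT_MAXAF, VT_ACMG, VT_PHENO) so the file can
#' be re-ingested (the prefix is stripped by the default sanitization
#' policy when listed in `strip_info_keys`).
#'
#' @param av Annotated variant table.
#' @param vs The originating biallelic `variant_set`.
#' @param path Output VCF path.
#' @return `path`, invisibly.
#' @export
write_annotated_vcf <- function(av, vs, path) {
  m <- match(vs$records$uid, av$uid)
  info <- sprintf(
    "VT_GENE=%s;VT_EFFECT=%s;VT_AA=%s;VT_MAXAF=%s;VT_ACMG=%s;VT_PHENO=%s",
    ifelse(is.na(av$gene_symbol[m]), ".", av$gene_symbol[m]),
    av$effect[m],
    ifelse(nzchar(av$aa_change[m]), av$aa_change[m], "."),
    format(av$max_af[m], trim = TRUE),
    ifelse(is.na(av$acmg_class[m]), ".", av$acmg_class[m]),
    ifelse(is.na(av$phenotype_score[m]), ".",
           format(av$phenotype_score[m], trim = TRUE)))
  vs$records$info <- info
  vs$header <- c(vs$header[-length(vs$header)],
                 sprintf("##INFO=<ID=VT_%s,Number=1,Type=String,Description=\"varitriage %s\">",
                         c("GENE", "EFFECT", "AA", "MAXAF", "ACMG", "PHENO"),
                         c("gene symbol", "worst effect", "protein change",
                           "max control AF", "ACMG class", "phenotype score")),
                 vs$header[length(vs$header)])
  write_vcf(vs, path)
}
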