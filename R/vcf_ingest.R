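# VCF ingest: tolerant parsing/sanitization, BED region filtering,
# multi-allelic decomposition and indel normalization.
#
# Coordinates: VCF positions are 1-based inclusive; BED intervals are 0-based
# half-open. Everything internal is 1-based; conversion happens exactly once,
# when a BED file is read.

#' Header policy for VCF sanitization
#'
#' Declares which header keys must be present in a sanitized VCF, which
#' chromosomes are admissible, and which INFO keys from pre-annotated inputs
#' must be stripped before re-annotation.
#'
#' @param required_fields Header keys guaranteed after sanitization. "DP" is
#'   injected as a FORMAT definition, "DP4" as INFO; other keys default to a
#'   generic INFO definition.
#' @param canonical Allowed chromosome set (normalized form; "chr" prefixes in
#'   the input are accepted and stripped).
#' @param strip_info_keys Annotation INFO keys removed from records so a
#'   previously annotated VCF is reduced to raw calls.
#' @return A list of class `header_policy`.
#' @export
header_policy <- function(required_fields = c("DP", "DP4"),
                          canonical = canonical_chromosomes(),
                          strip_info_keys = c("ANN", "EFF", "CSQ", "LOF", "NMD")) {
  stopifnot(length(canonical) > 0)
  structure(list(required_fields = required_fields,
                 canonical = canonical,
                 strip_info_keys = strip_info_keys),
            class = "header_policy")
}

#' Region set from a BED file
#'
#' Reads BED3+ (0-based half-open) and converts to 1-based inclusive
#' intervals indexed as a `GRanges` for fast point queries.
#'
#' @param bed Path to a BED file, or a data.frame with columns
#'   chrom/start/end already in BED convention.
#' @param label Human-readable label (e.g. "Exome").
#' @return A list of class `region_set` with the 1-based interval table and
#'   its `GRanges` index.
#' @export
region_set <- function(bed, label = "regions") {
  if (is.character(bed)) {
    df <- utils::read.table(bed, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE,
                            col.names = c("chrom", "start", "end", "name",
                                          "score", "strand")[1:max(3, count_bed_cols(bed))],
                            fill = TRUE)
  } else {
    df <- as.data.frame(bed)
  }
  df <- df[, c("chrom", "start", "end")]
  if (any(df$start >= df$end)) {
    stopf("region set '%s': BED intervals must satisfy start < end", label)
  }
  had_prefix <- any(grepl("^chr", df$chrom, ignore.case = TRUE))
  df$chrom <- normalize_chrom(df$chrom)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  structure(list(intervals = df, index = gr, label = label,
                 had_prefix = had_prefix),
            class = "region_set")
}

count_bed_cols <- function(path) {
  first <- readLines(path, n = 1)
  length(strsplit(first, "\t")[[1]])
}

new_variant_set <- function(records, genotypes, samples, header, log,
                            stage = c("raw", "biallelic")) {
  structure(list(records = records, genotypes = genotypes, samples = samples,
                 header = header, log = log, stage = match.arg(stage)),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set> %d record(s), %d sample(s), stage=%s\n",
              nrow(x$records), length(x$samples), x$stage))
  invisible(x)
}

log_row <- function(reason, n) data.frame(reason = reason, n = n,
                                          stringsAsFactors = FALSE)

#' Sanitize a VCF stream
#'
#' Validates and cleans VCF v4.x content: drops records on non-canonical
#' chromosomes, skips (and logs) malformed lines, strips pre-existing
#' annotation INFO keys, and injects missing required header definitions.
#' A sanitation log counts records dropped per reason.
#'
#' Individual bad lines are tolerated (clinical VCF dialects vary); the parse
#' fails only when more than half of the data lines are malformed, or when the
#' file declares no sample columns.
#'
#' @param vcf Path to a VCF (.vcf or .vcf.gz) or a character vector of VCF
#'   lines.
#' @param policy A [header_policy()].
#' @return A `variant_set` at stage "raw": records (chrom normalized, possibly
#'   multi-allelic `alt`), per-sample raw genotype fields (gt/dp/ad), the
#'   sanitized header, and the sanitation log.
#' @export
sanitize_vcf <- function(vcf, policy = header_policy()) {
  lines <- if (length(vcf) == 1 && file.exists(vcf)) {
    con <- if (grepl("\\.gz$", vcf)) gzfile(vcf) else file(vcf)
    on.exit(close(con), add = TRUE)
    readLines(con, warn = FALSE)
  } else {
    as.character(vcf)
  }
  meta <- lines[startsWith(lines, "##")]
  chrom_line <- lines[startsWith(lines, "#CHROM")]
  if (length(chrom_line) != 1) {
    stopf("not a valid VCF: expected exactly one #CHROM header line")
  }
  cols <- strsplit(chrom_line, "\t")[[1]]
  if (length(cols) < 10) {
    stopf("VCF has no sample columns; at least one sample is required")
  }
  samples <- cols[-(1:9)]
  data_lines <- lines[!startsWith(lines, "#") & nzchar(lines)]

  log <- empty_df(list(reason = character(), n = integer()))
  n_fields <- length(cols)
  recs <- vector("list", length(data_lines))
  genos <- vector("list", length(data_lines))
  n_malformed <- 0L
  n_noncanon <- 0L
  keep <- 0L

  for (i in seq_along(data_lines)) {
    f <- strsplit(data_lines[[i]], "\t", fixed = TRUE)[[1]]
    pos <- suppressWarnings(as.integer(f[2]))
    ok <- length(f) == n_fields &&
      !is.na(pos) && pos >= 1L &&
      grepl("^[ACGTN]+$", toupper(f[4])) &&
      nzchar(f[5]) && f[5] != "." &&
      !any(toupper(strsplit(f[5], ",", fixed = TRUE)[[1]]) == toupper(f[4]))
    if (!ok) {
      n_malformed <- n_malformed + 1L
      next
    }
    chrom <- normalize_chrom(f[1])
    if (!chrom %in% policy$canonical) {
      n_noncanon <- n_noncanon + 1L
      next
    }
    keep <- keep + 1L
    qual <- suppressWarnings(as.numeric(f[6]))
    info <- strip_info(f[8], policy$strip_info_keys)
    recs[[keep]] <- list(chrom = chrom, pos = pos, id = f[3],
                         ref = toupper(f[4]), alt = toupper(f[5]),
                         qual = qual, filter = f[7], info = info)
    genos[[keep]] <- parse_sample_fields(f[9], f[10:n_fields], samples)
  }
  if (length(data_lines) > 0 && n_malformed > length(data_lines) / 2) {
    stopf("systemic VCF malformation: %d of %d data lines unparseable",
          n_malformed, length(data_lines))
  }
  if (n_malformed > 0) log <- rbind(log, log_row("malformed_line", n_malformed))
  if (n_noncanon > 0) {
    log <- rbind(log, log_row("non_canonical_chromosome", n_noncanon))
  }

  records <- if (keep > 0) {
    do.call(rbind, lapply(recs[seq_len(keep)], function(r) {
      data.frame(r, stringsAsFactors = FALSE)
    }))
  } else {
    empty_df(list(chrom = character(), pos = integer(), id = character(),
                  ref = character(), alt = character(), qual = numeric(),
                  filter = character(), info = character()))
  }
  records$uid <- seq_len(nrow(records))
  genotypes <- if (keep > 0) {
    g <- do.call(rbind, genos[seq_len(keep)])
    g$uid <- rep(records$uid, each = length(samples))
    g
  } else {
    empty_df(list(sample_id = character(), gt = character(), dp = integer(),
                  ad = character(), uid = integer()))
  }
  header <- inject_headers(meta, policy$required_fields)
  new_variant_set(records, genotypes, samples, c(header, chrom_line), log,
                  stage = "raw")
}

strip_info <- function(info, keys) {
  if (length(keys) == 0 || info == "." || !nzchar(info)) return(info)
  toks <- strsplit(info, ";", fixed = TRUE)[[1]]
  key_of <- sub("=.*$", "", toks)
  kept <- toks[!key_of %in% keys]
  if (length(kept) == 0) "." else paste(kept, collapse = ";")
}

parse_sample_fields <- function(format, sample_strs, samples) {
  fmt <- strsplit(format, ":", fixed = TRUE)[[1]]
  i_gt <- match("GT", fmt)
  i_dp <- match("DP", fmt)
  i_ad <- match("AD", fmt)
  parts <- strsplit(sample_strs, ":", fixed = TRUE)
  get <- function(p, i) if (!is.na(i) && length(p) >= i) p[[i]] else NA_character_
  data.frame(
    sample_id = samples,
    gt = vapply(parts, get, character(1), i_gt),
    dp = suppressWarnings(as.integer(vapply(parts, get, character(1), i_dp))),
    ad = vapply(parts, get, character(1), i_ad),
    stringsAsFactors = FALSE
  )
}

inject_headers <- function(meta, required) {
  canned <- c(
    DP  = "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    DP4 = "##INFO=<ID=DP4,Number=4,Type=Integer,Description=\"Strand-specific reference and alternate read counts\">"
  )
  for (key in required) {
    pat <- sprintf("^##(INFO|FORMAT)=<ID=%s[,>]", key)
    if (!any(grepl(pat, meta))) {
      line <- if (key %in% names(canned)) canned[[key]] else
        sprintf("##INFO=<ID=%s,Number=.,Type=String,Description=\"%s\">", key, key)
      meta <- c(meta, line)
    }
  }
  meta
}

#' Restrict variants to a region set
#'
#' Keeps a record iff its 1-based position `p` falls inside some interval,
#' i.e. `start < p <= end` for the original BED 0-based half-open interval.
#' Chromosome naming differences (chr1 vs 1) are normalized before comparison;
#' a note is appended to the sanitation log when normalization was needed.
#'
#' @param vs A `variant_set`.
#' @param regions A [region_set()].
#' @return The filtered `variant_set` (log updated with drop counts).
#' @export
filter_regions <- function(vs, regions) {
  stopifnot(inherits(vs, "variant_set"), inherits(regions, "region_set"))
  if (nrow(vs$records) == 0) return(vs)
  q <- GenomicRanges::GRanges(vs$records$chrom,
                              IRanges::IRanges(vs$records$pos, width = 1L))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, regions$index))
  keep <- sort(unique(S4Vectors::queryHits(hits)))
  dropped <- nrow(vs$records) - length(keep)
  if (regions$had_prefix) {
    vs$log <- rbind(vs$log, log_row("chromosome_prefix_normalized", 0L))
  }
  if (dropped > 0) {
    vs$log <- rbind(vs$log, log_row("outside_regions", dropped))
  }
  subset_variant_set(vs, keep)
}

subset_variant_set <- function(vs, idx) {
  recs <- vs$records[idx, , drop = FALSE]
  keep_uid <- recs$uid
  vs$genotypes <- vs$genotypes[vs$genotypes$uid %in% keep_uid, , drop = FALSE]
  vs$records <- recs
  rownames(vs$records) <- NULL
  rownames(vs$genotypes) <- NULL
  vs
}

#' Split multi-allelic records into biallelic ones
#'
#' Emits one record per alternative allele. Genotypes are re-expressed
#' relative to that allele: a sample carrying allele i once is HET, twice is
#' HOM_ALT (haploid calls carrying the allele are treated as HOM_ALT, the
#' hemizygous convention), and otherwise HOM_REF; missing genotypes stay
#' MISSING. Per-allele supporting reads come from the AD vector; the shared
#' site depth (DP, falling back to the AD sum) is preserved.
#'
#' @param vs A `variant_set` at stage "raw".
#' @return A `variant_set` at stage "biallelic" with typed genotype columns
#'   sample_id/zygosity/depth/alt_reads/alt_fraction.
#' @export
split_multiallelic <- function(vs) {
  stopifnot(inherits(vs, "variant_set"))
  if (vs$stage != "raw") stopf("split_multiallelic expects a raw variant_set")
  out_rec <- list()
  out_gt <- list()
  next_uid <- 0L
  for (j in seq_len(nrow(vs$records))) {
    r <- vs$records[j, ]
    alts <- strsplit(r$alt, ",", fixed = TRUE)[[1]]
    g <- vs$genotypes[vs$genotypes$uid == r$uid, , drop = FALSE]
    for (i in seq_along(alts)) {
      next_uid <- next_uid + 1L
      rr <- r
      rr$alt <- alts[[i]]
      rr$uid <- next_uid
      out_rec[[next_uid]] <- rr
      out_gt[[next_uid]] <- genotype_vs_allele(g, i, next_uid)
    }
  }
  records <- if (length(out_rec)) do.call(rbind, out_rec) else
    vs$records[0, , drop = FALSE]
  genotypes <- if (length(out_gt)) do.call(rbind, out_gt) else
    empty_df(list(sample_id = character(), zygosity = character(),
                  depth = integer(), alt_reads = integer(),
                  alt_fraction = numeric(), uid = integer()))
  rownames(records) <- NULL
  rownames(genotypes) <- NULL
  new_variant_set(records, genotypes, vs$samples, vs$header, vs$log,
                  stage = "biallelic")
}

genotype_vs_allele <- function(g, allele_index, uid) {
  n <- nrow(g)
  zyg <- character(n)
  alt_reads <- rep(NA_integer_, n)
  depth <- rep(NA_integer_, n)
  for (k in seq_len(n)) {
    gt <- g$gt[[k]]
    alleles <- if (is.na(gt)) character() else strsplit(gt, "[/|]")[[1]]
    if (length(alleles) == 0 || any(alleles == ".") || any(is.na(alleles))) {
      zyg[k] <- "MISSING"
    } else {
      ai <- suppressWarnings(as.integer(alleles))
      cnt <- sum(ai == allele_index)
      zyg[k] <- if (cnt == 0) "HOM_REF"
        else if (cnt == length(ai)) "HOM_ALT" else "HET"
    }
    ad <- g$ad[[k]]
    advec <- if (!is.na(ad) && nzchar(ad) && ad != ".") {
      suppressWarnings(as.integer(strsplit(ad, ",", fixed = TRUE)[[1]]))
    } else integer()
    if (length(advec) >= allele_index + 1) alt_reads[k] <- advec[allele_index + 1]
    depth[k] <- if (!is.na(g$dp[[k]])) g$dp[[k]]
      else if (length(advec)) sum(advec, na.rm = TRUE) else NA_integer_
  }
  data.frame(sample_id = g$sample_id, zygosity = zyg, depth = depth,
             alt_reads = alt_reads,
             alt_fraction = ifelse(!is.na(depth) & depth > 0 & !is.na(alt_reads),
                                   alt_reads / depth, NA_real_),
             uid = uid, stringsAsFactors = FALSE)
}

#' Normalize a biallelic allele pair
#'
#' Trims the shared suffix, left-aligns through repeat context, then trims the
#' shared prefix, yielding the parsimonious leftmost representation. The
#' operation is idempotent. Fails loudly if the stated reference allele
#' disagrees with the reference sequence at the locus.
#'
#' @param chrom,pos,ref,alt A biallelic variant (1-based).
#' @param reference A `DNAStringSet` from [read_reference()].
#' @return A list with elements `pos`, `ref`, `alt`.
#' @export
normalize_indel <- function(chrom, pos, ref, alt, reference) {
  ref <- toupper(ref); alt <- toupper(alt)
  observed <- ref_seq(reference, chrom, pos, pos + nchar(ref) - 1L)
  if (observed != ref) {
    stopf("reference mismatch at %s:%d: VCF says '%s', reference has '%s'",
          normalize_chrom(chrom), pos, ref, observed)
  }
  repeat {
    changed <- FALSE
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0 && na > 0 &&
        substr(ref, nr, nr) == substr(alt, na, na) && (nr > 1 || na > 1)) {
      ref <- substr(ref, 1, nr - 1L)
      alt <- substr(alt, 1, na - 1L)
      changed <- TRUE
    }
    if (nchar(ref) == 0 || nchar(alt) == 0) {
      if (pos <= 1L) stopf("cannot left-extend past start of %s", chrom)
      pos <- pos - 1L
      b <- ref_seq(reference, chrom, pos, pos)
      ref <- paste0(b, ref)
      alt <- paste0(b, alt)
      changed <- TRUE
    }
    if (!changed) break
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Normalize every record of a biallelic variant set
#'
#' Applies [normalize_indel()] record-wise and recomputes variant keys.
#'
#' @param vs A `variant_set` at stage "biallelic".
#' @param reference A `DNAStringSet`.
#' @return The normalized `variant_set`; records gain a `key` column.
#' @export
normalize_variants <- function(vs, reference) {
  stopifnot(inherits(vs, "variant_set"))
  if (vs$stage != "biallelic") stopf("normalize_variants expects biallelic records")
  for (j in seq_len(nrow(vs$records))) {
    r <- vs$records[j, ]
    n <- normalize_indel(r$chrom, r$pos, r$ref, r$alt, reference)
    vs$records$pos[j] <- n$pos
    vs$records$ref[j] <- n$ref
    vs$records$alt[j] <- n$alt
  }
  vs$records$key <- variant_key(vs$records$chrom, vs$records$pos,
                                vs$records$ref, vs$records$alt)
  vs
}

#' Write a sanitized variant set back to VCF
#'
#' Round-trippable minimal writer: emits the sanitized header and one line per
#' record with GT:DP:AD genotype columns (raw stage) or GT:DP:AD reconstructed
#' from typed genotypes (biallelic stage).
#'
#' @param vs A `variant_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path) {
  header <- vs$header
  lines <- character(nrow(vs$records))
  for (j in seq_len(nrow(vs$records))) {
    r <- vs$records[j, ]
    g <- vs$genotypes[vs$genotypes$uid == r$uid, , drop = FALSE]
    g <- g[match(vs$samples, g$sample_id), , drop = FALSE]
    cells <- if (vs$stage == "raw") {
      paste(ifelse(is.na(g$gt), "./.", g$gt),
            ifelse(is.na(g$dp), ".", g$dp),
            ifelse(is.na(g$ad), ".", g$ad), sep = ":")
    } else {
      gt <- c(HOM_REF = "0/0", HET = "0/1", HOM_ALT = "1/1",
              MISSING = "./.")[g$zygosity]
      ad <- ifelse(is.na(g$alt_reads) | is.na(g$depth), ".",
                   paste(g$depth - g$alt_reads, g$alt_reads, sep = ","))
      paste(gt, ifelse(is.na(g$depth), ".", g$depth), ad, sep = ":")
    }
    lines[j] <- paste(c(r$chrom, r$pos, r$id, r$ref, r$alt,
                        ifelse(is.na(r$qual), ".", r$qual), r$filter, r$info,
                        "GT:DP:AD", cells), collapse = "\t")
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Write the sanitation log as TSV
#'
#' @param vs A `variant_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sanitation_log <- function(vs, path) {
  write_tsv(vs$log, path)
}

#' Ingest a VCF end to end
#'
#' Convenience wrapper running the fixed ingest order: sanitize, region
#' filter (optional), multi-allelic split, indel normalization (optional,
#' requires a reference).
#'
#' @param vcf VCF path or lines.
#' @param regions Optional [region_set()].
#' @param reference Optional `DNAStringSet` enabling normalization.
#' @param policy A [header_policy()].
#' @return A normalized biallelic `variant_set`.
#' @export
ingest_vcf <- function(vcf, regions = NULL, reference = NULL,
                       policy = header_policy()) {
  vs <- sanitize_vcf(vcf, policy)
  if (!is.null(regions)) vs <- filter_regions(vs, regions)
  vs <- split_multiallelic(vs)
  if (!is.null(reference)) vs <- normalize_variants(vs, reference)
  vs
}
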