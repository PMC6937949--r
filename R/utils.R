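# Shared helpers: chromosome naming, variant keys, small conveniences.

#' Canonical chromosome names
#'
#' The prefix-free canonical set used throughout the package: autosomes 1-22,
#' X, Y and MT. All chromosome names are normalized to this form at I/O
#' boundaries so that joins against knowledge tables never miss on naming.
#'
#' @return Character vector of canonical chromosome names.
#' @export
canonical_chromosomes <- function() {
  c(as.character(1:22), "X", "Y", "MT")
}

#' Normalize chromosome names to prefix-free form
#'
#' Strips a leading "chr" (any case) and maps "M" to "MT", so "chr1", "1",
#' "chrX" and "chrM" become "1", "1", "X" and "MT".
#'
#' @param x Character vector of chromosome names.
#' @return Character vector of normalized names.
#' @export
normalize_chrom <- function(x) {
  x <- sub("^[Cc][Hh][Rr]", "", as.character(x))
  x <- toupper(x)
  x[x == "M"] <- "MT"
  x
}

#' Canonical variant key
#'
#' Builds the "chrom:pos:ref:alt" key used to join variants against frequency,
#' assertion and prediction tables and the case store. Alleles are assumed
#' normalized (split, trimmed, left-aligned).
#'
#' @param chrom,pos,ref,alt Vectors describing biallelic variants.
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(normalize_chrom(chrom), pos, toupper(ref), toupper(alt), sep = ":")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with sprintf formatting, no call in the condition
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# empty prototype data.frame from a named list of column prototypes
empty_df <- function(proto) {
  as.data.frame(lapply(proto, function(x) x[0]), stringsAsFactors = FALSE)
}

# file md5 for version manifests; text content checksum via a temp file
content_checksum <- function(text) {
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  writeLines(text, tf)
  unname(tools::md5sum(tf))
}

read_tsv_strict <- function(path, required = character()) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stopf("table '%s' lacks required column(s): %s",
          path, paste(missing, collapse = ", "))
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
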