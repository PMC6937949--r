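# Reference genome access: a thin wrapper over Biostrings FASTA I/O giving a
# chromosome/start/end substring lookup with normalized chromosome names.

#' Load a reference genome from FASTA
#'
#' Reads a (possibly multi-sequence) FASTA and returns a `DNAStringSet` whose
#' names are normalized chromosome names (first whitespace-delimited word of
#' each FASTA header, "chr" prefix stripped).
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] keyed by normalized chromosome.
#' @export
read_reference <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1)
  names(seqs) <- normalize_chrom(nm)
  seqs
}

#' Extract reference sequence
#'
#' @param reference A `DNAStringSet` as returned by [read_reference()].
#' @param chrom Chromosome name (any naming style).
#' @param start,end 1-based inclusive coordinates.
#' @return Uppercase character string of the requested bases.
#' @export
ref_seq <- function(reference, chrom, start, end) {
  chrom <- normalize_chrom(chrom)
  if (!chrom %in% names(reference)) {
    stopf("chromosome '%s' not present in reference", chrom)
  }
  len <- length(reference[[chrom]])
  if (start < 1 || end > len || start > end) {
    stopf("coordinates %d-%d outside reference %s (length %d)",
          start, end, chrom, len)
  }
  toupper(as.character(Biostrings::subseq(reference[[chrom]], start, end)))
}

# reverse complement for plain character strings
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

comp_base <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}
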