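# VCF sanitization, region filtering, multi-allelic splitting, normalization.

test_that("sanitization drops non-canonical chromosomes and logs the reason", {
  vcf <- vcf_lines(c(
    vcf_row("chr1", 100, "A", "G", "0/1:20:10,10"),
    vcf_row("chrUn_gl000220", 500, "C", "T", "0/1:20:10,10")))
  vs <- sanitize_vcf(vcf)
  expect_equal(nrow(vs$records), 1)
  expect_equal(vs$records$chrom, "1")
  expect_equal(vs$log$n[vs$log$reason == "non_canonical_chromosome"], 1L)
})

test_that("missing required headers are injected without touching records", {
  vcf <- c("##fileformat=VCFv4.2",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "S1"), collapse = "\t"),
           vcf_row("1", 42, "A", "C", "0/1:15:8,7"))
  vs <- sanitize_vcf(vcf)
  expect_true(any(grepl("^##FORMAT=<ID=DP[,>]", vs$header)))
  expect_true(any(grepl("^##INFO=<ID=DP4[,>]", vs$header)))
  expect_equal(vs$records$pos, 42L)
  expect_equal(vs$records$ref, "A")
  expect_equal(vs$records$alt, "C")
})

test_that("a header-only VCF yields an empty record list and empty log", {
  vs <- sanitize_vcf(vcf_lines(character()))
  expect_equal(nrow(vs$records), 0)
  expect_equal(nrow(vs$log), 0)
})

test_that("pre-existing annotation INFO keys are stripped", {
  vcf <- vcf_lines(vcf_row("1", 10, "A", "G", "0/1:20:10,10",
                           info = "DP4=1,2,3,4;ANN=bad|stuff;AC=2"))
  vs <- sanitize_vcf(vcf)
  expect_equal(vs$records$info, "DP4=1,2,3,4;AC=2")
})

test_that("zero samples is a hard error; mostly-malformed input is a hard error", {
  no_samples <- c("##fileformat=VCFv4.2",
                  paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                          "FILTER", "INFO"), collapse = "\t"))
  expect_error(sanitize_vcf(no_samples), "sample")
  bad <- vcf_lines(c("garbage line", "another\tbad",
                     vcf_row("1", 5, "A", "G", "0/1:10:5,5")))
  expect_error(sanitize_vcf(bad), "malformation")
})

test_that("isolated malformed lines are skipped and logged", {
  vcf <- vcf_lines(c(vcf_row("1", 5, "A", "G", "0/1:10:5,5"),
                     vcf_row("1", 9, "C", "T", "1/1:12:0,12"),
                     "1\tnot_a_position\t.\tA\tG\t50\tPASS\t.\tGT\t0/1"))
  vs <- sanitize_vcf(vcf)
  expect_equal(nrow(vs$records), 2)
  expect_equal(vs$log$n[vs$log$reason == "malformed_line"], 1L)
})

test_that("region filtering honors the BED half-open convention", {
  vcf <- vcf_lines(c(vcf_row("chr1", 100, "A", "G", "0/1:20:10,10"),
                     vcf_row("chr1", 250, "C", "T", "0/1:20:10,10")))
  vs <- sanitize_vcf(vcf)
  # BED "chr1 99 100" covers exactly base 100 (1-based)
  keep <- filter_regions(vs, region_set(data.frame(
    chrom = "chr1", start = 99, end = 100)))
  expect_equal(keep$records$pos, 100L)
  # BED "chr1 100 200" starts at base 101, so position 100 is outside
  drop <- filter_regions(vs, region_set(data.frame(
    chrom = "chr1", start = 100, end = 200)))
  expect_equal(nrow(drop$records), 0)
})

test_that("region filtering equals the brute-force overlap scan", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 20
    recs <- data.frame(chrom = sample(c("1", "2"), n, replace = TRUE),
                       pos = sample(1:1000, n))
    rows <- vapply(seq_len(n), function(i) {
      vcf_row(recs$chrom[i], recs$pos[i], "A", "G", "0/1:20:10,10")
    }, character(1))
    vs <- sanitize_vcf(vcf_lines(rows))
    m <- 8
    bed <- data.frame(chrom = sample(c("1", "2"), m, replace = TRUE),
                      start = sample(0:900, m))
    bed$end <- bed$start + sample(10:120, m, replace = TRUE)
    got <- filter_regions(vs, region_set(bed))
    keep <- vapply(seq_len(nrow(vs$records)), function(i) {
      any(bed$chrom == vs$records$chrom[i] &
            bed$start < vs$records$pos[i] & vs$records$pos[i] <= bed$end)
    }, logical(1))
    expect_equal(got$records[, c("chrom", "pos")],
                 vs$records[keep, c("chrom", "pos")],
                 ignore_attr = TRUE)
  }
})

test_that("a 1/2 multi-allelic genotype splits into two HET biallelic records", {
  vcf <- vcf_lines(vcf_row("1", 50, "G", "A,T", "1/2:30:2,14,14"))
  vs <- split_multiallelic(sanitize_vcf(vcf))
  expect_equal(nrow(vs$records), 2)
  expect_equal(vs$records$alt, c("A", "T"))
  expect_equal(vs$genotypes$zygosity, c("HET", "HET"))
  expect_equal(vs$genotypes$alt_reads, c(14L, 14L))
  expect_equal(vs$genotypes$depth, c(30L, 30L))
})

test_that("a biallelic record passes through splitting unchanged", {
  vcf <- vcf_lines(vcf_row("1", 50, "G", "A", "0/1:30:16,14"))
  vs <- split_multiallelic(sanitize_vcf(vcf))
  expect_equal(nrow(vs$records), 1)
  expect_equal(vs$records$alt, "A")
  expect_equal(vs$genotypes$zygosity, "HET")
})

test_that("splitting conserves planted per-allele read counts and alleles", {
  set.seed(7)
  for (rep in 1:50) {
    n_alt <- sample(2:3, 1)
    alts <- sample(c("T", "C", "TA", "CG"), n_alt)
    ad <- sample(0:20, n_alt + 1, replace = TRUE)
    gt_alleles <- sample(0:n_alt, 2, replace = TRUE)
    gt <- paste(gt_alleles, collapse = "/")
    row <- vcf_row("1", 100, "A", paste(alts, collapse = ","),
                   sprintf("%s:%d:%s", gt, sum(ad), paste(ad, collapse = ",")))
    vs <- split_multiallelic(sanitize_vcf(vcf_lines(row)))
    expect_equal(nrow(vs$records), n_alt)
    for (i in seq_len(n_alt)) {
      g <- vs$genotypes[vs$genotypes$uid == i, ]
      expect_equal(g$alt_reads, ad[i + 1])
      cnt <- sum(gt_alleles == i)
      expect_equal(g$zygosity,
                   if (cnt == 0) "HOM_REF" else if (cnt == 2) "HOM_ALT"
                   else "HET")
    }
  }
})

test_that("indel normalization left-aligns through repeats and is idempotent", {
  ref <- Biostrings::DNAStringSet(c("1" = "TTCAAAAGTT"))
  # deleting one A of the run, stated rightmost: collapses to the anchored
  # leftmost representation CA>C at position 3
  n1 <- normalize_indel("1", 5, "AA", "A", ref)
  expect_equal(n1, list(pos = 3L, ref = "CA", alt = "C"))
  n2 <- normalize_indel("1", 3, "CAA", "CA", ref)
  expect_equal(n2, list(pos = 3L, ref = "CA", alt = "C"))
  again <- normalize_indel("1", n1$pos, n1$ref, n1$alt, ref)
  expect_equal(again, n1)
})

test_that("SNVs are untouched and reference mismatches are fatal", {
  ref <- Biostrings::DNAStringSet(c("1" = "TTCAAAAGTT"))
  expect_equal(normalize_indel("1", 3, "C", "G", ref),
               list(pos = 3L, ref = "C", alt = "G"))
  expect_error(normalize_indel("1", 3, "G", "A", ref), "mismatch")
})

test_that("normalization preserves the alternate haplotype on random indels", {
  apply_variant <- function(seq, pos, ref, alt) {
    paste0(substr(seq, 1, pos - 1), alt,
           substr(seq, pos + nchar(ref), nchar(seq)))
  }
  set.seed(21)
  for (rep in 1:100) {
    seq <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE,
                        prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
    ref_set <- Biostrings::DNAStringSet(c("1" = seq))
    pos <- sample(5:40, 1)
    if (runif(1) < 0.5) {
      len <- sample(1:4, 1)
      ref <- substr(seq, pos, pos + len)
      alt <- substr(seq, pos, pos)
    } else {
      ref <- substr(seq, pos, pos)
      alt <- paste0(ref, paste(sample(c("A", "T"), sample(1:3, 1),
                                      replace = TRUE), collapse = ""))
    }
    n <- normalize_indel("1", pos, ref, alt, ref_set)
    expect_equal(apply_variant(seq, n$pos, n$ref, n$alt),
                 apply_variant(seq, pos, ref, alt))
    expect_equal(normalize_indel("1", n$pos, n$ref, n$alt, ref_set), n)
  }
})

test_that("sanitized VCFs round-trip through the writer", {
  vcf <- vcf_lines(c(vcf_row("1", 5, "A", "G", "0/1:10:5,5"),
                     vcf_row("2", 9, "C", "T", "1/1:12:0,12")))
  vs <- sanitize_vcf(vcf)
  tf <- tempfile(fileext = ".vcf")
  write_vcf(vs, tf)
  vs2 <- sanitize_vcf(tf)
  expect_equal(vs2$records[, c("chrom", "pos", "ref", "alt")],
               vs$records[, c("chrom", "pos", "ref", "alt")])
  unlink(tf)
})
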