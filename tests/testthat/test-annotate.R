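# Consequence calling, call merging, frequency joins, prediction consensus.

test_that("CDS SNVs translate correctly on the plus strand", {
  idx <- make_tiny_index()
  # codon 2 GAG -> TAG
  stop_call <- call_consequence("1", 19, "G", "T", idx)
  expect_equal(stop_call$effect, "stop_gained")
  expect_equal(stop_call$severity_tier, "HIGH")
  expect_equal(stop_call$aa_change, "p.E2*")
  # codon 3 TTT -> TTC, both Phe
  syn <- call_consequence("1", 24, "T", "C", idx)
  expect_equal(syn$effect, "synonymous")
  expect_equal(syn$severity_tier, "LOW")
  # missense and start loss
  expect_equal(call_consequence("1", 20, "A", "T", idx)$effect, "missense")
  expect_equal(call_consequence("1", 17, "T", "A", idx)$effect, "start_lost")
})

test_that("the minus-strand transcript mirrors the plus-strand calls", {
  idx <- make_tiny_index()
  # chromosome 2 is the reverse complement; position 19 maps to 75-19=56
  stop_call <- call_consequence("2", 56, "C", "A", idx)
  expect_equal(stop_call$effect, "stop_gained")
  expect_equal(stop_call$aa_change, "p.E2*")
  syn <- call_consequence("2", 51, "A", "G", idx)
  expect_equal(syn$effect, "synonymous")
})

test_that("splice, UTR, intronic and intergenic positions are classified", {
  idx <- make_tiny_index()
  expect_equal(call_consequence("1", 26, "G", "A", idx)$effect, "splice_donor")
  expect_equal(call_consequence("1", 45, "G", "A", idx)$effect,
               "splice_acceptor")
  expect_equal(call_consequence("1", 30, "C", "A", idx)$effect,
               "splice_region")
  expect_equal(call_consequence("1", 36, "C", "A", idx)$effect, "intronic")
  expect_equal(call_consequence("1", 12, "T", "A", idx)$effect, "utr")
  expect_equal(call_consequence("1", 62, "A", "T", idx)$effect, "utr")
  far <- call_consequence("1", 5, "A", "T", idx)
  expect_equal(far$effect, "intergenic")
  expect_equal(far$severity_tier, "MODIFIER")
  # strand-aware splice sides on the minus strand: the donor is the
  # high-coordinate end of the intron, the acceptor the low end
  expect_equal(call_consequence("2", 49, "C", "A", idx)$effect,
               "splice_donor")
  expect_equal(call_consequence("2", 30, "C", "A", idx)$effect,
               "splice_acceptor")
})

test_that("CDS indels are classified by length mod 3", {
  ref <- make_tiny_reference()
  idx <- make_tiny_index()
  del3 <- substr(as.character(ref[["1"]]), 17, 20)
  inframe <- call_consequence("1", 17, del3, substr(del3, 1, 1), idx)
  expect_equal(inframe$effect, "inframe_indel")
  del1 <- substr(as.character(ref[["1"]]), 17, 18)
  fs <- call_consequence("1", 17, del1, substr(del1, 1, 1), idx)
  expect_equal(fs$effect, "frameshift")
  expect_equal(fs$severity_tier, "HIGH")
})

test_that("the caller agrees with the translation oracle on every CDS SNV", {
  ref <- make_tiny_reference()
  txs <- load_transcripts(tiny_transcripts())
  idx <- build_transcript_index(txs, ref)
  for (j in 1:2) {
    tx <- idx[[j]]
    chrom_seq <- as.character(ref[[tx$chrom]])
    for (pos in tx$cds_pos) {
      refb <- substr(chrom_seq, pos, pos)
      for (alt in setdiff(c("A", "C", "G", "T"), refb)) {
        got <- call_consequence(tx$chrom, pos, refb, alt, idx)
        got <- got[got$transcript_id == tx$transcript_id, ]
        expect_equal(got$effect, oracle_cds_snv(ref, txs[j, ], pos, alt),
                     label = sprintf("%s:%d %s>%s", tx$chrom, pos, refb, alt))
      }
    }
  }
})

test_that("call merging keeps the worst effect with deterministic tie-breaks", {
  mk <- function(effect, tx = "T1") {
    data.frame(transcript_id = tx, gene_symbol = "G", effect = effect,
               severity_tier = severity_tier(effect), aa_change = "",
               stringsAsFactors = FALSE)
  }
  calls <- rbind(mk("synonymous", "T1"), mk("missense", "T2"))
  expect_equal(merge_transcript_calls(calls)$effect, "missense")
  expect_equal(merge_transcript_calls(mk("utr"))$effect, "utr")
  # same tier: missense precedes inframe_indel in the fixed effect order
  tie <- rbind(mk("inframe_indel", "T1"), mk("missense", "T2"))
  expect_equal(merge_transcript_calls(tie)$effect, "missense")
  expect_equal(merge_transcript_calls(tie[2:1, ])$effect, "missense")
  # equal effects: lexicographic transcript id
  same <- rbind(mk("missense", "T9"), mk("missense", "T2"))
  expect_equal(merge_transcript_calls(same)$transcript_id, "T2")
  expect_error(merge_transcript_calls(mk("utr")[0, ]), "empty")
})

test_that("frequency lookup takes the maximum over present sources", {
  tab <- load_frequency_table(data.frame(
    chrom = "1", pos = 100, ref = "A", alt = "G",
    kg_like = 0.002, gnomad_like = 0.004, esp_like = NA))
  fr <- attach_frequencies(variant_key("1", 100, "A", "G"), tab)
  expect_equal(fr$max_af, 0.004)
  absent <- attach_frequencies(variant_key("1", 999, "C", "T"), tab)
  expect_equal(absent$max_af, 0)
})

test_that("frequency join equals a brute-force column-wise maximum", {
  set.seed(31)
  n <- 100
  tab_df <- data.frame(
    chrom = sample(c("1", "2"), n, replace = TRUE),
    pos = sample(1:5000, n), ref = "A", alt = "G",
    s1 = ifelse(runif(n) < 0.3, NA, round(runif(n), 4)),
    s2 = ifelse(runif(n) < 0.3, NA, round(runif(n), 4)),
    s3 = ifelse(runif(n) < 0.3, NA, round(runif(n), 4)))
  tab <- load_frequency_table(tab_df)
  keys <- c(tab$key[1:50], variant_key("1", 9999, "A", "G"))
  got <- attach_frequencies(keys, tab)
  for (i in seq_along(keys)) {
    m <- match(keys[i], tab$key)
    want <- if (is.na(m)) 0 else {
      v <- c(tab_df$s1[m], tab_df$s2[m], tab_df$s3[m])
      if (all(is.na(v))) 0 else max(v, na.rm = TRUE)
    }
    expect_equal(got$max_af[i], want)
  }
  expect_error(load_frequency_table(data.frame(
    chrom = "1", pos = 1, ref = "A", alt = "G", s1 = 1.2)), "outside")
})

test_that("prediction consensus matches majority rule on every verdict vector", {
  verdicts <- c("damaging", "tolerated", "unknown")
  grid <- expand.grid(verdicts, verdicts, verdicts, verdicts,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    v <- unlist(grid[i, ], use.names = FALSE)
    known <- v[v != "unknown"]
    want <- if (length(known) == 0) "unknown"
      else if (length(known) >= 2 &&
               sum(known == "damaging") > length(known) / 2) "damaging"
      else if (length(known) >= 2 &&
               sum(known == "tolerated") > length(known) / 2) "tolerated"
      else "mixed"
    expect_equal(severity_consensus(v), want)
  }
  expect_equal(severity_consensus(c("damaging", "damaging", "damaging",
                                    "tolerated")), "damaging")
  expect_equal(severity_consensus(rep("unknown", 4)), "unknown")
  expect_equal(severity_consensus(c("damaging", "damaging", "tolerated",
                                    "tolerated")), "mixed")
})

test_that("annotating twice yields identical records", {
  idx <- make_tiny_index()
  kb <- list(tx_index = idx,
             frequencies = load_frequency_table(data.frame(
               chrom = "1", pos = 19, ref = "G", alt = "T", s1 = 0.01)),
             assertions = load_assertions(data.frame(
               source = "clinvar_like", chrom = "1", pos = 19, ref = "G",
               alt = "T", gene_symbol = "GENEA", aa_change = "p.E2*",
               condition = "x", significance = "pathogenic")),
             predictions = load_predictions(data.frame(
               chrom = "1", pos = 19, ref = "G", alt = "T",
               sift_like = "damaging", polyphen_like = "damaging")))
  vs <- normalize_variants(split_multiallelic(sanitize_vcf(vcf_lines(
    vcf_row("1", 19, "G", "T", "0/1:30:15,15")))), make_tiny_reference())
  a1 <- annotate_variants(vs, kb)
  a2 <- annotate_variants(vs, kb)
  expect_identical(a1, a2)
  expect_equal(a1$gene_symbol, "GENEA")
  expect_equal(a1$max_af, 0.01)
  expect_equal(a1$consensus_severity, "damaging")
  expect_equal(a1$n_assertions, 1L)
})
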