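# Shared hand-built fixtures and independent oracles.

# A tiny two-chromosome reference with one transcript per chromosome.
# Chromosome 1 ('+' strand): pad(10) utr5(5) cds1(10) intron(20) cds2(14)
# utr3(5) pad(10); CDS = ATG GAG TTT CTG AAA GGG CCC TAA (8 codons).
# Chromosome 2 is the reverse complement, carrying the same gene on '-'.
tiny_cds <- "ATGGAGTTTCTGAAAGGGCCCTAA"

tiny_genome <- local({
  pad <- "ACGTACGTAC"
  utr5 <- "TTTTT"
  intron <- "GTAAGTCCCCCCCCCCCCAG"   # 20 bp with donor GT / acceptor AG
  utr3 <- "AAAAA"
  chr1 <- paste0(pad, utr5, substr(tiny_cds, 1, 10), intron,
                 substr(tiny_cds, 11, 24), utr3, pad)
  chr1
})

make_tiny_reference <- function() {
  chr2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(tiny_genome)))
  Biostrings::DNAStringSet(c("1" = tiny_genome, "2" = chr2))
}

tiny_transcripts <- function() {
  data.frame(
    transcript_id = c("TX1", "TX2"),
    gene_symbol = c("GENEA", "GENEB"),
    chrom = c("1", "2"),
    strand = c("+", "-"),
    exon_starts = c("11,46", "11,50"),
    exon_ends = c("25,64", "29,64"),
    cds_start = c(16L, 16L),
    cds_end = c(59L, 59L),
    stringsAsFactors = FALSE)
}

make_tiny_index <- function() {
  build_transcript_index(load_transcripts(tiny_transcripts()),
                         make_tiny_reference())
}

# minimal VCF text builder
vcf_lines <- function(rows, samples = "S1",
                      header_extra = character()) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    header_extra,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    rows)
}

vcf_row <- function(chrom, pos, ref, alt, gts, qual = "50", info = ".",
                    format = "GT:DP:AD") {
  paste(c(chrom, pos, ".", ref, alt, qual, "PASS", info, format, gts),
        collapse = "\t")
}

# Independent consequence oracle for CDS SNVs: mutate the chromosome string,
# re-extract the CDS by plain substring concatenation and translate both
# alleles with Biostrings, then classify from the amino-acid diff.
oracle_cds_snv <- function(reference, tx_row, pos, alt) {
  chrom_seq <- as.character(reference[[tx_row$chrom]])
  mutated <- chrom_seq
  substr(mutated, pos, pos) <- alt
  starts <- as.integer(strsplit(tx_row$exon_starts, ",")[[1]])
  ends <- as.integer(strsplit(tx_row$exon_ends, ",")[[1]])
  extract_cds <- function(s) {
    paste(vapply(seq_along(starts), function(i) {
      lo <- max(starts[i], tx_row$cds_start)
      hi <- min(ends[i], tx_row$cds_end)
      if (lo <= hi) substr(s, lo, hi) else ""
    }, character(1)), collapse = "")
  }
  to_aa <- function(s) {
    if (tx_row$strand == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(s), no.init.codon = TRUE)), "")[[1]]
  }
  aa0 <- to_aa(extract_cds(chrom_seq))
  aa1 <- to_aa(extract_cds(mutated))
  diff <- which(aa0 != aa1)
  if (length(diff) == 0) return("synonymous")
  i <- diff[1]
  if (aa1[i] == "*") return("stop_gained")
  if (i == 1) return("start_lost")
  "missense"
}

# Independent ACMG combining oracle: explicit rule table evaluated over
# strength counts, with the evidence-level contradiction clause.
oracle_combine <- function(codes) {
  pre <- sub("[0-9]+$", "", codes)
  n <- table(factor(pre, levels = c("PVS", "PS", "PM", "PP", "BA", "BS", "BP")))
  path_evidence <- sum(n[c("PVS", "PS", "PM", "PP")]) > 0
  benign_evidence <- sum(n[c("BA", "BS", "BP")]) > 0
  if (path_evidence && benign_evidence) return("uncertain_significance")
  rules_p <- list(
    function(n) n["PVS"] >= 1 && n["PS"] >= 1,
    function(n) n["PVS"] >= 1 && n["PM"] >= 2,
    function(n) n["PVS"] >= 1 && n["PM"] == 1 && n["PP"] == 1,
    function(n) n["PVS"] >= 1 && n["PP"] >= 2,
    function(n) n["PS"] >= 2,
    function(n) n["PS"] == 1 && n["PM"] >= 3,
    function(n) n["PS"] == 1 && n["PM"] == 2 && n["PP"] >= 2,
    function(n) n["PS"] == 1 && n["PM"] == 1 && n["PP"] >= 4)
  rules_lp <- list(
    function(n) n["PVS"] >= 1 && n["PM"] >= 1,
    function(n) n["PS"] == 1 && n["PM"] >= 1 && n["PM"] <= 2,
    function(n) n["PS"] == 1 && n["PP"] >= 2,
    function(n) n["PM"] >= 3,
    function(n) n["PM"] == 2 && n["PP"] >= 2,
    function(n) n["PM"] == 1 && n["PP"] >= 4)
  if (any(vapply(rules_p, function(f) f(n), logical(1)))) return("pathogenic")
  if (any(vapply(rules_lp, function(f) f(n), logical(1)))) {
    return("likely_pathogenic")
  }
  if (n["BA"] >= 1 || n["BS"] >= 2) return("benign")
  if ((n["BS"] == 1 && n["BP"] >= 1) || n["BP"] >= 2) return("likely_benign")
  "uncertain_significance"
}

acmg_code_set <- c("PVS1", "PS1", "PM2", "PM4", "PM5", "PP3", "PP5",
                   "BA1", "BS1", "BP4", "BP6", "BP7")

# minimal annotated-variant rows for genetic-model tests
model_av_row <- function(key, gene, zyg, max_af = 0, tier = "HIGH",
                         zyg_mother = NA, zyg_father = NA, score = 0,
                         reliable = TRUE, acmg = "uncertain_significance") {
  data.frame(uid = NA_integer_, key = key, gene_symbol = gene,
             zyg_proband = zyg, zyg_mother = zyg_mother,
             zyg_father = zyg_father, depth_mother = 30, depth_father = 30,
             reliability_pass = reliable, max_af = max_af,
             severity_tier = tier, phenotype_score = score,
             acmg_class = acmg, stringsAsFactors = FALSE)
}

# compound-het trio oracle: exhaustive pair enumeration over parental
# genotype configurations
oracle_compound_het <- function(zyg_mother, zyg_father) {
  carries <- function(z) z %in% c("HET", "HOM_ALT")
  homref <- function(z) z == "HOM_REF"
  n <- length(zyg_mother)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      mat_only_i <- carries(zyg_mother[i]) && homref(zyg_father[i])
      pat_only_j <- carries(zyg_father[j]) && homref(zyg_mother[j])
      if (mat_only_i && pat_only_j) return(TRUE)
    }
  }
  FALSE
}

# one shared fixture bundle per seed, built lazily and reused across tests
.fixture_env <- new.env(parent = emptyenv())
shared_bundle <- function(seed = 1) {
  key <- paste0("kb", seed)
  if (is.null(.fixture_env[[key]])) {
    dir <- file.path(tempdir(), sprintf("varitriage_bundle_%d", seed))
    .fixture_env[[key]] <- make_fixture_bundle(dir, sim_config(seed))
  }
  .fixture_env[[key]]
}

shared_case <- function(scenario, seed = 1) {
  kb <- shared_bundle(seed)
  dir <- file.path(tempdir(),
                   sprintf("varitriage_case_%s_%d", scenario, seed))
  if (!file.exists(file.path(dir, "case.vcf"))) {
    simulate_case(kb, scenario, sim_config(seed), dir)
  } else {
    truth <- kb$truths[[scenario]]
    list(vcf = file.path(dir, "case.vcf"),
         ped = file.path(dir, "case.ped"),
         sv = if (scenario == "enhancer_sv") file.path(dir, "svs.tsv") else NULL,
         truth = truth, dir = dir)
  }
}

fixture_scenarios <- c("de_novo_dominant", "recessive_hom", "compound_het",
                       "incidental", "enhancer_sv")

# robust accessors for parsed JSON reports (jsonlite may simplify arrays of
# objects to data.frames)
first_selected <- function(doc, model) {
  s <- doc$sections[[model]]$selected
  if (is.data.frame(s)) {
    row <- s[1, , drop = FALSE]
    out <- as.list(row)
    out$evidence <- row$evidence[[1]]
    out
  } else {
    s[[1]]
  }
}

method_entries <- function(doc) {
  m <- doc$methods
  if (is.data.frame(m)) {
    lapply(seq_len(nrow(m)), function(i) {
      list(model = m$model[i], filters = m$filters[[i]])
    })
  } else {
    m
  }
}

n_selected <- function(doc, model) {
  s <- doc$sections[[model]]$selected
  if (is.data.frame(s)) nrow(s) else length(s)
}
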