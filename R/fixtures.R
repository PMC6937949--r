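# Synthetic fixture generator: toy genome, transcript models, knowledge
# tables, gene documents, regulatory-element map, trio VCFs and SV calls with
# planted causal truths, so that every module and the end-to-end pipeline is
# testable with no external data.

FIXTURE_SCENARIOS <- c("de_novo_dominant", "recessive_hom", "compound_het",
                       "incidental", "enhancer_sv")

# run expr under a temporary RNG state; same seed => identical output bytes
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' @param seed Master seed; the same seed yields byte-identical fixtures.
#' @param n_background_variants Common background variants planted per case.
#' @param trio Generate a proband/mother/father trio (required by the de novo
#'   scenario) rather than a singleton.
#' @param af_shape1,af_shape2 Beta parameters of the background
#'   allele-frequency spectrum (favoring common alleles).
#' @param af_min Floor applied to background frequencies so every background
#'   variant stays separable from planted rare variants by the default 0.1%
#'   frequency cutoff.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_background_variants = 150, trio = TRUE,
                       af_shape1 = 2, af_shape2 = 1, af_min = 0.005) {
  structure(list(seed = seed, n_background_variants = n_background_variants,
                 trio = trio, af_shape1 = af_shape1, af_shape2 = af_shape2,
                 af_min = af_min),
            class = "sim_config")
}

#' Keywords of a planted scenario
#'
#' @param scenario One of the five fixture scenarios.
#' @return Character vector of phenotype keywords.
#' @export
scenario_keywords <- function(scenario) {
  switch(scenario,
    de_novo_dominant = c("seizures", "developmental delay"),
    recessive_hom = c("congenital diarrhea"),
    compound_het = c("retinitis pigmentosa", "night blindness"),
    incidental = c("hearing loss"),
    enhancer_sv = c("microcephaly", "intellectual disability"),
    stopf("unknown scenario '%s'", scenario))
}

scenario_gene <- function(scenario) {
  switch(scenario,
    de_novo_dominant = "TOYG1", recessive_hom = "TOYG3",
    compound_het = "TOYG5", incidental = "TOYG7", enhancer_sv = "TOYG9")
}

scenario_model <- function(scenario) {
  switch(scenario,
    de_novo_dominant = "dominant_het", recessive_hom = "recessive_hom",
    compound_het = "compound_het", incidental = "incidental",
    enhancer_sv = "sv")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_codons <- function(n) {
  all_codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T")), 1, paste,
                      collapse = "")
  sense <- setdiff(all_codons, STOP_CODONS)
  sample(sense, n, replace = TRUE)
}

# one 3-exon gene with a 300-bp CDS (100 codons); codons 40/50/60 forced to
# GAG so variant-planting helpers have a known mutable codon
build_gene <- function(symbol, strand, region_start) {
  codons <- c("ATG", random_codons(98), "TAA")
  codons[c(40, 50, 60)] <- "GAG"
  cds <- paste(codons, collapse = "")
  c1 <- substr(cds, 1, 90); c2 <- substr(cds, 91, 210)
  c3 <- substr(cds, 211, 300)
  sense <- paste0(random_dna(30), c1, random_dna(150), c2, random_dna(150),
                  c3, random_dna(30))
  genomic <- if (strand == "-") revcomp(sense) else sense
  s <- region_start
  list(symbol = symbol, strand = strand, seq = genomic,
       exon_starts = c(s, s + 270L, s + 540L),
       exon_ends = c(s + 119L, s + 389L, s + 659L),
       cds_start = s + 30L, cds_end = s + 629L,
       region = c(s, s + 659L))
}

#' Generate the toy reference genome and transcript models
#'
#' Twelve 3-exon genes with valid ORFs (ATG start, no internal stop, length
#' divisible by 3) on two chromosomes, alternating strands, plus the exome
#' BED covering the gene spans. Writes reference.fasta, transcripts.tsv and
#' regions.bed into `dir`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return list(reference, transcripts, dir), invisibly usable downstream.
#' @export
make_toy_reference_and_transcripts <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(config$seed * 1000L + 1L, {
    spacer <- c("1" = 800L, "2" = 2000L)
    genes <- list()
    chrom_seq <- c("1" = "", "2" = "")
    gi <- 0L
    tx_rows <- list()
    bed_rows <- list()
    for (chrom in c("1", "2")) {
      seq_parts <- character()
      pos <- 1L
      for (k in 1:6) {
        gi <- gi + 1L
        sp <- random_dna(spacer[[chrom]])
        seq_parts <- c(seq_parts, sp)
        pos <- pos + spacer[[chrom]]
        g <- build_gene(sprintf("TOYG%d", gi),
                        if (gi %% 2 == 1) "+" else "-", pos)
        seq_parts <- c(seq_parts, g$seq)
        pos <- pos + nchar(g$seq)
        genes[[g$symbol]] <- c(g, list(chrom = chrom))
        tx_rows[[gi]] <- data.frame(
          transcript_id = paste0(g$symbol, "-T1"), gene_symbol = g$symbol,
          chrom = chrom, strand = g$strand,
          exon_starts = paste(g$exon_starts, collapse = ","),
          exon_ends = paste(g$exon_ends, collapse = ","),
          cds_start = g$cds_start, cds_end = g$cds_end,
          stringsAsFactors = FALSE)
        bed_rows[[gi]] <- data.frame(
          chrom = chrom, start = max(0L, g$region[1] - 201L),
          end = g$region[2] + 200L, stringsAsFactors = FALSE)
      }
      seq_parts <- c(seq_parts, random_dna(spacer[[chrom]]))
      chrom_seq[[chrom]] <- paste(seq_parts, collapse = "")
    }
    ref <- Biostrings::DNAStringSet(chrom_seq)
    Biostrings::writeXStringSet(ref, file.path(dir, "reference.fasta"))
    transcripts <- do.call(rbind, tx_rows)
    write_tsv(transcripts, file.path(dir, "transcripts.tsv"))
    bed <- do.call(rbind, bed_rows)
    utils::write.table(bed, file.path(dir, "regions.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(list(reference = ref, transcripts = transcripts, dir = dir))
  })
}

# genomic SNV mutating CDS codon `codon_index` at in-codon position `within`
# to sense-strand base `alt_sense`, honoring strand
plant_cds_snv <- function(tx, codon_index, within, alt_sense) {
  off <- (codon_index - 1L) * 3L + within
  n <- length(tx$cds_pos)
  off_fwd <- if (tx$strand == "-") n - off + 1L else off
  pos <- tx$cds_pos[off_fwd]
  ref_sense <- substr(tx$cds_seq, off, off)
  if (tx$strand == "-") {
    list(chrom = tx$chrom, pos = pos, ref = comp_base(ref_sense),
         alt = comp_base(alt_sense))
  } else {
    list(chrom = tx$chrom, pos = pos, ref = ref_sense, alt = alt_sense)
  }
}

# the planted variant/event definitions; deterministic given the reference
planted_truths <- function(reference, transcripts) {
  tx_index <- build_transcript_index(transcripts, reference)
  tx_of <- function(gene) tx_index[[paste0(gene, "-T1")]]
  truths <- list()
  # codon 50 is GAG: G>T at base 1 creates TAG (stop); A>C at base 2 creates
  # GCG (missense); codons 40/60 likewise GAG for the compound-het pair
  t1 <- plant_cds_snv(tx_of("TOYG1"), 50, 1, "T")
  truths$de_novo_dominant <- list(
    scenario = "de_novo_dominant", causal_gene = "TOYG1",
    model = "dominant_het", variants = list(t1),
    keywords = scenario_keywords("de_novo_dominant"))
  t3 <- plant_cds_snv(tx_of("TOYG3"), 50, 2, "C")
  truths$recessive_hom <- list(
    scenario = "recessive_hom", causal_gene = "TOYG3",
    model = "recessive_hom", variants = list(t3),
    keywords = scenario_keywords("recessive_hom"))
  t5a <- plant_cds_snv(tx_of("TOYG5"), 40, 1, "T")
  t5b <- plant_cds_snv(tx_of("TOYG5"), 60, 2, "C")
  truths$compound_het <- list(
    scenario = "compound_het", causal_gene = "TOYG5",
    model = "compound_het", variants = list(t5a, t5b),
    keywords = scenario_keywords("compound_het"))
  t7 <- plant_cds_snv(tx_of("TOYG7"), 50, 1, "T")
  truths$incidental <- list(
    scenario = "incidental", causal_gene = "TOYG7", model = "incidental",
    variants = list(t7), keywords = scenario_keywords("incidental"))
  # enhancer in the intergenic spacer downstream of TOYG12, distal target
  # TOYG9 (reduced-distance emulation of a long-range element-gene link)
  tx12 <- tx_of("TOYG12")
  enh_start <- tx12$tx_end + 600L
  truths$enhancer_sv <- list(
    scenario = "enhancer_sv", causal_gene = "TOYG9", model = "sv",
    variants = list(),
    element = list(chrom = "2", start = enh_start, end = enh_start + 199L,
                   element_id = "GH_TOY_001"),
    sv = list(chrom = "2", start = enh_start - 100L, end = enh_start + 299L,
              sv_type = "DEL", copy_number = 1L),
    keywords = scenario_keywords("enhancer_sv"))
  truths
}

doc_row <- function(gene, section, text) {
  data.frame(gene_symbol = gene, section = section, text = text,
             stringsAsFactors = FALSE)
}

causal_doc <- function(gene, keywords, disease) {
  kw <- paste(keywords, collapse = " and ")
  rbind(
    doc_row(gene, "disorders", sprintf(
      "%s is the established disease gene for %s. Affected individuals present with %s; %s in this disorder is typically early-onset. Reported families segregate %s with the phenotype.",
      gene, disease, kw, keywords[1], gene)),
    doc_row(gene, "phenotypes", sprintf(
      "Core phenotype: %s. Additional features accompany %s in most cases.",
      kw, keywords[1])),
    doc_row(gene, "summaries", sprintf(
      "%s encodes a protein whose disruption causes %s.", gene, disease)))
}

background_doc <- function(gene) {
  rbind(
    doc_row(gene, "summaries", sprintf(
      "%s encodes a broadly expressed housekeeping protein.", gene)),
    doc_row(gene, "function", sprintf(
      "%s participates in core cellular metabolism.", gene)))
}

#' Generate the synthetic knowledgebase
#'
#' Writes gene documents (causal genes carry their scenario keywords in the
#' disorders/phenotypes sections; decoy genes carry one partial match in
#' publications), gene-to-gene links, the control frequency table over the
#' background variant sites, clinical assertions, prediction verdicts,
#' per-gene flags, the incidental panel, the regulatory-element map and a
#' version manifest, all into `dir` (which must already hold the reference
#' and transcripts from [make_toy_reference_and_transcripts()]).
#'
#' @param config A [sim_config()].
#' @param dir Fixture directory.
#' @return The loaded knowledgebase ([load_knowledgebase()]), invisibly.
#' @export
make_knowledgebase <- function(config, dir) {
  reference <- read_reference(file.path(dir, "reference.fasta"))
  transcripts <- load_transcripts(file.path(dir, "transcripts.tsv"))
  truths <- planted_truths(reference, transcripts)
  with_seed(config$seed * 1000L + 2L, {
    docs <- rbind(
      causal_doc("TOYG1", scenario_keywords("de_novo_dominant"),
                 "an epileptic encephalopathy"),
      doc_row("TOYG2", "publications",
              "One case report mentions seizures in a carrier of uncertain relevance."),
      causal_doc("TOYG3", scenario_keywords("recessive_hom"),
                 "a syndromic enteropathy"),
      causal_doc("TOYG5", scenario_keywords("compound_het"),
                 "an autosomal recessive retinal dystrophy"),
      doc_row("TOYG6", "publications",
              "Night blindness was noted once in a knockout screen."),
      causal_doc("TOYG7", scenario_keywords("incidental"),
                 "a dominantly inherited deafness"),
      causal_doc("TOYG9", scenario_keywords("enhancer_sv"),
                 "a neurodevelopmental disorder"),
      doc_row("TOYG10", "publications",
              "A single association study listed microcephaly among many traits."),
      background_doc("TOYG4"), background_doc("TOYG8"),
      background_doc("TOYG11"), background_doc("TOYG12"))
    write_tsv(docs, file.path(dir, "gene_docs.tsv"))

    links <- data.frame(
      gene_a = c("TOYG1", "TOYG3"), gene_b = c("TOYG2", "TOYG4"),
      link_type = c("interaction", "shared_pathway"),
      weight = c(0.6, 0.8), stringsAsFactors = FALSE)
    write_tsv(links, file.path(dir, "gene_links.tsv"))

    # background sites inside gene spans, avoiding the planted positions
    gi <- gene_intervals(transcripts)
    planted_pos <- unlist(lapply(truths, function(t) {
      vapply(t$variants, function(v) paste(v$chrom, v$pos), character(1))
    }))
    n <- config$n_background_variants
    rows <- list()
    tries <- 0L
    while (length(rows) < n && tries < n * 20L) {
      tries <- tries + 1L
      g <- gi[sample.int(nrow(gi), 1), ]
      pos <- sample(seq.int(g$start, g$end), 1)
      tag <- paste(g$chrom, pos)
      if (tag %in% planted_pos || tag %in% names(rows)) next
      refb <- ref_seq(reference, g$chrom, pos, pos)
      altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
      af <- max(round(stats::rbeta(1, config$af_shape1, config$af_shape2), 4),
                config$af_min)
      rows[[tag]] <- data.frame(
        chrom = g$chrom, pos = pos, ref = refb, alt = altb,
        kg_like = round(af * stats::runif(1, 0.5, 1), 5),
        esp_like = round(af * stats::runif(1, 0.5, 1), 5),
        gnomad_like = af,
        converge_like = round(af * stats::runif(1, 0.5, 1), 5),
        stringsAsFactors = FALSE)
    }
    freq <- do.call(rbind, rows)
    freq <- freq[order(freq$chrom, freq$pos), ]
    rownames(freq) <- NULL
    write_tsv(freq, file.path(dir, "frequencies.tsv"))

    v7 <- truths$incidental$variants[[1]]
    assertions <- data.frame(
      source = c("clinvar_like", "clinvar_like"),
      chrom = c(v7$chrom, freq$chrom[1]),
      pos = c(v7$pos, freq$pos[1]),
      ref = c(v7$ref, freq$ref[1]),
      alt = c(v7$alt, freq$alt[1]),
      gene_symbol = c("TOYG7", ""),
      aa_change = c("p.E50*", ""),
      condition = c("dominant deafness", "none"),
      significance = c("pathogenic", "benign"),
      stringsAsFactors = FALSE)
    write_tsv(assertions, file.path(dir, "assertions.tsv"))

    v3 <- truths$recessive_hom$variants[[1]]
    v5b <- truths$compound_het$variants[[2]]
    predictions <- data.frame(
      chrom = c(v3$chrom, v5b$chrom, freq$chrom[2]),
      pos = c(v3$pos, v5b$pos, freq$pos[2]),
      ref = c(v3$ref, v5b$ref, freq$ref[2]),
      alt = c(v3$alt, v5b$alt, freq$alt[2]),
      sift_like = c("damaging", "damaging", "tolerated"),
      polyphen_like = c("damaging", "damaging", "tolerated"),
      mutationtaster_like = c("damaging", "damaging", "tolerated"),
      gerp_like = c("damaging", "unknown", "unknown"),
      stringsAsFactors = FALSE)
    write_tsv(predictions, file.path(dir, "predictions.tsv"))

    gene_flags <- data.frame(
      gene_symbol = sprintf("TOYG%d", 1:12), lof_mechanism = 1L,
      disease_af_cutoff = 0.001, stringsAsFactors = FALSE)
    write_tsv(gene_flags, file.path(dir, "gene_flags.tsv"))
    writeLines(c("TOYG7", "TOYG11", "TOYG12"), file.path(dir, "panel.txt"))

    e <- truths$enhancer_sv$element
    tx2 <- transcripts[transcripts$gene_symbol == "TOYG2", ]
    elements <- data.frame(
      chrom = c(e$chrom, tx2$chrom),
      start = c(e$start, tx2$cds_start + 200L),
      end = c(e$end, tx2$cds_start + 350L),
      element_id = c(e$element_id, "GH_TOY_002"),
      element_confidence = c(0.8, 0.5),
      targets = c("TOYG9:0.7;TOYG12:0.9", "TOYG2:0.5"),
      stringsAsFactors = FALSE)
    write_tsv(elements, file.path(dir, "elements.tsv"))

    tables <- c(gene_docs = "gene_docs.tsv", gene_links = "gene_links.tsv",
                frequencies = "frequencies.tsv",
                assertions = "assertions.tsv",
                predictions = "predictions.tsv",
                gene_flags = "gene_flags.tsv", elements = "elements.tsv",
                transcripts = "transcripts.tsv")
    manifest <- data.frame(
      name = names(tables), file = unname(tables), version = "2026.1",
      checksum = unname(tools::md5sum(file.path(dir, tables))),
      stringsAsFactors = FALSE)
    write_tsv(manifest, file.path(dir, "manifest.tsv"))
  })
  invisible(load_knowledgebase(dir))
}

#' Load a fixture knowledgebase directory
#'
#' @param dir Directory produced by the fixture generators.
#' @return A list with reference, transcripts, tx_index, regions, gene_docs,
#'   links, frequencies, assertions, predictions, gene_flags, gene_panel,
#'   elements, manifest and the planted truths.
#' @export
load_knowledgebase <- function(dir) {
  reference <- read_reference(file.path(dir, "reference.fasta"))
  transcripts <- load_transcripts(file.path(dir, "transcripts.tsv"))
  kb <- list(
    dir = dir,
    reference = reference,
    transcripts = transcripts,
    tx_index = build_transcript_index(transcripts, reference),
    regions = region_set(file.path(dir, "regions.bed"), label = "Exome"),
    gene_docs = load_gene_docs(file.path(dir, "gene_docs.tsv")),
    links = load_gene_links(file.path(dir, "gene_links.tsv")),
    frequencies = load_frequency_table(file.path(dir, "frequencies.tsv")),
    assertions = load_assertions(file.path(dir, "assertions.tsv")),
    predictions = load_predictions(file.path(dir, "predictions.tsv")),
    gene_flags = load_gene_flags(file.path(dir, "gene_flags.tsv")),
    gene_panel = readLines(file.path(dir, "panel.txt"), warn = FALSE),
    elements = load_elements(file.path(dir, "elements.tsv")),
    manifest = read_tsv_strict(file.path(dir, "manifest.tsv"),
                               c("name", "version", "checksum"))
  )
  kb$truths <- planted_truths(reference, transcripts)
  kb
}

vcf_header_lines <- function(reference, samples) {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(reference),
            Biostrings::width(reference)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

gt_cell <- function(n_alt, dp, hemi = FALSE) {
  gt <- if (hemi) c("0", "1")[n_alt + 1L] else
    c("0/0", "0/1", "1/1")[n_alt + 1L]
  frac <- if (hemi) n_alt else n_alt / 2
  alt_reads <- round(dp * frac)
  sprintf("%s:%d:%d,%d", gt, dp, dp - alt_reads, alt_reads)
}

#' Simulate a case around a planted truth
#'
#' Draws Mendelian-consistent trio (or singleton) genotypes at the common
#' background sites of the knowledgebase, injects the scenario's causal
#' variants with their prescribed genotype pattern (e.g. de novo: proband HET
#' with homozygous-reference parents; compound het: one maternally- and one
#' paternally-transmitted HET), and writes the VCF, the PED file, the SV call
#' table (enhancer scenario) and an expected-answer sheet into `dir`.
#'
#' @param kb A loaded knowledgebase.
#' @param scenario One of the five scenarios.
#' @param config A [sim_config()]; de novo and compound het require
#'   `trio = TRUE`.
#' @param dir Output directory.
#' @return list(vcf, ped, sv, answer, truth) with file paths and the truth.
#' @export
simulate_case <- function(kb, scenario = FIXTURE_SCENARIOS, config = sim_config(),
                          dir = tempfile("case")) {
  scenario <- match.arg(scenario)
  if (!config$trio && scenario %in% c("de_novo_dominant", "compound_het")) {
    stopf("scenario '%s' requires a trio configuration", scenario)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- kb$truths[[scenario]]
  samples <- if (config$trio) c("PROBAND", "MOTHER", "FATHER") else "PROBAND"
  freq <- kb$frequencies
  with_seed(config$seed * 1000L + 3L + match(scenario, FIXTURE_SCENARIOS), {
    lines <- character()
    for (j in seq_len(nrow(freq))) {
      af <- freq$gnomad_like[j]
      mo <- sum(stats::runif(2) < af)
      fa <- sum(stats::runif(2) < af)
      pr <- (if (mo == 2) 1L else if (mo == 1) sample(0:1, 1) else 0L) +
            (if (fa == 2) 1L else if (fa == 1) sample(0:1, 1) else 0L)
      counts <- if (config$trio) c(pr, mo, fa) else pr
      if (all(counts == 0)) next
      dp <- stats::rpois(length(counts), 35) + 5L
      cells <- mapply(gt_cell, counts, dp)
      lines <- c(lines, paste(c(
        freq$chrom[j], freq$pos[j], ".", freq$ref[j], freq$alt[j],
        sprintf("%.1f", stats::runif(1, 40, 90)), "PASS", ".",
        "GT:DP:AD", cells), collapse = "\t"))
    }
    planted_counts <- switch(scenario,
      de_novo_dominant = list(c(1L, 0L, 0L)),
      recessive_hom = list(c(2L, 1L, 1L)),
      compound_het = list(c(1L, 1L, 0L), c(1L, 0L, 1L)),
      incidental = list(c(1L, 1L, 0L)),
      enhancer_sv = list())
    for (k in seq_along(truth$variants)) {
      v <- truth$variants[[k]]
      counts <- planted_counts[[k]]
      if (!config$trio) counts <- counts[1]
      cells <- vapply(counts, gt_cell, character(1), dp = 40L)
      lines <- c(lines, paste(c(
        v$chrom, v$pos, ".", v$ref, v$alt, "85.0", "PASS", ".",
        "GT:DP:AD", cells), collapse = "\t"))
    }
    ord <- order(vapply(strsplit(lines, "\t"), `[[`, character(1), 1),
                 as.integer(vapply(strsplit(lines, "\t"), `[[`,
                                   character(1), 2)))
    vcf_path <- file.path(dir, "case.vcf")
    writeLines(c(vcf_header_lines(kb$reference, samples), lines[ord]),
               vcf_path)

    ped_path <- NULL
    if (config$trio) {
      ped_path <- file.path(dir, "case.ped")
      writeLines(c("FAM1\tPROBAND\tFATHER\tMOTHER\t1\t2",
                   "FAM1\tFATHER\t0\t0\t1\t1",
                   "FAM1\tMOTHER\t0\t0\t2\t1"), ped_path)
    }

    sv_path <- NULL
    if (scenario == "enhancer_sv") {
      sv_path <- file.path(dir, "svs.tsv")
      tx4 <- kb$transcripts[kb$transcripts$gene_symbol == "TOYG4", ]
      sv <- truth$sv
      svs <- data.frame(
        chrom = c(sv$chrom, tx4$chrom, "1"),
        start = c(sv$start, tx4$cds_start, 10L),
        end = c(sv$end, tx4$cds_start + 4000L, 500L),
        sv_type = c(sv$sv_type, "DUP", "DEL"),
        copy_number = c(sv$copy_number, 3L, 1L), stringsAsFactors = FALSE)
      write_tsv(svs, sv_path)
    }

    keys <- vapply(truth$variants, function(v) {
      variant_key(v$chrom, v$pos, v$ref, v$alt)
    }, character(1))
    answer_path <- file.path(dir, "expected_answer.tsv")
    write_tsv(data.frame(
      scenario = scenario, causal_gene = truth$causal_gene,
      model = truth$model, variant_keys = paste(keys, collapse = ","),
      sv_span = if (is.null(truth$sv)) "" else
        sprintf("%s:%d-%d", truth$sv$chrom, truth$sv$start, truth$sv$end),
      stringsAsFactors = FALSE), answer_path)

    list(vcf = vcf_path, ped = ped_path, sv = sv_path, answer = answer_path,
         truth = truth, dir = dir)
  })
}

#' Build a complete fixture bundle
#'
#' Reference + transcripts + knowledgebase in one directory; convenience
#' entry point for tests and the command line.
#'
#' @param dir Output directory.
#' @param config A [sim_config()].
#' @return The loaded knowledgebase.
#' @export
make_fixture_bundle <- function(dir, config = sim_config()) {
  make_toy_reference_and_transcripts(config, dir)
  make_knowledgebase(config, dir)
  load_knowledgebase(dir)
}

#' Phenotype classes of the large-account fixture
#'
#' The four keyword-defined phenotype classes used for account resolution
#' statistics: growth retardation, developmental delay, epilepsy and
#' genitalia symptoms, each with its common associated keywords.
#'
#' @return Named list: class name -> character vector of keywords.
#' @export
account_phenotype_classes <- function() {
  list(
    "Growth Retardation" = c("Short stature"),
    "Developmental Delay" = c("Mental retardation", "Delayed speech",
                              "Motor delay"),
    "Epilepsy" = c("Seizures", "Convulsion", "Spasm"),
    "Genitalia symptoms" = c("Scrotum", "Micropenis", "Hypogonadism",
                             "Hypospadia"))
}

#' Per-class case counts of the large-account fixture
#'
#' Total and resolved case counts per phenotype class for the emulated
#' large hospital account.
#'
#' @return data.frame: class, total, resolved.
#' @export
account_class_counts <- function() {
  data.frame(
    class = c("Growth Retardation", "Developmental Delay", "Epilepsy",
              "Genitalia symptoms"),
    total = c(107L, 174L, 191L, 131L),
    resolved = c(66L, 101L, 121L, 30L),
    stringsAsFactors = FALSE)
}

#' Build the large-account fixture store
#'
#' Deterministically generates a case store whose per-class totals and
#' resolved counts match the given summary: each case carries one keyword of
#' its class (cycling through the class keywords) and resolved cases carry
#' one High- or Med-marked selected variant.
#'
#' @param counts data.frame as [account_class_counts()].
#' @param classes Class definitions as [account_phenotype_classes()].
#' @return A `case_store`.
#' @export
make_account_store <- function(counts = account_class_counts(),
                               classes = account_phenotype_classes()) {
  store <- case_store()
  for (i in seq_len(nrow(counts))) {
    cls <- counts$class[i]
    kws <- classes[[cls]]
    for (k in seq_len(counts$total[i])) {
      resolved <- k <= counts$resolved[i]
      sel <- if (resolved) {
        data.frame(variant_key = sprintf("1:%d:A:G", 1000L + k),
                   gene_symbol = "TOYG1",
                   relevance = if (k %% 2 == 0) "Med" else "High",
                   pathogenicity = "likely_pathogenic", note = "",
                   stringsAsFactors = FALSE)
      } else NULL
      store <- store_add_case(store, case_record(
        case_id = sprintf("GX-%d-%03d", i, k),
        keywords = kws[(k - 1L) %% length(kws) + 1L],
        date = sprintf("2018-%02d-%02d", (k - 1L) %% 12 + 1L,
                       (k - 1L) %% 28 + 1L),
        selections = sel))
    }
  }
  store
}
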