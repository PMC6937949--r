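# Keyword search, direct/indirect scoring, minicards, gene ranking.

demo_doc <- data.frame(
  gene_symbol = "GENEA",
  section = c("disorders", "publications", "summaries"),
  text = c("Chronic diarrhea with onset in infancy; diarrhea persists.",
           "One report of watery diarrhea after weaning.",
           "GENEA encodes a transporter."),
  stringsAsFactors = FALSE)

test_that("search counts per-section whole-word hits case-insensitively", {
  q <- keyword_query("diarrhea")
  sr <- search_gene(demo_doc, q)
  expect_equal(sr$counts[["disorders"]], 2L)
  expect_equal(sr$counts[["publications"]], 1L)
  expect_equal(sr$matched_terms, "diarrhea")
  # case-insensitive
  sr2 <- search_gene(demo_doc, keyword_query("DIARRHEA"))
  expect_equal(sum(sr2$counts), 3L)
  # whole-word: no hit inside a longer word
  sr3 <- search_gene(demo_doc, keyword_query("iarrhe"))
  expect_equal(length(sr3$matched_terms), 0)
  expect_error(keyword_query(character()), "at least one")
})

test_that("search agrees with a naive boundary-checked substring scan", {
  naive_count <- function(text, term) {
    text <- tolower(text); term <- tolower(term)
    n <- 0L
    k <- nchar(term)
    for (i in seq_len(max(0, nchar(text) - k + 1))) {
      if (substr(text, i, i + k - 1) != term) next
      before <- if (i == 1) "" else substr(text, i - 1, i - 1)
      after <- substr(text, i + k, i + k)
      if (!grepl("[a-z0-9]", before) && !grepl("[a-z0-9]", after)) n <- n + 1L
    }
    n
  }
  set.seed(13)
  words <- c("ataxia", "seizures", "tremor", "gait", "and", "with")
  for (rep in 1:20) {
    text <- paste(sample(words, 30, replace = TRUE), collapse = " ")
    doc <- data.frame(gene_symbol = "G", section = "disorders", text = text,
                      stringsAsFactors = FALSE)
    term <- sample(words[1:4], 1)
    sr <- search_gene(doc, keyword_query(term))
    expect_equal(sum(sr$counts), naive_count(text, term))
  }
})

test_that("AND queries require every term; OR queries any", {
  q_and <- keyword_query(c("diarrhea", "unicorn"), operator = "AND")
  expect_equal(sum(search_gene(demo_doc, q_and)$counts), 0L)
  q_or <- keyword_query(c("diarrhea", "unicorn"), operator = "OR")
  expect_equal(sum(search_gene(demo_doc, q_or)$counts), 3L)
})

test_that("the direct score follows the weighted log-saturation formula", {
  expect_equal(score_direct(integer(), n_matched = 0, n_terms = 1), 0)
  expect_equal(score_direct(c(disorders = 1L), c(disorders = 3.0), 1, 1), 3.0)
  expect_equal(
    score_direct(c(disorders = 3L, publications = 1L),
                 c(disorders = 3.0, publications = 1.0), 1, 2),
    (3 * log2(4) + 1 * log2(2)) / 2)
})

test_that("doubling every hit count strictly increases the direct score", {
  set.seed(17)
  w <- default_section_weights()
  for (rep in 1:100) {
    counts <- sample(1:10, 3)
    names(counts) <- sample(names(w), 3)
    s1 <- score_direct(counts, w, 1, 1)
    s2 <- score_direct(counts * 2L, w, 1, 1)
    expect_gt(s2, s1)
  }
})

test_that("indirect scoring takes the best damped neighbor contribution", {
  links <- load_gene_links(data.frame(
    gene_a = "A", gene_b = "B", link_type = "interaction", weight = 0.8))
  expect_equal(score_indirect("Z", links, c(A = 10, B = 0))$score, 0)
  got <- score_indirect("A", links, c(A = 0, B = 10))
  expect_equal(got$score, 0.8 * 0.5 * 10)
  expect_equal(got$via_gene, "B")
})

test_that("indirect scores equal a brute-force neighbor scan on random graphs", {
  set.seed(19)
  for (rep in 1:30) {
    genes <- paste0("G", 1:8)
    n_links <- sample(3:10, 1)
    pairs <- t(replicate(n_links, sample(genes, 2)))
    links <- data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2],
                        link_type = "interaction",
                        weight = round(runif(n_links, 0.1, 1), 3),
                        stringsAsFactors = FALSE)
    direct <- stats::setNames(round(runif(8, 0, 10), 2), genes)
    for (g in genes) {
      got <- score_indirect(g, links, direct)
      best <- 0
      for (k in seq_len(n_links)) {
        if (links$gene_a[k] == g) {
          best <- max(best, links$weight[k] * 0.5 * direct[links$gene_b[k]])
        }
        if (links$gene_b[k] == g) {
          best <- max(best, links$weight[k] * 0.5 * direct[links$gene_a[k]])
        }
      }
      expect_equal(got$score, unname(best))
    }
  }
})

test_that("a gene scores zero iff it has no hit and no scoring neighbor", {
  docs <- rbind(demo_doc, data.frame(
    gene_symbol = "GENEB", section = "summaries",
    text = "GENEB does something else.", stringsAsFactors = FALSE),
    data.frame(gene_symbol = "GENEC", section = "summaries",
               text = "GENEC is unrelated.", stringsAsFactors = FALSE))
  links <- load_gene_links(data.frame(
    gene_a = "GENEB", gene_b = "GENEA", link_type = "shared_pathway",
    weight = 0.9))
  sc <- score_phenotypes(docs, links, keyword_query("diarrhea"))
  tot <- stats::setNames(sc$total, sc$gene_symbol)
  expect_gt(tot[["GENEA"]], 0)    # direct hits
  expect_gt(tot[["GENEB"]], 0)    # linked to a scoring gene
  expect_equal(tot[["GENEC"]], 0) # no hit, no scoring neighbor
  expect_equal(sc$mode[sc$gene_symbol == "GENEB"], "indirect")
  expect_equal(sc$via_gene[sc$gene_symbol == "GENEB"], "GENEA")
})

test_that("adding an OR term never decreases any gene's direct score", {
  docs <- rbind(demo_doc, data.frame(
    gene_symbol = "GENEB", section = "disorders",
    text = "Seizures with fever.", stringsAsFactors = FALSE))
  s1 <- score_phenotypes(docs, NULL, keyword_query("diarrhea"))
  s2 <- score_phenotypes(docs, NULL, keyword_query(c("diarrhea", "seizures")))
  for (g in s1$gene_symbol) {
    d1 <- s1$direct_score[s1$gene_symbol == g] * 1        # 1 term
    d2 <- s2$direct_score[s2$gene_symbol == g] * 2        # 2 terms, unscale
    expect_gte(d2 + 1e-12, d1)
  }
})

test_that("minicard snippets are verbatim substrings with intact markers", {
  q <- keyword_query("diarrhea")
  cards <- build_minicard(demo_doc, q, window = 15)
  expect_gt(nrow(cards), 0)
  for (k in seq_len(nrow(cards))) {
    stripped <- gsub("\\[\\[|\\]\\]", "", cards$snippet[k])
    sect <- demo_doc$text[demo_doc$section == cards$section[k]]
    expect_true(grepl(stripped, sect, fixed = TRUE))
    inner <- sub(".*\\[\\[(.*)\\]\\].*", "\\1", cards$snippet[k])
    expect_equal(tolower(inner), "diarrhea")
  }
  # hit at text start: left window clipped, markers intact
  doc0 <- data.frame(gene_symbol = "G", section = "disorders",
                     text = "diarrhea from day one", stringsAsFactors = FALSE)
  c0 <- build_minicard(doc0, q, window = 50)
  expect_equal(c0$snippet, "[[diarrhea]] from day one")
  # cap keeps the first hit by position
  c1 <- build_minicard(demo_doc, q, window = 50, cap = 1)
  expect_equal(sum(c1$section == "disorders"), 1L)
  expect_match(c1$snippet[c1$section == "disorders"], "^Chronic \\[\\[diarrhea\\]\\]")
})

test_that("gene ranking is deterministic with documented tie-breaks", {
  sc <- data.frame(
    gene_symbol = c("B", "A", "C", "D"),
    total = c(5.2, 0, 7.1, 5.2),
    matched_count = c(1L, 0L, 2L, 2L), stringsAsFactors = FALSE)
  r <- rank_genes(sc)
  expect_equal(r$gene_symbol, c("C", "D", "B", "A"))
  set.seed(3)
  for (rep in 1:10) {
    expect_equal(rank_genes(sc[sample(nrow(sc)), ]), r)
  }
})
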