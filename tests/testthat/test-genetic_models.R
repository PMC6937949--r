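# Filter cascades, reliability gates, inheritance models, incidental panel.

test_that("reliability passes only when all thresholds clear", {
  expect_true(reliability_filter(50, 30, 0.48)$pass)
  expect_false(reliability_filter(50, 5, 0.48)$pass)
  got <- reliability_filter(50, NA, 0.48)
  expect_false(got$pass)
  expect_equal(got$reason, "missing_metrics")
})

test_that("reliability equals the brute-force threshold conjunction", {
  set.seed(23)
  th <- list(min_qual = 20, min_depth = 8, min_alt_fraction = 0.2)
  qual <- sample(c(NA, 0, 10, 19, 20, 21, 90), 200, replace = TRUE)
  depth <- sample(c(NA, 0, 7, 8, 9, 40), 200, replace = TRUE)
  af <- sample(c(NA, 0, 0.1, 0.19, 0.2, 0.21, 1), 200, replace = TRUE)
  got <- reliability_filter(qual, depth, af, th)$pass
  for (i in 1:200) {
    want <- !is.na(qual[i]) && !is.na(depth[i]) && !is.na(af[i]) &&
      qual[i] >= 20 && depth[i] >= 8 && af[i] >= 0.2
    expect_equal(got[i], want)
  }
})

test_that("the worked two-step cascade counts survivors as logged", {
  av <- do.call(rbind, c(
    lapply(1:3, function(i) model_av_row(paste0("k", i), "G1", "HET",
                                         max_af = 0)),
    list(model_av_row("k4", "G1", "HET", max_af = 0.2)),
    lapply(5:10, function(i) model_av_row(paste0("k", i), "G2", "HOM_ALT",
                                          max_af = 0))))
  cascade <- list(
    list(name = "het_only", column = "zyg_proband", op = "==", value = "HET"),
    list(name = "rare", column = "max_af", op = "<", value = 0.001))
  res <- apply_cascade(av, cascade)
  expect_equal(nrow(res$variants), 3)
  expect_equal(res$log$n_in, c(10L, 4L))
  expect_equal(res$log$n_out, c(4L, 3L))
})

test_that("an empty cascade is the identity and step counts telescope", {
  av <- do.call(rbind, lapply(1:6, function(i) {
    model_av_row(paste0("k", i), "G1", sample(c("HET", "HOM_ALT"), 1),
                 max_af = runif(1, 0, 0.01))
  }))
  expect_identical(apply_cascade(av, list())$variants, av)
  set.seed(29)
  for (rep in 1:10) {
    cascade <- list(
      list(name = "a", column = "max_af", op = "<", value = runif(1, 0, 0.01)),
      list(name = "b", column = "zyg_proband", op = "==", value = "HET"),
      list(name = "c", column = "max_af", op = ">=", value = 0))
    lg <- apply_cascade(av, cascade)$log
    expect_equal(lg$n_in[-1], lg$n_out[-length(lg$n_out)])
    expect_true(all(diff(c(lg$n_in[1], lg$n_out)) <= 0))
  }
  expect_error(apply_cascade(av, list(list(name = "x", column = "nope",
                                           op = "==", value = 1))),
               "missing column")
})

trio_protocol <- default_protocol(analysis_type = "trio-exome",
                                  keywords = "x", af_cutoff = 0.001)
trio <- list(proband_id = "P", mother_id = "M", father_id = "F",
             affected = TRUE)

test_that("the dominant model applies the four default filters", {
  av <- rbind(
    model_av_row("k1", "G1", "HET", max_af = 0, tier = "HIGH",
                 zyg_mother = "HOM_REF", zyg_father = "HOM_REF"),
    model_av_row("k2", "G1", "HET", max_af = 0.002, tier = "HIGH",
                 zyg_mother = "HET", zyg_father = "HOM_REF"),
    model_av_row("k3", "G2", "HOM_ALT", max_af = 0, tier = "HIGH"),
    model_av_row("k4", "G2", "HET", max_af = 0, tier = "LOW"),
    model_av_row("k5", "G3", "HET", max_af = 0, tier = "MODERATE",
                 reliable = FALSE))
  res <- model_dominant_het(av, trio_protocol, trio)
  expect_equal(res$candidates$key, "k1")
  expect_equal(res$candidates$de_novo, "de_novo")
  expect_equal(res$log$n_out, c(4L, 3L, 2L, 1L))
})

test_that("de novo status needs adequate parental depth", {
  av <- model_av_row("k1", "G1", "HET", zyg_mother = "HOM_REF",
                     zyg_father = "HOM_REF")
  av$depth_mother <- 5
  res <- model_dominant_het(av, trio_protocol, trio)
  expect_equal(res$candidates$de_novo, "de_novo_unconfirmed")
})

test_that("the recessive model flags Mendelian-inconsistent trios", {
  av <- rbind(
    model_av_row("k1", "G1", "HOM_ALT", zyg_mother = "HET",
                 zyg_father = "HET"),
    model_av_row("k2", "G2", "HOM_ALT", zyg_mother = "HET",
                 zyg_father = "HOM_REF"),
    model_av_row("k3", "G3", "HET"))
  res <- model_recessive_hom(av, trio_protocol, trio)
  expect_setequal(res$candidates$key, c("k1", "k2"))
  expect_equal(
    res$candidates$trio_consistency[res$candidates$key == "k1"],
    "consistent")
  expect_equal(
    res$candidates$trio_consistency[res$candidates$key == "k2"],
    "mendelian_inconsistent")
})

test_that("compound-het needs one maternal-only and one paternal-only HET", {
  av <- rbind(
    model_av_row("k1", "G1", "HET", zyg_mother = "HET",
                 zyg_father = "HOM_REF"),
    model_av_row("k2", "G1", "HET", zyg_mother = "HOM_REF",
                 zyg_father = "HET"),
    model_av_row("k3", "G2", "HET", zyg_mother = "HET",
                 zyg_father = "HOM_REF"),
    model_av_row("k4", "G2", "HET", zyg_mother = "HET",
                 zyg_father = "HOM_REF"),
    model_av_row("k5", "G3", "HET", zyg_mother = "HET",
                 zyg_father = "HOM_REF"))
  res <- model_compound_het(av, trio_protocol, trio)
  expect_equal(res$groups$gene_symbol, "G1")
  expect_equal(res$groups$status, "in_trans")
  expect_setequal(res$candidates$key, c("k1", "k2"))
})

test_that("singleton compound-het groups are flagged phase_unknown", {
  av <- rbind(model_av_row("k1", "G1", "HET"),
              model_av_row("k2", "G1", "HET"))
  res <- model_compound_het(av, trio_protocol, pedigree = NULL)
  expect_equal(res$groups$status, "phase_unknown")
})

test_that("trio compound-het agrees with the exhaustive pair oracle", {
  set.seed(37)
  zygs <- c("HOM_REF", "HET", "HOM_ALT")
  for (rep in 1:60) {
    n <- sample(2:4, 1)
    zm <- sample(zygs, n, replace = TRUE)
    zf <- sample(zygs, n, replace = TRUE)
    av <- do.call(rbind, lapply(seq_len(n), function(i) {
      model_av_row(paste0("k", i), "G1", "HET", zyg_mother = zm[i],
                   zyg_father = zf[i])
    }))
    res <- model_compound_het(av, trio_protocol, trio)
    want <- oracle_compound_het(zm, zf)
    expect_equal(nrow(res$groups) == 1 &&
                   res$groups$status[1] == "in_trans", want)
  }
})

test_that("incidental findings gate on panel membership and ACMG class", {
  av <- rbind(
    model_av_row("k1", "PANEL1", "HET", acmg = "likely_pathogenic"),
    model_av_row("k2", "PANEL1", "HET", acmg = "uncertain_significance"),
    model_av_row("k3", "OTHER", "HET", acmg = "pathogenic"))
  res <- incidental_findings(av, c("PANEL1", "PANEL2"))
  expect_equal(res$candidates$key, "k1")
  expect_warning(incidental_findings(av, character()), "empty")
})

test_that("model outputs are subsets of their input sorted by phenotype score", {
  av <- rbind(
    model_av_row("k1", "G1", "HET", score = 2),
    model_av_row("k2", "G2", "HET", score = 9),
    model_av_row("k3", "G3", "HET", score = 5))
  res <- model_dominant_het(av, trio_protocol, NULL)
  expect_equal(res$candidates$key, c("k2", "k3", "k1"))
  expect_true(all(res$candidates$key %in% av$key))
})
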