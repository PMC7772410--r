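mk_ev <- function(label, channel, evalue = 1e-10, tag = "p1",
                  identifier = "SYN00001") {
  n <- max(length(label), length(channel), length(evalue))
  data.frame(locus_tag = rep_len(tag, n),
             channel = rep_len(channel, n),
             function_label = rep_len(label, n),
             identifier = rep_len(identifier, n),
             evalue = rep_len(evalue, n),
             source = "test", stringsAsFactors = FALSE)
}

test_that("evidence filter applies the inclusive 1e-5 cutoff and DUF removal", {
  ev <- mk_ev(c("kinase", "kinase", "kinase", "DUF1234 family protein"),
              "domain", evalue = c(1e-6, 1e-4, 1e-5, 1e-12))
  out <- filter_evidence(ev)
  expect_equal(out$evalue, c(1e-6, 1e-5))  # 1e-4 dropped, boundary kept
  # DUF matched in identifier as well as in the label
  ev2 <- mk_ev("uncharacterized domain", "motif", identifier = "DUF0042")
  expect_equal(nrow(filter_evidence(ev2)), 0L)
  expect_equal(nrow(filter_evidence(ev2, drop_duf = FALSE)), 1L)
  # DUF as substring of a longer token does not match
  ev3 <- mk_ev("induftrial protein", "motif")
  expect_equal(nrow(filter_evidence(ev3)), 1L)
})

test_that("label normalization casefolds, strips punctuation, sorts tokens", {
  expect_equal(normalize_label("AAA+ ATPase"), normalize_label("aaa ATPase"))
  expect_equal(normalize_label("cell division inhibitor"),
               normalize_label("inhibitor, cell division"))
  expect_equal(normalize_label("!!!"), "unassigned")
  syn <- data.frame(variant = "methionine—tRNA ligase",
                    canonical = "methionyl-tRNA synthetase")
  expect_equal(normalize_label("Methionine—tRNA Ligase", syn),
               normalize_label("methionyl-tRNA synthetase"))
})

test_that("agreement score counts distinct channels with tie-breaks", {
  # same label from all six channels scores the maximum 6
  ev <- mk_ev("SepF cell division protein",
              c("motif", "domain", "structure", "evolutionary",
                "physchem", "localization"))
  res <- prediction_agreement_score(ev)
  expect_equal(res$score, 6L)
  # no evidence
  expect_equal(prediction_agreement_score(ev[0, ]),
               list(label = "unassigned", score = 0L))
  # 3 channels vs 1 channel
  ev <- rbind(mk_ev("label A", c("motif", "domain", "structure")),
              mk_ev("label B", "evolutionary"))
  res <- prediction_agreement_score(ev)
  expect_equal(res$label, normalize_label("label A"))
  expect_equal(res$score, 3L)
  # duplicate hits within one channel count once
  ev <- mk_ev("label A", c("motif", "motif", "motif"))
  expect_equal(prediction_agreement_score(ev)$score, 1L)
  # count tie broken by lowest best e-value
  ev <- rbind(mk_ev("zeta", c("motif", "domain"), evalue = 1e-20),
              mk_ev("alpha", c("structure", "evolutionary"), evalue = 1e-10))
  expect_equal(prediction_agreement_score(ev)$label, "zeta")
  # full tie broken lexicographically
  ev <- rbind(mk_ev("zeta", "motif", evalue = 1e-10),
              mk_ev("alpha", "domain", evalue = 1e-10))
  expect_equal(prediction_agreement_score(ev)$label, "alpha")
})

test_that("literature component is the maximum matching provenance level", {
  lab <- normalize_label("cell division inhibitor")
  lit <- data.frame(locus_tag = "p1",
                    function_label = c("Cell division inhibitor",
                                       "cell division inhibitor",
                                       "unrelated function"),
                    provenance_level = c(2L, 4L, 6L),
                    reference = "r", stringsAsFactors = FALSE)
  expect_equal(literature_score(lit, lab), 4L)
  expect_equal(literature_score(lit[3, ], lab), 0L)
  expect_equal(literature_score(NULL, lab), 0L)
  # same-organism provenance scores the maximum 6
  lit6 <- data.frame(locus_tag = "p1", function_label = "cell division inhibitor",
                     provenance_level = 6L, reference = "r")
  expect_equal(literature_score(lit6, lab), 6L)
})

test_that("combined confidence adds components and applies the <3 rejection", {
  expect_equal(combined_confidence(6, 6)$combined, 12L)
  expect_true(combined_confidence(6, 6)$retained)
  expect_false(combined_confidence(2, 6)$retained)
  expect_false(combined_confidence(6, 2)$retained)
  r33 <- combined_confidence(3, 3)
  expect_equal(r33$combined, 6L)
  expect_true(r33$retained)
  expect_error(combined_confidence(7, 0), "0..6")
  expect_error(combined_confidence(0, -1), "0..6")
})

test_that("combined confidence is monotone: raising a component never hurts", {
  grid <- expand.grid(p = 0:6, l = 0:6)
  cc <- combined_confidence(grid$p, grid$l)
  for (i in seq_len(nrow(grid))) {
    if (grid$p[i] < 6) {
      j <- which(grid$p == grid$p[i] + 1 & grid$l == grid$l[i])
      expect_gte(cc$combined[j], cc$combined[i])
      expect_true(!cc$retained[i] || cc$retained[j])
    }
  }
})

test_that("noisy-OR combination matches closed forms and inclusion-exclusion", {
  expect_equal(sifter_combine(c(0.5, 0.5)), 0.75)
  expect_equal(sifter_combine(c(1.0, 0.2)), 1.0)
  expect_equal(sifter_combine(0.3), 0.3)
  expect_equal(sifter_combine(numeric()), 0)
  expect_error(sifter_combine(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::with_seed(17, {
    for (k in 1:4) {
      for (rep in 1:10) {
        s <- runif(k)
        expect_equal(sifter_combine(s), oracle_sifter(s))
        # permutation invariance and lower bound
        expect_equal(sifter_combine(rev(s)), sifter_combine(s))
        expect_gte(sifter_combine(s), max(s) - 1e-12)
      }
    }
  })
})

test_that("composite model score uses the configured linear coefficients", {
  expect_equal(qmean5(0, 0, 0, 0, 0), 0)
  expect_equal(qmean5(1, 0, 0, 0, 0), 0.3)
  expect_equal(qmean5(0, 1, 0, 0, 0), 0.17)
  expect_equal(qmean5(0, 0, 1, 0, 0), 0.7)
  expect_equal(qmean5(0, 0, 0, 1, 0), 80)
  expect_equal(qmean5(0, 0, 0, 0, 1), 45)
  expect_error(qmean5(NA, 0, 0, 0, 0), "finite")
  # substitutable coefficients
  expect_equal(qmean5(1, 1, 1, 1, 1,
                      coefficients = c(torsion = 1, pairwise = 1,
                                       solvation = 1, sse = 1, acc = 1)), 5)
})

test_that("quality-weighted model average", {
  expect_equal(weighted_model_average(c(0.4, 0.8), c(1, 1)), 0.6)
  expect_equal(weighted_model_average(0.55, 3), 0.55)
  expect_equal(weighted_model_average(c(0.4, 0.8), c(1, 3)), 0.7)
  expect_error(weighted_model_average(c(0.4, 0.8), c(0, 0)), "degenerate")
  expect_error(weighted_model_average(numeric(), numeric()), "nonempty")
})

test_that("batch scoring agrees with per-protein scoring primitives", {
  cfg <- generator_config(n_proteins = 120, seed = 5)
  prot <- gen_proteome(cfg)
  ev <- gen_evidence(prot, cfg)
  lit <- gen_literature(prot, cfg)
  sc <- score_proteins(prot, ev$evidence, lit$literature)
  filtered <- filter_evidence(ev$evidence)
  for (tag in sample(prot$locus_tag, 15)) {
    one <- prediction_agreement_score(filtered[filtered$locus_tag == tag, ])
    i <- which(sc$locus_tag == tag)
    expect_equal(sc$winning_label[i], one$label)
    expect_equal(sc$prediction_component[i], one$score)
    lit_one <- lit$literature[lit$literature$locus_tag == tag, ]
    expect_equal(sc$literature_component[i],
                 literature_score(lit_one, one$label))
  }
  expect_equal(sc$combined, sc$prediction_component + sc$literature_component)
  expect_true(all(sc$combined <= 12))
})
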