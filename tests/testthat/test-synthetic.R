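test_that("generation is fully deterministic under a fixed seed", {
  cfg <- generator_config(n_proteins = 10, seed = 1)
  expect_identical(gen_proteome(cfg), gen_proteome(cfg))
  prot <- gen_proteome(cfg)
  expect_identical(gen_evidence(prot, cfg), gen_evidence(prot, cfg))
  expect_identical(gen_literature(prot, cfg), gen_literature(prot, cfg))
  expect_identical(gen_genome_layout(cfg), gen_genome_layout(cfg))
  # different seed, different draws
  cfg2 <- generator_config(n_proteins = 10, seed = 2)
  expect_false(identical(gen_proteome(cfg2)$sequence, prot$sequence))
})

test_that("generator leaves the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(gen_proteome(generator_config(n_proteins = 5, seed = 9)))
  expect_identical(.Random.seed, before)
})

test_that("keyword fraction 1 makes every protein a candidate", {
  prot <- gen_proteome(generator_config(n_proteins = 40, seed = 4,
                                        keyword_fraction = 1))
  expect_equal(nrow(select_hypothetical(prot)), 40L)
  prot0 <- gen_proteome(generator_config(n_proteins = 40, seed = 4,
                                         keyword_fraction = 0))
  expect_equal(nrow(select_hypothetical(prot0)), 0L)
})

test_that("isoleucine-skewed composition pushes mean proteome GRAVY positive", {
  comp <- setNames(rep(0.01, 20), c("A","C","D","E","F","G","H","I","K","L",
                                    "M","N","P","Q","R","S","T","V","W","Y"))
  comp["I"] <- 0.81
  prot <- gen_proteome(generator_config(n_proteins = 60, seed = 6,
                                        composition = comp))
  cfg <- physchem_config()
  g <- vapply(prot$sequence, gravy, numeric(1), config = cfg)
  expect_gt(mean(g), 0)
})

test_that("full agreement forces prediction component 6; zero agreement <= 1", {
  cfg1 <- generator_config(n_proteins = 30, seed = 12, channel_agreement = 1,
                           fraction_duf = 0)
  prot <- gen_proteome(cfg1)
  ev <- gen_evidence(prot, cfg1)
  sc <- score_proteins(prot, ev$evidence)
  expect_true(all(sc$prediction_component == 6L))
  expect_true(all(ev$truth$n_support == 6L))

  cfg0 <- generator_config(n_proteins = 30, seed = 12, channel_agreement = 0,
                           fraction_duf = 0)
  ev0 <- gen_evidence(prot, cfg0)
  sc0 <- score_proteins(prot, ev0$evidence)
  expect_true(all(sc0$prediction_component <= 1L))  # distinct decoys never agree
})

test_that("realized channel support matches the binomial expectation", {
  cfg <- generator_config(n_proteins = 2000, seed = 33,
                          channel_agreement = 0.5, fraction_duf = 0)
  ev <- gen_evidence(gen_proteome(cfg), cfg)
  m <- mean(ev$truth$n_support)
  se <- sqrt(6 * 0.5 * 0.5 / 2000)
  expect_lt(abs(m - 3.0), 3 * se)
})

test_that("literature levels follow the configured distribution edge cases", {
  prot <- gen_proteome(generator_config(n_proteins = 50, seed = 14))
  cfg6 <- generator_config(n_proteins = 50, seed = 14,
                           literature_level_probs = c(0, 0, 0, 0, 0, 0, 1))
  lit6 <- gen_literature(prot, cfg6)
  expect_equal(nrow(lit6$literature), 50L)
  expect_true(all(lit6$literature$provenance_level == 6L))
  cfg0 <- generator_config(n_proteins = 50, seed = 14,
                           literature_level_probs = c(1, 0, 0, 0, 0, 0, 0))
  lit0 <- gen_literature(prot, cfg0)
  expect_equal(nrow(lit0$literature), 0L)
  # no literature record means nothing is retained regardless of prediction
  cfgA <- generator_config(n_proteins = 50, seed = 14, channel_agreement = 1,
                           fraction_duf = 0)
  sc <- score_proteins(prot, gen_evidence(prot, cfgA)$evidence,
                       lit0$literature)
  expect_false(any(sc$retained))
})

test_that("retained fraction tracks the product of tail probabilities", {
  cfg <- generator_config(n_proteins = 2000, seed = 77,
                          channel_agreement = 0.5, fraction_duf = 0)
  prot <- gen_proteome(cfg)
  sc <- score_proteins(prot, gen_evidence(prot, cfg)$evidence,
                       gen_literature(prot, cfg)$literature)
  p_c <- sum(stats::dbinom(3:6, 6, 0.5))   # P(channel support >= 3)
  p_l <- 4 / 7                              # P(literature level >= 3), uniform 0..6
  p <- p_c * p_l
  se <- sqrt(p * (1 - p) / 2000)
  expect_lt(abs(mean(sc$retained) - p), 3 * se)
})

test_that("planted layouts are recovered for random specs over many seeds", {
  withr::with_seed(1001, {
    for (i in 1:100) {
      k <- sample(1:4, 1)
      spec <- data.frame(size = sample(2:6, k, replace = TRUE),
                         gap = sample(c(20L, 50L, 150L), k, replace = TRUE))
      cfg <- generator_config(seed = sample.int(1e6, 1), cluster_spec = spec)
      rep_i <- cluster_report(detect_clusters(gen_genome_layout(cfg)))
      expect_equal(sort(rep_i$n_genes), sort(spec$size))
    }
  })
})

test_that("gen_dataset writes a consistent, re-readable bundle", {
  dir <- withr::local_tempdir()
  d <- gen_dataset(generator_config(n_proteins = 25, seed = 18), dir = dir)
  expect_true(all(file.exists(d$paths)))
  prot <- read_fasta(d$paths[["proteome"]])
  expect_equal(prot, d$proteome)
  ev <- read_evidence_table(d$paths[["evidence"]])
  expect_equal(nrow(ev), nrow(d$evidence))
  lit <- read_literature_table(d$paths[["literature"]])
  expect_equal(lit$provenance_level, d$literature$provenance_level)
})
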