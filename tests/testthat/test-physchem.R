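cfg <- physchem_config()

test_that("instability index follows the dipeptide-weight closed forms", {
  # homopolymer: 10 * (L-1) / L * DIWV(xx)
  expect_equal(instability_index(strrep("W", 10), cfg),
               10 * 9 / 10 * cfg$diwv[["WW"]])
  # L = 2: 5 * DIWV(x1 x2)
  expect_equal(instability_index("MK", cfg), 5 * cfg$diwv[["MK"]])
  expect_error(instability_index("M", cfg), "shorter than 2")
  expect_error(instability_index("MKX", cfg), "non-standard")
  # permissive mode drops ambiguity codes from the sums
  expect_equal(instability_index("MKXV", cfg, permissive = TRUE),
               instability_index("MKV", cfg))
})

test_that("reference sequences match externally computed property values", {
  # frozen values computed with an independent implementation (Biopython
  # ProtParam) before the package build
  s1 <- "MKWVTFISLLLLFSSAYS"
  expect_equal(instability_index(s1, cfg), 17.5666667, tolerance = 1e-6)
  expect_equal(gravy(s1, cfg), 1.2888889, tolerance = 1e-6)
  expect_equal(molecular_weight(s1, cfg), 2106.5243, tolerance = 1e-2)
  expect_equal(aliphatic_index(s1, cfg), 130.0, tolerance = 1e-6)
  s2 <- "ACDEFGHIKLMNPQRSTVWY"
  expect_equal(instability_index(s2, cfg), 84.74, tolerance = 1e-6)
  expect_equal(gravy(s2, cfg), -0.49, tolerance = 1e-6)
  expect_equal(molecular_weight(s2, cfg), 2395.7134, tolerance = 1e-2)
  expect_equal(aliphatic_index(s2, cfg), 58.5, tolerance = 1e-6)
})

test_that("stability classification is strict at the threshold", {
  expect_equal(classify_stability(39.99, cfg), "stable")
  expect_equal(classify_stability(40.01, cfg), "unstable")
  expect_equal(classify_stability(40.0, cfg), "unstable")
  expect_error(classify_stability(NaN, cfg), "finite")
})

test_that("aliphatic index closed forms and coefficients", {
  expect_equal(aliphatic_index(strrep("A", 30), cfg), 100)
  expect_equal(aliphatic_index(strrep("G", 30), cfg), 0)
  expect_equal(aliphatic_index(strrep("V", 30), cfg), 290)
  expect_equal(aliphatic_index(strrep("L", 12), cfg), 390)
})

test_that("gravy is a mean: homopolymer value and concatenation identity", {
  expect_equal(gravy(strrep("I", 7), cfg), cfg$hydropathy[["I"]])
  withr::with_seed(42, {
    s1 <- random_protein(31); s2 <- random_protein(57)
    expect_equal(gravy(paste0(s1, s2), cfg),
                 (31 * gravy(s1, cfg) + 57 * gravy(s2, cfg)) / 88)
  })
})

test_that("molecular weight does peptide-bond bookkeeping", {
  expect_equal(molecular_weight("G", cfg), 75.0666, tolerance = 1e-3)
  expect_equal(molecular_weight("GA", cfg),
               molecular_weight("G", cfg) + molecular_weight("A", cfg) -
                 cfg$water_mass)
  expect_error(molecular_weight("", cfg), "empty|non-standard")
})

test_that("theoretical pI is a zero of the charge curve and orders acid/base", {
  withr::with_seed(7, {
    for (i in 1:5) {
      s <- random_protein(80)
      pi <- theoretical_pi(s, cfg)
      expect_lt(abs(net_charge(s, pi, cfg)), 1e-3)
      expect_equal(pi, oracle_pi_grid(s, cfg), tolerance = 0.01)
    }
  })
  expect_gt(theoretical_pi(strrep("K", 20), cfg),
            theoretical_pi(strrep("D", 20), cfg))
})

test_that("net charge is strictly decreasing in pH", {
  withr::with_seed(13, {
    s <- random_protein(60)
    grid <- seq(0.5, 13.5, by = 0.25)
    q <- net_charge(s, grid, cfg)
    expect_true(all(diff(q) < 0))
  })
})

test_that("properties agree with brute-force oracles on 100 random sequences", {
  withr::with_seed(2024, {
    for (i in 1:100) {
      s <- random_protein(sample(10:200, 1))
      expect_equal(instability_index(s, cfg), oracle_instability(s, cfg))
      expect_equal(gravy(s, cfg), oracle_gravy(s, cfg))
      expect_equal(molecular_weight(s, cfg), oracle_mw(s, cfg))
      expect_equal(aliphatic_index(s, cfg), oracle_aliphatic(s, cfg))
    }
  })
})

test_that("permutation invariance holds for gravy/aliphatic but not instability", {
  withr::with_seed(99, {
    ii_diff <- FALSE
    for (i in 1:20) {
      s <- random_protein(50)
      perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
      expect_equal(gravy(perm, cfg), gravy(s, cfg))
      expect_equal(aliphatic_index(perm, cfg), aliphatic_index(s, cfg))
      if (abs(instability_index(perm, cfg) - instability_index(s, cfg)) > 1e-9)
        ii_diff <- TRUE
    }
    expect_true(ii_diff)  # dipeptide statistic depends on residue order
  })
})

test_that("gravy is bounded by the hydropathy scale extremes", {
  withr::with_seed(5, {
    for (i in 1:20) {
      g <- gravy(random_protein(sample(5:80, 1)), cfg)
      expect_gte(g, min(cfg$hydropathy))
      expect_lte(g, max(cfg$hydropathy))
    }
  })
})

test_that("batch profile is consistent with scalar calls", {
  prot <- gen_proteome(generator_config(n_proteins = 5, seed = 21))
  prof <- physchem_profile(prot, cfg)
  expect_equal(prof$instability_index[3],
               instability_index(prot$sequence[3], cfg))
  expect_equal(prof$stability_class,
               classify_stability(prof$instability_index, cfg))
  expect_true(all(prof$molecular_weight > 0))
  expect_true(all(prof$theoretical_pi > 0 & prof$theoretical_pi < 14))
})
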