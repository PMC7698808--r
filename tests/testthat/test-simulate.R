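test_that("tryptic cleavage follows the K/R-not-before-P rule", {
  expect_setequal(trypsin_digest("AKCPR", missed_cleavages = 0),
                  c("AK", "CPR"))
  expect_identical(trypsin_digest("AKPGR", missed_cleavages = 0), "AKPGR")
  frags <- trypsin_digest("GQEFTITGQKRALEQATR", missed_cleavages = 1)
  expect_true(all(c("GQEFTITGQKR", "ALEQATR") %in% frags))
  # min length filter
  expect_false("R" %in% trypsin_digest("GQEFTITGQKRALEQATR",
                                       missed_cleavages = 0, min_length = 2))
})

test_that("zero-missed-cleavage products reconstruct 100 random proteins", {
  prots <- random_proteins(100, seed = 6)
  for (pr in prots) {
    frags <- trypsin_digest(pr, missed_cleavages = 0)
    expect_identical(paste(frags, collapse = ""), pr)
  }
})

test_that("digestion respects absorbing C-termini", {
  m <- cleavage_model()
  # all rates zero: nothing happens
  null_model <- cleavage_model(rate = stats::setNames(
    numeric(20), names(mass_constants()$residues)))
  tc <- simulate_digestion("YGGFMKR", null_model, 100, times = c(0, 300))
  expect_equal(tc$fraction[tc$time == 300 & tc$species == "YGGFMKR"], 1)

  # acidic C-terminus is not processed under the default model
  tc2 <- simulate_digestion("ARLSQKFPKAE", m, 100, times = c(0, 300))
  expect_equal(tc2$fraction[tc2$time == 300 & tc2$species == "ARLSQKFPKAE"], 1)
})

test_that("Arg removal dominates the Met-enkephalin heptapeptide time course", {
  m <- cleavage_model()
  tc <- simulate_digestion("YGGFMKR", m, 100, times = c(0, 30, 60, 120, 300))
  at300 <- tc[tc$time == 300, ]
  frac <- stats::setNames(at300$fraction, at300$species)
  expect_lt(frac[["YGGFMKR"]], 0.01)   # precursor essentially gone
  expect_gt(frac[["YGGFMK"]], 0.90)    # Lys-terminal product accumulates
  # the Lys-terminal analogue is only partially processed
  tck <- simulate_digestion("YGGFMKK", m, 100, times = c(0, 300))
  expect_gt(tck$fraction[tck$time == 300 & tck$species == "YGGFMKK"], 0.5)
  expect_lt(tck$fraction[tck$time == 300 & tck$species == "YGGFMKK"], 0.95)
  expect_error(simulate_digestion("YGGFMKR", m, 100, times = c(-1, 10)),
               "negative")
})

test_that("molar fractions are conserved and precursor decay is monotone", {
  m <- cleavage_model()
  peps <- c("YGGFMKR", "AELEQLKGQGKSR", "GQEFTITGQKR", "AKAKAKR")
  times <- c(0, 10, 50, 100, 500, 960)
  for (p in peps) {
    for (conc in c(0.1, 1, 10, 100)) {
      tc <- simulate_digestion(p, m, conc, times = times)
      sums <- tapply(tc$fraction, tc$time, sum)
      expect_true(all(abs(sums - 1) < 1e-9))
      prec <- tc$fraction[tc$species == p]
      expect_true(all(diff(prec) <= 1e-12))
    }
    # monotone in enzyme concentration at fixed time
    rem <- vapply(c(0.1, 1, 10, 100), function(conc) {
      tc <- simulate_digestion(p, m, conc, times = c(0, 960))
      tc$fraction[tc$time == 960 & tc$species == p]
    }, numeric(1))
    expect_true(all(diff(rem) <= 1e-12))
  }
})

test_that("stochastic digestion agrees with the exact chain solution", {
  m <- cleavage_model()
  set.seed(9)
  exact <- simulate_digestion("YGGFMKR", m, 100, times = c(0, 60, 300))
  stoch <- simulate_digestion("YGGFMKR", m, 100, times = c(0, 60, 300),
                              method = "stochastic", n_molecules = 20000)
  merged <- merge(exact, stoch, by = c("time", "species"))
  expect_lt(max(abs(merged$fraction.x - merged$fraction.y)), 0.02)
})

test_that("simulated experiments are deterministic and carry coherent truth", {
  lib <- synthetic_cellular_library(10, seed = 2)
  ex1 <- simulate_lcms(lib, noise_cv = 0.05, seed = 11)
  ex2 <- simulate_lcms(lib, noise_cv = 0.05, seed = 11)
  expect_identical(ex1$features, ex2$features)

  ex3 <- simulate_lcms(lib, noise_cv = 0.05, seed = 12)
  expect_false(identical(ex1$features, ex3$features))

  # every feature traces to a recorded (peptide, label, charge) triple
  expect_equal(nrow(ex1$features), nrow(ex1$feature_truth))
  expect_true(all(ex1$feature_truth$label %in% names(ex1$design$conc_nM)))
  expect_error(simulate_lcms(list()), "empty")
})

test_that("zero-noise simulation feeds the classifier its exact truth", {
  # a non-cleavable peptide: all ratios exactly 1, non-substrate downstream
  ex <- simulate_lcms(list("TSVDNE"), noise_cv = 0, seed = 1)
  ratios <- compute_ratios(ex$noiseless["TSVDNE", ], ex$design)
  expect_true(all(ratios$ratios == 1))
  expect_identical(classify_record(ratios)$classification, "non_substrate")
  expect_identical(ex$truth$class, "non_substrate")

  # a strongly cleavable peptide classifies as a good substrate
  ex2 <- simulate_lcms(list("AKAGFLKR"), noise_cv = 0, seed = 1)
  r2 <- compute_ratios(ex2$noiseless["AKAGFLKR", ], ex2$design)
  expect_lt(r2$ratios[["100"]], 0.4)
  expect_identical(classify_record(r2)$classification, "good_substrate")
  expect_identical(ex2$truth$class[ex2$truth$peptide == "AKAGFLKR"],
                   "good_substrate")
})

test_that("the full pipeline recovers all classes from a noiseless experiment", {
  lib <- synthetic_cellular_library(20, seed = 1)
  ex <- simulate_lcms(lib, noise_cv = 0, seed = 1)
  res <- run_pipeline(ex$features, pipeline_config(), library = ex$library)
  got <- res$ratio_table[!is.na(res$ratio_table$sequence),
                         c("sequence", "classification")]
  merged <- merge(ex$truth, got, by.x = "peptide", by.y = "sequence")
  expect_equal(nrow(merged), nrow(ex$truth))
  expect_identical(merged$class, merged$classification)
})
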