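test_that("threshold classification reproduces the canonical examples", {
  expect_identical(
    classify_record(c(`100` = 0.02, `10` = 0.94, `1` = 1.08, `0.1` = 1.00)),
    "good_substrate")
  expect_identical(
    classify_record(c(`100` = 0.57, `10` = 1.04, `1` = 1.00)),
    "weak_substrate")
  expect_identical(
    classify_record(c(`100` = 1.52, `10` = 0.78, `1` = 1.04)),
    "product")
  expect_identical(
    classify_record(c(`100` = 1.0, `10` = 1.0, `1` = 1.0)),
    "non_substrate")
  expect_identical(
    classify_record(c(`100` = NA_real_, `10` = NA_real_)),
    "unclassified")
  # a depleted peptide is a substrate even when a low dose drifts above the
  # product cut (as in the published cellular-library data)
  expect_identical(
    classify_record(c(`100` = 0.31, `10` = 0.89, `1` = 1.24, `0.1` = 1.07)),
    "good_substrate")
  # the top-dose ratio decides even when it is itself missing: the highest
  # measured concentration is used
  expect_identical(
    classify_record(c(`100` = NA, `10` = 0.30, `1` = 1.0)),
    "good_substrate")
})

test_that("classification is a total partition of ratio space", {
  set.seed(3)
  classes <- c("good_substrate", "weak_substrate", "non_substrate",
               "product", "unclassified")
  for (i in 1:300) {
    r <- stats::runif(4, 0, 2)
    r[stats::runif(4) < 0.2] <- NA
    names(r) <- c(100, 10, 1, 0.1)
    cls <- classify_record(r)
    expect_length(cls, 1)
    expect_true(cls %in% classes)
    if (any(!is.na(r))) expect_false(cls == "unclassified")
  }
})

test_that("published ratio rows reproduce every printed class label", {
  hs <- classify_table(hek_substrates())
  expect_identical(hs$classification, hs$type)
  hp <- classify_table(hek_products())
  expect_identical(hp$classification, hp$type)
  tr <- classify_table(tryptic_tab())
  expect_identical(tr$classification, tr$type)
  # headline counts: tryptic library 1 good / 5 weak / 2 products,
  # cellular library 4 products
  expect_equal(sum(tr$classification == "good_substrate"), 1)
  expect_equal(sum(tr$classification == "weak_substrate"), 5)
  expect_equal(sum(tr$classification == "product"), 2)
  expect_equal(sum(hp$classification == "product"), 4)
})

test_that("products link to their one-residue-longer precursors", {
  ev <- link_product("GQEFTITGQK", list("GQEFTITGQKR", "ALEQATR"))
  expect_identical(ev$cleaved_aa, "R")
  expect_identical(ev$p1, "K")
  expect_identical(ev$p1_prime, "R")

  ev2 <- link_product("ADKVPKTAENF", list("ADKVPKTAENFR"))
  expect_identical(ev2$cleaved_aa, "R")

  expect_null(link_product("GQEFTITGQK", list("ALEQATR")))
  expect_error(link_product("AAA", list("AAAR", "AAAK")), "ambiguous")
  # restriction by removable residue
  expect_null(link_product("GQEFTITGQK", list("GQEFTITGQKW"),
                           allowed_cleaved = c("R", "K")))
})

test_that("mass-mode linkage recognises a one-residue mass gap", {
  # precursor - product mass difference of an Arg residue
  mc <- mass_constants()
  expect_equal(mc$residues[["R"]], 156.10111, tolerance = 1e-5)
  ev <- link_product("GQEFTITGQK", list("GQEFTITGQKR"), mode = "mass")
  expect_identical(ev$cleaved_aa, "R")
  # a same-length decoy whose mass gap is not one Arg is not matched
  expect_null(link_product("GQEFTITGQK", list("AAEFTITGQKR"), mode = "mass",
                           mass_tol = 0.01))
})

test_that("linking after dropping the C-terminal residue is the identity", {
  set.seed(4)
  for (i in 1:100) {
    s <- random_peptide_string(min_len = 2)
    prod <- substr(s, 1, nchar(s) - 1)
    ev <- link_product(prod, list(s))
    expect_identical(format(ev$precursor), s)
    expect_identical(ev$cleaved_aa, substr(s, nchar(s), nchar(s)))
  }
})

test_that("cleavage events keep exact mass bookkeeping", {
  mc <- mass_constants()
  ev <- cleavage_event("GQEFTITGQKR", "GQEFTITGQK")
  expect_equal(monoisotopic_mass(ev$precursor) -
                 monoisotopic_mass(ev$product),
               mc$residues[[ev$cleaved_aa]], tolerance = 1e-10)
  expect_error(cleavage_event("GQEFTITGQKR", "ALEQATR"))
})
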