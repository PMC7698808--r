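test_that("peptide notation parses and round-trips", {
  p <- parse_peptide("Ac-ADEIAKAQVAR")
  expect_equal(p$sequence, "ADEIAKAQVAR")
  expect_equal(p$n_term, "acetyl")
  expect_length(p$ox, 0)

  q <- parse_peptide("SAMoxTEEAAVAIKAMAK")
  expect_equal(q$sequence, "SAMTEEAAVAIKAMAK")
  expect_equal(q$n_term, "free")
  expect_equal(q$ox, 3L)

  r <- parse_peptide("IIEPSLR")
  expect_equal(r$n_term, "free")
  expect_length(r$ox, 0)

  for (s in c("Ac-ADEIAKAQVAR", "SAMoxTEEAAVAIKAMAK", "IIEPSLR",
              "Ac-SAMoxTEEAAVAIKAMoxAK")) {
    expect_identical(format(parse_peptide(s)), s)
  }
})

test_that("malformed notation is rejected", {
  expect_error(parse_peptide(""), "empty")
  expect_error(parse_peptide("Ac-"), "empty")
  expect_error(parse_peptide("PEPTIXDE"), "unknown residue")
  expect_error(parse_peptide("SALoxTE"), "non-Met")
  expect_error(parse_peptide("oxM"), "no preceding residue")
  expect_error(peptide("AMA", ox = 1), "only supported on Met")
  expect_error(peptide("AMA", ox = 9), "out of range")
})

test_that("monoisotopic masses reproduce published values to <= 10 ppm", {
  cases <- c("IIEPSLR" = 826.49, "Ac-ADEIAKAQVAR" = 1212.65,
             "SAMoxTEEAAVAIKAMAK" = 1636.82, "AELEQLKGQGKSR" = 1442.78,
             "GQEFTITGQK" = 1107.56)
  for (s in names(cases)) {
    expect_lt(abs(ppm_error(cases[[s]], monoisotopic_mass(s))), 10)
  }
  # single glycine: one residue plus water
  expect_equal(monoisotopic_mass("G"), 75.0320, tolerance = 1e-6)
})

test_that("every fixture theoretical mass (bar flagged rows) recomputes to <= 10 ppm", {
  expect_true(validate_fixture_masses(hek_substrates()))
  expect_true(validate_fixture_masses(hek_products()))
  expect_true(validate_fixture_masses(tryptic_tab()))
})

test_that("tag counts and expected charges match the published cellular-library rows", {
  for (tab in list(hek_substrates(), hek_products())) {
    expect_identical(count_tags(tab$sequence), as.integer(tab$t))
    expect_identical(predict_charge(tab$sequence), as.integer(tab$z))
  }
  expect_equal(count_tags("EKTPKTPKGPSSVEDIKA"), 5L)
  expect_equal(count_tags("Ac-TTTTTFKGVDPNSRNSSR"), 1L)
  expect_equal(predict_charge("Ac-ADEIAKAQVAR"), 2L)  # acetyl N-terminus not counted
  expect_equal(predict_charge("VFDVELL"), 1L)
})

test_that("tag count never exceeds expected charge", {
  set.seed(42)
  for (i in 1:200) {
    s <- random_peptide_string()
    p <- peptide(s, n_term = sample(c("free", "acetyl"), 1))
    expect_lte(count_tags(p), predict_charge(p))
  }
})

test_that("labeled m/z places tags and protons correctly", {
  expect_equal(labeled_mz("IIEPSLR", "D0", 2), 477.803, tolerance = 1e-3)
  # deuterium step: 3 x (2H - 1H)
  p <- "VFDVELL"  # T = 1
  expect_equal(labeled_mz(p, "D3", 1) - labeled_mz(p, "D0", 1),
               3.01883, tolerance = 1e-5)
  # 13C step between the two heaviest labels
  expect_equal(labeled_mz(p, "D12", 1) - labeled_mz(p, "D9", 1),
               3.01007, tolerance = 1e-5)
  # tags scale with lysine count: T tags worth of label mass over Z charges
  mc <- mass_constants()
  expect_equal(labeled_mz("AKAKA", "D9", 3) - labeled_mz("AKAKA", "D0", 3),
               3 * (mc$tags[["D9"]] - mc$tags[["D0"]]) / 3)
  expect_error(labeled_mz("AKAKA", "D0", 2), "below tag count")
})

test_that("ppm error is the standard relative deviation", {
  expect_equal(ppm_error(826.49, 826.49), 0)
  expect_equal(ppm_error(1000.01, 1000.00), 10, tolerance = 1e-9)
  expect_equal(ppm_error(123.456, 123.456), 0)
  expect_error(ppm_error(1, 0), "positive")
})

test_that("fragment ladders carry modifications and complement to the parent mass", {
  mc <- mass_constants()
  lad <- fragment_ladder("IIEPSLR")
  b2 <- lad$mz[lad$ion == "b" & lad$index == 2]
  y1 <- lad$mz[lad$ion == "y" & lad$index == 1]
  expect_equal(b2, 227.175, tolerance = 1e-3)
  expect_equal(y1, 175.119, tolerance = 1e-3)  # C-terminal Arg

  # acetyl shifts b-ions only; oxidation shifts the ions spanning the site
  lad_ac <- fragment_ladder("Ac-IIEPSLR")
  expect_equal(lad_ac$mz[lad_ac$ion == "b"], lad$mz[lad$ion == "b"] + mc$acetyl)
  expect_equal(lad_ac$mz[lad_ac$ion == "y"], lad$mz[lad$ion == "y"])

  expect_error(fragment_ladder("G"), "length >= 2")
})

test_that("b/y complementarity holds on 1000 random peptides", {
  set.seed(1)
  mc <- mass_constants()
  for (i in 1:1000) {
    p <- peptide(random_peptide_string(),
                 n_term = sample(c("free", "acetyl"), 1))
    lad <- fragment_ladder(p)
    n <- nchar(p$sequence)
    b <- lad$mz[lad$ion == "b"][order(lad$index[lad$ion == "b"])]
    y <- lad$mz[lad$ion == "y"][order(lad$index[lad$ion == "y"])]
    expect_equal(b + rev(y),
                 rep(monoisotopic_mass(p) + 2 * mc$proton, n - 1),
                 tolerance = 1e-9)
  }
})

test_that("mass additivity under C-terminal cleavage is exact", {
  set.seed(2)
  mc <- mass_constants()
  for (i in 1:200) {
    p <- peptide(random_peptide_string(min_len = 3),
                 n_term = sample(c("free", "acetyl"), 1))
    n <- nchar(p$sequence)
    last <- substr(p$sequence, n, n)
    trunc <- peptide(substr(p$sequence, 1, n - 1), n_term = p$n_term)
    expect_equal(monoisotopic_mass(trunc) + mc$residues[[last]],
                 monoisotopic_mass(p), tolerance = 1e-12)
  }
})

test_that("identification acceptance applies all four filters", {
  p <- parse_peptide("IIEPSLR")
  lad <- fragment_ladder(p)$mz
  good <- accept_identification(p, parent_mass = monoisotopic_mass(p),
                                parent_charge = 2,
                                observed_fragments = lad[1:10],
                                tags_observed = 1)
  expect_true(good$accept)

  off <- accept_identification(p,
                               parent_mass = monoisotopic_mass(p) * (1 + 60e-6),
                               parent_charge = 2,
                               observed_fragments = lad[1:10],
                               tags_observed = 1)
  expect_false(off$accept)
  expect_identical(off$failed, "parent_mass")

  # 7 of 10 fragments matched: below the 80% requirement
  frags <- c(lad[1:7], 999.9, 1500.5, 2000.1)
  part <- accept_identification(p, monoisotopic_mass(p), 2, frags, 1)
  expect_false(part$accept)
  expect_identical(part$failed, "fragments")
  expect_equal(part$fragment_fraction, 0.7)

  wrongz <- accept_identification(p, monoisotopic_mass(p), 3, lad[1:10], 1)
  expect_identical(wrongz$failed, "charge")
  wrongt <- accept_identification(p, monoisotopic_mass(p), 2, lad[1:10], 2)
  expect_identical(wrongt$failed, "tags")

  none <- accept_identification(p, monoisotopic_mass(p), 2, numeric(0), 1)
  expect_false(none$accept)
  expect_true("fragments" %in% none$failed)
})
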