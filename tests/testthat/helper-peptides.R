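# random peptide generator for property-style tests
random_peptide_string <- function(min_len = 2, max_len = 20) {
  residues <- names(mass_constants()$residues)
  len <- sample(min_len:max_len, 1)
  paste(sample(residues, len, replace = TRUE), collapse = "")
}

# published quantification rows used repeatedly across tests
hek_substrates <- function() cpz_fixture("hek_substrates")
hek_products <- function() cpz_fixture("hek_products")
tryptic_tab <- function() cpz_fixture("tryptic")

ratio_cols <- function(tab) grep("^ratio_", names(tab), value = TRUE)
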