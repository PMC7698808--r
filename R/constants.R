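#' Monoisotopic mass constants
#'
#' Returns the set of monoisotopic masses used throughout the package:
#' residue masses for the 20 standard amino acids, water, the proton,
#' modification deltas (N-terminal acetylation, methionine oxidation), and
#' the added mass per trimethylammonium-butyryl (TMAB) isotopic tag for each
#' of the five label channels.
#'
#' The TMAB moiety (C7H14NO+, carrying a fixed positive charge) adds
#' 128.1075 Da per derivatised amine in its all-hydrogen (D0) form. The
#' heavier channels replace hydrogens with deuterium in steps of three
#' (D3, D6, D9: +3 x 1.006277 Da each step); D12 additionally replaces
#' three 12C with 13C (+3 x 1.003355 Da relative to D9). Tags react with
#' free alpha- and epsilon-amines, so the tag count of a peptide equals its
#' lysine count plus one for a free N-terminus.
#'
#' @param overrides named list replacing any of the default entries
#'   (`residues`, `water`, `proton`, `acetyl`, `oxidation`, `tags`).
#' @return A list with elements `residues` (named numeric, Da), `water`,
#'   `proton`, `acetyl`, `oxidation` (Da), and `tags` (named numeric, Da per
#'   tag for labels D0, D3, D6, D9, D12).
#' @examples
#' mc <- mass_constants()
#' mc$tags["D3"] - mc$tags["D0"]  # one three-deuterium step
#' @export
mass_constants <- function(overrides = NULL) {
  d_step <- 3 * (2.014101778 - 1.007825032)   # 3 x (2H - 1H)
  c13_step <- 3 * (13.00335484 - 12)          # 3 x (13C - 12C)
  const <- list(
    residues = c(
      G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
      V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
      I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
      K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
      F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
    ),
    water = 18.010565,
    proton = 1.007276,
    acetyl = 42.010565,
    oxidation = 15.994915,
    tags = c(
      D0 = 128.107539,
      D3 = 128.107539 + d_step,
      D6 = 128.107539 + 2 * d_step,
      D9 = 128.107539 + 3 * d_step,
      D12 = 128.107539 + 3 * d_step + c13_step
    )
  )
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides), all(names(overrides) %in% names(const)))
    const[names(overrides)] <- overrides
  }
  # invariants: tag masses strictly increasing, equal deuterium steps
  stopifnot(all(diff(const$tags) > 0))
  steps <- diff(const$tags[c("D0", "D3", "D6", "D9")])
  stopifnot(max(abs(steps - steps[1])) < 1e-9)
  const
}

#' Read mass constants from a YAML-free key=value config file
#'
#' Simple override mechanism: lines of the form `water=18.010565` or
#' `residue.X=123.456` or `tag.D0=128.1075`. Unknown keys are an error.
#'
#' @param path path to the config file.
#' @return A mass constants list as from [mass_constants()].
#' @export
read_mass_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  const <- mass_constants()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- as.numeric(trimws(kv[2]))
    if (is.na(val)) stop("non-numeric value in config line: ", ln)
    if (grepl("^residue\\.", key)) {
      const$residues[sub("^residue\\.", "", key)] <- val
    } else if (grepl("^tag\\.", key)) {
      const$tags[sub("^tag\\.", "", key)] <- val
    } else if (key %in% c("water", "proton", "acetyl", "oxidation")) {
      const[[key]] <- val
    } else {
      stop("unknown config key: ", key)
    }
  }
  const
}

# Label channels in increasing mass order; used for design validation and
# multiplet spacing.
tmab_labels <- function() c("D0", "D3", "D6", "D9", "D12")
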