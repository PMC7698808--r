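#' Neutral monoisotopic mass of a peptide
#'
#' Sum of residue monoisotopic masses plus one water, plus the acetyl delta
#' for an acetylated N-terminus and one oxidation delta per oxidised Met.
#' TMAB label masses are never included here: result tables report the
#' unlabeled neutral mass.
#'
#' @param p a peptide object, an annotated sequence string, or a character
#'   vector of such strings (vectorised).
#' @param constants mass constants, see [mass_constants()].
#' @return Neutral monoisotopic mass in Da (numeric, same length as `p` for
#'   character input).
#' @examples
#' monoisotopic_mass("IIEPSLR")          # 826.49
#' monoisotopic_mass("Ac-ADEIAKAQVAR")   # 1212.65
#' @export
monoisotopic_mass <- function(p, constants = mass_constants()) {
  if (is.character(p) && length(p) > 1L) {
    return(vapply(p, monoisotopic_mass, numeric(1), constants = constants,
                  USE.NAMES = FALSE))
  }
  p <- as_peptide(p)
  res <- peptide_residues(p)
  sum(constants$residues[res]) + constants$water +
    (p$n_term == "acetyl") * constants$acetyl +
    length(p$ox) * constants$oxidation
}

#' Number of isotopic tags incorporated into a peptide
#'
#' Amine-reactive TMAB tags label the N-terminal alpha-amine (when free, not
#' acetylated) and every Lys epsilon-amine. Tyrosine labeling is reversed
#' during sample work-up, so Tyr never contributes.
#'
#' @inheritParams monoisotopic_mass
#' @return Integer tag count T.
#' @examples
#' count_tags("EKTPKTPKGPSSVEDIKA")   # 5
#' count_tags("Ac-TTTTTFKGVDPNSRNSSR")  # 1
#' @export
count_tags <- function(p) {
  if (is.character(p) && length(p) > 1L) {
    return(vapply(p, count_tags, integer(1), USE.NAMES = FALSE))
  }
  p <- as_peptide(p)
  res <- peptide_residues(p)
  as.integer(sum(res == "K") + (p$n_term == "free"))
}

#' Expected charge of a labeled peptide ion
#'
#' Basic residues (Arg, Lys, His) plus one for a free N-terminus. Each TMAB
#' tag replaces the proton on the amine it labels with its own fixed
#' positive charge, so the expected charge is unchanged by labeling and
#' always satisfies Z >= T.
#'
#' @inheritParams monoisotopic_mass
#' @return Integer expected charge Z.
#' @examples
#' predict_charge("AELEQLKGQGKSR")   # 4
#' predict_charge("Ac-ADEIAKAQVAR")  # 2
#' @export
predict_charge <- function(p) {
  if (is.character(p) && length(p) > 1L) {
    return(vapply(p, predict_charge, integer(1), USE.NAMES = FALSE))
  }
  p <- as_peptide(p)
  res <- peptide_residues(p)
  as.integer(sum(res %in% c("R", "K", "H")) + (p$n_term == "free"))
}

#' m/z of a TMAB-labeled peptide ion
#'
#' Each of the T tags carries one fixed positive charge and its label-specific
#' mass; the remaining Z - T charges are protons:
#' mz = (M + T * tag_mass + (Z - T) * proton) / Z.
#'
#' @param p peptide object or annotated string.
#' @param label one of `"D0"`, `"D3"`, `"D6"`, `"D9"`, `"D12"`.
#' @param charge ion charge Z; must be >= the tag count of `p`.
#' @param constants mass constants.
#' @return m/z in Th.
#' @examples
#' labeled_mz("IIEPSLR", "D0", charge = 2)  # 477.803
#' @export
labeled_mz <- function(p, label, charge, constants = mass_constants()) {
  p <- as_peptide(p)
  label <- match.arg(label, tmab_labels())
  t_tags <- count_tags(p)
  if (charge < t_tags) {
    stop("charge (", charge, ") below tag count (", t_tags, ") for ",
         format(p))
  }
  (monoisotopic_mass(p, constants) + t_tags * constants$tags[[label]] +
      (charge - t_tags) * constants$proton) / charge
}

#' Parts-per-million mass error
#'
#' @param observed observed mass (Da).
#' @param theoretical theoretical mass (Da), must be positive.
#' @return (observed - theoretical) / theoretical * 1e6. Vectorised.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical mass must be positive")
  (observed - theoretical) / theoretical * 1e6
}

#' b/y fragment-ion ladder
#'
#' Singly protonated b- and y-ion masses for a peptide of length n >= 2:
#' n-1 b-ions (prefix residue sums plus any N-terminal/internal modification
#' mass plus one proton) and n-1 y-ions (suffix sums plus water plus one
#' proton). Complementarity: b_i + y_(n-i) = neutral mass + 2 protons.
#'
#' @inheritParams monoisotopic_mass
#' @return A data.frame with columns `ion` ("b"/"y"), `index`, and `mz`.
#' @examples
#' fragment_ladder("IIEPSLR")
#' @export
fragment_ladder <- function(p, constants = mass_constants()) {
  p <- as_peptide(p)
  res <- peptide_residues(p)
  n <- length(res)
  if (n < 2L) stop("fragment ladder requires peptide length >= 2")
  masses <- constants$residues[res]
  if (length(p$ox)) masses[p$ox] <- masses[p$ox] + constants$oxidation
  nterm_delta <- (p$n_term == "acetyl") * constants$acetyl
  b <- cumsum(masses)[-n] + nterm_delta + constants$proton
  y <- rev(cumsum(rev(masses))[-n]) + constants$water + constants$proton
  data.frame(
    ion = rep(c("b", "y"), each = n - 1L),
    index = c(seq_len(n - 1L), rev(seq_len(n - 1L))),
    mz = unname(c(b, y))
  )
}

#' Identification acceptance filter
#'
#' Applies the acceptance rules used for multiplex peptidomics
#' identifications: the parent mass must fall within `tol_ppm` of the
#' theoretical mass, the observed charge must equal the predicted charge
#' (basic residues plus free N-terminus), the observed tag count must equal
#' the expected count, and at least `min_match` of the observed major
#' fragments must match a predicted b- or y-ion within `frag_tol` Da.
#'
#' @param candidate peptide object or annotated string.
#' @param parent_mass observed neutral parent mass (Da).
#' @param parent_charge observed charge.
#' @param observed_fragments numeric vector of observed singly protonated
#'   fragment masses; an empty vector fails the fragment criterion (it never
#'   raises an error).
#' @param tags_observed observed number of isotopic tags.
#' @param tol_ppm parent mass tolerance in ppm (default 50).
#' @param min_match minimum matched fragment fraction (default 0.8).
#' @param frag_tol absolute fragment tolerance in Da (default 0.02).
#' @param constants mass constants.
#' @return A list with `accept` (logical), `checks` (named logical vector for
#'   `parent_mass`, `charge`, `tags`, `fragments`), `ppm`,
#'   `fragment_fraction`, and `failed` (names of failed checks).
#' @export
accept_identification <- function(candidate, parent_mass, parent_charge,
                                  observed_fragments, tags_observed,
                                  tol_ppm = 50, min_match = 0.8,
                                  frag_tol = 0.02,
                                  constants = mass_constants()) {
  p <- as_peptide(candidate)
  theor <- monoisotopic_mass(p, constants)
  ppm <- ppm_error(parent_mass, theor)
  ladder <- fragment_ladder(p, constants)$mz
  frac <- if (length(observed_fragments) == 0L) {
    0
  } else {
    mean(vapply(observed_fragments,
                function(f) any(abs(ladder - f) <= frag_tol), logical(1)))
  }
  checks <- c(
    parent_mass = abs(ppm) <= tol_ppm,
    charge = parent_charge == predict_charge(p),
    tags = tags_observed == count_tags(p),
    fragments = frac >= min_match
  )
  list(
    accept = all(checks),
    checks = checks,
    ppm = ppm,
    fragment_fraction = frac,
    failed = names(checks)[!checks]
  )
}
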