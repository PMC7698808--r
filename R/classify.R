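#' Classify a ratio record as substrate, product, or neither
#'
#' Applies fixed intensity-ratio thresholds. Writing r_max for the ratio at
#' the highest enzyme concentration with a measured value:
#' * `good_substrate` if 1 - r_max >= `good_cut` (default a >= 60% decrease),
#' * `weak_substrate` if 1 - r_max >= `weak_cut` (a 20-60% decrease),
#' * otherwise `product` if any measured ratio exceeds `product_cut`
#'   (default 1.20, i.e. an increase above 120% of the control),
#' * otherwise `non_substrate`.
#'
#' The substrate test at the top concentration takes precedence over the
#' product test: a clearly depleted peptide is a substrate even if a low
#' concentration channel drifts above `product_cut` (observed in real data,
#' where a good substrate can show a 1.2x ratio at the lowest dose). A
#' record with no measured non-control ratios is `unclassified`.
#'
#' @param r a `"ratio_record"` from [compute_ratios()], or a named numeric
#'   vector of ratios whose names are enzyme concentrations in nM.
#' @param good_cut minimum fractional decrease for a good substrate (0.60).
#' @param weak_cut minimum fractional decrease for a weak substrate (0.20).
#' @param product_cut ratio above which an increase marks a product (1.20).
#' @return For a ratio vector, the classification string. For a
#'   `"ratio_record"`, the record with `classification` filled in and a
#'   `partial_low_dose` attribute: TRUE when the second-highest dose also
#'   shows a decrease (a diagnostic echo of the behaviour typical of good
#'   substrates, not a classification criterion).
#' @examples
#' classify_record(c(`100` = 0.02, `10` = 0.94, `1` = 1.08, `0.1` = 1.00))
#' classify_record(c(`100` = 1.52, `10` = 0.78, `1` = 1.04))
#' @export
classify_record <- function(r, good_cut = 0.60, weak_cut = 0.20,
                            product_cut = 1.20) {
  rec <- NULL
  if (inherits(r, "ratio_record")) {
    rec <- r
    r <- r$ratios
  }
  stopifnot(is.numeric(r), !is.null(names(r)))
  conc <- as.numeric(names(r))
  measured <- !is.na(r)
  cls <- if (!any(measured)) {
    "unclassified"
  } else {
    r_max <- r[measured][which.max(conc[measured])]
    decrease <- 1 - r_max
    if (decrease >= good_cut) {
      "good_substrate"
    } else if (decrease >= weak_cut) {
      "weak_substrate"
    } else if (any(r[measured] > product_cut)) {
      "product"
    } else {
      "non_substrate"
    }
  }
  if (is.null(rec)) return(cls)
  rec$classification <- cls
  ord <- order(conc[measured], decreasing = TRUE)
  attr(rec, "partial_low_dose") <-
    length(ord) >= 2 && (1 - r[measured][ord[2]]) > 0
  rec
}

#' Classify every row of a ratio table
#'
#' Convenience wrapper applying [classify_record()] to a data.frame whose
#' ratio columns are named `ratio_<conc>nM` (as written by the report
#' writers and the bundled fixtures).
#'
#' @param tab data.frame with `ratio_*nM` columns (NA = not detected).
#' @inheritParams classify_record
#' @return `tab` with a `classification` column appended (or replaced).
#' @export
classify_table <- function(tab, good_cut = 0.60, weak_cut = 0.20,
                           product_cut = 1.20) {
  rc <- grep("^ratio_", names(tab), value = TRUE)
  if (!length(rc)) stop("no ratio_* columns found")
  conc <- as.numeric(sub("^ratio_([0-9.]+)nM$", "\\1", rc))
  if (any(is.na(conc))) stop("malformed ratio column names: ",
                             paste(rc[is.na(conc)], collapse = ", "))
  tab$classification <- vapply(seq_len(nrow(tab)), function(i) {
    r <- as.numeric(tab[i, rc])
    names(r) <- conc
    classify_record(r, good_cut, weak_cut, product_cut)
  }, character(1))
  tab
}

#' Link a product peptide to its precursor
#'
#' A carboxypeptidase product differs from its precursor by the loss of a
#' single C-terminal residue. Given a library of candidate precursors, this
#' returns the cleavage event whose precursor sequence equals the product
#' sequence plus one residue (sequence mode), or whose neutral mass exceeds
#' the product's by one residue mass within `mass_tol` Da (mass mode).
#'
#' @param product peptide object or annotated string.
#' @param library list/vector of candidate precursor peptides (objects or
#'   strings).
#' @param allowed_cleaved residues the enzyme may remove (default all 20).
#' @param mode `"sequence"` (default) or `"mass"`.
#' @param mass_tol mass-mode tolerance in Da (default 0.01).
#' @param constants mass constants.
#' @return A `"cleavage_event"` (list with `precursor`, `product`,
#'   `cleaved_aa`, `p1`, `p1_prime`) or `NULL` when no precursor matches.
#'   Multiple distinct matching precursors raise an error listing them.
#' @examples
#' link_product("GQEFTITGQK", list("GQEFTITGQKR", "ALEQATR"))
#' @export
link_product <- function(product, library,
                         allowed_cleaved = names(mass_constants()$residues),
                         mode = c("sequence", "mass"), mass_tol = 0.01,
                         constants = mass_constants()) {
  mode <- match.arg(mode)
  product <- as_peptide(product)
  library <- lapply(library, as_peptide)
  hits <- Filter(Negate(is.null), lapply(library, function(prec) {
    if (peptide_length(prec) != peptide_length(product) + 1L) return(NULL)
    last <- substr(prec$sequence, peptide_length(prec), peptide_length(prec))
    if (!last %in% allowed_cleaved) return(NULL)
    ok <- if (mode == "sequence") {
      substr(prec$sequence, 1L, peptide_length(product)) ==
        product$sequence && prec$n_term == product$n_term
    } else {
      abs(monoisotopic_mass(prec, constants) -
            monoisotopic_mass(product, constants) -
            constants$residues[[last]]) <= mass_tol
    }
    if (!ok) return(NULL)
    cleavage_event(prec, product, constants = constants, check = mode == "sequence")
  }))
  if (length(hits) == 0L) return(NULL)
  seqs <- vapply(hits, function(h) format(h$precursor), character(1))
  hits <- hits[!duplicated(seqs)]
  if (length(hits) > 1L) {
    stop("ambiguous precursor for ", format(product), ": ",
         paste(unique(seqs), collapse = ", "))
  }
  hits[[1]]
}

#' Construct a cleavage event
#'
#' Records one carboxypeptidase cleavage in Schechter-Berger terms: the
#' removed C-terminal residue occupies P1' and the precursor's penultimate
#' residue occupies P1.
#'
#' @param precursor,product peptides (objects or strings); the product must
#'   equal the precursor minus its C-terminal residue when `check = TRUE`.
#' @param constants mass constants.
#' @param check verify the sequence relation and exact mass bookkeeping.
#' @return A `"cleavage_event"` list with `precursor`, `product`,
#'   `cleaved_aa`, `p1`, `p1_prime`.
#' @export
cleavage_event <- function(precursor, product, constants = mass_constants(),
                           check = TRUE) {
  precursor <- as_peptide(precursor)
  product <- as_peptide(product)
  n <- peptide_length(precursor)
  res <- peptide_residues(precursor)
  if (check) {
    stopifnot(peptide_length(product) == n - 1L,
              substr(precursor$sequence, 1L, n - 1L) == product$sequence)
  }
  structure(
    list(precursor = precursor, product = product,
         cleaved_aa = res[n], p1 = res[n - 1L], p1_prime = res[n]),
    class = "cleavage_event"
  )
}

#' @export
print.cleavage_event <- function(x, ...) {
  cat(sprintf("<cleavage_event> %s -> %s  (P1'=%s removed, P1=%s)\n",
              format(x$precursor), format(x$product), x$p1_prime, x$p1))
  invisible(x)
}
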