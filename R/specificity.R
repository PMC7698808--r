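#' C-terminal cleavage-site context of a peptide
#'
#' In the Schechter-Berger convention for carboxypeptidases the residue that
#' the enzyme removes (the current C-terminus) is P1' and the penultimate
#' residue is P1.
#'
#' @param p peptide object or annotated string, length >= 2.
#' @return Named character vector `c(p1_prime = ..., p1 = ...)`.
#' @examples
#' cterm_context("IIEPSLR")  # P1' = R, P1 = L
#' @export
cterm_context <- function(p) {
  p <- as_peptide(p)
  res <- peptide_residues(p)
  n <- length(res)
  if (n < 2L) stop("cleavage-site context requires peptide length >= 2")
  c(p1_prime = res[n], p1 = res[n - 1L])
}

#' Positional residue-frequency profile by substrate class
#'
#' Tallies the residue at P1' or P1 for each classified peptide, per class,
#' over the full 20-residue support (residues never observed get explicit
#' zeros so profiles are comparable across experiments). For P1 analysis the
#' tally is usually restricted to peptides whose P1' residue is permissive
#' for the enzyme (`restrict_p1prime`), since a non-permissive C-terminus
#' makes the penultimate residue uninformative.
#'
#' @param peptides list/vector of peptides (objects or strings).
#' @param classes character vector of classifications, parallel to
#'   `peptides` (values as produced by [classify_record()]).
#' @param position `"p1_prime"` (default) or `"p1"`.
#' @param restrict_p1prime optional residue set; peptides whose P1' lies
#'   outside it are dropped before tallying (typically `c("R", "K")` for a
#'   basic carboxypeptidase).
#' @return A `"specificity_profile"`: list with `position`, `counts` and
#'   `frequencies` (class x residue matrices; frequencies are rows summing
#'   to 1 for non-empty classes), and `n_per_class`.
#' @export
build_profile <- function(peptides, classes,
                          position = c("p1_prime", "p1"),
                          restrict_p1prime = NULL) {
  position <- match.arg(position)
  stopifnot(length(peptides) == length(classes))
  residues <- names(mass_constants()$residues)
  class_levels <- c("good_substrate", "weak_substrate", "non_substrate",
                    "product", "unclassified")
  classes <- factor(classes, levels = class_levels)
  counts <- matrix(0L, nrow = length(class_levels), ncol = length(residues),
                   dimnames = list(class_levels, residues))
  for (i in seq_along(peptides)) {
    ctx <- cterm_context(peptides[[i]])
    if (!is.null(restrict_p1prime) &&
        !ctx[["p1_prime"]] %in% restrict_p1prime) next
    res <- ctx[[if (position == "p1_prime") "p1_prime" else "p1"]]
    counts[as.character(classes[i]), res] <-
      counts[as.character(classes[i]), res] + 1L
  }
  n_per_class <- rowSums(counts)
  freqs <- counts / ifelse(n_per_class > 0, n_per_class, 1)
  structure(
    list(position = position, counts = counts, frequencies = freqs,
         n_per_class = n_per_class),
    class = "specificity_profile"
  )
}

#' @export
print.specificity_profile <- function(x, ...) {
  cat("<specificity_profile> position:",
      if (x$position == "p1_prime") "P1'" else "P1", "\n")
  nonzero <- x$counts[, colSums(x$counts) > 0, drop = FALSE]
  print(nonzero)
  invisible(x)
}

#' Residue preference summary with enrichment over non-substrates
#'
#' Ranks residues by their frequency among substrates (good + weak by
#' default) and reports the ratio to the non-substrate background
#' frequency. The enrichment is a descriptive convenience, not an
#' inferential statistic; residues absent from the background give an
#' infinite ratio flagged in `background_missing`.
#'
#' @param profile a `"specificity_profile"` from [build_profile()].
#' @param substrate_classes classes pooled as "substrate" (default good +
#'   weak).
#' @return data.frame with columns `residue`, `substrate_count`,
#'   `substrate_freq`, `background_freq`, `enrichment`,
#'   `background_missing`, ordered by decreasing substrate frequency;
#'   residues unobserved among substrates are dropped.
#' @export
preference_summary <- function(profile,
                               substrate_classes = c("good_substrate",
                                                     "weak_substrate")) {
  stopifnot(inherits(profile, "specificity_profile"))
  sub_counts <- colSums(profile$counts[substrate_classes, , drop = FALSE])
  n_sub <- sum(sub_counts)
  sub_freq <- if (n_sub > 0) sub_counts / n_sub else sub_counts
  bg_counts <- profile$counts["non_substrate", ]
  n_bg <- sum(bg_counts)
  bg_freq <- if (n_bg > 0) bg_counts / n_bg else bg_counts
  keep <- sub_counts > 0
  out <- data.frame(
    residue = names(sub_counts)[keep],
    substrate_count = unname(sub_counts[keep]),
    substrate_freq = unname(sub_freq[keep]),
    background_freq = unname(bg_freq[keep]),
    enrichment = unname(ifelse(bg_freq[keep] > 0,
                               sub_freq[keep] / bg_freq[keep], Inf)),
    background_missing = unname(bg_freq[keep] == 0)
  )
  out[order(-out$substrate_freq, out$residue), , drop = FALSE]
}

#' Write a specificity profile as a class x residue TSV
#'
#' @param profile a `"specificity_profile"`.
#' @param path output file path.
#' @param what `"counts"` or `"frequencies"`.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, what = c("counts", "frequencies")) {
  what <- match.arg(what)
  m <- profile[[what]]
  df <- data.frame(class = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bar-chart rendering of a specificity profile
#'
#' Simple base-graphics rendering hook: grouped bars of per-class residue
#' frequencies for classes with at least one observation.
#'
#' @param x a `"specificity_profile"`.
#' @param ... passed to [graphics::barplot()].
#' @return The profile, invisibly.
#' @export
plot.specificity_profile <- function(x, ...) {
  keep <- x$n_per_class > 0
  m <- x$frequencies[keep, , drop = FALSE]
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                    xlab = if (x$position == "p1_prime") "P1' residue"
                           else "P1 residue",
                    ylab = "frequency", ...)
  invisible(x)
}
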