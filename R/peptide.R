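#' Construct a peptide object
#'
#' A peptide is an ordered string of one-letter amino-acid codes plus an
#' N-terminal state (free or acetylated) and a possibly-empty set of
#' methionine oxidations given as 1-based sequence positions.
#'
#' @param sequence one-letter amino-acid string (20 standard codes).
#' @param n_term `"free"` or `"acetyl"`.
#' @param ox integer vector of 1-based positions carrying an oxidation;
#'   every position must be a Met.
#' @param precursor optional free-text name of the protein precursor.
#' @return An object of class `"peptide"`.
#' @examples
#' peptide("ADEIAKAQVAR", n_term = "acetyl")
#' @export
peptide <- function(sequence, n_term = c("free", "acetyl"), ox = integer(),
                    precursor = NA_character_) {
  n_term <- match.arg(n_term)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty peptide sequence")
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(res, names(mass_constants()$residues))
  if (length(bad)) {
    stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "))
  }
  ox <- as.integer(ox)
  if (length(ox)) {
    if (any(ox < 1L | ox > length(res))) stop("oxidation position out of range")
    if (any(res[ox] != "M")) stop("oxidation is only supported on Met")
    ox <- sort(unique(ox))
  }
  structure(
    list(sequence = sequence, n_term = n_term, ox = ox,
         precursor = precursor),
    class = "peptide"
  )
}

#' Parse modification-annotated peptide notation
#'
#' Reads the notation used in quantitative peptidomics result tables: an
#' optional `"Ac-"` prefix marks an acetylated N-terminus, and `"ox"`
#' immediately after a residue letter marks oxidation of that residue
#' (Met only), e.g. `"SAMoxTEEAAVAIKAMAK"`.
#'
#' @param text annotated sequence string.
#' @param precursor optional precursor protein name.
#' @return A [peptide()] object. `format()` on the result round-trips to the
#'   identical input string.
#' @examples
#' parse_peptide("Ac-ADEIAKAQVAR")
#' parse_peptide("SAMoxTEEAAVAIKAMAK")
#' @export
parse_peptide <- function(text, precursor = NA_character_) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- trimws(text)
  n_term <- "free"
  if (startsWith(raw, "Ac-")) {
    n_term <- "acetyl"
    raw <- substr(raw, 4L, nchar(raw))
  }
  if (!nzchar(raw)) stop("empty peptide sequence in: ", text)
  chars <- strsplit(raw, "")[[1]]
  seq_chars <- character(0)
  ox <- integer(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "o" && i < length(chars) && chars[i + 1L] == "x") {
      if (length(seq_chars) == 0L) stop("'ox' with no preceding residue in: ", text)
      if (seq_chars[length(seq_chars)] != "M") {
        stop("'ox' after non-Met residue '", seq_chars[length(seq_chars)],
             "' in: ", text)
      }
      ox <- c(ox, length(seq_chars))
      i <- i + 2L
    } else {
      if (!ch %in% LETTERS) stop("unexpected character '", ch, "' in: ", text)
      seq_chars <- c(seq_chars, ch)
      i <- i + 1L
    }
  }
  peptide(paste(seq_chars, collapse = ""), n_term = n_term, ox = ox,
          precursor = precursor)
}

#' Coerce to a peptide object
#'
#' Character input is run through [parse_peptide()]; peptide objects pass
#' through unchanged.
#'
#' @param x a peptide object or a single annotated sequence string.
#' @return A [peptide()] object.
#' @export
as_peptide <- function(x) {
  if (inherits(x, "peptide")) return(x)
  if (is.character(x) && length(x) == 1L) return(parse_peptide(x))
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to peptide")
}

#' @export
format.peptide <- function(x, ...) {
  chars <- strsplit(x$sequence, "")[[1]]
  if (length(x$ox)) {
    chars[x$ox] <- paste0(chars[x$ox], "ox")
  }
  paste0(if (x$n_term == "acetyl") "Ac-" else "", paste(chars, collapse = ""))
}

#' @export
print.peptide <- function(x, ...) {
  cat("<peptide> ", format(x), sep = "")
  if (!is.na(x$precursor)) cat("  [", x$precursor, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
as.character.peptide <- function(x, ...) format(x)

peptide_length <- function(p) nchar(as_peptide(p)$sequence)

peptide_residues <- function(p) strsplit(as_peptide(p)$sequence, "")[[1]]
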