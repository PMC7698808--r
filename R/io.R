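#' Read and write LC-MS feature tables
#'
#' Features are tab-separated tables with columns `mz`, `intensity`, `rt`
#' (minutes), and optionally `charge` (empty/NA when unknown).
#'
#' @param path file path.
#' @return `read_feature_table()`: a data.frame of features.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  missing_cols <- setdiff(c("mz", "intensity", "rt"), names(df))
  if (length(missing_cols)) {
    stop("feature table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"charge" %in% names(df)) df$charge <- NA_integer_
  df
}

#' @param features data.frame of features.
#' @rdname read_feature_table
#' @return `write_feature_table()`: `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write MGF-style peak lists
#'
#' A minimal text peak-list dialect: one `BEGIN IONS`/`END IONS` block per
#' feature with `PEPMASS=<mz> <intensity>`, `RTINSECONDS=<rt*60>`, and an
#' optional `CHARGE=<z>+` line.
#'
#' @param path file path.
#' @return `read_mgf()`: a feature data.frame (`mz`, `intensity`, `rt`,
#'   `charge`).
#' @export
read_mgf <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  out <- list()
  cur <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "BEGIN IONS") {
      cur <- list(mz = NA_real_, intensity = NA_real_, rt = NA_real_,
                  charge = NA_integer_)
    } else if (ln == "END IONS") {
      if (is.null(cur)) stop("line ", i, ": END IONS without BEGIN IONS")
      out[[length(out) + 1L]] <- as.data.frame(cur)
      cur <- NULL
    } else if (!is.null(cur) && grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- kv[1]; val <- kv[2]
      if (key == "PEPMASS") {
        parts <- strsplit(val, "[[:space:]]+")[[1]]
        cur$mz <- as.numeric(parts[1])
        if (length(parts) > 1) cur$intensity <- as.numeric(parts[2])
      } else if (key == "RTINSECONDS") {
        cur$rt <- as.numeric(val) / 60
      } else if (key == "CHARGE") {
        cur$charge <- as.integer(sub("\\+$", "", val))
      }
    }
  }
  if (!is.null(cur)) stop("unterminated BEGIN IONS block")
  if (!length(out)) {
    return(data.frame(mz = numeric(), intensity = numeric(), rt = numeric(),
                      charge = integer()))
  }
  do.call(rbind, out)
}

#' @param features data.frame of features.
#' @rdname read_mgf
#' @return `write_mgf()`: `path`, invisibly.
#' @export
write_mgf <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(features))) {
    writeLines(c(
      "BEGIN IONS",
      sprintf("TITLE=feature_%d", i),
      sprintf("PEPMASS=%.6f %.6f", features$mz[i], features$intensity[i]),
      sprintf("RTINSECONDS=%.3f", features$rt[i] * 60),
      if (!is.na(features$charge[i])) {
        sprintf("CHARGE=%d+", as.integer(features$charge[i]))
      },
      "END IONS"
    ), con)
  }
  invisible(path)
}

#' Read a peptide table
#'
#' Tab-separated table with a `sequence` column in the annotated notation
#' (`Ac-` prefix, inline `ox`) and an optional `precursor` column.
#'
#' @param path file path.
#' @return List of [peptide()] objects.
#' @export
read_peptide_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  if (!"sequence" %in% names(df)) {
    stop("peptide table ", path, " lacks a 'sequence' column")
  }
  prec <- if ("precursor" %in% names(df)) df$precursor else
    rep(NA_character_, nrow(df))
  lapply(seq_len(nrow(df)), function(i) {
    tryCatch(parse_peptide(df$sequence[i], precursor = prec[i]),
             error = function(e) {
               stop("line ", i + 1L, " of ", path, ": ", conditionMessage(e))
             })
  })
}

#' Load a bundled quantification fixture
#'
#' Published carboxypeptidase Z characterization results transcribed as
#' tab-separated tables: dansyl-substrate kinetic constants
#' (`"kinetics"`), the cellular (HEK293T) library substrate and product
#' quantifications (`"hek_substrates"`, `"hek_products"`), and the tryptic
#' library quantification (`"tryptic"`). Ratio columns are named
#' `ratio_<conc>nM`; "n.d." entries load as NA.
#'
#' @param name fixture name.
#' @return A data.frame.
#' @examples
#' head(cpz_fixture("hek_substrates"))
#' @export
cpz_fixture <- function(name = c("kinetics", "hek_substrates",
                                 "hek_products", "tryptic")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("cpz_", name, ".tsv"),
                      package = "cpspec", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    na.strings = c("n.d.", "ND", "NA", ""))
}

#' Validate fixture theoretical masses
#'
#' Recomputes the neutral monoisotopic mass of every peptide in a fixture
#' table and compares it with the transcribed `theor_m` column. Rows whose
#' `mass_check` column is `"skip"` (transcribed values that are internally
#' inconsistent in the original report) are excluded.
#'
#' @param tab fixture data.frame with `sequence`, `theor_m`, and optionally
#'   `mass_check` columns.
#' @param tol_ppm maximum allowed deviation (default 10 ppm).
#' @return TRUE invisibly; disagreement raises an error naming the row.
#' @export
validate_fixture_masses <- function(tab, tol_ppm = 10) {
  keep <- if ("mass_check" %in% names(tab)) tab$mass_check != "skip" else
    rep(TRUE, nrow(tab))
  for (i in which(keep)) {
    calc <- monoisotopic_mass(tab$sequence[i])
    dev <- abs(ppm_error(tab$theor_m[i], calc))
    if (dev > tol_ppm) {
      stop("fixture mass mismatch for ", tab$sequence[i], ": transcribed ",
           tab$theor_m[i], ", computed ", round(calc, 4), " (",
           round(dev, 1), " ppm)")
    }
  }
  invisible(TRUE)
}
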