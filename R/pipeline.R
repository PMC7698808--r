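#' Pipeline configuration
#'
#' Collects every threshold and tolerance the analysis uses, with the
#' standard defaults: 50 ppm parent mass tolerance, 0.02 Da fragment
#' tolerance and 80% minimum fragment match for identification acceptance;
#' 10 ppm m/z and 0.5 min retention windows for multiplet grouping; 60%/20%
#' decrease cuts and 1.20 increase cut for classification; and the
#' permissive P1' residue set \{R, K\} used to restrict P1 profiling.
#'
#' @param design an [experiment_design()].
#' @param good_cut,weak_cut,product_cut classification thresholds, see
#'   [classify_record()].
#' @param parent_tol_ppm,frag_tol,min_fragment_match identification filter
#'   settings, see [accept_identification()].
#' @param mz_tol_ppm,rt_window,T_range,charges grouping settings, see
#'   [group_peaksets()].
#' @param permissive_p1prime residues considered permissive at P1' when
#'   building the restricted P1 profile.
#' @param seed RNG seed recorded with every run.
#' @return A `"pipeline_config"` list.
#' @export
pipeline_config <- function(design = cellular_design(),
                            good_cut = 0.60, weak_cut = 0.20,
                            product_cut = 1.20,
                            parent_tol_ppm = 50, frag_tol = 0.02,
                            min_fragment_match = 0.8,
                            mz_tol_ppm = 10, rt_window = 0.5,
                            T_range = 1:6, charges = 1:4,
                            permissive_p1prime = c("R", "K"),
                            seed = 1) {
  stopifnot(inherits(design, "experiment_design"),
            good_cut > weak_cut, weak_cut > 0, product_cut > 1)
  structure(
    list(design = design, good_cut = good_cut, weak_cut = weak_cut,
         product_cut = product_cut, parent_tol_ppm = parent_tol_ppm,
         frag_tol = frag_tol, min_fragment_match = min_fragment_match,
         mz_tol_ppm = mz_tol_ppm, rt_window = rt_window,
         T_range = T_range, charges = charges,
         permissive_p1prime = permissive_p1prime, seed = seed),
    class = "pipeline_config"
  )
}

# Candidate peptides for peakset identification: the library itself plus
# every one-residue C-terminal truncation (possible carboxypeptidase
# products).
identification_candidates <- function(library) {
  library <- lapply(library, as_peptide)
  cands <- library
  for (p in library) {
    n <- peptide_length(p)
    if (n >= 2L) {
      cands <- c(cands, list(
        peptide(substr(p$sequence, 1L, n - 1L), n_term = p$n_term,
                ox = p$ox[p$ox < n], precursor = p$precursor)
      ))
    }
  }
  cands[!duplicated(vapply(cands, format, character(1)))]
}

# Match one peakset against candidate peptides by tag count, charge and
# labeled m/z of its first present channel.
identify_peakset <- function(ps, candidates, design, mz_tol_ppm = 10) {
  present <- names(ps$channel_intensity)[!is.na(ps$channel_intensity)]
  if (!length(present)) return(NULL)
  base_label <- present[1]
  for (p in candidates) {
    if (count_tags(p) != ps$n_tags) next
    if (max(1L, predict_charge(p)) != ps$charge) next
    mz <- labeled_mz(p, base_label, ps$charge)
    if (abs(mz - ps$base_mz) <= mz * mz_tol_ppm * 1e-6) return(p)
  }
  NULL
}

#' Run the quantification-classification-profiling pipeline
#'
#' From raw features: groups label multiplets, computes enzyme/no-enzyme
#' ratios, optionally identifies peak sets against a candidate peptide
#' library (the library plus its one-residue C-terminal truncations),
#' classifies every record, and builds P1' and restricted P1 specificity
#' profiles from the identified records. From a pre-quantified ratio table
#' (a data.frame with a `sequence` column and `ratio_<conc>nM` columns, as
#' the bundled fixtures): skips straight to classification and profiling.
#'
#' The run is deterministic given input, configuration and seed; the `log`
#' element records every stage with the thresholds it used.
#'
#' @param input feature data.frame (`mz`, `intensity`, `rt`, `charge`) or
#'   ratio table (see above).
#' @param config a [pipeline_config()].
#' @param library optional list of peptides (objects or strings) used for
#'   peak-set identification when `input` is a feature table.
#' @return A list of class `"pipeline_result"` with `ratio_table`
#'   (data.frame incl. `classification`), `profile_p1prime`, `profile_p1`
#'   (restricted to permissive P1'), `preferences`
#'   (see [preference_summary()]), `n_unidentified`, and `log` (character).
#' @export
run_pipeline <- function(input, config = pipeline_config(), library = NULL) {
  stopifnot(is.data.frame(input))
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  note("seed=%d design=%s control=%s", config$seed, config$design$name,
       config$design$control)

  if (nrow(input) == 0L) {
    warning("empty input; returning empty report")
    empty <- build_profile(list(), character(0))
    return(structure(list(ratio_table = input, profile_p1prime = empty,
                          profile_p1 = empty, preferences = NULL,
                          n_unidentified = 0L,
                          log = c(log, "empty input")),
                     class = "pipeline_result"))
  }

  if ("sequence" %in% names(input)) {
    note("input: ratio table with %d rows", nrow(input))
    tab <- classify_table(input, config$good_cut, config$weak_cut,
                          config$product_cut)
    note("classify: good_cut=%.2f weak_cut=%.2f product_cut=%.2f",
         config$good_cut, config$weak_cut, config$product_cut)
    peps <- lapply(tab$sequence, parse_peptide)
    n_unident <- 0L
  } else {
    stopifnot(all(c("mz", "intensity", "rt") %in% names(input)))
    note("input: %d features", nrow(input))
    grouped <- group_peaksets(input, config$design, config$T_range,
                              config$mz_tol_ppm, config$rt_window,
                              config$charges)
    note("grouping: mz_tol=%g ppm rt_window=%g min -> %d peak sets, %d singletons",
         config$mz_tol_ppm, config$rt_window, length(grouped$peaksets),
         nrow(grouped$singletons))
    candidates <- if (!is.null(library)) {
      identification_candidates(library)
    } else list()
    rows <- list()
    peps <- list()
    n_unident <- 0L
    conc_cols <- sort(setdiff(config$design$conc_nM, 0), decreasing = TRUE)
    for (ps in grouped$peaksets) {
      ctrl <- config$design$control
      if (is.na(ps$channel_intensity[[ctrl]]) ||
          ps$channel_intensity[[ctrl]] <= 0) {
        note("skipped peak set at m/z %.4f: control channel missing",
             ps$base_mz)
        next
      }
      rec <- compute_ratios(ps, config$design)
      rec <- classify_record(rec, config$good_cut, config$weak_cut,
                             config$product_cut)
      hit <- if (length(candidates)) {
        identify_peakset(ps, candidates, config$design, config$mz_tol_ppm)
      } else NULL
      if (is.null(hit)) n_unident <- n_unident + 1L
      row <- data.frame(
        sequence = if (!is.null(hit)) format(hit) else NA_character_,
        base_mz = ps$base_mz, rt = ps$rt, z = ps$charge, t = ps$n_tags,
        classification = rec$classification
      )
      for (conc in conc_cols) {
        row[[sprintf("ratio_%gnM", conc)]] <-
          unname(rec$ratios[as.character(conc)])
      }
      rows[[length(rows) + 1L]] <- row
      peps[[length(peps) + 1L]] <- hit
    }
    tab <- do.call(rbind, rows)
    note("identification: %d of %d peak sets unidentified", n_unident,
         length(grouped$peaksets))
  }

  keep <- !vapply(peps, is.null, logical(1)) & !is.na(tab$sequence)
  id_peps <- peps[keep]
  id_classes <- tab$classification[keep]
  prof_p1p <- build_profile(id_peps, id_classes, position = "p1_prime")
  prof_p1 <- build_profile(id_peps, id_classes, position = "p1",
                           restrict_p1prime = config$permissive_p1prime)
  note("profiles: P1' over %d identified records; P1 restricted to {%s}",
       sum(keep), paste(config$permissive_p1prime, collapse = ","))
  prefs <- preference_summary(prof_p1p)

  structure(
    list(ratio_table = tab, profile_p1prime = prof_p1p, profile_p1 = prof_p1,
         preferences = prefs, n_unidentified = n_unident, log = log),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(table(x$ratio_table$classification))
  cat(x$log, sep = "\n")
  invisible(x)
}

#' Write a classification report
#'
#' Tab-separated report mirroring the published table layout; missing
#' ratios are rendered "n.d.".
#'
#' @param result a `"pipeline_result"` or its `ratio_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  tab <- if (inherits(result, "pipeline_result")) result$ratio_table else
    result
  out <- tab
  for (col in grep("^ratio_", names(out), value = TRUE)) {
    out[[col]] <- ifelse(is.na(out[[col]]), "n.d.",
                         format(out[[col]], trim = TRUE))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
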