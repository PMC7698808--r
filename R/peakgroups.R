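#' Multiplex experiment design
#'
#' Maps TMAB label channels to enzyme concentrations. Exactly one channel
#' must carry concentration 0 (the no-enzyme control).
#'
#' @param conc_nM named numeric vector, names drawn from D0/D3/D6/D9/D12,
#'   values in nM, distinct, one of them 0.
#' @param name free-text experiment name.
#' @return An object of class `"experiment_design"` with elements
#'   `conc_nM`, `control` (control label), and `name`.
#' @examples
#' experiment_design(c(D0 = 100, D3 = 10, D6 = 1, D9 = 0.1, D12 = 0))
#' @export
experiment_design <- function(conc_nM, name = "experiment") {
  stopifnot(is.numeric(conc_nM), !is.null(names(conc_nM)))
  if (!all(names(conc_nM) %in% tmab_labels())) {
    stop("labels must be among ", paste(tmab_labels(), collapse = ", "))
  }
  if (anyDuplicated(names(conc_nM))) stop("duplicate label channels")
  if (any(conc_nM < 0)) stop("enzyme concentrations must be >= 0")
  if (anyDuplicated(conc_nM)) stop("enzyme concentrations must be distinct")
  if (sum(conc_nM == 0) != 1L) stop("exactly one channel must be the no-enzyme control (0 nM)")
  # keep channels in increasing label-mass order
  conc_nM <- conc_nM[order(match(names(conc_nM), tmab_labels()))]
  structure(
    list(conc_nM = conc_nM, control = names(conc_nM)[conc_nM == 0],
         name = name),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("<experiment_design> ", x$name, "\n", sep = "")
  for (lab in names(x$conc_nM)) {
    cat(sprintf("  %-4s %8g nM%s\n", lab, x$conc_nM[[lab]],
                if (lab == x$control) "  (control)" else ""))
  }
  invisible(x)
}

#' Five-plex cellular-library design
#'
#' D0 = 100 nM, D3 = 10 nM, D6 = 1 nM, D9 = 0.1 nM enzyme; D12 = no-enzyme
#' control. This is the dose scheme used with a cellular (HEK293T-derived)
#' peptide library.
#'
#' @return An [experiment_design()].
#' @export
cellular_design <- function() {
  experiment_design(c(D0 = 100, D3 = 10, D6 = 1, D9 = 0.1, D12 = 0),
                    name = "cellular 5-plex")
}

#' Four-plex tryptic-library design
#'
#' D0 = no-enzyme control; D3 = 1 nM, D6 = 10 nM, D9 = 100 nM enzyme.
#'
#' @return An [experiment_design()].
#' @export
tryptic_design <- function() {
  experiment_design(c(D0 = 0, D3 = 1, D6 = 10, D9 = 100),
                    name = "tryptic 4-plex")
}

# Expected m/z offset of each design channel relative to the first design
# channel, for a peptide carrying t_tags tags at charge z.
channel_mz_offsets <- function(design, t_tags, z,
                               constants = mass_constants()) {
  tags <- constants$tags[names(design$conc_nM)]
  t_tags * (tags - tags[1]) / z
}

#' Group LC-MS features into isotopic-label multiplets
#'
#' Scans a feature list for peak sets: groups of >= 2 co-eluting features at
#' one charge whose m/z spacings match the label-channel tag-mass increments
#' T * (tag mass difference) / Z for some tag count T. Features are ordered
#' deterministically by (retention time, m/z); each feature joins at most
#' one set; among competing (T, Z, anchor-channel) interpretations the one
#' matching the most channels and then the smallest summed m/z residual
#' wins.
#'
#' @param features data.frame with columns `mz`, `intensity`, `rt`, and
#'   optionally `charge` (NA allowed).
#' @param design an [experiment_design()].
#' @param T_range candidate tag counts (default 1:6).
#' @param mz_tol_ppm m/z matching tolerance in ppm (default 10).
#' @param rt_window maximum retention-time spread of a set in minutes
#'   (default 0.5).
#' @param charges candidate charges tried when a feature's charge is unknown
#'   (default 1:4).
#' @param constants mass constants.
#' @return A list with `peaksets` (list of `"peakset"` objects carrying
#'   `charge`, `n_tags`, `base_mz`, `rt`, and `channel_intensity`, a named
#'   vector over design labels with NA for absent channels) and `singletons`
#'   (data.frame of unassigned features).
#' @export
group_peaksets <- function(features, design, T_range = 1:6,
                           mz_tol_ppm = 10, rt_window = 0.5,
                           charges = 1:4, constants = mass_constants()) {
  stopifnot(is.data.frame(features),
            all(c("mz", "intensity", "rt") %in% names(features)))
  if (!"charge" %in% names(features)) features$charge <- NA_integer_
  features <- features[order(features$rt, features$mz), , drop = FALSE]
  rownames(features) <- NULL
  n <- nrow(features)
  assigned <- logical(n)
  labels <- names(design$conc_nM)
  n_chan <- length(labels)
  peaksets <- list()

  for (i in seq_len(n)) {
    if (assigned[i]) next
    z_cand <- if (!is.na(features$charge[i])) features$charge[i] else charges
    best <- NULL
    for (z in z_cand) {
      for (t_tags in T_range[T_range <= z]) {
        offsets <- channel_mz_offsets(design, t_tags, z, constants)
        # anchor feature i at channel position a; match later channels only
        for (a in seq_len(n_chan - 1L)) {
          exp_mz <- features$mz[i] + (offsets - offsets[a])
          members <- rep(NA_integer_, n_chan)
          members[a] <- i
          resid <- 0
          for (cpos in seq(a + 1L, n_chan)) {
            cand <- which(!assigned &
                            abs(features$rt - features$rt[i]) <= rt_window &
                            abs(features$mz - exp_mz[cpos]) <=
                              exp_mz[cpos] * mz_tol_ppm * 1e-6)
            cand <- setdiff(cand, members)
            if (length(cand)) {
              err <- abs(features$mz[cand] - exp_mz[cpos])
              pick <- cand[which.min(err)]
              members[cpos] <- pick
              resid <- resid + min(err)
            }
          }
          n_found <- sum(!is.na(members))
          if (n_found >= 2L) {
            cand_set <- list(members = members, z = z, t = t_tags,
                             n_found = n_found, resid = resid)
            if (is.null(best) || cand_set$n_found > best$n_found ||
                (cand_set$n_found == best$n_found &&
                 cand_set$resid < best$resid)) {
              best <- cand_set
            }
          }
        }
      }
    }
    if (!is.null(best)) {
      idx <- best$members
      intens <- rep(NA_real_, n_chan)
      intens[!is.na(idx)] <- features$intensity[idx[!is.na(idx)]]
      names(intens) <- labels
      ps <- structure(
        list(charge = best$z, n_tags = best$t,
             base_mz = features$mz[i],
             rt = mean(features$rt[idx[!is.na(idx)]]),
             channel_intensity = intens,
             feature_rows = idx),
        class = "peakset"
      )
      peaksets[[length(peaksets) + 1L]] <- ps
      assigned[idx[!is.na(idx)]] <- TRUE
    }
  }
  list(peaksets = peaksets,
       singletons = features[!assigned, , drop = FALSE])
}

#' @export
print.peakset <- function(x, ...) {
  cat(sprintf("<peakset> base m/z %.4f  Z=%d T=%d  rt %.2f min\n",
              x$base_mz, x$charge, x$n_tags, x$rt))
  print(x$channel_intensity)
  invisible(x)
}

#' Per-concentration intensity ratios of a peak set
#'
#' For each non-control channel present in the peak set, the ratio of its
#' peak intensity to the no-enzyme control intensity. Absent channels give
#' missing ratios (reported as NA, rendered "n.d." in reports); a missing or
#' zero control channel is an error. No normalisation is applied: raw peak
#' intensities are compared (optionally see `normalize` in
#' [run_pipeline()]).
#'
#' @param ps a `"peakset"` from [group_peaksets()], or a named numeric
#'   vector of per-label intensities.
#' @param design an [experiment_design()].
#' @param peptide optional peptide (object or string) identified for the set.
#' @return A `"ratio_record"`: list with `peptide`, `ratios` (named numeric,
#'   names are enzyme concentrations in nM, NA for absent channels) and
#'   `classification` (initially NA, see [classify_record()]).
#' @examples
#' compute_ratios(c(D0 = 20, D3 = 940, D6 = 1080, D9 = 1000, D12 = 1000),
#'                cellular_design())
#' @export
compute_ratios <- function(ps, design, peptide = NULL) {
  intens <- if (inherits(ps, "peakset")) ps$channel_intensity else ps
  stopifnot(is.numeric(intens), !is.null(names(intens)))
  ctrl <- design$control
  if (!ctrl %in% names(intens) || is.na(intens[[ctrl]]) ||
      intens[[ctrl]] <= 0) {
    id <- if (inherits(ps, "peakset")) {
      sprintf("peak set at m/z %.4f", ps$base_mz)
    } else "intensity vector"
    stop("missing or non-positive control channel (", ctrl, ") in ", id)
  }
  noncontrol <- setdiff(names(design$conc_nM), ctrl)
  ratios <- vapply(noncontrol, function(lab) {
    if (lab %in% names(intens) && !is.na(intens[[lab]])) {
      intens[[lab]] / intens[[ctrl]]
    } else NA_real_
  }, numeric(1))
  names(ratios) <- as.character(design$conc_nM[noncontrol])
  ratios <- ratios[order(as.numeric(names(ratios)), decreasing = TRUE)]
  structure(
    list(peptide = if (!is.null(peptide)) as_peptide(peptide) else NULL,
         ratios = ratios, classification = NA_character_),
    class = "ratio_record"
  )
}

#' @export
print.ratio_record <- function(x, ...) {
  cat("<ratio_record>")
  if (!is.null(x$peptide)) cat(" ", format(x$peptide))
  if (!is.na(x$classification)) cat("  [", x$classification, "]", sep = "")
  cat("\n")
  shown <- ifelse(is.na(x$ratios), "n.d.", sprintf("%.2f", x$ratios))
  cat(paste0("  ", names(x$ratios), " nM: ", shown, collapse = "\n"), "\n")
  invisible(x)
}
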