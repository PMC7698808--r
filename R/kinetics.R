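#' Michaelis-Menten velocity
#'
#' v = Vmax * S / (Km + S).
#'
#' @param S substrate concentration(s), uM, >= 0.
#' @param Vmax maximum velocity (same units as the returned velocity).
#' @param Km Michaelis constant, uM, > 0.
#' @return Velocity, vectorised over `S`.
#' @examples
#' mm_velocity(1905, Vmax = 0.53, Km = 1905)  # half of Vmax
#' @export
mm_velocity <- function(S, Vmax, Km) {
  if (Km <= 0) stop("Km must be positive")
  if (any(S < 0)) stop("substrate concentrations must be >= 0")
  Vmax * S / (Km + S)
}

#' Fit the Michaelis-Menten model to substrate-velocity data
#'
#' Nonlinear least-squares fit of v = Vmax * S / (Km + S). Starting values
#' follow the usual heuristic: Vmax0 is the largest observed velocity and
#' Km0 is the substrate concentration at half of Vmax0, linearly
#' interpolated. The primary optimiser is [stats::nls()] (Gauss-Newton);
#' on failure the Levenberg-Marquardt implementation in
#' [minpack.lm::nlsLM()] is tried, and an error reporting the residuals is
#' raised if neither converges.
#'
#' @param S substrate concentrations (uM).
#' @param v velocities (arbitrary rate units; uM/s if `enzyme_nM` is given
#'   so that kcat comes out in 1/s).
#' @param enzyme_nM optional enzyme concentration in nM; when supplied,
#'   kcat = Vmax / (enzyme in uM) and kcat/Km are reported.
#' @return A `"kinetic_fit"`: list with `Km`, `Vmax`, `kcat`,
#'   `kcat_over_Km`, `se` (named standard errors from the fit covariance),
#'   `residuals`, `data`, and `enzyme_nM`. `kcat` fields are NA without
#'   `enzyme_nM`.
#' @examples
#' S <- c(0, 66, 125, 250, 500, 1000, 1500, 2500)
#' v <- mm_velocity(S, Vmax = 0.53, Km = 1905)
#' fit_mm(S, v, enzyme_nM = 100)
#' @export
fit_mm <- function(S, v, enzyme_nM = NULL) {
  stopifnot(length(S) == length(v), all(S >= 0))
  if (length(unique(S)) < 4L) stop("need >= 4 distinct substrate concentrations")
  if (all(v == 0)) stop("all velocities are zero; nothing to fit")
  df <- data.frame(S = S, v = v)
  vmax0 <- max(v)
  half <- vmax0 / 2
  ord <- order(S)
  km0 <- stats::approx(v[ord], S[ord], xout = half, ties = mean)$y
  if (is.na(km0) || km0 <= 0) km0 <- stats::median(S[S > 0])
  fit <- tryCatch(
    stats::nls(v ~ Vmax * S / (Km + S), data = df,
               start = list(Vmax = vmax0, Km = km0)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(v ~ Vmax * S / (Km + S), data = df,
                        start = list(Vmax = vmax0, Km = km0),
                        lower = c(Vmax = 0, Km = 1e-9)),
      error = function(e) NULL
    )
  }
  if (is.null(fit)) {
    pred0 <- mm_velocity(S, vmax0, km0)
    stop("Michaelis-Menten fit did not converge; residuals at start values: ",
         paste(sprintf("%.3g", v - pred0), collapse = ", "))
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(Vmax = NA_real_, Km = NA_real_))
  kcat <- kcat_se <- kkm <- kkm_se <- NA_real_
  if (!is.null(enzyme_nM)) {
    e_uM <- enzyme_nM / 1000
    kcat <- unname(est["Vmax"]) / e_uM
    kcat_se <- unname(se["Vmax"]) / e_uM
    kkm <- kcat / unname(est["Km"])
    # first-order error propagation for the ratio
    kkm_se <- abs(kkm) * sqrt((kcat_se / kcat)^2 +
                                (unname(se["Km"]) / unname(est["Km"]))^2)
  }
  structure(
    list(Km = unname(est["Km"]), Vmax = unname(est["Vmax"]),
         kcat = kcat, kcat_over_Km = kkm,
         se = c(Vmax = unname(se["Vmax"]), Km = unname(se["Km"]),
                kcat = kcat_se, kcat_over_Km = kkm_se),
         residuals = unname(stats::residuals(fit)),
         data = df, enzyme_nM = enzyme_nM),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("<kinetic_fit>\n")
  cat(sprintf("  Km   = %.4g +/- %.2g uM\n", x$Km, x$se[["Km"]]))
  cat(sprintf("  Vmax = %.4g +/- %.2g\n", x$Vmax, x$se[["Vmax"]]))
  if (!is.na(x$kcat)) {
    cat(sprintf("  kcat = %.4g +/- %.2g 1/s   ([E] = %g nM)\n",
                x$kcat, x$se[["kcat"]], x$enzyme_nM))
    cat(sprintf("  kcat/Km = %.4g +/- %.2g 1/(uM s)\n",
                x$kcat_over_Km, x$se[["kcat_over_Km"]]))
  }
  invisible(x)
}

#' Generate a synthetic kinetic dataset
#'
#' Velocities from [mm_velocity()] at the supplied substrate
#' concentrations, optionally with multiplicative Gaussian noise
#' (v * (1 + N(0, cv))).
#'
#' @param Km,kcat generating parameters (uM, 1/s).
#' @param enzyme_nM enzyme concentration (nM); Vmax = kcat * [E].
#' @param S substrate concentrations (uM); default the typical assay series.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (default 0 = noiseless).
#' @return data.frame with columns `S` and `v`.
#' @export
simulate_kinetics <- function(Km, kcat, enzyme_nM = 100,
                              S = c(0, 66, 125, 250, 500, 1000, 1500, 2500),
                              noise_cv = 0) {
  vmax <- kcat * enzyme_nM / 1000
  v <- mm_velocity(S, vmax, Km)
  if (noise_cv > 0) v <- v * (1 + stats::rnorm(length(v), 0, noise_cv))
  data.frame(S = S, v = v)
}
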