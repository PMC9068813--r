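# EMSA quantification: release fractions from gel densitometry, the
# quadratic (ligand-depletion) single-site binding model, apparent-Kd
# fitting, and pause-release time courses.

#' Fraction of NELF released from the paused elongation complex
#'
#' Densitometric release readout from one gel lane:
#' `fraction = I(Pol II-DSIF) / (I(Pol II-DSIF) + I(Pol II-DSIF-NELF))`.
#' The Pol II-DSIF band grows as the eRNA strips NELF off the paused
#' elongation complex (PEC), so the fraction runs from 0 (no release) to 1
#' (complete release).
#'
#' @param i_poldsif Band intensity of the Pol II-DSIF complex (>= 0).
#' @param i_pec Band intensity of the intact PEC (Pol II-DSIF-NELF) (>= 0).
#' @return Release fraction in \[0, 1\]; `NA` (with a warning) when both
#'   intensities are zero.
#' @export
release_fraction <- function(i_poldsif, i_pec) {
  if (any(i_poldsif < 0) || any(i_pec < 0))
    stop("band intensities must be non-negative")
  total <- i_poldsif + i_pec
  out <- ifelse(total == 0, NA_real_, i_poldsif / total)
  if (anyNA(out)) warning("lane(s) with zero total intensity: fraction undefined")
  out
}

#' Quadratic single-site (ligand-depletion) binding model
#'
#' Fraction of receptor bound at total ligand concentration `L` when ligand
#' depletion cannot be neglected (receptor and ligand concentrations are
#' comparable, as in the EMSA release setup where the PEC is at 0.1 uM and
#' the eRNA series starts at 0.15 uM):
#' \deqn{f(L) = A \frac{(R + L + K_d) - \sqrt{(R + L + K_d)^2 - 4RL}}{2R}}
#' For `kd >> R` this converges to the familiar hyperbola `A L / (L + kd)`.
#'
#' @param L Total ligand (eRNA) concentration(s), uM, >= 0.
#' @param kd Apparent dissociation constant, uM, > 0.
#' @param amplitude Saturating fraction `A`, in (0, 1.2].
#' @param R Total receptor (PEC) concentration, uM, > 0. Default 0.1.
#' @return Model fraction(s) in \[0, amplitude\].
#' @export
quadratic_model <- function(L, kd, amplitude = 1, R = 0.1) {
  if (any(L < 0)) stop("ligand concentration must be >= 0")
  if (kd <= 0) stop("kd must be > 0")
  if (R <= 0) stop("receptor total must be > 0")
  s <- R + L + kd
  disc <- s^2 - 4 * R * L
  if (any(disc < 0)) stop("negative discriminant: invalid inputs")
  amplitude * (s - sqrt(disc)) / (2 * R)
}

#' Build a binding curve object
#'
#' @param concentrations Ligand concentrations, uM, strictly increasing.
#' @param fractions Release fractions in \[0, 1\], one per concentration, or
#'   a matrix with one column per replicate.
#' @param receptor_total Total receptor concentration, uM. Default 0.1.
#' @return An object of class `binding_curve`.
#' @export
binding_curve <- function(concentrations, fractions, receptor_total = 0.1) {
  fractions <- as.matrix(fractions)
  if (nrow(fractions) != length(concentrations))
    stop("concentrations and fractions lengths differ")
  if (is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be strictly increasing")
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (any(fractions < 0 | fractions > 1, na.rm = TRUE))
    stop("fractions must lie in [0, 1]")
  structure(
    list(concentrations = concentrations, fractions = fractions,
         receptor_total = receptor_total),
    class = "binding_curve"
  )
}

#' @export
print.binding_curve <- function(x, ...) {
  cat("binding_curve:", length(x$concentrations), "concentrations,",
      ncol(x$fractions), "replicate(s), R =", x$receptor_total, "uM\n")
  invisible(x)
}

#' Fit the quadratic binding model to a release curve
#'
#' Nonlinear least squares (Levenberg-Marquardt, via \pkg{minpack.lm}) over
#' `(kd, amplitude)`, or over `kd` alone when the amplitude is fixed.
#' Initialisation uses `amplitude = max(fraction)` and `kd` at the
#' concentration nearest half-maximum, plus a multistart over five
#' log-spaced `kd` values; the best residual is kept. With per-replicate
#' fraction columns the pointwise mean is fitted (matching quantification of
#' mean curves across gel replicates); set `per_replicate = TRUE` to fit
#' each column separately.
#'
#' @param curve A [binding_curve()].
#' @param fix_amplitude Optional fixed amplitude (e.g. 1 for complete
#'   conversion); `NULL` (default) fits it in (0, 1.2].
#' @param per_replicate Fit each replicate column separately and return a
#'   list of fits.
#' @return An object of class `binding_fit` with elements `kd`, `amplitude`,
#'   `residual_sum`, `converged`, `kd_stderr` (from the Jacobian curvature
#'   at the optimum), and `fitted` (model values at the input
#'   concentrations).
#' @export
fit_binding <- function(curve, fix_amplitude = NULL, per_replicate = FALSE) {
  stopifnot(inherits(curve, "binding_curve"))
  if (per_replicate && ncol(curve$fractions) > 1L) {
    fits <- lapply(seq_len(ncol(curve$fractions)), function(j) {
      sub <- binding_curve(curve$concentrations, curve$fractions[, j],
                           curve$receptor_total)
      fit_binding(sub, fix_amplitude = fix_amplitude)
    })
    return(fits)
  }
  L <- curve$concentrations
  y <- rowMeans(curve$fractions)
  R <- curve$receptor_total
  if (length(L) < 3L) stop("need >= 3 concentration points")

  failed <- function(msg) {
    structure(list(kd = NA_real_, amplitude = NA_real_,
                   residual_sum = NA_real_, converged = FALSE,
                   kd_stderr = NA_real_, fitted = rep(NA_real_, length(L)),
                   message = msg),
              class = "binding_fit")
  }
  if (stats::sd(y) == 0) return(failed("flat curve: kd unidentifiable"))

  amp0 <- max(y)
  if (amp0 <= 0) return(failed("all fractions zero: unidentifiable"))
  kd_half <- L[which.min(abs(y - amp0 / 2))]
  kd_starts <- unique(c(kd_half, 10^seq(log10(min(L) / 10), log10(max(L) * 10),
                                        length.out = 5)))
  best <- NULL
  for (kd0 in kd_starts) {
    fit <- tryCatch({
      if (is.null(fix_amplitude)) {
        minpack.lm::nlsLM(
          y ~ quadratic_model(L, kd, amplitude, R),
          start = list(kd = kd0, amplitude = min(amp0, 1.2)),
          lower = c(kd = 1e-8, amplitude = 1e-6),
          upper = c(kd = Inf, amplitude = 1.2),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        )
      } else {
        amplitude <- fix_amplitude
        minpack.lm::nlsLM(
          y ~ quadratic_model(L, kd, amplitude, R),
          start = list(kd = kd0),
          lower = c(kd = 1e-8),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        )
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(failed("no multistart converged"))

  co <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients["kd", "Std. Error"],
                 error = function(e) NA_real_)
  structure(
    list(
      kd           = unname(co[["kd"]]),
      amplitude    = if (is.null(fix_amplitude)) unname(co[["amplitude"]]) else fix_amplitude,
      residual_sum = best$rss,
      converged    = TRUE,
      kd_stderr    = se,
      fitted       = stats::fitted(best$fit),
      message      = "ok"
    ),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("binding_fit: apparent Kd = %.4g uM (SE %.3g), amplitude = %.3g, RSS = %.3g\n",
                x$kd, x$kd_stderr, x$amplitude, x$residual_sum))
  } else {
    cat("binding_fit: not converged (", x$message, ")\n", sep = "")
  }
  invisible(x)
}

#' Pause-release time course from lane densitometry
#'
#' For each time point, the intensity of the first transcript band above the
#' pause site is normalised against the total intensity of the corresponding
#' lane, yielding the released fraction over time.
#'
#' @param band_intensity Target-band intensity per lane (>= 0).
#' @param lane_total Total lane intensity per lane (>= 0).
#' @param times Time points (min), ordered, one per lane.
#' @return Data frame with columns `time` and `released_fraction` (`NA`,
#'   flagged with a warning, where the lane total is zero).
#' @export
pause_release_timecourse <- function(band_intensity, lane_total, times) {
  if (length(band_intensity) != length(times) ||
      length(lane_total) != length(times))
    stop("one band and lane-total intensity needed per time point")
  if (is.unsorted(times)) stop("times must be ordered")
  if (any(band_intensity < 0) || any(lane_total < 0))
    stop("intensities must be non-negative")
  frac <- ifelse(lane_total == 0, NA_real_, band_intensity / lane_total)
  if (anyNA(frac)) warning("lane(s) with zero total intensity: fraction undefined")
  data.frame(time = times, released_fraction = frac)
}
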