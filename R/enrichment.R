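#' Isotopic enrichment curve
#'
#' IE(t) = 100 * (F_t - F_0): the percentage-point excess of the labeled
#' isotope ratio over its pre-dose baseline. IE at t = 0 is exactly zero by
#' construction; negative values at later times (baseline noise) are
#' retained, not clamped.
#'
#' @param times Sampling times (minutes), strictly increasing from 0.
#' @param f_series Isotope ratios F_t per timepoint, in [0, 1].
#' @param f0 Baseline ratio; defaults to the t = 0 entry of
#'   \code{f_series}.
#' @param metabolite Optional metabolite name carried on the curve.
#' @return A list of class \code{enrichment_curve} with fields
#'   \code{metabolite}, \code{times}, \code{ie} (percent) and
#'   \code{normalized} flags.
#' @export
compute_enrichment <- function(times, f_series, f0 = NULL,
                               metabolite = NA_character_) {
  stopifnot(length(times) == length(f_series))
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing from 0")
  }
  if (is.null(f0)) f0 <- f_series[1]
  if (any(f_series < 0 | f_series > 1, na.rm = TRUE) || f0 < 0 || f0 > 1) {
    stop("isotope ratios must lie in [0, 1]")
  }
  ie <- 100 * (f_series - f0)
  ie[1] <- 0
  structure(list(metabolite = metabolite, times = times, ie = ie,
                 normalized = c(dose = FALSE, concentration = FALSE)),
            class = "enrichment_curve")
}

#' Normalize an enrichment curve for dose and endogenous concentration
#'
#' Multiplies the curve by the dose factor (nominal dose / actual dose) and
#' by the metabolite's concentration factor (subject mean unlabeled signal /
#' control mean unlabeled signal), converting enrichment towards a relative
#' label-amount scale against the control pools. Normalizing twice is an
#' error.
#'
#' @param curve An \code{enrichment_curve}.
#' @param dose_factor Nominal / actual dose; > 0.
#' @param conc_factor Subject pool / control pool signal ratio; > 0.
#' @return The normalized curve with flags set.
#' @export
normalize_curve <- function(curve, dose_factor = 1, conc_factor = 1) {
  stopifnot(inherits(curve, "enrichment_curve"))
  if (dose_factor <= 0 || conc_factor <= 0) stop("factors must be > 0")
  if (any(curve$normalized)) stop("curve is already normalized")
  curve$ie <- curve$ie * dose_factor * conc_factor
  curve$normalized[] <- TRUE
  curve
}

#' Area under an enrichment curve
#'
#' Trapezoidal area over the test window (0 to \code{t_end} minutes) using
#' the actual sampling times. The curve must reach \code{t_end}; no
#' extrapolation is performed. A net-negative curve yields a negative area.
#'
#' @param curve An \code{enrichment_curve}, or a numeric vector of IE values
#'   (in which case \code{times} must be given).
#' @param times Sampling times when \code{curve} is a plain vector.
#' @param t_end End of the test window (minutes), default 120.
#' @return Area in percent x minutes.
#' @export
auc <- function(curve, times = NULL, t_end = 120) {
  if (inherits(curve, "enrichment_curve")) {
    times <- curve$times
    ie <- curve$ie
  } else {
    ie <- curve
    if (is.null(times)) stop("times required for a plain numeric curve")
  }
  if (max(times) < t_end) {
    stop("curve does not reach ", t_end, " min; refusing to extrapolate")
  }
  inside <- times <= t_end
  pracma::trapz(times[inside], ie[inside])
}

#' Concentration-stability exclusion rule
#'
#' Metabolites whose total (labeled + unlabeled, IS-normalized) signal
#' varies strongly over the test are excluded from the semi-quantitative
#' sums: excluded iff the CV across timepoints strictly exceeds the
#' threshold (a CV of exactly 10\% is included).
#'
#' @param total_signal Per-timepoint total-signal proxy (>= 3 timepoints).
#' @param threshold CV threshold, default 0.10.
#' @return List with \code{include} (logical) and \code{cv}.
#' @export
concentration_stability_filter <- function(total_signal, threshold = 0.10) {
  x <- total_signal[!is.na(total_signal)]
  if (length(x) < 3) stop("need >= 3 timepoints for the stability filter")
  cv <- stats::sd(x) / mean(x)
  list(include = !(cv > threshold), cv = cv)
}
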