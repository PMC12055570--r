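#' Internal-standard normalization
#'
#' Scales every integrated peak area by its internal-standard response, so
#' that run-to-run injection and ionization drift cancels. Labeled and
#' unlabeled isotopologues of a replicate share the same IS divisor, which
#' leaves isotope ratios untouched.
#'
#' @param records Raw peak-record data.frame (columns subject_id, matrix,
#'   time_min, metabolite, isotopologue, replicate, area, is_area).
#' @return The records with an added \code{value = area / is_area} column
#'   and a \code{provenance} column ("measured" for every cell at this
#'   stage; absent areas keep NA values).
#' @export
normalize_to_is <- function(records) {
  req <- c("subject_id", "matrix", "time_min", "metabolite", "isotopologue",
           "replicate", "area", "is_area")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  bad <- !is.na(records$area) & (is.na(records$is_area) | records$is_area <= 0)
  if (any(bad)) {
    stop("missing or non-positive internal-standard area for ", sum(bad),
         " record(s); run flagged invalid")
  }
  records$value <- records$area / records$is_area
  records$provenance <- "measured"
  records
}

#' Triplicate outlier detection (30\% rule)
#'
#' A run is omitted iff its relative deviation from the mean of the other
#' two runs of the triplicate exceeds the threshold. If two or more runs
#' are flagged (no consensus pair exists) the whole triplicate is marked
#' invalid rather than keeping an arbitrary pair. With fewer than three
#' values present no outlier test is applied.
#'
#' @param values Numeric vector of up to 3 replicate values (NAs allowed).
#' @param threshold Relative-deviation threshold, default 0.30.
#' @return A list with \code{keep} (logical per input value), \code{invalid}
#'   (whole-triplicate flag) and \code{values} (kept values).
#' @export
detect_triplicate_outliers <- function(values, threshold = 0.30) {
  keep <- !is.na(values)
  invalid <- FALSE
  idx <- which(keep)
  if (length(idx) == 3) {
    dev <- vapply(1:3, function(i) {
      others <- mean(values[idx[-i]])
      if (others == 0) return(Inf * (values[idx[i]] != 0))
      abs(values[idx[i]] - others) / abs(others)
    }, numeric(1))
    flagged <- dev > threshold
    if (sum(flagged) == 1) {
      keep[idx[flagged]] <- FALSE
    } else if (sum(flagged) >= 2) {
      keep[] <- FALSE
      invalid <- TRUE
    }
  }
  list(keep = keep, invalid = invalid, values = values[keep])
}

#' Impute missing values in a per-timepoint series
#'
#' Completion order: (1) a missing replicate is imputed as the mean of the
#' surviving replicates at that timepoint (this happens upstream when
#' replicates are averaged); (2) a fully missing non-baseline timepoint is
#' linearly interpolated between the nearest measured timepoints (nearest
#' value carried at the edges); (3) a missing baseline isotope ratio is set
#' to the 15N natural-abundance constant. Measured values are never altered,
#' which makes the operation idempotent.
#'
#' @param times Timepoints (minutes), sorted, including 0.
#' @param values Per-timepoint values with NAs to fill.
#' @param baseline Value used for a missing t = 0 entry; default the 15N
#'   natural abundance. Use NULL to skip baseline substitution.
#' @return Completed numeric vector, plus a "provenance" attribute marking
#'   "measured" or "imputed" per timepoint.
#' @export
impute_missing <- function(times, values, baseline = natural_abundance("15N")) {
  stopifnot(length(times) == length(values))
  if (all(is.na(values))) stop("all timepoints missing; metabolite unusable")
  prov <- ifelse(is.na(values), "imputed", "measured")
  if (!is.null(baseline) && times[1] == 0 && is.na(values[1])) {
    values[1] <- baseline
  }
  if (anyNA(values)) {
    ok <- !is.na(values)
    if (sum(ok) == 1) {
      values[!ok] <- values[ok]
    } else {
      values <- stats::approx(times[ok], values[ok], xout = times,
                              rule = 2)$y
    }
  }
  attr(values, "provenance") <- prov
  values
}

#' Isotope ratio: labeled over total signal
#'
#' F = labeled / (labeled + unlabeled), e.g. 15N / (14N + 15N).
#'
#' @param labeled,unlabeled Non-negative intensities (vectorized).
#' @return Ratio in [0, 1]; NA propagates.
#' @export
isotope_ratio <- function(labeled, unlabeled) {
  if (any(labeled < 0, na.rm = TRUE) || any(unlabeled < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative")
  }
  tot <- labeled + unlabeled
  if (any(!is.na(tot) & tot == 0)) {
    stop("undefined isotope ratio: labeled and unlabeled both zero")
  }
  labeled / tot
}
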