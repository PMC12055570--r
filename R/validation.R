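#' Lower limit of quantitative differentiation (LLOQD)
#'
#' The smallest enrichment reliably distinguishable from the natural-
#' abundance baseline: three times the standard deviation (critical
#' difference) of the baseline isotope ratio, expressed in percent
#' enrichment.
#'
#' @param baseline_ratios Replicate baseline isotope ratios (fractions);
#'   at least 3 required.
#' @param as_percent If TRUE (default) the input fractions are converted to
#'   percent-enrichment units; set FALSE if the input is already in percent.
#' @return LLOQD in percent enrichment.
#' @export
lloqd <- function(baseline_ratios, as_percent = TRUE) {
  if (length(baseline_ratios) < 3) stop("need >= 3 baseline replicates")
  s <- stats::sd(baseline_ratios)
  if (s == 0) warning("zero baseline SD; LLOQD degenerate at 0")
  3 * s * if (as_percent) 100 else 1
}

#' Precision as coefficient of variation
#'
#' CV = 100 * SD / mean using the sample (n - 1) standard deviation.
#' Intra-experiment precision uses within-day replicates; inter-experiment
#' precision uses day-level means across days.
#'
#' @param values Replicate (or day-mean) measurements, >= 2.
#' @return CV in percent.
#' @export
precision_cv <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need >= 2 values for a CV")
  m <- mean(values)
  if (m == 0) stop("undefined CV: mean is zero")
  100 * stats::sd(values) / m
}

#' Mass accuracy in parts per million
#'
#' ppm = 1e6 * (measured - exact) / exact; a measured mass below the exact
#' mass yields a negative ppm.
#'
#' @param measured_mz,exact_mz Measured and theoretical monoisotopic m/z.
#' @return ppm error (vectorized).
#' @export
mass_accuracy_ppm <- function(measured_mz, exact_mz) {
  if (any(exact_mz <= 0)) stop("exact m/z must be > 0")
  1e6 * (measured_mz - exact_mz) / exact_mz
}

#' Aggregate mass accuracy over runs
#' @param ppm Vector of per-run ppm errors.
#' @return List with \code{mean} and \code{rms}.
#' @export
mass_accuracy_summary <- function(ppm) {
  list(mean = mean(ppm), rms = sqrt(mean(ppm^2)))
}

#' Carry-over check
#'
#' Percentage of a metabolite's signal detected in a blank run injected
#' directly after a sample.
#'
#' @param blank_after_sample Blank-run intensity.
#' @param sample Sample-run intensity (> 0).
#' @param threshold Pass threshold in percent; default 0 (below detection).
#' @return List with \code{percent} and \code{pass}.
#' @export
carryover_check <- function(blank_after_sample, sample, threshold = 0) {
  if (sample <= 0) stop("sample intensity must be > 0")
  pct <- 100 * blank_after_sample / sample
  list(percent = pct, pass = pct <= threshold)
}

#' Plasma vs dried-blood-spot correlation
#'
#' Pearson correlation over paired enrichment values pooled across
#' metabolites and timepoints.
#'
#' @param plasma,dbs Paired enrichment vectors (>= 3 complete pairs).
#' @return Pearson r.
#' @export
matrix_correlation <- function(plasma, dbs) {
  ok <- stats::complete.cases(plasma, dbs)
  if (sum(ok) < 3) stop("need >= 3 complete pairs")
  if (stats::sd(plasma[ok]) == 0 || stats::sd(dbs[ok]) == 0) {
    stop("undefined correlation: zero variance")
  }
  stats::cor(plasma[ok], dbs[ok], method = "pearson")
}

#' Storage-stability delta
#'
#' Percent change of enrichment between two storage conditions (e.g.
#' immediate measurement vs 1 year at -80 degrees C).
#'
#' @param before,after Enrichment values under the two conditions.
#' @return Percent change (negative = decrease), vectorized.
#' @export
stability_delta <- function(before, after) {
  if (any(before == 0)) stop("undefined delta: zero reference enrichment")
  100 * (after - before) / before
}

#' Cohort comparison of RUF or AUC values
#'
#' Two groups: unpaired two-tailed Welch t-test. Three or more groups:
#' one-way ANOVA followed by Tukey HSD pairwise comparisons. Significance
#' threshold 0.05.
#'
#' @param values Numeric outcome values.
#' @param group Group labels (factor or character), same length.
#' @param alpha Significance level, default 0.05.
#' @return A list of class \code{group_comparison}: \code{method},
#'   \code{p_value} (overall), \code{pairwise} (data.frame of pairwise
#'   p-values, adjusted for >= 3 groups), \code{significant}.
#' @export
group_compare <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  stopifnot(length(values) == length(group))
  sizes <- table(group)
  if (length(sizes) < 2) stop("need >= 2 groups")
  if (any(sizes < 2)) stop("each group needs >= 2 values")
  if (length(sizes) == 2) {
    tt <- stats::t.test(values ~ group, var.equal = FALSE)
    pw <- data.frame(comparison = paste(levels(group), collapse = "-"),
                     p_adj = tt$p.value, stringsAsFactors = FALSE)
    out <- list(method = "t-test", p_value = tt$p.value, pairwise = pw)
  } else {
    fit <- stats::aov(values ~ group)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$group
    pw <- data.frame(comparison = rownames(tk), p_adj = tk[, "p adj"],
                     row.names = NULL, stringsAsFactors = FALSE)
    out <- list(method = "anova+tukey", p_value = p, pairwise = pw)
  }
  out$significant <- out$p_value < alpha
  structure(out, class = "group_comparison")
}

#' Validation report over a paired plasma/DBS fixture
#'
#' Convenience wrapper assembling LLOQD, intra-experiment precision and
#' the matrix correlation from long tables of baseline ratios and paired
#' enrichments.
#'
#' @param baseline Data.frame with columns metabolite, matrix, ratio
#'   (replicate baseline isotope ratios).
#' @param paired Optional data.frame with columns plasma and dbs (paired
#'   enrichment values).
#' @return A list of class \code{validation_report}: \code{lloqd}
#'   data.frame, \code{precision} data.frame (CV of baseline ratios), and
#'   \code{matrix_r}.
#' @export
validation_report <- function(baseline, paired = NULL) {
  parts <- split(baseline, list(baseline$metabolite, baseline$matrix),
                 drop = TRUE)
  tab <- do.call(rbind, lapply(parts, function(d) {
    data.frame(metabolite = d$metabolite[1], matrix = d$matrix[1],
               lloqd_percent = lloqd(d$ratio),
               cv_percent = precision_cv(d$ratio),
               n = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(
    lloqd = tab[, c("metabolite", "matrix", "lloqd_percent", "n")],
    precision = tab[, c("metabolite", "matrix", "cv_percent", "n")],
    matrix_r = if (!is.null(paired)) matrix_correlation(paired$plasma,
                                                        paired$dbs)
  ), class = "validation_report")
}
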