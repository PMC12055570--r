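## End-to-end processing: raw peak records -> isotope ratios -> enrichment
## curves -> AUCs -> R, T, RUF, recovery.

## Process one assay (one subject x matrix occasion). `records` must
## already carry the IS-normalized `value` column. Returns per-metabolite
## F series, total-signal series, mean unlabeled signal, and bookkeeping.
process_assay <- function(records, config = assay_config()) {
  times <- config$time_grid
  out <- list()
  n_outliers <- 0L
  n_invalid_triplicates <- 0L
  for (m in config$metabolites) {
    d <- records[records$metabolite == m, , drop = FALSE]
    if (!nrow(d)) next
    lab <- d[d$isotopologue == "15N", , drop = FALSE]
    unl <- d[d$isotopologue == "unlabeled", , drop = FALSE]
    L <- matrix(NA_real_, length(times), 3)
    U <- matrix(NA_real_, length(times), 3)
    L[cbind(match(lab$time_min, times), lab$replicate)] <- lab$value
    U[cbind(match(unl$time_min, times), unl$replicate)] <- unl$value
    tot <- L + U
    Fr <- ifelse(!is.na(tot) & tot > 0, L / tot, NA_real_)

    f_t <- numeric(length(times))
    tot_t <- numeric(length(times))
    for (i in seq_along(times)) {
      o <- detect_triplicate_outliers(Fr[i, ], config$outlier_threshold)
      n_outliers <- n_outliers + sum(!o$keep & !is.na(Fr[i, ]))
      n_invalid_triplicates <- n_invalid_triplicates + o$invalid
      f_t[i] <- if (any(o$keep)) mean(Fr[i, o$keep]) else NA_real_
      ot <- detect_triplicate_outliers(tot[i, ], config$outlier_threshold)
      tot_t[i] <- if (any(ot$keep)) mean(tot[i, ot$keep]) else NA_real_
    }
    if (all(is.na(f_t))) {
      out[[m]] <- list(usable = FALSE)
      next
    }
    f_t <- impute_missing(times, f_t, baseline = natural_abundance("15N"))
    tot_t <- impute_missing(times, tot_t, baseline = NULL)
    out[[m]] <- list(
      usable = TRUE,
      f_series = as.numeric(f_t),
      total_series = as.numeric(tot_t),
      mean_unlabeled = mean(U, na.rm = TRUE),
      n_imputed = sum(attr(f_t, "provenance") == "imputed")
    )
  }
  list(metabolites = out, times = times,
       n_outliers = n_outliers,
       n_invalid_triplicates = n_invalid_triplicates)
}

## Curves, exclusions and AUCs for one processed assay, normalized by the
## dose factor and (when a control mean is available) the per-metabolite
## concentration factor.
assay_curves <- function(proc, config, dose_factor = 1,
                         control_mean_unlabeled = NULL) {
  curves <- list()
  aucs <- c()
  included <- character(0)
  cvs <- c()
  for (m in names(proc$metabolites)) {
    pm <- proc$metabolites[[m]]
    if (!isTRUE(pm$usable)) next
    conc_factor <- 1
    if (!is.null(control_mean_unlabeled) &&
        is.finite(control_mean_unlabeled[m]) &&
        control_mean_unlabeled[m] > 0) {
      conc_factor <- pm$mean_unlabeled / control_mean_unlabeled[m]
    }
    curve <- compute_enrichment(proc$times, pm$f_series, metabolite = m)
    curve <- normalize_curve(curve, dose_factor, conc_factor)
    st <- concentration_stability_filter(pm$total_series,
                                         config$stability_cv_threshold)
    curves[[m]] <- curve
    aucs[m] <- auc(curve, t_end = max(config$time_grid))
    cvs[m] <- st$cv
    if (st$include) included <- c(included, m)
  }
  list(curves = curves, aucs = aucs, included = included, stability_cv = cvs)
}

#' Run the full ureagenesis analysis pipeline
#'
#' Processes raw peak records of one or more assays end to end:
#' internal-standard normalization, triplicate outlier rejection (30\%
#' rule), missing-value imputation, isotope ratios, percent enrichment
#' curves with dose and endogenous-concentration normalization, trapezoidal
#' AUCs, the concentration-stability exclusion, and the R / T / RUF /
#' tracer-recovery computations against a control reference. The reference
#' is built from the cohort's own control subjects unless a persisted one
#' is supplied. The pipeline is fully deterministic.
#'
#' @param records Raw peak records (long format, possibly many subjects).
#' @param subjects Metadata data.frame: subject_id, group, matrix,
#'   weight_kg, dose_mg_per_kg.
#' @param config An \code{assay_config}.
#' @param reference Optional \code{control_reference}; required when the
#'   cohort contains no CONTROL subjects.
#' @return A list of class \code{ruf_pipeline}: \code{results} (one row per
#'   assay: R, T, RUF, recovery, partition shares, per-metabolite AUCs,
#'   exclusions and preprocessing counts), \code{reference}, \code{curves}
#'   (long data.frame of normalized enrichment curves).
#' @export
run_pipeline <- function(records, subjects, config = assay_config(),
                         reference = NULL) {
  stopifnot(inherits(config, "assay_config"))
  records <- normalize_to_is(records)
  keys <- unique(subjects[, c("subject_id", "matrix")])

  procs <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- records$subject_id == keys$subject_id[i] &
      records$matrix == keys$matrix[i]
    process_assay(records[sel, , drop = FALSE], config)
  })

  is_control <- subjects$group[match(keys$subject_id,
                                     subjects$subject_id)] == "CONTROL"
  if (is.null(reference) && !any(is_control)) {
    stop("no controls in cohort and no persisted reference supplied")
  }

  ## control cohort mean unlabeled signal per metabolite, for the
  ## endogenous-concentration normalization of every assay
  if (!is.null(reference) && !is.null(reference$mean_unlabeled)) {
    ctrl_unlab <- reference$mean_unlabeled
  } else {
    ctrl_unlab <- sapply(config$metabolites, function(m) {
      v <- vapply(procs[is_control], function(p) {
        pm <- p$metabolites[[m]]
        if (is.null(pm) || !isTRUE(pm$usable)) NA_real_ else pm$mean_unlabeled
      }, numeric(1))
      mean(v, na.rm = TRUE)
    })
  }

  rows <- vector("list", nrow(keys))
  curve_rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    meta <- subjects[subjects$subject_id == keys$subject_id[i] &
                       subjects$matrix == keys$matrix[i], ][1, ]
    dose_factor <- config$nominal_dose_mg_per_kg / meta$dose_mg_per_kg
    ac <- assay_curves(procs[[i]], config, dose_factor, ctrl_unlab)
    R <- compute_R(ac$aucs, ac$included)
    T_abs <- compute_T(ac$aucs, meta$dose_mg_per_kg, meta$weight_kg,
                       config$pool_umol_per_L, config$v_dist_L_per_kg,
                       t_span = max(config$time_grid),
                       included = ac$included)
    rec <- tracer_recovery(ac$aucs, meta$dose_mg_per_kg, meta$weight_kg,
                           config$pool_umol_per_L, config$v_dist_L_per_kg,
                           t_span = max(config$time_grid),
                           included = ac$included)
    row <- data.frame(subject_id = meta$subject_id, group = meta$group,
                      matrix = meta$matrix, R = R, T = T_abs,
                      recovery = rec$recovery, uc_share = rec$uc_share,
                      alt_share = rec$alt_share,
                      excluded = paste(setdiff(names(ac$aucs), ac$included),
                                       collapse = ";"),
                      n_outliers = procs[[i]]$n_outliers,
                      n_invalid_triplicates = procs[[i]]$n_invalid_triplicates,
                      stringsAsFactors = FALSE)
    for (m in config$metabolites) {
      row[[paste0("auc_", m)]] <-
        if (m %in% names(ac$aucs)) unname(ac$aucs[m]) else NA_real_
    }
    rows[[i]] <- row
    curve_rows[[i]] <- do.call(rbind, lapply(ac$curves, function(cv) {
      data.frame(subject_id = meta$subject_id, matrix = meta$matrix,
                 metabolite = cv$metabolite, time_min = cv$times,
                 ie = cv$ie, stringsAsFactors = FALSE)
    }))
  }
  results <- do.call(rbind, rows)
  curves <- do.call(rbind, curve_rows)
  rownames(results) <- rownames(curves) <- NULL

  ## T-mode calibration: rescale T so the control mean hits the designated
  ## target; the factor cancels in the RUF ratio. Recovery stays absolute.
  calib <- 1
  if (config$t_mode == "control_calibrated") {
    base_T <- if (!is.null(reference)) reference$T_bar_C else
      mean(results$T[is_control])
    calib <- config$t_calibration_target / base_T
    results$T <- results$T * calib
  }

  if (is.null(reference)) {
    ctrl_curves <- curves[curves$subject_id %in%
                            keys$subject_id[is_control], , drop = FALSE]
    reference <- build_control_reference(results[is_control, , drop = FALSE],
                                         curves = ctrl_curves,
                                         mean_unlabeled = ctrl_unlab)
  } else if (config$t_mode == "control_calibrated") {
    reference$T_bar_C <- config$t_calibration_target
  }

  results$RUF <- vapply(seq_len(nrow(results)), function(i) {
    compute_RUF(results$R[i], results$T[i], reference)
  }, numeric(1))

  structure(list(results = results, reference = reference, curves = curves,
                 config = config), class = "ruf_pipeline")
}
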