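#' Urea-cycle label partition R
#'
#' R = (A_urea + A_cit + A_arg) / (A_urea + A_cit + A_arg + A_gln + A_gly +
#' A_glu): the relative amount of observed label that was metabolized
#' through the urea cycle, from the enrichment-curve areas of the included
#' metabolites. Metabolites excluded by the concentration-stability filter
#' drop out of numerator and denominator consistently.
#'
#' @param aucs Named numeric vector of per-metabolite AUCs (percent x min).
#' @param included Character vector of metabolites passing the stability
#'   filter; defaults to all metabolites present in \code{aucs}.
#' @return R as a dimensionless fraction.
#' @export
compute_R <- function(aucs, included = names(aucs)) {
  aucs <- aucs[names(aucs) %in% included]
  num <- sum(aucs[names(aucs) %in% UREA_CYCLE_METABOLITES], na.rm = TRUE)
  den <- sum(aucs, na.rm = TRUE)
  if (!is.finite(den) || den <= 0) {
    stop("undefined R: total AUC denominator is not positive")
  }
  num / den
}

## Convert a per-metabolite AUC (% x min) to a label amount (umol):
## time-averaged enrichment fraction times the pool size.
auc_to_amount_umol <- function(aucs, pool_umol_per_L, v_dist_L_per_kg,
                               weight_kg, t_span = 120) {
  pools <- pool_umol_per_L[names(aucs)]
  if (anyNA(pools)) {
    stop("missing pool concentration for: ",
         paste(names(aucs)[is.na(pools)], collapse = ", "))
  }
  (aucs / 100) / t_span * pools * v_dist_L_per_kg * weight_kg
}

#' Absorbed-and-metabolized tracer fraction T
#'
#' T = 100 * T_measured / T_theoretical. T_measured converts each
#' metabolite's enrichment AUC into a 15N amount through its endogenous
#' pool concentration, the distribution-volume constant and body weight,
#' and sums over the included metabolites; T_theoretical is the
#' administered 15N amount. In \code{"control_calibrated"} mode the result
#' is additionally multiplied by a cohort-level factor chosen so the
#' control mean matches a designated value (the factor cancels in the RUF
#' ratio).
#'
#' @param aucs Named per-metabolite AUCs (percent x min).
#' @param dose_mg_per_kg Administered dose (mg/kg). @param weight_kg Body
#'   weight (kg).
#' @param pool_umol_per_L Endogenous concentrations (umol/L).
#' @param v_dist_L_per_kg Distribution volume (L/kg).
#' @param t_span Test duration (min), default 120.
#' @param included Metabolites passing the stability filter.
#' @param calibration Multiplicative calibration factor (1 in absolute
#'   mode).
#' @return T in percent.
#' @export
compute_T <- function(aucs, dose_mg_per_kg, weight_kg,
                      pool_umol_per_L = assay_config()$pool_umol_per_L,
                      v_dist_L_per_kg = 0.6, t_span = 120,
                      included = names(aucs), calibration = 1) {
  if (dose_mg_per_kg <= 0) stop("dose must be > 0")
  aucs <- aucs[names(aucs) %in% included]
  amounts <- auc_to_amount_umol(aucs, pool_umol_per_L, v_dist_L_per_kg,
                                weight_kg, t_span)
  100 * sum(amounts) / dose_umol(dose_mg_per_kg, weight_kg) * calibration
}

#' Tracer recovery with label-partition breakdown
#'
#' The percentage of the administered tracer observed across the six
#' measured metabolite pools over the test -- computed identically to the
#' absolute-mode T -- together with the per-metabolite share of the
#' recovered label and its split between the urea cycle and the
#' alternative pathways.
#'
#' @inheritParams compute_T
#' @return List with \code{recovery} (percent), \code{partition}
#'   (per-metabolite shares summing to 1), \code{uc_share} and
#'   \code{alt_share}.
#' @export
tracer_recovery <- function(aucs, dose_mg_per_kg, weight_kg,
                            pool_umol_per_L = assay_config()$pool_umol_per_L,
                            v_dist_L_per_kg = 0.6, t_span = 120,
                            included = names(aucs)) {
  if (dose_mg_per_kg <= 0) stop("dose must be > 0")
  aucs <- aucs[names(aucs) %in% included]
  amounts <- auc_to_amount_umol(aucs, pool_umol_per_L, v_dist_L_per_kg,
                                weight_kg, t_span)
  recovery <- 100 * sum(amounts) / dose_umol(dose_mg_per_kg, weight_kg)
  partition <- amounts / sum(amounts)
  list(recovery = recovery,
       partition = partition,
       uc_share = sum(partition[names(partition) %in%
                                  UREA_CYCLE_METABOLITES]),
       alt_share = sum(partition[names(partition) %in%
                                   ALTERNATIVE_METABOLITES]))
}

#' Relative ureagenesis function
#'
#' RUF = 100 * (R_P * T_P) / (R_bar_C * T_bar_C): the subject's urea-cycle
#' label product expressed as a percentage of the control-cohort product of
#' separately averaged means.
#'
#' @param R_P,T_P Subject partition fraction and tracer fraction.
#' @param reference A \code{control_reference} from
#'   [build_control_reference()].
#' @return RUF in percent.
#' @export
compute_RUF <- function(R_P, T_P, reference) {
  stopifnot(inherits(reference, "control_reference"))
  den <- reference$R_bar_C * reference$T_bar_C
  if (!is.finite(den) || den == 0) stop("zero control denominator")
  100 * (R_P * T_P) / den
}

#' Build the control reference
#'
#' Averages R and T over the control cohort (arithmetic means), computes
#' each control's RUF against those cohort means (leave-in by default,
#' leave-one-out optionally), derives the RUF reference range as mean
#' +/- SD, and stores per-metabolite mean +/- SEM control enrichment
#' curves and mean unlabeled signals for later normalization of patients.
#'
#' @param results Data.frame with one row per control assay and columns
#'   \code{R} and \code{T} (as from [run_pipeline()]).
#' @param curves Optional long data.frame of control curves (subject_id,
#'   metabolite, time_min, ie).
#' @param mean_unlabeled Optional named vector of the cohort-mean
#'   IS-normalized unlabeled signal per metabolite.
#' @param leave_one_out If TRUE each control's RUF uses the means of the
#'   other controls.
#' @return A list of class \code{control_reference}: R_bar_C, T_bar_C,
#'   control_rufs, ruf_range, mean_curves, mean_unlabeled, n_controls.
#' @export
build_control_reference <- function(results, curves = NULL,
                                    mean_unlabeled = NULL,
                                    leave_one_out = FALSE) {
  n <- nrow(results)
  if (is.null(n) || n < 2) stop("need >= 2 controls to build a reference")
  R_bar <- mean(results$R)
  T_bar <- mean(results$T)
  rufs <- if (leave_one_out) {
    vapply(seq_len(n), function(i) {
      100 * results$R[i] * results$T[i] /
        (mean(results$R[-i]) * mean(results$T[-i]))
    }, numeric(1))
  } else {
    100 * results$R * results$T / (R_bar * T_bar)
  }
  mean_curves <- NULL
  if (!is.null(curves)) {
    mean_curves <- do.call(rbind, lapply(
      split(curves, list(curves$metabolite, curves$time_min), drop = TRUE),
      function(d) data.frame(metabolite = d$metabolite[1],
                             time_min = d$time_min[1],
                             mean_ie = mean(d$ie),
                             sem_ie = stats::sd(d$ie) / sqrt(nrow(d)))))
    mean_curves <- mean_curves[order(mean_curves$metabolite,
                                     mean_curves$time_min), ]
    rownames(mean_curves) <- NULL
  }
  structure(list(
    R_bar_C = R_bar, T_bar_C = T_bar,
    control_rufs = rufs,
    ruf_range = c(lower = mean(rufs) - stats::sd(rufs),
                  upper = mean(rufs) + stats::sd(rufs)),
    mean_curves = mean_curves,
    mean_unlabeled = mean_unlabeled,
    n_controls = n
  ), class = "control_reference")
}

#' Persist / restore a control reference
#'
#' @param reference A \code{control_reference}. @param path YAML file path.
#' @return \code{path} (write) or the restored reference (read).
#' @export
write_control_reference <- function(reference, path) {
  stopifnot(inherits(reference, "control_reference"))
  x <- unclass(reference)
  x$ruf_range <- as.list(x$ruf_range)
  x$control_rufs <- as.numeric(x$control_rufs)
  if (!is.null(x$mean_unlabeled)) x$mean_unlabeled <- as.list(x$mean_unlabeled)
  if (!is.null(x$mean_curves)) x$mean_curves <- as.list(x$mean_curves)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_control_reference
#' @export
read_control_reference <- function(path) {
  x <- yaml::read_yaml(path)
  mc <- if (!is.null(x$mean_curves)) as.data.frame(x$mean_curves) else NULL
  structure(list(
    R_bar_C = x$R_bar_C, T_bar_C = x$T_bar_C,
    control_rufs = as.numeric(x$control_rufs),
    ruf_range = unlist(x$ruf_range),
    mean_curves = mc,
    mean_unlabeled = if (!is.null(x$mean_unlabeled)) unlist(x$mean_unlabeled),
    n_controls = x$n_controls
  ), class = "control_reference")
}

#' Pre/post-therapy comparison
#'
#' Deltas of RUF, tracer recovery and pathway partition between two assays
#' of the same subject (e.g. before and after liver transplantation or gene
#' therapy), plus per-metabolite AUC changes. Comparing assays from
#' different sampling matrices triggers a warning, since enrichment levels
#' are matrix-dependent.
#'
#' @param pre,post Single rows of the [run_pipeline()] results table for
#'   the same subject.
#' @return A list of class \code{therapy_report}: deltas of RUF, recovery,
#'   uc_share, alt_share, and per-metabolite AUC deltas.
#' @export
compare_pre_post <- function(pre, post) {
  if (pre$subject_id != post$subject_id) {
    stop("pre and post must belong to the same subject")
  }
  if (!identical(pre$matrix, post$matrix)) {
    warning("pre and post assays use different matrices (", pre$matrix,
            " vs ", post$matrix, "); interpret deltas with caution")
  }
  pre_aucs <- unlist(pre[paste0("auc_", assay_metabolites())])
  post_aucs <- unlist(post[paste0("auc_", assay_metabolites())])
  names(pre_aucs) <- names(post_aucs) <- assay_metabolites()
  structure(list(
    subject_id = pre$subject_id,
    delta_RUF = post$RUF - pre$RUF,
    delta_recovery = post$recovery - pre$recovery,
    delta_uc_share = post$uc_share - pre$uc_share,
    delta_alt_share = post$alt_share - pre$alt_share,
    delta_auc = post_aucs - pre_aucs
  ), class = "therapy_report")
}
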