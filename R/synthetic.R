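## Tracer-kinetics simulator.
##
## A linear oral-bolus model: the tracer dose sits in the gut and is absorbed
## into the central ammonia pool with first-order rate ka; a fraction f_abs
## of the dose ever reaches the measured pools (the rest is lost to
## first-pass protein synthesis and unmeasured fates). Absorbed label is
## routed instantaneously into the six product pools -- a fraction
## f_uc * residual_flux through the urea cycle (split among urea,
## citrulline, arginine) and the remainder into the alternative nitrogen
## sinks (glutamine, glycine, glutamate) -- and leaves each pool with
## first-order clearance ke. Each pool's label amount therefore follows a
## Bateman curve, and enrichment is label amount divided by pool size
## (pool concentration x distribution volume x weight).

#' Kinetic parameters for the tracer simulator
#'
#' @param ka First-order gut absorption rate (1/min).
#' @param ke First-order systemic label clearance rate (1/min).
#' @param f_abs Fraction of the administered dose absorbed into the measured
#'   metabolite pools (0-1); the complement is lost to unmeasured fates.
#' @param f_uc Fraction of absorbed label routed through the urea cycle (0-1).
#' @param split_uc Named fractions partitioning urea-cycle label among
#'   urea, citrulline, arginine (sum to 1).
#' @param split_alt Named fractions partitioning alternative-route label among
#'   glutamine, glycine, glutamate (sum to 1).
#' @param pool_umol_per_L Endogenous metabolite concentrations (umol/L).
#' @param v_dist_L_per_kg Distribution volume per body weight (L/kg).
#' @return A list of class \code{kinetic_parameters}.
#' @export
kinetic_parameters <- function(ka = 0.06,
                               ke = 0.004,
                               f_abs = NULL,
                               f_uc = 0.85,
                               split_uc = c(urea = 0.88, citrulline = 0.05,
                                            arginine = 0.07),
                               split_alt = c(glutamine = 0.65, glycine = 0.20,
                                             glutamate = 0.15),
                               pool_umol_per_L = assay_config()$pool_umol_per_L,
                               v_dist_L_per_kg = 0.6) {
  if (is.null(f_abs)) {
    ## calibrate so the designed mean recovery over the 0-120 min assay
    ## grid (trapezoidal time-average, i.e. what the AUC accounting of the
    ## analysis reports) is the healthy-control value of 51%
    f_abs <- 0.51 / recovery_shape(ka, ke, 120, assay_config()$time_grid)
  }
  p <- structure(list(ka = ka, ke = ke, f_abs = f_abs, f_uc = f_uc,
                      split_uc = split_uc[UREA_CYCLE_METABOLITES],
                      split_alt = split_alt[ALTERNATIVE_METABOLITES],
                      pool_umol_per_L = pool_umol_per_L[assay_metabolites()],
                      v_dist_L_per_kg = v_dist_L_per_kg),
                 class = "kinetic_parameters")
  validate_kinetic_parameters(p)
  p
}

validate_kinetic_parameters <- function(p) {
  if (!is.finite(p$ka) || p$ka <= 0 || !is.finite(p$ke) || p$ke < 0) {
    stop("invalid kinetic parameters: rates must be positive (ke may be 0)")
  }
  if (p$f_abs <= 0 || p$f_abs > 1) stop("f_abs must be in (0, 1]")
  if (p$f_uc < 0 || p$f_uc > 1) stop("f_uc must be in [0, 1]")
  if (abs(sum(p$split_uc) - 1) > 1e-9 || abs(sum(p$split_alt) - 1) > 1e-9) {
    stop("split fractions must each sum to 1")
  }
  if (any(p$split_uc < 0) || any(p$split_alt < 0)) {
    stop("split fractions must be non-negative")
  }
  if (any(!is.finite(p$pool_umol_per_L)) || any(p$pool_umol_per_L <= 0)) {
    stop("pool concentrations must be positive")
  }
  if (p$v_dist_L_per_kg <= 0) stop("v_dist must be positive")
  invisible(p)
}

## Bateman time course of the fraction of routed label present in a pool:
## ka/(ka-ke) * (exp(-ke t) - exp(-ka t)), with the ka == ke limit handled.
bateman_fraction <- function(t, ka, ke) {
  if (abs(ka - ke) < 1e-12) {
    ka * t * exp(-ka * t)
  } else {
    ka / (ka - ke) * (exp(-ke * t) - exp(-ka * t))
  }
}

## Time-averaged Bateman fraction over [0, t_span]: the designed recovery of
## a subject is f_abs times this shape factor. With `times` given, the
## average is the trapezoidal one on that sampling grid (the quantity the
## AUC-based analysis actually measures); otherwise the exact integral.
recovery_shape <- function(ka, ke, t_span = 120, times = NULL) {
  if (!is.null(times)) {
    times <- sort(unique(times[times <= t_span]))
    return(pracma::trapz(times, bateman_fraction(times, ka, ke)) / t_span)
  }
  if (ke < 1e-12) {
    (1 - (1 - exp(-ka * t_span)) / (ka * t_span))
  } else if (abs(ka - ke) < 1e-12) {
    int <- (1 - exp(-ka * t_span) * (1 + ka * t_span)) / ka
    int / t_span
  } else {
    ka / (ka - ke) *
      ((1 - exp(-ke * t_span)) / (ke * t_span) -
       (1 - exp(-ka * t_span)) / (ka * t_span))
  }
}

#' Designed tracer recovery of a parameter set
#'
#' Closed-form time-average over the test window of the fraction of the
#' administered label residing in the six measured pools: what an ideal,
#' noise-free pipeline run would report as tracer recovery.
#'
#' @param params A \code{kinetic_parameters} object.
#' @param preset A \code{disease_preset}; label routed to unmeasured
#'   intermediates (\code{unmeasured_loss}) is discounted.
#' @param t_span Test duration in minutes. Default 120.
#' @param times Sampling grid used for the trapezoidal time-average; the
#'   assay grid by default. NULL gives the exact continuous-time integral.
#' @return Designed recovery in percent.
#' @export
designed_recovery <- function(params, preset = disease_preset("CONTROL"),
                              t_span = 120,
                              times = assay_config()$time_grid) {
  f_eff <- params$f_uc * preset$residual_flux
  captured <- f_eff * (1 - preset$unmeasured_loss) + (1 - f_eff)
  100 * params$f_abs * captured *
    recovery_shape(params$ka, params$ke, t_span, times)
}

#' Disease presets for the simulator
#'
#' Encodes the qualitative enrichment patterns of the urea-cycle disorders:
#' a residual urea-cycle flux scaling, optional redistribution of label
#' within the urea-cycle and alternative splits (e.g. citrulline
#' accumulation in argininosuccinate synthetase/lyase deficiency, very low
#' glycine labeling in citrin deficiency), and, for lyase deficiency, label
#' trapped in the unmeasured argininosuccinate pool.
#'
#' @param name One of CONTROL, CPS1D, OTCD, ASSD, ASLD, ARGD, CTND, HHH.
#' @return A list of class \code{disease_preset} with fields \code{name},
#'   \code{residual_flux}, \code{split_uc}/\code{split_alt} overrides (or
#'   NULL) and \code{unmeasured_loss}.
#' @export
disease_preset <- function(name = c("CONTROL", "CPS1D", "OTCD", "ASSD",
                                    "ASLD", "ARGD", "CTND", "HHH")) {
  name <- match.arg(name)
  preset <- switch(name,
    CONTROL = list(residual_flux = 1, split_uc = NULL, split_alt = NULL,
                   unmeasured_loss = 0),
    CPS1D = list(residual_flux = 0.08, split_uc = NULL, split_alt = NULL,
                 unmeasured_loss = 0),
    OTCD = list(residual_flux = 0.35, split_uc = NULL, split_alt = NULL,
                unmeasured_loss = 0),
    ASSD = list(residual_flux = 0.20,
                split_uc = c(urea = 0.08, citrulline = 0.87, arginine = 0.05),
                split_alt = NULL, unmeasured_loss = 0),
    ASLD = list(residual_flux = 0.30,
                split_uc = c(urea = 0.15, citrulline = 0.70, arginine = 0.15),
                split_alt = NULL, unmeasured_loss = 0.30),
    ARGD = list(residual_flux = 0.45,
                split_uc = c(urea = 0.55, citrulline = 0.05, arginine = 0.40),
                split_alt = NULL, unmeasured_loss = 0),
    CTND = list(residual_flux = 0.55, split_uc = NULL,
                ## glycine labeling collapses to under a tenth of controls
                split_alt = c(glutamine = 0.796, glycine = 0.004,
                              glutamate = 0.20),
                unmeasured_loss = 0),
    HHH = list(residual_flux = 0.45, split_uc = NULL, split_alt = NULL,
               unmeasured_loss = 0)
  )
  preset$name <- name
  if (preset$residual_flux < 0 || preset$residual_flux > 1) {
    stop("residual_flux must be in [0, 1]")
  }
  structure(preset, class = "disease_preset")
}

#' Set the residual urea-cycle flux of a preset
#'
#' Convenience for severity grids and therapy simulations (a liver
#' transplant restores \code{residual_flux} towards 1).
#'
#' @param preset A \code{disease_preset}.
#' @param residual_flux New residual flux in [0, 1].
#' @return The modified preset.
#' @export
with_residual_flux <- function(preset, residual_flux) {
  stopifnot(inherits(preset, "disease_preset"),
            residual_flux >= 0, residual_flux <= 1)
  preset$residual_flux <- residual_flux
  preset
}

#' Measurement noise model
#'
#' @param cv Technical coefficient of variation of the isotope ratio and of
#'   peak intensities, either a single number or a named vector per
#'   metabolite. Defaults reflect plasma performance (sub-2\% for urea, a
#'   few percent for amino acids; dried blood spots are noisier).
#' @param missing_rate Probability that a replicate measurement is absent.
#' @param outlier_rate Probability that a replicate is aberrantly inflated or
#'   deflated beyond the 30\% triplicate rule.
#' @param matrix "plasma" or "DBS"; DBS doubles the technical CV.
#' @return A list of class \code{noise_model}.
#' @export
noise_model <- function(cv = c(urea = 0.016, citrulline = 0.035,
                               arginine = 0.062, glutamine = 0.025,
                               glycine = 0.030, glutamate = 0.040),
                        missing_rate = 0.01,
                        outlier_rate = 0.02,
                        matrix = c("plasma", "DBS")) {
  matrix <- match.arg(matrix)
  if (length(cv) == 1) cv <- stats::setNames(rep(cv, 6), assay_metabolites())
  cv <- cv[assay_metabolites()]
  if (any(is.na(cv)) || any(cv < 0)) stop("cv must be >= 0 per metabolite")
  if (matrix == "DBS") cv <- cv * 2
  if (missing_rate < 0 || missing_rate > 1 ||
      outlier_rate < 0 || outlier_rate > 1) {
    stop("rates must be in [0, 1]")
  }
  structure(list(cv = cv, missing_rate = missing_rate,
                 outlier_rate = outlier_rate, matrix = matrix),
            class = "noise_model")
}

#' Noise-free noise model
#' @param matrix Sampling matrix.
#' @return A \code{noise_model} with all CVs and rates zero.
#' @export
noise_free <- function(matrix = "plasma") {
  noise_model(cv = 0, missing_rate = 0, outlier_rate = 0, matrix = matrix)
}

#' Simulate true (noise-free) enrichment curves
#'
#' Solves the oral-bolus routing model in closed form and returns, for each
#' metabolite, the fraction of its pool that is tracer-derived label at each
#' sampling time.
#'
#' @param params A \code{kinetic_parameters} object.
#' @param preset A \code{disease_preset}.
#' @param times Sampling times in minutes; must include 0.
#' @param dose_mg_per_kg Administered dose (mg/kg).
#' @param weight_kg Body weight (kg).
#' @return Matrix \code{length(times) x 6} of enrichment fractions with
#'   times as rownames and metabolites as colnames; the first row (t = 0)
#'   is exactly zero.
#' @export
simulate_true_enrichment <- function(params,
                                     preset = disease_preset("CONTROL"),
                                     times = assay_config()$time_grid,
                                     dose_mg_per_kg = 2,
                                     weight_kg = 70) {
  validate_kinetic_parameters(params)
  stopifnot(inherits(preset, "disease_preset"))
  if (!0 %in% times) stop("times must include 0 (baseline)")
  times <- sort(unique(times))
  f_eff <- params$f_uc * preset$residual_flux
  split_uc <- if (is.null(preset$split_uc)) params$split_uc else
    preset$split_uc[UREA_CYCLE_METABOLITES]
  split_alt <- if (is.null(preset$split_alt)) params$split_alt else
    preset$split_alt[ALTERNATIVE_METABOLITES]
  if (abs(sum(split_uc) - 1) > 1e-9 || abs(sum(split_alt) - 1) > 1e-9) {
    stop("preset split overrides must sum to 1")
  }
  route <- c(f_eff * (1 - preset$unmeasured_loss) * split_uc,
             (1 - f_eff) * split_alt)

  dose <- dose_umol(dose_mg_per_kg, weight_kg)       # umol of 15N
  shape <- bateman_fraction(times, params$ka, params$ke)
  pool_amount <- params$pool_umol_per_L[assay_metabolites()] *
    params$v_dist_L_per_kg * weight_kg               # umol per pool
  label <- outer(shape, route) * (params$f_abs * dose)
  enrich <- sweep(label, 2, pool_amount, "/")
  dimnames(enrich) <- list(times, assay_metabolites())
  enrich[as.character(0), ] <- 0
  enrich
}

#' Render one assay: true curves to noisy triplicate peak areas
#'
#' Converts true enrichment fractions into the long peak-area table the
#' preprocessing stage consumes: labeled and unlabeled isotopologue areas
#' with internal-standard areas, per timepoint and technical replicate
#' (1-3). The labeled-to-total ratio at baseline equals the 15N natural
#' abundance plus technical noise. Per-injection intensity drift is applied
#' to the analyte and its internal standard jointly, so internal-standard
#' scaling can remove it downstream.
#'
#' @param true_curves Matrix from [simulate_true_enrichment()].
#' @param noise A \code{noise_model}.
#' @param dose_mg_per_kg,weight_kg Assay dose and subject weight.
#' @param matrix "plasma" or "DBS".
#' @param subject_id Subject identifier.
#' @param pool_umol_per_L Pool concentrations used to scale base intensities.
#' @param seed Optional integer seed; if supplied the rendering is
#'   reproducible on its own (otherwise it draws from the current RNG
#'   stream, e.g. within [simulate_cohort()]).
#' @return A long-format data.frame of raw peak records with columns
#'   subject_id, matrix, time_min, metabolite, isotopologue, replicate,
#'   area, is_area.
#' @export
render_assay <- function(true_curves, noise = noise_model(),
                         dose_mg_per_kg = 2, weight_kg = 70,
                         matrix = c("plasma", "DBS"),
                         subject_id = "S1",
                         pool_umol_per_L = assay_config()$pool_umol_per_L,
                         seed = NULL) {
  matrix <- match.arg(matrix)
  if (!is.null(seed)) set.seed(as.integer(seed))
  stopifnot(inherits(noise, "noise_model"))
  times <- as.numeric(rownames(true_curves))
  mets <- colnames(true_curves)
  na15 <- natural_abundance("15N")

  grid <- expand.grid(replicate = 1:3, time_min = times, metabolite = mets,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  f_true <- true_curves[cbind(match(grid$time_min, times),
                              match(grid$metabolite, mets))] + na15
  cv <- noise$cv[grid$metabolite]

  ## per-injection intensity drift, shared by analyte and internal standard
  inj <- exp(stats::rnorm(n, 0, 0.15))
  base <- 1000 * pool_umol_per_L[grid$metabolite]
  total_area <- base * inj * exp(stats::rnorm(n, 0, pmax(cv, 0)))
  is_area <- 5e5 * inj

  f_obs <- f_true * (1 + stats::rnorm(n, 0, 1) * cv)
  ## aberrant peak integrations: inflate/deflate a replicate beyond the
  ## 30% triplicate rule
  out <- stats::runif(n) < noise$outlier_rate
  f_obs[out] <- f_obs[out] * ifelse(stats::runif(sum(out)) < 0.5, 1.6, 0.55)
  f_obs <- pmin(pmax(f_obs, 0), 1)

  miss <- stats::runif(n) < noise$missing_rate

  rec <- data.frame(
    subject_id = subject_id,
    matrix = matrix,
    time_min = rep(grid$time_min, 2),
    metabolite = rep(grid$metabolite, 2),
    isotopologue = rep(c("unlabeled", "15N"), each = n),
    replicate = rep(grid$replicate, 2),
    area = c((1 - f_obs) * total_area, f_obs * total_area),
    is_area = rep(is_area, 2),
    stringsAsFactors = FALSE
  )
  rec$area[rep(miss, 2)] <- NA_real_
  rec[order(rec$metabolite, rec$time_min, rec$replicate, rec$isotopologue), ,
      drop = FALSE]
}

#' Simulate a cohort of subject assays
#'
#' Draws n subjects around a disease preset with log-normal inter-subject
#' jitter on the absorption and clearance rates, a Beta-distributed absorbed
#' fraction (bounded by label conservation), and log-normal body weights,
#' then renders each subject's noisy triplicate peak-area table.
#'
#' @param n Number of subjects (>= 1).
#' @param preset A \code{disease_preset}.
#' @param noise A \code{noise_model}.
#' @param inter_subject_cv Coefficient of variation of the subject-level
#'   absorbed fraction; absorption/clearance rates get 0.75x this CV and the
#'   urea-cycle routing fraction 0.25x. Default 0.20, chosen so the control
#'   cohort's recovery spread matches the reported healthy-control spread.
#' @param seed Integer seed; all randomness (parameters and measurement
#'   noise) is reproducible from it.
#' @param params Baseline \code{kinetic_parameters}.
#' @param dose_mg_per_kg Nominal dose. @param matrix Sampling matrix.
#' @return A list of class \code{cohort} with \code{records} (stacked raw
#'   peak records), \code{subjects} (metadata: subject_id, group, matrix,
#'   weight_kg, dose_mg_per_kg, designed_recovery) and \code{truth}
#'   (per-subject kinetic parameters and true curves).
#' @export
simulate_cohort <- function(n, preset = disease_preset("CONTROL"),
                            noise = noise_model(),
                            inter_subject_cv = 0.20,
                            seed = 1L,
                            params = kinetic_parameters(),
                            dose_mg_per_kg = 2,
                            matrix = c("plasma", "DBS")) {
  if (n < 1) stop("n must be >= 1")
  matrix <- match.arg(matrix)
  set.seed(as.integer(seed))

  draw_lognorm <- function(n, cv) {
    if (cv <= 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + cv^2))
    exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))   # mean-preserving multiplier
  }
  draw_beta <- function(n, mean, cv) {
    if (cv <= 0) return(rep(mean, n))
    v <- (cv * mean)^2
    nu <- mean * (1 - mean) / v - 1
    if (nu <= 0) stop("inter_subject_cv too large for bounded f_abs")
    stats::rbeta(n, mean * nu, (1 - mean) * nu)
  }

  ka <- params$ka * draw_lognorm(n, 0.75 * inter_subject_cv)
  ke <- params$ke * draw_lognorm(n, 0.75 * inter_subject_cv)
  f_abs <- draw_beta(n, params$f_abs, inter_subject_cv)
  f_uc <- pmin(params$f_uc * draw_lognorm(n, 0.25 * inter_subject_cv), 0.98)
  weight <- 70 * draw_lognorm(n, 0.20)

  prefix <- if (preset$name == "CONTROL") "C" else preset$name
  ids <- sprintf("%s%02d", prefix, seq_len(n))

  records <- vector("list", n)
  truth <- vector("list", n)
  designed <- numeric(n)
  for (i in seq_len(n)) {
    p_i <- params
    p_i$ka <- ka[i]; p_i$ke <- ke[i]; p_i$f_abs <- f_abs[i]
    p_i$f_uc <- f_uc[i]
    curves <- simulate_true_enrichment(p_i, preset,
                                       dose_mg_per_kg = dose_mg_per_kg,
                                       weight_kg = weight[i])
    designed[i] <- designed_recovery(p_i, preset)
    records[[i]] <- render_assay(curves, noise, dose_mg_per_kg, weight[i],
                                 matrix, ids[i])
    truth[[i]] <- list(params = p_i, curves = curves)
  }
  names(truth) <- ids
  structure(list(
    records = do.call(rbind, records),
    subjects = data.frame(subject_id = ids, group = preset$name,
                          matrix = matrix, weight_kg = weight,
                          dose_mg_per_kg = dose_mg_per_kg,
                          designed_recovery = designed,
                          stringsAsFactors = FALSE),
    truth = truth,
    seed = as.integer(seed)
  ), class = "cohort")
}
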