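#' @keywords internal
"_PACKAGE"

## Metabolite panels. The assay follows six nitrogen pools: the three
## urea-cycle products and the three main alternative nitrogen sinks.
UREA_CYCLE_METABOLITES <- c("urea", "citrulline", "arginine")
ALTERNATIVE_METABOLITES <- c("glutamine", "glycine", "glutamate")

#' Metabolites quantified by the ureagenesis assay
#'
#' @return Character vector of the six target metabolites, urea-cycle
#'   products first.
#' @export
assay_metabolites <- function() {
  c(UREA_CYCLE_METABOLITES, ALTERNATIVE_METABOLITES)
}

#' Urea-cycle product metabolites
#' @return Character vector: urea, citrulline, arginine.
#' @export
urea_cycle_metabolites <- function() UREA_CYCLE_METABOLITES

#' Alternative-pathway metabolites
#' @return Character vector: glutamine, glycine, glutamate.
#' @export
alternative_metabolites <- function() ALTERNATIVE_METABOLITES

## Natural isotopic abundances (IUPAC representative values).
NATURAL_ABUNDANCE <- c(`15N` = 0.003663, `13C` = 0.010816)

#' Natural abundance of a heavy isotope
#'
#' Background fraction of the heavy isotope present without any tracer;
#' this is the intrinsic baseline of every isotope-ratio measurement.
#'
#' @param isotope "15N" or "13C".
#' @return Abundance as a fraction.
#' @export
natural_abundance <- function(isotope = "15N") {
  if (!isotope %in% names(NATURAL_ABUNDANCE)) {
    stop("unknown isotope: ", isotope)
  }
  unname(NATURAL_ABUNDANCE[isotope])
}

## Molar mass of the tracer salt [15N]NH4Cl (g/mol): 15N 15.0001089,
## H 1.00782503 x 4, Cl 35.45 (standard atomic weight).
TRACER_MOLAR_MASS_G_PER_MOL <- 15.0001089 + 4 * 1.00782503 + 35.45

#' Convert a tracer dose from mg/kg to mmol/kg
#'
#' Uses the molar mass of [15N]ammonium chloride (54.48 g/mol). The
#' standard oral dose of 2 mg/kg corresponds to 0.037 mmol/kg.
#'
#' @param dose_mg_per_kg Dose in mg of [15N]NH4Cl per kg body weight.
#' @return Dose in mmol/kg.
#' @export
#' @examples
#' dose_mmol_per_kg(2)
dose_mmol_per_kg <- function(dose_mg_per_kg = 2) {
  stopifnot(is.numeric(dose_mg_per_kg), all(dose_mg_per_kg > 0))
  dose_mg_per_kg / TRACER_MOLAR_MASS_G_PER_MOL
}

#' Administered [15N] amount in micromoles
#'
#' @param dose_mg_per_kg Dose in mg/kg of [15N]NH4Cl (one 15N per molecule).
#' @param weight_kg Body weight in kg.
#' @return Administered 15N amount, micromoles.
#' @export
dose_umol <- function(dose_mg_per_kg, weight_kg) {
  stopifnot(weight_kg > 0)
  dose_mmol_per_kg(dose_mg_per_kg) * 1000 * weight_kg
}
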