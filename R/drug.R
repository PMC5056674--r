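#' Physicochemical and biochemical constants for methylphenidate
#'
#' Bundles the drug-specific constants used throughout the absorption model.
#' Methylphenidate is a monoprotic weak base (pKa 8.77) with low
#' lipophilicity (logP 0.20) and high intrinsic solubility; its effective
#' human jejunal permeability was calibrated against clinical
#' immediate-release data and is carried here as a constant.
#'
#' @param MW Molecular weight, g/mol.
#' @param pKa Basic pKa (monoprotic).
#' @param logP Octanol/water log partition coefficient.
#' @param S0 Intrinsic (unionized) aqueous solubility, mg/L. The default
#'   back-calculates the predicted solubility of 9,250 mg/L at pH 10.58.
#' @param Papp In vitro apparent permeability (MDCK monolayer), cm/s.
#' @param HPeff Effective human intestinal permeability, cm/s (calibrated;
#'   see [effective_permeability()] for the regression-based estimate).
#' @param MW_water Molecular weight of water, g/mol.
#' @param gut_partition Enterocyte:blood partition coefficient (set equal to
#'   the hepatic partition coefficient, 5.66).
#' @return A list of class `drug_properties`.
#' @examples
#' props <- drug_properties()
#' aqueous_solubility(10.58, props) # ~9250 mg/L
#' @export
drug_properties <- function(MW = 233.3062, pKa = 8.77, logP = 0.20, S0 = 9109,
                            Papp = 24.7e-6, HPeff = 0.963e-4,
                            MW_water = 18.015, gut_partition = 5.66) {
  vals <- list(MW = MW, pKa = pKa, logP = logP, S0 = S0, Papp = Papp,
               HPeff = HPeff, MW_water = MW_water, gut_partition = gut_partition)
  for (nm in setdiff(names(vals), "logP")) {
    if (!is.numeric(vals[[nm]]) || length(vals[[nm]]) != 1 ||
        !is.finite(vals[[nm]]) || vals[[nm]] <= 0) {
      stop(sprintf("`%s` must be a positive finite number", nm), call. = FALSE)
    }
  }
  if (HPeff >= 1) stop("`HPeff` must be below 1 cm/s", call. = FALSE)
  structure(vals, class = "drug_properties")
}

#' Diffusion-layer dissolution parameters
#'
#' Parameters of the Noyes-Whitney diffusion-layer dissolution law for
#' spherical particles: diffusion coefficient (cm^2/min), particle density
#' (g/mL), particle radius and diffusion-layer thickness (um, converted to cm
#' internally), and the unit-reconciliation factor 60 x 100 carried by the
#' printed rate law. The particle radius is held constant (no shrinking-core
#' update).
#'
#' @param diff_coeff Diffusion coefficient, cm^2/min.
#' @param rho Particle density, g/mL.
#' @param r_particle Particle radius, um.
#' @param dlt Diffusion layer thickness, um.
#' @param unit_factor Trailing unit-reconciliation constant of the printed
#'   rate law (60 converts minutes to hours; the remaining factor of 100 is
#'   reproduced as printed).
#' @return A list of class `dissolution_params`.
#' @export
dissolution_params <- function(diff_coeff = 1e-4, rho = 1, r_particle = 5,
                               dlt = 30, unit_factor = 60 * 100) {
  vals <- list(diff_coeff = diff_coeff, rho = rho, r_particle = r_particle,
               dlt = dlt, unit_factor = unit_factor)
  if (any(vapply(vals, function(x) !is.numeric(x) || x <= 0, logical(1)))) {
    stop("all dissolution parameters must be strictly positive", call. = FALSE)
  }
  structure(vals, class = "dissolution_params")
}

#' Unionized fraction of a monoprotic base
#'
#' Henderson-Hasselbalch: `1 / (1 + 10^(pKa - pH))`. The ionized and
#' unionized fractions sum to one exactly.
#'
#' @param pH Luminal pH.
#' @param pKa Basic pKa.
#' @return Fraction in \[0, 1\]. Vectorised.
#' @export
unionized_fraction <- function(pH, pKa) {
  1 / (1 + 10^(pKa - pH))
}

#' pH-dependent aqueous solubility of a weak base
#'
#' `S0 * (1 + 10^(pKa - pH))`: total (ionized + unionized) solubility from
#' the intrinsic solubility of the free base. Strictly decreasing in pH; at
#' gastric pH the ionized term makes the solubility effectively unlimited.
#'
#' @param pH Luminal pH.
#' @param props A [drug_properties()] record.
#' @return Solubility in mg/L (equivalently ug/mL). Vectorised over `pH`.
#' @export
aqueous_solubility <- function(pH, props = drug_properties()) {
  props$S0 * (1 + 10^(props$pKa - pH))
}

#' Bile-salt contribution to luminal solubility
#'
#' Solubilization by bile micelles: `SR * SCaq * MW * bile`, with
#' solubilization ratio `SR = 10^(0.606 logP + 2.234)` and aqueous
#' solubilization capacity `SCaq = Solwater * (MW_water / MW) * 1e-6`, where
#' `Solwater` is the pH-dependent aqueous solubility at the same pH.
#'
#' @param pH Luminal pH.
#' @param bile_mM Bile salt concentration, mM (>= 0).
#' @param props A [drug_properties()] record.
#' @return Additional solubility in mg/L. Vectorised.
#' @export
bile_solubility <- function(pH, bile_mM, props = drug_properties()) {
  if (any(bile_mM < 0, na.rm = TRUE)) {
    stop("`bile_mM` must be non-negative", call. = FALSE)
  }
  solwater <- aqueous_solubility(pH, props)
  SR <- 10^(0.606 * props$logP + 2.234)
  SCaq <- solwater * (props$MW_water / props$MW) * 1e-6
  SR * SCaq * props$MW * bile_mM
}

#' Total luminal solubility
#'
#' Sum of the aqueous and bile-salt contributions.
#'
#' @inheritParams bile_solubility
#' @return Solubility in mg/L. Vectorised.
#' @export
total_solubility <- function(pH, bile_mM, props = drug_properties()) {
  aqueous_solubility(pH, props) + bile_solubility(pH, bile_mM, props)
}

#' Noyes-Whitney dissolution rate in a luminal compartment
#'
#' Diffusion-layer dissolution rate for spherical particles,
#' `3 D / (rho r_p h V) * Csolid * (Solif - Cdiss) * 60 * 100` in ug/h, with
#' particle radius `r_p` and layer thickness `h` converted from um to cm.
#' The rate is zero without solid and reverses sign under supersaturation
#' (precipitation).
#'
#' @param c_solid Undissolved drug concentration in the lumen, ug/mL.
#' @param c_diss Dissolved drug concentration, ug/mL.
#' @param solubility Local saturation solubility, mg/L (= ug/mL).
#' @param v_lumen Lumen volume, mL (> 0).
#' @param params A [dissolution_params()] record.
#' @return Dissolution rate in ug/h.
#' @export
dissolution_rate <- function(c_solid, c_diss, solubility, v_lumen,
                             params = dissolution_params()) {
  if (any(v_lumen <= 0)) stop("`v_lumen` must be positive", call. = FALSE)
  rp_cm <- params$r_particle * 1e-4
  dlt_cm <- params$dlt * 1e-4
  3 * params$diff_coeff / (params$rho * rp_cm * dlt_cm * v_lumen) *
    c_solid * (solubility - c_diss) * params$unit_factor
}

#' Regression estimate of effective human permeability
#'
#' In vitro to in vivo permeability scaling
#' `log10 HPeff = 0.86 + 0.92 log10 Papp` (MDCK apparent permeability to
#' human jejunal effective permeability). The simulation itself uses the
#' calibrated constant in [drug_properties()] (`HPeff = 0.963e-4` cm/s),
#' which does not coincide with this regression applied to the measured
#' `Papp`; the regression is kept as the documented provenance of the
#' estimate's order of magnitude.
#'
#' @param Papp Apparent permeability, cm/s (> 0).
#' @return Estimated effective permeability, cm/s.
#' @export
effective_permeability <- function(Papp) {
  if (any(Papp <= 0)) stop("`Papp` must be positive", call. = FALSE)
  10^(0.86 + 0.92 * log10(Papp))
}
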