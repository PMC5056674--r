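#' Whole-body (systemic) physiology of a subject
#'
#' The systemic layer is a minimal flow-limited circulation: a plasma
#' (central) compartment plus liver, richly perfused and slowly perfused
#' lumped tissues, with venous return to plasma. The liver receives arterial
#' blood directly (hepatic artery) and the pooled portal outflow of the eight
#' intestinal segments. Tissue partition coefficients default to the hepatic
#' value 5.66 for liver, gut wall and richly perfused tissue and 2.0 for
#' slowly perfused tissue.
#'
#' Fractional perfusion must sum to one:
#' `flow_liver_total + flow_richly + flow_slowly = 1`, with
#' `flow_liver_total = flow_hepatic_artery + 8 * gut segment flow`. By
#' default `flow_richly` is derived as the balance.
#'
#' @param body_weight Body weight, kg.
#' @param sex `"male"` or `"female"` (sets the hepatic flow fraction:
#'   0.255 vs 0.27 of cardiac output).
#' @param cardiac_output Blood flow, L/h. Default `5.2 * 60 * (BW/70)^0.75`.
#' @param plasma_volume,liver_volume,richly_volume,slowly_volume Tissue
#'   volumes, L (density 1 kg/L). Defaults scale linearly with body weight.
#' @param flow_hepatic_artery Hepatic arterial fraction of cardiac output.
#' @param flow_slowly Slowly perfused fraction of cardiac output.
#' @param flow_richly Richly perfused fraction; default balances the total
#'   to one.
#' @param P_liver,P_richly,P_slowly Tissue:blood partition coefficients.
#' @return A list of class `subject_physiology`.
#' @export
subject_physiology <- function(body_weight = 70, sex = c("male", "female"),
                               cardiac_output = NULL,
                               plasma_volume = 0.0424 * body_weight,
                               liver_volume = 0.0257 * body_weight,
                               richly_volume = 0.10 * body_weight,
                               slowly_volume = 0.60 * body_weight,
                               flow_hepatic_artery = 0.065,
                               flow_slowly = 0.35,
                               flow_richly = NULL,
                               P_liver = 5.66, P_richly = 5.66,
                               P_slowly = 2.0) {
  sex <- match.arg(sex)
  if (body_weight <= 0) stop("`body_weight` must be positive", call. = FALSE)
  flow_liver_total <- flow_hepatic_artery + 8 * gut_flow_fraction(sex)
  flow_richly <- flow_richly %||% (1 - flow_liver_total - flow_slowly)
  flows <- c(flow_liver_total, flow_richly, flow_slowly)
  if (any(flows <= 0)) stop("fractional flows must be positive", call. = FALSE)
  if (abs(sum(flows) - 1) > 1e-8) {
    stop("fractional flows must sum to 1 across perfused compartments",
         call. = FALSE)
  }
  vols <- plasma_volume + liver_volume + richly_volume + slowly_volume
  if (vols > body_weight) {
    stop("tissue volumes exceed body weight", call. = FALSE)
  }
  structure(list(
    body_weight = body_weight, sex = sex,
    cardiac_output = cardiac_output %||% (5.2 * 60 * (body_weight / 70)^0.75),
    plasma_volume = plasma_volume, liver_volume = liver_volume,
    richly_volume = richly_volume, slowly_volume = slowly_volume,
    flow_hepatic_artery = flow_hepatic_artery,
    flow_richly = flow_richly, flow_slowly = flow_slowly,
    P_liver = P_liver, P_richly = P_richly, P_slowly = P_slowly
  ), class = "subject_physiology")
}

#' Hepatic metabolism and gut-loss parameters
#'
#' Enantioselective hepatic hydrolysis by carboxylesterase hCES1A1 is
#' saturable and mutually competitive between the d- and l-enantiomers;
#' hepatic oxidation is first-order; non-specific loss in the gut wall is
#' first-order on the enterocyte amount. Parameters carrying the `C` suffix
#' are allometric coefficients applied as `value * BW^0.75`.
#'
#' @param Kmliverd,Kmliverl Michaelis constants for d- and l-MPH hydrolysis,
#'   ug/L.
#' @param VmaxliverdC,VmaxliverlC Maximum hydrolysis velocities,
#'   ug/h/kg^0.75.
#' @param KmetdC,KmetlC First-order hepatic oxidation clearances,
#'   L/h/kg^0.75.
#' @param K5dC,K5lC First-order gut non-specific loss constants,
#'   1/h/kg^0.75. The l-enantiomer constant is ~48-fold larger, which is
#'   what suppresses circulating l-MPH after oral dosing.
#' @return A list of class `metabolism_params`.
#' @export
metabolism_params <- function(Kmliverd = 27600, Kmliverl = 10172,
                              VmaxliverdC = 25826, VmaxliverlC = 52404,
                              KmetdC = 0.43, KmetlC = 0.43,
                              K5dC = 0.79, K5lC = 37.8) {
  vals <- list(Kmliverd = Kmliverd, Kmliverl = Kmliverl,
               VmaxliverdC = VmaxliverdC, VmaxliverlC = VmaxliverlC,
               KmetdC = KmetdC, KmetlC = KmetlC, K5dC = K5dC, K5lC = K5lC)
  if (any(vapply(vals, function(x) !is.numeric(x) || x < 0, logical(1)))) {
    stop("metabolism parameters must be non-negative numbers", call. = FALSE)
  }
  structure(vals, class = "metabolism_params")
}

#' Competitive hepatic hydrolysis rates for the two enantiomers
#'
#' Michaelis-Menten hydrolysis with mutual competitive inhibition at the
#' shared carboxylesterase:
#' `v_d = Vmaxd BW^0.75 C_d / (Kmd (1 + C_l/Kml) + C_d)` and symmetrically
#' for the l-enantiomer. Concentrations are hepatic free concentrations
#' (tissue concentration divided by the liver partition coefficient).
#'
#' @param c_liver_d,c_liver_l Free hepatic concentrations, ug/L (>= 0).
#' @param params A [metabolism_params()] record.
#' @param body_weight Body weight, kg.
#' @return Named numeric vector `c(d = ..., l = ...)`, ug/h.
#' @export
hepatic_hydrolysis_rates <- function(c_liver_d, c_liver_l,
                                     params = metabolism_params(),
                                     body_weight = 70) {
  if (c_liver_d < 0 || c_liver_l < 0) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  bw75 <- body_weight^0.75
  v_d <- params$VmaxliverdC * bw75 * c_liver_d /
    (params$Kmliverd * (1 + c_liver_l / params$Kmliverl) + c_liver_d)
  v_l <- params$VmaxliverlC * bw75 * c_liver_l /
    (params$Kmliverl * (1 + c_liver_d / params$Kmliverd) + c_liver_l)
  c(d = v_d, l = v_l)
}
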