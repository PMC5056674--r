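#' Assemble a complete model parameterization
#'
#' Bundles everything a simulation needs: the formulation, the subject's
#' systemic physiology, the GI physiology table (resolved to the
#' formulation's prandial state and the subject's sex unless supplied), the
#' drug constants, the metabolism/gut-loss constants and the dissolution
#' parameters. The result is the unit that [simulate_mph()],
#' [run_population()] and [sensitivity_screen()] operate on, and the object
#' that parameter paths address.
#'
#' @param formulation An `mph_formulation` (see [formulation()],
#'   [builtin_formulation()]).
#' @param subject A [subject_physiology()] record.
#' @param physiology A [gi_physiology()] table; defaults to the table for
#'   the formulation's prandial state and the subject's sex.
#' @param drug A [drug_properties()] record.
#' @param metabolism A [metabolism_params()] record.
#' @param dissolution A [dissolution_params()] record.
#' @return A list of class `mph_model`.
#' @examples
#' m <- mph_model(builtin_formulation("IR-MPH"))
#' param_get(m, "physiology.jejunum1.pH")
#' @export
mph_model <- function(formulation,
                      subject = subject_physiology(),
                      physiology = NULL,
                      drug = drug_properties(),
                      metabolism = metabolism_params(),
                      dissolution = dissolution_params()) {
  stopifnot(inherits(formulation, "mph_formulation"))
  physiology <- physiology %||%
    gi_physiology(formulation$prandial_state, subject$sex)
  state <- attr(physiology, "state")
  if (!is.null(state) && !identical(state, formulation$prandial_state)) {
    stop(sprintf(
      "physiology is %s-state but the formulation is dosed %s",
      state, formulation$prandial_state), call. = FALSE)
  }
  structure(list(formulation = formulation, subject = subject,
                 physiology = physiology, drug = drug,
                 metabolism = metabolism, dissolution = dissolution),
            class = "mph_model")
}

#' Address model parameters by path
#'
#' Parameters anywhere in an assembled model are addressed with dotted
#' paths: `"drug.HPeff"`, `"metabolism.K5dC"`,
#' `"subject.cardiac_output"`, `"formulation.dose_mg"`,
#' `"formulation.weibull.tlag"`, and — for the GI table —
#' `"physiology.<segment>.<column>"`, e.g. `"physiology.jejunum1.pH"`.
#' Setting a geometry field (`length`, `radius`) recomputes the segment's
#' surface area from the formula.
#'
#' @param model An `mph_model`.
#' @param path Dotted parameter path.
#' @param value Replacement value (scalar, for `param_set`).
#' @return `param_get()` returns the numeric value; `param_set()` returns
#'   the modified model.
#' @export
param_get <- function(model, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  top <- parts[1]
  if (top == "physiology") {
    if (length(parts) != 3) stop("physiology paths are physiology.<segment>.<column>", call. = FALSE)
    i <- match(parts[2], model$physiology$segment)
    if (is.na(i)) stop(sprintf("unknown segment '%s'", parts[2]), call. = FALSE)
    col <- parts[3]
    if (!col %in% names(model$physiology)) {
      stop(sprintf("unknown physiology column '%s'", col), call. = FALSE)
    }
    return(model$physiology[[col]][i])
  }
  comp <- model[[top]]
  if (is.null(comp)) stop(sprintf("unknown parameter path '%s'", path), call. = FALSE)
  for (p in parts[-1]) {
    comp <- comp[[p]]
    if (is.null(comp)) stop(sprintf("unknown parameter path '%s'", path), call. = FALSE)
  }
  comp
}

#' @rdname param_get
#' @export
param_set <- function(model, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  top <- parts[1]
  if (top == "physiology") {
    i <- match(parts[2], model$physiology$segment)
    col <- parts[3]
    if (is.na(i) || !col %in% names(model$physiology)) {
      stop(sprintf("unknown parameter path '%s'", path), call. = FALSE)
    }
    model$physiology[[col]][i] <- value
    if (col %in% c("length", "radius") && !is.na(model$physiology$segment_class[i])) {
      model$physiology$surface_area[i] <- surface_area(
        model$physiology$length[i], model$physiology$radius[i],
        model$physiology$segment_class[i])
    }
    return(model)
  }
  if (is.null(model[[top]])) stop(sprintf("unknown parameter path '%s'", path), call. = FALSE)
  if (length(parts) == 2) {
    if (is.null(model[[top]][[parts[2]]])) {
      stop(sprintf("unknown parameter path '%s'", path), call. = FALSE)
    }
    model[[top]][[parts[2]]] <- value
  } else if (length(parts) == 3) {
    if (is.null(model[[top]][[parts[2]]][[parts[3]]])) {
      stop(sprintf("unknown parameter path '%s'", path), call. = FALSE)
    }
    model[[top]][[parts[2]]][[parts[3]]] <- value
  } else {
    stop(sprintf("unknown parameter path '%s'", path), call. = FALSE)
  }
  model
}

#' First-order intestinal transit rate constants
#'
#' Transit between serial GI compartments is first-order with rate
#' `1 / transit_time`; the outflow of the ascending colon is the
#' fecal-excretion sink.
#'
#' @param physiology A [gi_physiology()] table.
#' @return A tibble with `segment` and `rate` (1/h).
#' @export
transit_rates <- function(physiology) {
  if (any(physiology$transit_time <= 0)) {
    stop("transit times must be positive", call. = FALSE)
  }
  tibble::tibble(segment = physiology$segment,
                 rate = 1 / physiology$transit_time)
}

#' Passive trans-mucosal absorption flux for one segment
#'
#' Passive diffusion from lumen into enterocytes:
#' `3600 * HPeff * ESA * NI * (Cdiss - Cmem/1000)` in ug/h, where `NI` is the
#' unionized fraction at the segment's pH and the factor 1000 reconciles the
#' luminal (ug/mL) and enterocyte (ug/L) concentration scales. The flux is
#' bidirectional; there is no gastric absorption.
#'
#' @param c_diss Dissolved luminal concentration, ug/mL.
#' @param c_mem Enterocyte concentration, ug/L.
#' @param segment One-row slice of a physiology table (not the stomach).
#' @param props A [drug_properties()] record.
#' @return Flux in ug/h (positive into the enterocyte).
#' @export
absorption_flux <- function(c_diss, c_mem, segment, props = drug_properties()) {
  if (identical(segment$segment, "stomach")) {
    stop("no absorption occurs in the stomach", call. = FALSE)
  }
  ni <- unionized_fraction(segment$pH, props$pKa)
  3600 * props$HPeff * segment$surface_area * ni * (c_diss - c_mem / 1000)
}
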