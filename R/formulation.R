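#' Weibull release parameters
#'
#' The extended-release component is released according to the empirical
#' Weibull law `W(t) = 1 - exp(-(t - tlag)^b / a)` for `t > tlag` and 0
#' before. `tlag` is the latency before any release (hours), `a` is the time
#' scale (h^b) and `b` the shape: `b = 1` exponential, `b > 1` sigmoid,
#' `b < 1` parabolic.
#'
#' @param tlag Lag time, h (>= 0).
#' @param a Scale parameter, h^b (> 0).
#' @param b Shape parameter (> 0).
#' @return A list of class `weibull_params`.
#' @export
weibull_params <- function(tlag = 4, a = 0.5, b = 2) {
  if (a <= 0 || b <= 0 || tlag < 0) {
    stop("require a > 0, b > 0, tlag >= 0", call. = FALSE)
  }
  structure(list(tlag = tlag, a = a, b = b), class = "weibull_params")
}

#' Cumulative Weibull release fraction
#'
#' @param t Time since dose, h (>= 0). Vectorised.
#' @param params A [weibull_params()] record.
#' @return Fraction of the releasable depot released by `t`, in \[0, 1\];
#'   non-decreasing, 0 at `t <= tlag`, tending to 1.
#' @examples
#' weibull_cumulative(5, weibull_params(4, 6, 4)) # 1 - exp(-1/6)
#' @export
weibull_cumulative <- function(t, params) {
  u <- pmax(t - params$tlag, 0)
  1 - exp(-u^params$b / params$a)
}

#' Weibull release hazard
#'
#' The instantaneous hazard of the Weibull law,
#' `(b/a) (t - tlag)^(b-1)` for `t > tlag`, else 0. Applying this rate to a
#' static depot reproduces [weibull_cumulative()] exactly; it diverges with
#' time for `b > 1`, so a depot held in place always empties completely.
#'
#' @inheritParams weibull_cumulative
#' @return Hazard in 1/h. Vectorised.
#' @export
weibull_hazard <- function(t, params) {
  u <- t - params$tlag
  ifelse(u > 0, (params$b / params$a) * u^(params$b - 1), 0)
}

#' Weibull release-rate coefficient
#'
#' The density of the Weibull law,
#' `(b/a) (t - tlag)^(b-1) exp(-(t - tlag)^b / a)`, used by the simulator as
#' the first-order release coefficient applied to the unreleased depot in
#' each intestinal segment. Its integral over all time is exactly 1, so a
#' depot held in a single compartment releases the fraction
#' `1 - exp(-W(t))`, approaching `1 - exp(-1) = 63.2%` — beads carry a finite
#' release capability rather than an ever-growing hazard. See the methods
#' vignette for why this, and not [weibull_hazard()], is the in-transit
#' release rule.
#'
#' @inheritParams weibull_cumulative
#' @return Rate coefficient in 1/h. Vectorised.
#' @export
weibull_release_rate <- function(t, params) {
  u <- t - params$tlag
  ifelse(u > 0,
         (params$b / params$a) * u^(params$b - 1) * exp(-u^params$b / params$a),
         0)
}

#' Construct a formulation specification
#'
#' A formulation is a total dose split between an immediate-release (IR)
#' fraction, which enters the stomach as solid particles and dissolves by the
#' Noyes-Whitney law, and an extended-release (ER) fraction, which transits
#' as intact beads and releases by the Weibull law only within the intestine.
#' Marketed products are racemic; the dose is split d:l by
#' `enantiomer_split`.
#'
#' @param name Label.
#' @param dose_mg Total dose, mg (> 0).
#' @param ir_fraction Fraction of the dose that is immediate-release, in
#'   \[0, 1\]. The ER fraction is the complement.
#' @param weibull A [weibull_params()] record, or `NULL` for a pure IR
#'   product (`ir_fraction = 1`).
#' @param prandial_state `"fasted"` or `"fed"`; must match the physiology
#'   used for simulation.
#' @param enantiomer_split Fraction of the dose that is the d-enantiomer.
#' @return A list of class `mph_formulation`.
#' @export
formulation <- function(name, dose_mg, ir_fraction, weibull = NULL,
                        prandial_state = c("fasted", "fed"),
                        enantiomer_split = 0.5) {
  prandial_state <- match.arg(prandial_state)
  if (dose_mg < 0) stop("`dose_mg` must be non-negative", call. = FALSE)
  if (ir_fraction < 0 || ir_fraction > 1) {
    stop("`ir_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (ir_fraction < 1 && is.null(weibull)) {
    stop("formulations with an ER fraction need `weibull` release parameters",
         call. = FALSE)
  }
  structure(list(name = name, dose_mg = dose_mg, ir_fraction = ir_fraction,
                 weibull = weibull, prandial_state = prandial_state,
                 enantiomer_split = enantiomer_split),
            class = "mph_formulation")
}

# name, default dose, IR fraction, Weibull (a, b; tlag 4 throughout), state
.builtin_catalogue <- function() {
  tibble::tibble(
    name = c("IR-MPH", "MLR-MPH", "Ritalin LA", "Metadate CD",
             "Medikinet Retard"),
    dose_mg = c(20, 20, 40, 20, 20),
    ir_fraction = c(1, 0.40, 0.50, 0.30, 0.50),
    tlag = c(NA, 4, 4, 4, 4),
    a = c(NA, 6, 0.5, 0.5, 0.5),
    b = c(NA, 4, 2, 2, 2),
    prandial_state = c("fasted", "fasted", "fasted", "fasted", "fed")
  )
}

#' Built-in formulation catalogue
#'
#' The five studied products: a pure IR reference; the multilayer-release
#' beads MLR-MPH (40:60 IR:ER, slow sigmoid release); the SODAS product
#' Ritalin LA (50:50); the Diffucaps product Metadate CD (30:70); and the
#' enteric-coated Medikinet Retard (50:50), which is dosed fed. All ER
#' products share a 4 h release lag.
#'
#' @return A tibble with one row per product: `name`, default `dose_mg`,
#'   `ir_fraction`, Weibull `tlag`/`a`/`b` (NA for pure IR) and
#'   `prandial_state`.
#' @seealso [builtin_formulation()] to instantiate one entry.
#' @export
builtin_formulations <- function() {
  .builtin_catalogue()
}

#' Instantiate a built-in formulation
#'
#' @param name One of the names in [builtin_formulations()].
#' @param dose_mg Optional dose override, mg.
#' @return An `mph_formulation` object.
#' @examples
#' builtin_formulation("MLR-MPH")
#' builtin_formulation("Ritalin LA", dose_mg = 20)
#' @export
builtin_formulation <- function(name, dose_mg = NULL) {
  cat_tbl <- .builtin_catalogue()
  row <- cat_tbl[cat_tbl$name == name, ]
  if (nrow(row) != 1) {
    stop(sprintf("unknown formulation '%s'; see builtin_formulations()", name),
         call. = FALSE)
  }
  wb <- if (row$ir_fraction < 1) weibull_params(row$tlag, row$a, row$b) else NULL
  formulation(row$name, dose_mg %||% row$dose_mg, row$ir_fraction, wb,
              row$prandial_state)
}

#' Read / write a formulation catalogue as JSON
#'
#' The on-disk dialect is a JSON array of objects with fields `name`,
#' `dose_mg`, `ir_fraction`, `tlag_h`, `A`, `b` and `prandial_state`
#' (release fields `null` for pure IR rows).
#'
#' @param catalogue A tibble in the layout of [builtin_formulations()].
#' @param path File path.
#' @return `read_formulations()` returns the catalogue tibble;
#'   `write_formulations()` returns `path` invisibly.
#' @export
write_formulations <- function(catalogue, path) {
  out <- tibble::tibble(
    name = catalogue$name, dose_mg = catalogue$dose_mg,
    ir_fraction = catalogue$ir_fraction, tlag_h = catalogue$tlag,
    A = catalogue$a, b = catalogue$b, prandial_state = catalogue$prandial_state
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname write_formulations
#' @export
read_formulations <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("name", "dose_mg", "ir_fraction", "tlag_h", "A", "b",
            "prandial_state")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("formulation file is missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    name = raw$name, dose_mg = as.numeric(raw$dose_mg),
    ir_fraction = as.numeric(raw$ir_fraction),
    tlag = as.numeric(raw$tlag_h), a = as.numeric(raw$A),
    b = as.numeric(raw$b), prandial_state = raw$prandial_state
  )
}
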