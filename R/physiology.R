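#' Gastrointestinal segment names, in anatomical order
#'
#' The absorption model divides the gut into nine serial compartments:
#' stomach, duodenum, two jejunal segments, three ileal segments, caecum and
#' ascending colon. All physiology tables and segment-resolved outputs use
#' this ordering.
#'
#' @format Character vector of length 9.
#' @export
gi_segments <- c(
  "stomach", "duodenum", "jejunum1", "jejunum2",
  "ileum1", "ileum2", "ileum3", "caecum", "ascending_colon"
)

#' Effective absorptive surface area of an intestinal segment
#'
#' Computes the effective surface area from macroscopic cylinder geometry with
#' anatomical enlargement factors (plicae circulares, villi and microvilli for
#' the small intestine; a single microvillus factor for the large intestine):
#' small intestine `length * diameter * pi * 1.57 * 6.5 * 13`, large intestine
#' `length * diameter * pi * 6.5`, with `diameter = 2 * radius`.
#'
#' @param length Segment length in cm.
#' @param radius Segment radius in cm.
#' @param segment_class `"small"` or `"large"` intestine.
#' @return Surface area in cm^2. Vectorised over `length` and `radius`.
#' @examples
#' surface_area(15, 1.6, "small")    # duodenum, ~19995 cm^2
#' surface_area(29.02, 2.5, "large") # ascending colon, ~2961 cm^2
#' @export
surface_area <- function(length, radius, segment_class = c("small", "large")) {
  segment_class <- match.arg(segment_class)
  if (any(!is.finite(length) | length <= 0) || any(!is.finite(radius) | radius <= 0)) {
    stop("invalid geometry: `length` and `radius` must be strictly positive",
         call. = FALSE)
  }
  enlargement <- if (segment_class == "small") 1.57 * 6.5 * 13 else 6.5
  length * 2 * radius * pi * enlargement
}

#' Fraction of cardiac output perfusing each intestinal segment
#'
#' Portal (gut) blood flow is taken as total hepatic flow minus the hepatic
#' arterial flow, distributed evenly over the eight absorbing segments.
#' Total hepatic flow is 0.255 of cardiac output in males and 0.27 in
#' females; the hepatic artery receives 0.065 in both sexes.
#'
#' @param sex `"male"` or `"female"`.
#' @return Fraction of cardiac output per segment (0.02375 male,
#'   0.025625 female; conventionally rounded to 0.024 / 0.026).
#' @export
gut_flow_fraction <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  liver_flow <- if (sex == "male") 0.255 else 0.27
  (liver_flow - 0.065) / 8
}

# Reference GI physiology: pH, transit, volumes, geometry, bile and wall
# parameters for an adult human, with fasted/fed alternatives where the state
# changes them (stomach pH and emptying time; proximal intestinal pH; bile).
# Stomach geometry/flow/wall fields are absent: the stomach contributes only
# dissolution and emptying, no absorption.
.gi_reference <- function() {
  tibble::tibble(
    segment            = gi_segments,
    pH_fasted          = c(1.3, 6.0, 6.2, 6.4, 6.6, 6.9, 7.4, 6.4, 6.8),
    pH_fed             = c(4.9, 5.4, 5.4, 6.0, 6.6, 6.9, 7.4, 6.4, 6.8),
    transit_time_fasted = c(0.25, 0.26, 0.95, 0.76, 0.59, 0.43, 0.31, 4.50, 13.5),
    transit_time_fed   = c(1.00, 0.26, 0.95, 0.76, 0.59, 0.43, 0.31, 4.50, 13.5),
    lumen_volume       = c(50, 48, 175, 140, 109, 79, 56, 53, 57),
    length             = c(NA, 15, 62, 62, 62, 62, 62, 13.75, 29.02),
    radius             = c(NA, 1.6, 1.5, 1.34, 1.18, 1.01, 0.85, 3.5, 2.5),
    segment_class      = c(NA, rep("small", 6), rep("large", 2)),
    bile_fasted        = c(NA, 2.8, 2.33, 2.03, 1.41, 1.16, 0.14, 0, 0),
    bile_fed           = c(NA, 14.44, 12.02, 10.46, 7.28, 5.99, 0.73, 0, 0),
    wall_mass_fraction_male   = c(NA, 0.00077, 0.0019, 0.0019, 0.0014, 0.0014,
                                  0.0014, 0.0004, 0.00085),
    wall_mass_fraction_female = c(NA, 0.00088, 0.0019, 0.0019, 0.0015, 0.0015,
                                  0.0015, 0.0004, 0.00093)
  )
}

#' Default gastrointestinal physiology table
#'
#' Returns the nine-segment GI physiology resolved to a prandial state and
#' sex: luminal pH, mean transit time, lumen volume, cylinder geometry with
#' the derived effective surface area, bile salt concentration, the fraction
#' of cardiac output perfusing each segment, and the gut-wall (enterocyte)
#' mass fraction of body weight. Surface areas are recomputed from length and
#' radius with [surface_area()] rather than carried as constants, so the
#' column stays consistent with the geometry under perturbation.
#'
#' The fed state swaps stomach pH 1.3 to 4.9, gastric emptying 0.25 h to 1 h,
#' lowers proximal small-intestinal pH, and raises bile concentrations.
#' Segments without a fed-specific value keep their single reference value;
#' lumen volumes are state-invariant (no meal-volume adjustment is applied).
#'
#' @param state Prandial state, `"fasted"` or `"fed"`.
#' @param sex `"male"` or `"female"` (affects perfusion and wall mass).
#' @return A tibble with one row per segment in anatomical order and
#'   attributes `state` and `sex`. Stomach geometry, flow and wall fields are
#'   `NA` (no gastric absorption).
#' @examples
#' gi_physiology()
#' gi_physiology("fed")$pH[1] # 4.9
#' @export
gi_physiology <- function(state = c("fasted", "fed"), sex = c("male", "female")) {
  state <- match.arg(state)
  sex <- match.arg(sex)
  ref <- .gi_reference()
  fed <- state == "fed"
  out <- tibble::tibble(
    segment       = ref$segment,
    pH            = if (fed) ref$pH_fed else ref$pH_fasted,
    transit_time  = if (fed) ref$transit_time_fed else ref$transit_time_fasted,
    lumen_volume  = ref$lumen_volume,
    length        = ref$length,
    radius        = ref$radius,
    segment_class = ref$segment_class,
    surface_area  = NA_real_,
    bile_conc     = if (fed) ref$bile_fed else ref$bile_fasted,
    flow_fraction = c(NA, rep(gut_flow_fraction(sex), 8)),
    wall_mass_fraction = if (sex == "male") ref$wall_mass_fraction_male
                         else ref$wall_mass_fraction_female
  )
  intestinal <- !is.na(out$segment_class)
  small <- intestinal & out$segment_class == "small"
  large <- intestinal & out$segment_class == "large"
  out$surface_area[small] <- surface_area(out$length[small], out$radius[small], "small")
  out$surface_area[large] <- surface_area(out$length[large], out$radius[large], "large")
  attr(out, "state") <- state
  attr(out, "sex") <- sex
  class(out) <- c("gi_physiology", class(out))
  validate_physiology(out)
  out
}

#' Validate a GI physiology table
#'
#' Checks the structural invariants a physiology table must satisfy before
#' simulation: nine segments in anatomical order (stomach first), strictly
#' positive physical quantities, pH within 1-8, transit times within
#' (0, 24] h, non-negative bile (zero in caecum and ascending colon for the
#' built-in table), and surface areas consistent with the geometric formula
#' to within 0.5%.
#'
#' @param physiology A tibble as returned by [gi_physiology()] or
#'   [read_physiology()].
#' @return The table, invisibly, if valid; otherwise an error naming the
#'   violated invariant.
#' @export
validate_physiology <- function(physiology) {
  p <- physiology
  if (!identical(p$segment, gi_segments)) {
    stop("physiology must contain the nine GI segments in anatomical order",
         call. = FALSE)
  }
  if (any(p$pH < 1 | p$pH > 8)) stop("pH values must lie in [1, 8]", call. = FALSE)
  if (any(p$transit_time <= 0 | p$transit_time > 24)) {
    stop("transit times must lie in (0, 24] h", call. = FALSE)
  }
  if (any(p$lumen_volume <= 0)) stop("lumen volumes must be positive", call. = FALSE)
  intest <- p$segment != "stomach"
  pos_cols <- c("length", "radius", "surface_area", "flow_fraction",
                "wall_mass_fraction")
  for (col in pos_cols) {
    if (any(!is.finite(p[[col]][intest]) | p[[col]][intest] <= 0)) {
      stop(sprintf("intestinal `%s` must be strictly positive", col), call. = FALSE)
    }
  }
  if (any(p$bile_conc[intest] < 0)) stop("bile concentrations must be >= 0", call. = FALSE)
  expected <- ifelse(p$segment_class[intest] == "small",
                     surface_area(p$length[intest], p$radius[intest], "small"),
                     surface_area(p$length[intest], p$radius[intest], "large"))
  rel <- abs(p$surface_area[intest] - expected) / expected
  if (any(rel > 0.005)) {
    stop("surface areas deviate from the geometric formula by more than 0.5%",
         call. = FALSE)
  }
  invisible(p)
}

# Column headers used in the CSV dialect for physiology tables.
.phys_csv_names <- c(
  segment = "Compartment", pH = "pH", transit_time = "Transit Time (hr)",
  lumen_volume = "Volume (mL)", length = "Length (cm)", radius = "Radius (cm)",
  segment_class = "Class", surface_area = "Surface area (cm2)",
  bile_conc = "Bile Con (mM)",
  flow_fraction = "Blood Flow (fraction of cardiac output)",
  wall_mass_fraction = "Mass (fraction of body weight)"
)

#' Read / write a physiology table as CSV
#'
#' One row per segment, with the conventional printed column headers
#' (`Compartment`, `pH`, `Transit Time (hr)`, ...). `read_physiology()`
#' validates the table on load.
#'
#' @param physiology A physiology tibble.
#' @param path File path.
#' @return `read_physiology()` returns a validated physiology tibble;
#'   `write_physiology()` returns `path` invisibly.
#' @export
write_physiology <- function(physiology, path) {
  out <- physiology
  names(out) <- .phys_csv_names[names(out)]
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_physiology
#' @export
read_physiology <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(unname(.phys_csv_names), names(raw))
  if (length(missing) > 0) {
    stop("physiology CSV is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- raw[, unname(.phys_csv_names)]
  names(out) <- names(.phys_csv_names)
  out <- tibble::as_tibble(out)
  class(out) <- c("gi_physiology", class(out))
  validate_physiology(out)
  out
}
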