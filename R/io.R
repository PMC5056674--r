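#' Load a run configuration file
#'
#' Reads a JSON configuration and assembles a fully validated model plus run
#' settings, filling every omitted field with the package defaults (IR
#' product, 20 mg, fasted 70 kg male). Recognised top-level keys:
#' `formulation` (a catalogue name, or an object with `name`, `dose_mg`,
#' `ir_fraction`, `tlag_h`, `A`, `b`, `prandial_state`), `dose_mg`, `sex`,
#' `subject`, `metabolism`, `drug`, `dissolution`, `physiology` (an object
#' of `segment: {column: value}` overrides), `seed` and `t_end`. Unknown
#' keys, and overrides that violate a type invariant, are rejected with an
#' error naming the offending field.
#'
#' @param path Path to a JSON file. An empty file (or `{}`) yields the
#'   default configuration.
#' @return A list of class `mph_run_config` with elements `model`, `seed`,
#'   `t_end`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path),
                               call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  cfg <- if (!nzchar(trimws(txt))) list() else
    jsonlite::fromJSON(txt, simplifyVector = TRUE)
  allowed <- c("formulation", "dose_mg", "sex", "subject", "metabolism",
               "drug", "dissolution", "physiology", "seed", "t_end")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  frm <- if (is.null(cfg$formulation)) {
    builtin_formulation("IR-MPH", cfg$dose_mg)
  } else if (is.character(cfg$formulation)) {
    builtin_formulation(cfg$formulation, cfg$dose_mg)
  } else {
    f <- cfg$formulation
    wb <- if (!is.null(f$A)) weibull_params(f$tlag_h %||% 4, f$A, f$b) else NULL
    formulation(f$name %||% "custom", f$dose_mg %||% cfg$dose_mg %||% 20,
                f$ir_fraction %||% 1, wb, f$prandial_state %||% "fasted")
  }
  sex <- cfg$sex %||% "male"
  subj <- do.call(subject_physiology,
                  c(list(sex = sex), as.list(cfg$subject)))
  metab <- do.call(metabolism_params, as.list(cfg$metabolism))
  drug <- do.call(drug_properties, as.list(cfg$drug))
  dsl <- do.call(dissolution_params, as.list(cfg$dissolution))
  model <- mph_model(frm, subject = subj, drug = drug, metabolism = metab,
                     dissolution = dsl)
  if (!is.null(cfg$physiology)) {
    for (seg in names(cfg$physiology)) {
      for (col in names(cfg$physiology[[seg]])) {
        model <- param_set(model, paste("physiology", seg, col, sep = "."),
                           cfg$physiology[[seg]][[col]])
      }
    }
    validate_physiology(model$physiology)
  }
  structure(list(model = model, seed = cfg$seed %||% 1L,
                 t_end = cfg$t_end %||% 24),
            class = "mph_run_config")
}

#' Write a run configuration file
#'
#' Serialises an `mph_run_config` back to the JSON dialect read by
#' [load_run_config()]; a write-then-read round trip reproduces the
#' configuration.
#'
#' @param config An `mph_run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  m <- config$model
  frm <- m$formulation
  out <- list(
    formulation = list(
      name = frm$name, dose_mg = frm$dose_mg, ir_fraction = frm$ir_fraction,
      tlag_h = frm$weibull$tlag, A = frm$weibull$a, b = frm$weibull$b,
      prandial_state = frm$prandial_state),
    sex = m$subject$sex,
    subject = unclass(m$subject)[setdiff(names(m$subject), "sex")],
    metabolism = unclass(m$metabolism),
    drug = unclass(m$drug),
    dissolution = unclass(m$dissolution),
    seed = config$seed, t_end = config$t_end
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Segment-resolved release/absorption report
#'
#' Formats a simulation's segment table the way such results are
#' conventionally printed: one column per intestinal segment plus a total,
#' one row for the ER release fractions (% of the ER sub-dose; omitted for
#' pure IR products) and one for the absorption-into-enterocyte fractions
#' (% of the total dose), all to one decimal place. Totals are computed from
#' unrounded values.
#'
#' @param sim An `mph_sim` result.
#' @return A tibble with a `quantity` column followed by one column per
#'   segment and `Total`.
#' @export
report_segment_table <- function(sim) {
  stopifnot(inherits(sim, "mph_sim"))
  seg <- sim$segments
  pretty <- c(duodenum = "Duodenum", jejunum1 = "Jejunum1",
              jejunum2 = "Jejunum2", ileum1 = "Ileum1", ileum2 = "Ileum2",
              ileum3 = "Ileum3", caecum = "Caecum",
              ascending_colon = "Ascending Colon")
  make_row <- function(label, vals) {
    row <- as.list(round(vals, 1))
    names(row) <- pretty[seg$segment]
    dplyr::bind_cols(tibble::tibble(quantity = label),
                     tibble::as_tibble(row),
                     tibble::tibble(Total = round(sum(vals), 1)))
  }
  rows <- list()
  if (!all(is.na(seg$released_pct))) {
    rows <- c(rows, list(make_row("Released (% of ER component)",
                                  seg$released_pct)))
  }
  rows <- c(rows, list(make_row("Absorbed (% of total dose)",
                                seg$absorbed_pct)))
  dplyr::bind_rows(rows)
}

#' Write simulation outputs as CSV
#'
#' Emits the plasma curve (`<prefix>_plasma.csv`: `time_h`,
#' `conc_d_ng_ml`, `conc_l_ng_ml`, `conc_total_ng_ml`), the mass ledger
#' (`<prefix>_ledger.csv`) and the segment report
#' (`<prefix>_segments.csv`).
#'
#' @param sim An `mph_sim` result.
#' @param prefix Output path prefix.
#' @return Character vector of the written paths, invisibly.
#' @export
write_simulation_csv <- function(sim, prefix) {
  stopifnot(inherits(sim, "mph_sim"))
  plasma <- tibble::tibble(
    time_h = sim$plasma$time,
    conc_d_ng_ml = sim$plasma$conc_d,
    conc_l_ng_ml = sim$plasma$conc_l,
    conc_total_ng_ml = sim$plasma$conc_total
  )
  paths <- paste0(prefix, c("_plasma.csv", "_ledger.csv", "_segments.csv"))
  readr::write_csv(plasma, paths[1])
  readr::write_csv(sim$ledger, paths[2])
  readr::write_csv(report_segment_table(sim), paths[3])
  invisible(paths)
}
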