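#' Model parameters for the wood-formation simulator
#'
#' Constructs the full set of model constants with defaults taken from the
#' calibrated/literature values for boreal Scots pine. All values can be
#' overridden by name. Units follow the fixed um / mg / ml / day / degC
#' convention used throughout the package; temperatures enter the
#' Boltzmann-Arrhenius expressions in kelvin only.
#'
#' @param ... named overrides of any default field (see Details).
#'
#' @details Fields:
#' \describe{
#'   \item{eta}{resistance to carbohydrate diffusion between cells, day ml^-1 (4360)}
#'   \item{mu0}{relative radial growth rate at `T0`, um um^-1 day^-1 (0.0570)}
#'   \item{omega}{normalised cell-wall mass growth rate, mg ml^-1 day^-1 (19.4)}
#'   \item{Ea, Eaw}{effective activation energies for enlargement / wall building, eV (0.374, 1.43)}
#'   \item{Km}{effective Michaelis constant for wall building, mg ml^-1 (5.1)}
#'   \item{f}{mode of cell-size regulation, 0 = sizer, 1 = adder (0.48)}
#'   \item{g_asym}{growth dependence on division asymmetry (0.43)}
#'   \item{La, Lt}{cell axial / tangential length, um (2680, 50.1)}
#'   \item{rho}{cell-wall mass density, mg ml^-1 (1.54e3)}
#'   \item{sigma_a, sigma}{SD of division-asymmetry and birth-size noise (0.105, 0.227)}
#'   \item{Wp}{primary cell-wall thickness, um (0.8)}
#'   \item{chi_b}{mean cell radial length at birth, um (8.8)}
#'   \item{theta_p}{phloem carbohydrate concentration, mg ml^-1 (95)}
#'   \item{f_phloem}{probability the initial's non-initial daughter is phloem (0.315)}
#'   \item{zone_coeffs}{intercepts/slopes of the developmental-zone regressions
#'     (um and um h^-1; the pre-DOY-185 enlargement-only pair is in um and
#'     um day^-1 of DOY, being a temporal extension of the post-185 regime)}
#'   \item{T0}{reference temperature, K (283.15)}
#'   \item{k_B}{Boltzmann constant, eV K^-1 (8.617e-5)}
#'   \item{dorm_doy, chill_start_doy, dd_start_doy}{phenology DOY thresholds (231, 306, 32)}
#' }
#'
#' @return An object of class `xylo_params` (a validated named list).
#' @examples
#' p <- model_params()
#' p$Km
#' model_params(eta = 1000)$eta
#' @export
model_params <- function(...) {
  p <- list(
    eta = 4360,
    mu0 = 0.0570,
    omega = 19.4,
    Ea = 0.374,
    Eaw = 1.43,
    Km = 5.1,
    f = 0.48,
    g_asym = 0.43,
    La = 2680,
    rho = 1.54e3,
    sigma_a = 0.105,
    sigma = 0.227,
    Lt = 50.1,
    Wp = 0.8,
    chi_b = 8.8,
    theta_p = 95,
    f_phloem = 0.315,
    zone_coeffs = list(
      a_p = -50.9, b_p = 7.47,
      a_e_early = 1257, b_e_early = -5.01,
      a_e_late = -744, b_e_late = 51.7,
      a_t = -427, b_t = 68.8
    ),
    T0 = 283.15,
    k_B = 8.617e-5,
    dorm_doy = 231,
    chill_start_doy = 306,
    dd_start_doy = 32
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == "")) {
      stop("all parameter overrides must be named", call. = FALSE)
    }
    bad <- setdiff(names(over), names(p))
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    if ("zone_coeffs" %in% names(over)) {
      zc <- over$zone_coeffs
      badz <- setdiff(names(zc), names(p$zone_coeffs))
      if (length(badz)) {
        stop("unknown zone coefficient(s): ", paste(badz, collapse = ", "),
             call. = FALSE)
      }
      p$zone_coeffs[names(zc)] <- zc
      over$zone_coeffs <- NULL
    }
    p[names(over)] <- over
  }
  validate_params(p)
  structure(p, class = "xylo_params")
}

validate_params <- function(p) {
  pos <- c("eta", "mu0", "omega", "Km", "La", "Lt", "rho", "sigma_a", "sigma",
           "Wp", "chi_b", "theta_p", "T0", "k_B")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("parameter '", nm, "' must be a single strictly positive number",
           call. = FALSE)
    }
  }
  for (nm in c("Ea", "Eaw")) {
    if (!is.numeric(p[[nm]]) || p[[nm]] < 0) {
      stop("parameter '", nm, "' must be non-negative", call. = FALSE)
    }
  }
  if (p$f < 0 || p$f > 1) stop("'f' must lie in [0, 1]", call. = FALSE)
  if (p$f_phloem < 0 || p$f_phloem > 1) {
    stop("'f_phloem' must lie in [0, 1]", call. = FALSE)
  }
  if (2 * p$Wp >= p$La || 2 * p$Wp >= p$Lt) {
    stop("primary wall thickness too large: need 2*Wp < La and 2*Wp < Lt",
         call. = FALSE)
  }
  for (nm in c("dorm_doy", "chill_start_doy", "dd_start_doy")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v > 366 || v != round(v)) {
      stop("parameter '", nm, "' must be an integer DOY in 1..366", call. = FALSE)
    }
  }
  zc <- p$zone_coeffs
  need <- c("a_p", "b_p", "a_e_early", "b_e_early", "a_e_late", "b_e_late",
            "a_t", "b_t")
  if (!all(need %in% names(zc))) {
    stop("zone_coeffs must contain: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Scenario configuration for model experiments
#'
#' Describes the deviations from the default model used by the in-silico
#' experiments: fixed temperatures for the growth kinetics, frozen
#' developmental-zone widths, removal of autumn dormancy, carbohydrate
#' saturation, and additive temperature anomalies applied to selected
#' processes. The default object is the full (unmodified) model.
#'
#' @param fixed_temp_C optional fixed temperature (degC) used for cell
#'   enlargement and wall thickening kinetics (dormancy forcing is unaffected).
#' @param fixed_zone_widths_doy optional DOY whose (non-dormant) zone widths
#'   are used on every day of the year.
#' @param autumn_dormancy logical; if `FALSE` dormancy is never re-imposed in
#'   autumn (the spring chilling release still applies to the initial state).
#' @param sugar_saturation logical; if `TRUE` wall growth proceeds at its
#'   carbohydrate-saturated rate and the diffusion solver is bypassed.
#' @param delta_T_K additive temperature anomaly, K.
#' @param delta_T_targets character vector, subset of
#'   `c("enlargement_rate", "thickening_rate", "proliferation_zone_cells",
#'   "enlargement_zone_cells")`; the processes/cell groups the anomaly is
#'   applied to. Must be non-empty iff `delta_T_K != 0`.
#' @param dormancy_forcing_uses_anomaly logical; by default the anomaly is
#'   never applied to the dormancy (chilling / degree-day) forcing.
#'
#' @return An object of class `xylo_scenario`.
#' @examples
#' scenario_config()                      # full model
#' scenario_config(delta_T_K = 2,
#'   delta_T_targets = c("enlargement_rate", "thickening_rate"))
#' @export
scenario_config <- function(fixed_temp_C = NULL,
                            fixed_zone_widths_doy = NULL,
                            autumn_dormancy = TRUE,
                            sugar_saturation = FALSE,
                            delta_T_K = 0,
                            delta_T_targets = character(),
                            dormancy_forcing_uses_anomaly = FALSE) {
  valid <- c("enlargement_rate", "thickening_rate",
             "proliferation_zone_cells", "enlargement_zone_cells")
  delta_T_targets <- as.character(delta_T_targets)
  bad <- setdiff(delta_T_targets, valid)
  if (length(bad)) {
    stop("unknown delta_T target(s): ", paste(bad, collapse = ", "),
         "; valid: ", paste(valid, collapse = ", "), call. = FALSE)
  }
  if ((delta_T_K != 0) != (length(delta_T_targets) > 0)) {
    stop("delta_T_targets must be non-empty exactly when delta_T_K != 0",
         call. = FALSE)
  }
  if (!is.null(fixed_temp_C) && !is.numeric(fixed_temp_C)) {
    stop("fixed_temp_C must be numeric or NULL", call. = FALSE)
  }
  if (!is.null(fixed_zone_widths_doy)) {
    d <- fixed_zone_widths_doy
    if (!is.numeric(d) || d < 1 || d > 366 || d != round(d)) {
      stop("fixed_zone_widths_doy must be an integer DOY in 1..366",
           call. = FALSE)
    }
  }
  structure(list(
    fixed_temp_C = fixed_temp_C,
    fixed_zone_widths_doy = fixed_zone_widths_doy,
    autumn_dormancy = isTRUE(autumn_dormancy),
    sugar_saturation = isTRUE(sugar_saturation),
    delta_T_K = delta_T_K,
    delta_T_targets = delta_T_targets,
    dormancy_forcing_uses_anomaly = isTRUE(dormancy_forcing_uses_anomaly)
  ), class = "xylo_scenario")
}

#' Load a run configuration from a YAML file
#'
#' Reads a YAML configuration with up to three top-level blocks: `params`
#' (model constants, see [model_params()]), `scenario` (see
#' [scenario_config()]) and `run` (run settings: `latitude`, `years`,
#' `n_files`, `seed`). Absent keys take their defaults; unknown keys are
#' rejected. `overrides` (e.g. parsed command-line flags) take precedence
#' over file values, which take precedence over defaults.
#'
#' @param path path to a YAML file.
#' @param overrides optional named list with the same structure as the file,
#'   applied on top of it.
#' @return A list with elements `params` (`xylo_params`), `scenario`
#'   (`xylo_scenario`) and `run` (named list).
#' @seealso [save_config()] for the serialization inverse.
#' @export
load_config <- function(path, overrides = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("malformed config file '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("config file must be a YAML mapping", call. = FALSE)
  build_config(cfg, overrides)
}

build_config <- function(cfg, overrides = NULL) {
  bad <- setdiff(names(cfg), c("params", "scenario", "run"))
  if (length(bad)) {
    stop("unknown top-level config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  merge_block <- function(base, extra) {
    if (is.null(extra)) return(base)
    if (!is.list(extra)) stop("config blocks must be mappings", call. = FALSE)
    utils::modifyList(base, extra)
  }
  pargs <- merge_block(cfg$params %||% list(),
                       if (!is.null(overrides)) overrides$params)
  sargs <- merge_block(cfg$scenario %||% list(),
                       if (!is.null(overrides)) overrides$scenario)
  run <- merge_block(list(latitude = 64.35, years = 5L, n_files = 100L,
                          seed = 1L),
                     cfg$run)
  run <- merge_block(run, if (!is.null(overrides)) overrides$run)
  badr <- setdiff(names(run), c("latitude", "years", "n_files", "seed"))
  if (length(badr)) {
    stop("unknown run key(s): ", paste(badr, collapse = ", "), call. = FALSE)
  }
  list(params = do.call(model_params, pargs),
       scenario = do.call(scenario_config, sargs),
       run = run)
}

#' Serialize a configuration back to YAML
#'
#' Writes the fully normalized configuration (all defaults filled in), so that
#' `load_config(save_config(cfg, f))` reproduces `cfg` exactly.
#'
#' @param cfg a list as returned by [load_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  out <- list(
    params = unclass(cfg$params),
    scenario = Filter(Negate(is.null), unclass(cfg$scenario)),
    run = cfg$run
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.xylo_params <- function(x, ...) {
  cat("<xylo_params>\n")
  flat <- unclass(x)
  zc <- flat$zone_coeffs
  flat$zone_coeffs <- NULL
  for (nm in names(flat)) cat(sprintf("  %-16s %s\n", nm, format(flat[[nm]])))
  cat("  zone_coeffs:\n")
  for (nm in names(zc)) cat(sprintf("    %-14s %s\n", nm, format(zc[[nm]])))
  invisible(x)
}

#' @export
print.xylo_scenario <- function(x, ...) {
  cat("<xylo_scenario>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-30s %s\n", nm,
                if (is.null(v)) "NULL" else paste(format(v), collapse = ", ")))
  }
  invisible(x)
}
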