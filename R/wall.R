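#' Cell, primary-wall and lumen volumes
#'
#' Cells are cuboid with fixed axial and tangential lengths, so total volume
#' is `V_c = La * Lt * L_r / 1e12` (ml; lengths in um). The required primary
#' wall volume is the shell of thickness `Wp`:
#' `V_wp = V_c - (La - 2 Wp)(Lt - 2 Wp)(L_r - 2 Wp)/1e12`. The lumen is what
#' wall mass has not occluded: `V_l = V_c - M/rho`.
#'
#' @param L_r radial length, um (vectorized).
#' @param M wall mass, mg (vectorized).
#' @param params a [model_params()] object.
#' @return Volume(s) in ml.
#' @examples
#' cell_volume(17.6)
#' lumen_volume(17.6, 1e-3)
#' @export
cell_volume <- function(L_r, params = model_params()) {
  if (any(L_r < 0)) stop("radial length must be non-negative", call. = FALSE)
  params$La * params$Lt * L_r / 1e12
}

#' @rdname cell_volume
#' @export
primary_wall_volume <- function(L_r, params = model_params()) {
  inner <- (params$La - 2 * params$Wp) * (params$Lt - 2 * params$Wp) *
    pmax(L_r - 2 * params$Wp, 0) / 1e12
  cell_volume(L_r, params) - inner
}

#' @rdname cell_volume
#' @export
lumen_volume <- function(L_r, M, params = model_params()) {
  V_c <- cell_volume(L_r, params)
  V_l <- V_c - M / params$rho
  if (any(V_l < -1e-15)) {
    stop("wall mass exceeds cell volume (integration bug): max overshoot ",
         format(max(M / params$rho - V_c)), " ml", call. = FALSE)
  }
  pmax(V_l, 0)
}

#' Carbohydrate-saturated wall growth rate
#'
#' The maximum (carbohydrate-saturated) rate of wall deposition is linear in
#' lumen volume (a proxy for wall-building machinery) with Boltzmann-Arrhenius
#' temperature kinetics: `dM_max = omega * V_l * exp((Eaw/k_B)(1/T0 - 1/T))`.
#' Cells that only have primary walls (proliferation and enlargement-only
#' zones) are additionally capped by the remaining primary-wall headroom,
#' `dM_max <- min(dM_max, rho * V_wp - M)` (floored at 0); because `V_wp`
#' grows with the cell, enlarging cells regain headroom daily.
#'
#' @param V_l lumen volume, ml (vectorized).
#' @param T_K temperature, kelvin.
#' @param stage `"primary"` or `"secondary"`.
#' @param L_r radial length, um (needed for the primary cap).
#' @param M current wall mass, mg (needed for the primary cap).
#' @param params a [model_params()] object.
#' @return Saturated wall growth rate, mg cell^-1 day^-1.
#' @export
max_wall_growth <- function(V_l, T_K, stage = c("secondary", "primary"),
                            L_r = NULL, M = NULL, params = model_params()) {
  stage <- match.arg(stage)
  if (any(V_l < 0)) stop("lumen volume must be non-negative", call. = FALSE)
  dM_max <- params$omega * V_l * arrhenius_factor(T_K, params$Eaw, params)
  if (stage == "primary") {
    if (is.null(L_r) || is.null(M)) {
      stop("primary stage requires L_r and M for the wall cap", call. = FALSE)
    }
    cap <- pmax(params$rho * primary_wall_volume(L_r, params) - M, 0)
    dM_max <- pmin(dM_max, cap)
  }
  pmax(dM_max, 0)
}

#' Realized wall growth rate at a carbohydrate concentration
#'
#' Michaelis-Menten dependence of wall deposition on the cytoplasmic
#' carbohydrate concentration: `dM = dM_max * theta / (theta + Km)`.
#'
#' @param theta carbohydrate concentration, mg ml^-1 (vectorized).
#' @param dM_max saturated rate, mg cell^-1 day^-1.
#' @param params a [model_params()] object.
#' @return Wall growth rate, mg cell^-1 day^-1.
#' @examples
#' wall_growth_rate(5.1, 1)  # half-saturation
#' @export
wall_growth_rate <- function(theta, dM_max, params = model_params()) {
  if (any(theta < 0)) stop("theta must be non-negative", call. = FALSE)
  dM_max * theta / (theta + params$Km)
}
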