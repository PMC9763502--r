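#' Developmental-zone widths for one day
#'
#' Computes the inner-edge distances (from the inner phloem edge, um) of the
#' proliferation (`z_p`), enlargement-only (`z_e`) and secondary
#' wall-thickening (`z_t`) zones from daylength, with the regime rules of the
#' underlying empirical fits:
#' \itemize{
#'   \item `z_p = a_p + b_p * dl`, using the DOY-185 daylength on earlier
#'     non-dormant days (its assumed seasonal maximum) and the DOY-231
#'     daylength (first dormant day) throughout dormancy;
#'   \item `z_e = a_e + b_e * dl` for DOY >= 185; before DOY 185 the width is
#'     a linear extension in time of the post-185 rate of change,
#'     `z_e = 1257 - 5.01 * DOY`;
#'   \item `z_t = a_t + b_t * dl` on all days.
#' }
#' Each daylength-based width is capped at its 24-h-daylength value (needed
#' north of the Arctic circle), floored at 0, and the ordering
#' `z_t >= z_e >= z_p` is then enforced by raising outer widths to inner ones.
#'
#' @param doy integer day of year.
#' @param dl daylength on that day, hours in `[0, 24]`.
#' @param dormant logical; are the proliferation/enlargement zones dormant?
#' @param latitude site latitude (needed for the frozen DOY-185/231 daylengths).
#' @param params a [model_params()] object.
#' @param raw if `TRUE`, return the regime-rule widths before the 24-h cap,
#'   flooring and ordering (used for diagnostics and tests).
#' @return Named numeric vector `c(z_p, z_e, z_t)`, um.
#' @examples
#' zone_widths(200, dl = 20, dormant = FALSE, latitude = 64.35)
#' @export
zone_widths <- function(doy, dl, dormant, latitude, params = model_params(),
                        raw = FALSE) {
  if (dl < 0 || dl > 24) stop("daylength must lie in [0, 24]", call. = FALSE)
  zc <- params$zone_coeffs
  doy <- min(doy, 365)

  dl_p <- if (dormant) {
    daylength_hours(latitude, 231)
  } else if (doy < 185) {
    daylength_hours(latitude, 185)
  } else {
    dl
  }
  z_p <- zc$a_p + zc$b_p * dl_p
  z_p <- min(z_p, zc$a_p + zc$b_p * 24)

  z_e <- if (doy < 185) {
    # temporal extension of the post-185 regime (predictor is DOY)
    zc$a_e_early + zc$b_e_early * doy
  } else {
    zc$a_e_late + zc$b_e_late * dl
  }
  # no zone width may exceed its value at 24 h daylength (polar day)
  z_e <- min(z_e, zc$a_e_late + zc$b_e_late * 24)

  z_t <- zc$a_t + zc$b_t * dl
  z_t <- min(z_t, zc$a_t + zc$b_t * 24)

  if (raw) return(c(z_p = z_p, z_e = z_e, z_t = z_t))

  z_p <- max(z_p, 0)
  z_e <- max(z_e, 0, z_p)
  z_t <- max(z_t, 0, z_e)
  c(z_p = z_p, z_e = z_e, z_t = z_t)
}

#' Degree-day requirement for dormancy release
#'
#' Chilling-conditioned thermal-time model: the degree-day sum required for
#' spring release of cambial dormancy declines exponentially with the
#' accumulated number of chill days,
#' `dd_req = 15 + 4401.8 * exp(-0.042 * cd)` (degC day).
#'
#' @param cd chill-day count (days with mean temperature below 0 degC since
#'   the autumn chilling window opened); non-negative, vectorized.
#' @return Required degree-day sum, degC day.
#' @examples
#' dormancy_release_threshold(c(0, 50, 600))
#' @export
dormancy_release_threshold <- function(cd) {
  if (any(cd < 0)) stop("chill-day count must be non-negative", call. = FALSE)
  15 + 4401.8 * exp(-0.042 * cd)
}

#' Initial dormancy state
#'
#' @param dormant initial dormancy flag (simulations start dormant on 1 Jan).
#' @return A `xylo_dormancy` list with fields `dormant`, `cd` (chill days),
#'   `dd` (degree-day sum), `release_doy` (DOY of release this year or `NA`).
#' @export
dormancy_state <- function(dormant = TRUE) {
  structure(list(dormant = dormant, cd = 0, dd = 0, release_doy = NA_integer_),
            class = "xylo_dormancy")
}

#' Advance the dormancy state by one day
#'
#' Applies, in order: annual resets of the degree-day sum (at `dd_start_doy`,
#' DOY 32) and the chill-day count (at `chill_start_doy`, DOY 306); autumn
#' re-imposition of dormancy (at `dorm_doy`, DOY 231, unless
#' `autumn_dormancy = FALSE`); the release test; and the day's accumulation.
#' Release occurs on the first day in the first half of the year (DOY <= 182)
#' on which the degree-day sum accumulated through the previous day meets the
#' chilling-conditioned requirement ([dormancy_release_threshold()]).
#' Chilling and forcing act sequentially: chill days count days with
#' `t_mean < 0` in the autumn/winter window from DOY 306 until the forcing
#' window opens, and degree-days then accumulate as `max(t_mean, 0)` from
#' DOY 32 (a day at exactly 0 degC counts toward neither sum).
#'
#' @param state a `xylo_dormancy` object.
#' @param doy integer day of year.
#' @param t_mean daily mean temperature, degC (the dormancy forcing; scenario
#'   anomalies are not applied to it unless explicitly requested).
#' @param params a [model_params()] object.
#' @param autumn_dormancy logical; if `FALSE`, skip the DOY-231 re-imposition.
#' @return The updated `xylo_dormancy` object.
#' @export
update_dormancy <- function(state, doy, t_mean, params = model_params(),
                            autumn_dormancy = TRUE) {
  doy <- min(doy, 365)
  if (doy == 1L) state$release_doy <- NA_integer_
  if (doy == params$dd_start_doy) state$dd <- 0
  if (doy == params$chill_start_doy) state$cd <- 0
  if (autumn_dormancy && doy == params$dorm_doy) state$dormant <- TRUE

  if (state$dormant && doy <= 182 && doy >= params$dd_start_doy &&
      state$dd >= dormancy_release_threshold(state$cd)) {
    state$dormant <- FALSE
    state$release_doy <- as.integer(doy)
  }

  # chilling and forcing are sequential: chill days accumulate from the
  # autumn window start until the degree-day window opens at DOY 32
  in_chill_window <- doy >= params$chill_start_doy || doy < params$dd_start_doy
  if (state$dormant && in_chill_window && t_mean < 0) state$cd <- state$cd + 1
  if (doy >= params$dd_start_doy && doy <= 182) {
    state$dd <- state$dd + max(t_mean, 0)
  }
  state
}

#' Daily zone-width and dormancy schedule for a climate series
#'
#' Runs the dormancy model over the full (multi-year) climate series and
#' evaluates the zone widths on every day, applying scenario rules: frozen
#' zone widths (`fixed_zone_widths_doy`) and removal of autumn dormancy.
#' Dormancy forcing uses the unmodified temperature series unless
#' `dormancy_forcing_uses_anomaly` is set, in which case `delta_T_K` is added.
#'
#' @param climate a `xylo_climate` data frame.
#' @param latitude site latitude, degrees.
#' @param params a [model_params()] object.
#' @param scenario a [scenario_config()] object.
#' @return A data frame with one row per day: `year`, `doy`, `t_mean`,
#'   `daylength`, `dormant`, `release` (logical), `z_p`, `z_e`, `z_t`.
#' @export
zone_schedule <- function(climate, latitude, params = model_params(),
                          scenario = scenario_config()) {
  n <- nrow(climate)
  if (n == 0) stop("empty climate series", call. = FALSE)
  if (any(diff(which(climate$doy == 1L)) < 300)) {
    stop("climate series does not look like consecutive calendar days",
         call. = FALSE)
  }
  dorm_t <- climate$t_mean +
    if (scenario$dormancy_forcing_uses_anomaly) scenario$delta_T_K else 0

  frozen <- NULL
  if (!is.null(scenario$fixed_zone_widths_doy)) {
    d0 <- scenario$fixed_zone_widths_doy
    frozen <- zone_widths(d0, daylength_hours(latitude, d0), dormant = FALSE,
                          latitude = latitude, params = params)
  }

  st <- dormancy_state(dormant = TRUE)
  dormant <- logical(n)
  release <- logical(n)
  z <- matrix(0, n, 3, dimnames = list(NULL, c("z_p", "z_e", "z_t")))
  for (i in seq_len(n)) {
    st <- update_dormancy(st, climate$doy[i], dorm_t[i], params,
                          autumn_dormancy = scenario$autumn_dormancy)
    dormant[i] <- st$dormant
    release[i] <- !is.na(st$release_doy) && st$release_doy == climate$doy[i]
    z[i, ] <- if (is.null(frozen)) {
      zone_widths(climate$doy[i], climate$daylength[i], st$dormant,
                  latitude, params)
    } else frozen
  }
  data.frame(year = climate$year, doy = climate$doy, t_mean = climate$t_mean,
             daylength = climate$daylength, dormant = dormant,
             release = release, z_p = z[, 1], z_e = z[, 2], z_t = z[, 3])
}
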