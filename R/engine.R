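# A radial file is a list of parallel vectors ordered from the cell adjacent
# to the phloem (index 1, the initial) inward:
#   L      current radial length, um
#   Lb     radial length at birth, um
#   eps    growth dependence on relative birth size
#   Ld     division length, um (meaningful while proliferating)
#   M      wall mass, mg
#   theta  cytoplasmic carbohydrate concentration, mg ml^-1
#   status 1 proliferating, 2 enlarging, 3 thickening, 4 mature
#   ord    birth order (global formation index within the file)
# plus bookkeeping: file_id, next_ord, n_added (xylem cells added this year),
# flux_year (cumulative phloem influx, mg), phloem_mass_out (mg).

STATUS_PROLIF <- 1L
STATUS_ENLARGE <- 2L
STATUS_THICKEN <- 3L
STATUS_MATURE <- 4L

#' Initialize a radial file of cambial cells
#'
#' Enacts the initialization protocol: build a provisional file of 100 cells
#' with radial lengths `chi_b * (1 + Z_a)`, let each divide once keeping one
#' daughter, retain only the daughters whose centres fall inside the
#' proliferation zone on day 1 (its dormant width), and assign each retained
#' cell its growth factor `epsilon` and division length. Cell 1 is the
#' file's initial; every cell starts with a complete primary wall
#' (`M = rho * V_wp`) and phloem-level carbohydrate concentration.
#'
#' @param file_id integer identifier.
#' @param z_p_day1 proliferation-zone width on day 1 (dormant), um.
#' @param params a [model_params()] object.
#' @param seed optional seed; if `NULL` the current RNG stream is used (the
#'   ensemble driver seeds one stream per file).
#' @return A radial-file state list.
#' @export
initialize_file <- function(file_id, z_p_day1, params = model_params(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n0 <- 100L
  Za0 <- clamp(stats::rnorm(n0, 0, params$sigma_a), -0.49, 0.49)
  L0 <- params$chi_b * (1 + Za0)
  # one division each; the daughter kept is the (0.5 - Z_a) one
  Za1 <- clamp(stats::rnorm(n0, 0, params$sigma_a), -0.49, 0.49)
  Lb <- L0 * (0.5 - Za1)
  eps <- 1 - params$g_asym * (-2 * Za1)
  Ld <- draw_division_length(Lb, params)

  centre <- cumsum(Lb) - Lb / 2
  keep <- centre <= z_p_day1
  if (!any(keep)) {
    stop("initialization failed: proliferation zone (", signif(z_p_day1, 3),
         " um) too narrow to retain any cell", call. = FALSE)
  }
  keep <- seq_len(max(which(keep)))  # centres increase: retained set is a prefix
  n <- length(keep)
  list(
    file_id = as.integer(file_id),
    L = Lb[keep], Lb = Lb[keep], eps = eps[keep], Ld = Ld[keep],
    M = params$rho * primary_wall_volume(Lb[keep], params),
    theta = rep(params$theta_p, n),
    status = rep(STATUS_PROLIF, n),
    ord = seq_len(n),
    next_ord = n + 1L,
    n_added = 0L,
    flux_year = 0,
    phloem_mass_out = 0
  )
}

# replace element `idx` of every per-cell vector with the supplied daughters
splice_all <- function(fs, idx, cells, statuses, ords) {
  num <- function(field, vals) append(fs[[field]][-idx], vals, after = idx - 1L)
  for (nm in names(cells)) fs[[nm]] <- num(nm, cells[[nm]])
  fs$status <- append(fs$status[-idx], statuses, after = idx - 1L)
  fs$ord <- append(fs$ord[-idx], ords, after = idx - 1L)
  fs
}

#' Advance a radial file by one day
#'
#' Ordered sub-steps: (1) classify each cell by the distance of its centre
#' from the inner phloem edge against the day's zone widths (forward-only
#' status transitions); (2) when not dormant, enlarge proliferation- and
#' enlargement-zone cells at the temperature-dependent rate; (3) divide
#' proliferating cells that have reached their division length, drawing the
#' phloem/xylem fate of the initial's daughter; (4) evaluate the day's
#' saturated wall demands on the post-growth geometry (primary-wall cap for
#' proliferating/enlarging cells, zero while those zones are dormant;
#' uncapped secondary deposition for thickening cells); (5) solve the
#' carbohydrate diffusion equilibrium across
#' the living cells (or take `dM = dM_max` under sugar saturation) and
#' deposit the realized wall mass. Mature cells beyond the thickening zone
#' take no further part.
#'
#' @param fs radial-file state (see [initialize_file()]).
#' @param zw numeric `c(z_p, z_e, z_t)` for the day, um.
#' @param dormant logical dormancy flag for the day.
#' @param t_mean daily mean temperature, degC.
#' @param scenario a [scenario_config()] object.
#' @param params a [model_params()] object.
#' @return The updated file state; the day's phloem influx is accumulated in
#'   `fs$flux_year`.
#' @export
step_day <- function(fs, zw, dormant, t_mean, scenario = scenario_config(),
                     params = model_params()) {
  n <- length(fs$L)
  # (1) classification by cell centre
  centre <- cumsum(fs$L) - fs$L / 2
  cls <- 1L + (centre > zw[1]) + (centre > zw[2]) + (centre > zw[3])
  fs$status <- pmax(fs$status, cls)

  dT <- scenario$delta_T_K
  tg <- scenario$delta_T_targets
  t_kin <- if (!is.null(scenario$fixed_temp_C)) scenario$fixed_temp_C else t_mean

  # (2) enlargement
  if (!dormant) {
    t_pro <- t_kin + dT * (("enlargement_rate" %in% tg) ||
                             ("proliferation_zone_cells" %in% tg))
    t_enl <- t_kin + dT * (("enlargement_rate" %in% tg) ||
                             ("enlargement_zone_cells" %in% tg))
    pro <- fs$status == STATUS_PROLIF
    enl <- fs$status == STATUS_ENLARGE
    if (any(pro)) {
      mu <- enlargement_rate(t_pro + 273.15, params)
      fs$L[pro] <- fs$L[pro] + radial_increment(fs$L[pro], mu, fs$eps[pro])
    }
    if (any(enl)) {
      mu <- enlargement_rate(t_enl + 273.15, params)
      fs$L[enl] <- fs$L[enl] + radial_increment(fs$L[enl], mu, fs$eps[enl])
    }

    # (3) division, innermost dividing cell first so indices stay valid
    div_idx <- which(fs$status == STATUS_PROLIF & fs$L >= fs$Ld)
    for (idx in rev(div_idx)) {
      mother <- list(L_r = fs$L[idx], L_r_d = fs$Ld[idx], M = fs$M[idx],
                     theta = fs$theta[idx])
      d <- divide_cell(mother, params)
      if (idx == 1L) {
        fate <- initial_division_fate(params)
        # daughter `a` renews the initial in the outer (phloem-adjacent) slot
        fs$L[1] <- d$a$L_r; fs$Lb[1] <- d$a$L_r_b; fs$eps[1] <- d$a$epsilon
        fs$Ld[1] <- d$a$L_r_d; fs$M[1] <- d$a$M
        if (fate == "phloem") {
          fs$phloem_mass_out <- fs$phloem_mass_out + d$b$M
        } else {
          fs <- splice_all(
            fs, 1L,
            cells = list(L = c(d$a$L_r, d$b$L_r), Lb = c(d$a$L_r_b, d$b$L_r_b),
                         eps = c(d$a$epsilon, d$b$epsilon),
                         Ld = c(d$a$L_r_d, d$b$L_r_d), M = c(d$a$M, d$b$M),
                         theta = rep(mother$theta, 2)),
            statuses = rep(STATUS_PROLIF, 2L),
            ords = c(fs$ord[1], fs$next_ord)
          )
          fs$next_ord <- fs$next_ord + 1L
          fs$n_added <- fs$n_added + 1L
        }
      } else {
        fs <- splice_all(
          fs, idx,
          cells = list(L = c(d$a$L_r, d$b$L_r), Lb = c(d$a$L_r_b, d$b$L_r_b),
                       eps = c(d$a$epsilon, d$b$epsilon),
                       Ld = c(d$a$L_r_d, d$b$L_r_d), M = c(d$a$M, d$b$M),
                       theta = rep(mother$theta, 2)),
          statuses = rep(STATUS_PROLIF, 2L),
          ords = c(fs$ord[idx], fs$next_ord)
        )
        fs$next_ord <- fs$next_ord + 1L
        fs$n_added <- fs$n_added + 1L
      }
    }
  }

  # (4) wall demands on post-growth geometry; (5) transport and deposition
  m <- sum(fs$status <= STATUS_THICKEN)  # living cells form the outer block
  if (m > 0) {
    live <- seq_len(m)
    t_wall <- t_kin + dT * ("thickening_rate" %in% tg)
    V_l <- lumen_volume(fs$L[live], fs$M[live], params)
    primary <- fs$status[live] <= STATUS_ENLARGE
    dM_max <- numeric(m)
    # dormancy halts all activity of the proliferation/enlargement zones,
    # including primary-wall deposition; dormant cells still conduct
    # carbohydrate (zero demand leaves the gradient flat across them)
    if (any(primary) && !dormant) {
      dM_max[primary] <- max_wall_growth(
        V_l[primary], t_wall + 273.15, "primary",
        L_r = fs$L[live][primary], M = fs$M[live][primary], params = params)
    }
    if (any(!primary)) {
      dM_max[!primary] <- max_wall_growth(V_l[!primary], t_wall + 273.15,
                                          "secondary", params = params)
    }
    if (scenario$sugar_saturation) {
      dM <- dM_max
      fs$theta[live] <- params$theta_p
      flux <- sum(dM)
    } else {
      sol <- solve_equilibrium(dM_max, params$theta_p, params$eta, params)
      dM <- sol$dM
      fs$theta[live] <- sol$theta
      flux <- sol$flux_in
    }
    fs$M[live] <- fs$M[live] + dM
    fs$flux_year <- fs$flux_year + flux
  }
  fs
}

finalize_ring <- function(fs, year, params) {
  n <- length(fs$L)
  m <- sum(fs$status == STATUS_PROLIF)  # proliferating cells are the outer block
  if (m == n) {
    return(list(fs = fs, cells = NULL, n_unfinished = 0L))
  }
  idx <- rev(seq.int(m + 1L, n))  # innermost (earliest formed) first
  L <- fs$L[idx]
  M <- fs$M[idx]
  V_c <- cell_volume(L, params)
  abs_pos <- cumsum(L) - L / 2
  width <- sum(L)
  cells <- data.frame(
    year = year, file_id = fs$file_id,
    cell_id = fs$ord[idx],
    birth_order = seq_along(idx),
    L_r_um = L, mass_mg = M,
    density_g_cm3 = cell_density(M, V_c),
    abs_pos_um = abs_pos,
    norm_position = abs_pos / width
  )
  n_unfinished <- sum(fs$status[idx] < STATUS_MATURE)
  keep <- seq_len(m)
  fs$L <- fs$L[keep]; fs$Lb <- fs$Lb[keep]; fs$eps <- fs$eps[keep]
  fs$Ld <- fs$Ld[keep]; fs$M <- fs$M[keep]; fs$theta <- fs$theta[keep]
  fs$status <- fs$status[keep]; fs$ord <- fs$ord[keep]
  list(fs = fs, cells = cells, n_unfinished = n_unfinished)
}

#' Advance a radial file through one simulation year
#'
#' Runs [step_day()] over a full year of forcing and finalizes the annual
#' ring: at year end, every cell no longer in the proliferation zone is
#' written to the ring record (ordered from the earliest-formed, innermost
#' cell outward) and proliferation-zone cells (including the initial) are
#' carried over to the next year.
#'
#' @param fs radial-file state.
#' @param sched one year of the [zone_schedule()] table.
#' @param scenario a [scenario_config()] object.
#' @param params a [model_params()] object.
#' @return List with `fs` (carried-over file), `cells` (per-cell ring record,
#'   `NULL` for an empty ring) and `n_unfinished` (cells finalized before
#'   reaching maturity).
#' @export
step_year <- function(fs, sched, scenario = scenario_config(),
                      params = model_params()) {
  fs$n_added <- 0L
  fs$flux_year <- 0
  zp <- sched$z_p; ze <- sched$z_e; zt <- sched$z_t
  dorm <- sched$dormant; tm <- sched$t_mean
  gs_cells <- 0
  gs_days <- 0L
  for (i in seq_len(nrow(sched))) {
    fs <- step_day(fs, c(zp[i], ze[i], zt[i]), dorm[i], tm[i],
                   scenario, params)
    if (!dorm[i]) {
      gs_cells <- gs_cells + length(fs$L)
      gs_days <- gs_days + 1L
    }
  }
  out <- finalize_ring(fs, sched$year[1], params)
  out$fs$n_added <- fs$n_added
  out$fs$flux_year <- fs$flux_year
  # mean cells per file across the growing (non-dormant) season
  out$fs$gs_mean_cells <- if (gs_days > 0) gs_cells / gs_days else NA_real_
  out
}

#' Run an ensemble of independent radial files
#'
#' Simulates `n_files` stochastically independent radial files over the full
#' climate series, with proliferating cells carried over between years.
#' Per-file RNG streams are derived deterministically from `seed`, so results
#' are bit-reproducible.
#'
#' @param climate a `xylo_climate` data frame covering whole years.
#' @param latitude site latitude, degrees.
#' @param n_files number of radial files in the ensemble.
#' @param scenario a [scenario_config()] object.
#' @param params a [model_params()] object.
#' @param seed master integer seed.
#' @return A `xylo_sim` list: `cells` (per-cell ring records across files and
#'   years), `rings` (per file-year summaries, see [summary_metrics()], plus
#'   `n_added`, the xylem cells created that year; `gs_mean_cells`, the file
#'   cell count averaged over growing-season days; and `flux_in_mg`, the
#'   year's cumulative phloem influx), `zones` (the daily [zone_schedule()]),
#'   plus the `params`, `scenario`, `latitude` and `seed` used.
#' @examples
#' \donttest{
#' cl <- synthesize_climate(64.35, 1994:1995, seed = 2)
#' sim <- run_ensemble(cl, n_files = 3, seed = 2)
#' head(sim$rings)
#' }
#' @export
run_ensemble <- function(climate, latitude = 64.35, n_files = 100,
                         scenario = scenario_config(),
                         params = model_params(), seed = 1) {
  if (n_files < 1) stop("n_files must be >= 1", call. = FALSE)
  sched <- zone_schedule(climate, latitude, params, scenario)
  years <- unique(sched$year)
  by_year <- split(sched, factor(sched$year, levels = years))

  file_seeds <- local_rng(seed, sample.int(.Machine$integer.max - 1L, n_files))

  cell_frames <- list()
  ring_rows <- list()
  n_unfinished <- 0L
  for (fid in seq_len(n_files)) {
    set.seed(file_seeds[fid])
    fs <- initialize_file(fid, z_p_day1 = by_year[[1]]$z_p[1], params = params)
    for (yr in seq_along(years)) {
      out <- step_year(fs, by_year[[yr]], scenario, params)
      fs <- out$fs
      n_unfinished <- n_unfinished + out$n_unfinished
      if (!is.null(out$cells)) {
        cell_frames[[length(cell_frames) + 1L]] <- out$cells
        ring_rows[[length(ring_rows) + 1L]] <- cbind(
          data.frame(year = years[yr], file_id = fid,
                     n_added = fs$n_added,
                     gs_mean_cells = fs$gs_mean_cells,
                     flux_in_mg = fs$flux_year),
          summary_metrics(out$cells)
        )
      } else {
        ring_rows[[length(ring_rows) + 1L]] <- data.frame(
          year = years[yr], file_id = fid, n_added = fs$n_added,
          gs_mean_cells = fs$gs_mean_cells,
          flux_in_mg = fs$flux_year, ring_width_um = 0, ring_mass_mg = 0,
          n_cells = 0L, mean_density_g_cm3 = NA_real_,
          max_density_g_cm3 = NA_real_, earlywood_fraction = NA_real_
        )
      }
    }
  }
  if (n_unfinished > 0) {
    warning(n_unfinished, " cell(s) were finalized before reaching maturity ",
            "(still enlarging or thickening at year end)", call. = FALSE)
  }
  cells <- if (length(cell_frames)) do.call(rbind, cell_frames) else
    data.frame()
  structure(list(cells = cells, rings = do.call(rbind, ring_rows),
                 zones = sched, params = params, scenario = scenario,
                 latitude = latitude, seed = seed, n_files = n_files),
            class = "xylo_sim")
}

#' @export
print.xylo_sim <- function(x, ...) {
  cat("<xylo_sim> ", x$n_files, " radial file(s), years ",
      paste(range(x$zones$year), collapse = "-"), "\n", sep = "")
  if (nrow(x$rings)) {
    agg <- stats::aggregate(cbind(n_cells, ring_width_um, max_density_g_cm3) ~
                              year, data = x$rings, FUN = mean)
    cat("mean ring summaries by year:\n")
    print(agg, row.names = FALSE)
  }
  invisible(x)
}
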