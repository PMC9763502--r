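#' Cell-mass density
#'
#' Density of a cell as wall mass over total cell volume, in g cm^-3
#' (mass in mg, volume in ml).
#'
#' @param M wall mass, mg (vectorized).
#' @param V_c cell volume, ml.
#' @return Density, g cm^-3.
#' @examples
#' cell_density(2e-3, cell_volume(30))
#' @export
cell_density <- function(M, V_c) {
  if (any(V_c <= 0)) stop("cell volume must be positive", call. = FALSE)
  (M / V_c) / 1000
}

# centered running mean over three adjacent bins; empty (NA) bins stay NA,
# edge bins use the available neighbours
running_mean3 <- function(x) {
  n <- length(x)
  if (n == 0) return(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    w <- x[max(1, i - 1):min(n, i + 1)]
    out[i] <- mean(w, na.rm = TRUE)
  }
  out
}

profile_one <- function(pos, value, breaks) {
  bin <- findInterval(pos, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  nb <- length(breaks) - 1L
  s <- tapply(value, factor(bin, levels = seq_len(nb)), mean)
  list(mean = as.numeric(s), n = as.integer(table(factor(bin, levels = seq_len(nb)))))
}

#' Normalized ring density profile
#'
#' Mean cell-mass density against normalized ring position (0 = start of the
#' ring, the earliest-formed cell; 1 = ring end at the phloem side). Cells
#' are pooled across radial files into fixed-width bins of ring fraction
#' (unweighted per-cell means), smoothed with a running mean over three
#' adjacent bins. With multiple years, a profile is computed per year and
#' the profiles are then averaged (grand mean), matching the convention of
#' ensemble mean ring profiles.
#'
#' @param cells per-cell ring records (the `cells` element of a `xylo_sim`),
#'   needing columns `norm_position`, `density_g_cm3` and, for multi-year
#'   input, `year`.
#' @param bin_width bin width in ring fraction (default 0.02).
#' @param smooth logical; apply the 3-bin running mean.
#' @return A data frame: `bin_center` (ring fraction), `mean_density`
#'   (g cm^-3; `NA` for empty bins), `n_cells` (pooled over years).
#' @export
normalized_profile <- function(cells, bin_width = 0.02, smooth = TRUE) {
  if (is.null(cells) || nrow(cells) == 0) {
    return(data.frame(bin_center = numeric(0), mean_density = numeric(0),
                      n_cells = integer(0)))
  }
  breaks <- seq(0, 1, by = bin_width)
  yrs <- if ("year" %in% names(cells)) unique(cells$year) else 1
  mats <- lapply(yrs, function(y) {
    sub <- if (length(yrs) > 1 || "year" %in% names(cells)) {
      cells[cells$year == y, ]
    } else cells
    pr <- profile_one(sub$norm_position, sub$density_g_cm3, breaks)
    m <- pr$mean
    if (smooth) m <- running_mean3(m)
    cbind(m, pr$n)
  })
  dens <- sapply(mats, function(m) m[, 1])
  ncnt <- sapply(mats, function(m) m[, 2])
  if (is.null(dim(dens))) dens <- matrix(dens, ncol = length(yrs))
  if (is.null(dim(ncnt))) ncnt <- matrix(ncnt, ncol = length(yrs))
  data.frame(
    bin_center = (breaks[-1] + breaks[-length(breaks)]) / 2,
    mean_density = rowMeans(dens, na.rm = TRUE),
    n_cells = as.integer(rowSums(ncnt))
  )
}

#' Absolute-distance ring profile
#'
#' As [normalized_profile()] but binned on absolute distance from the ring
#' start in um (40 um bins for density profiles, 100 um for cell-length
#' profiles), pooling all cells supplied (filter to one year first when
#' emulating single-year profiles).
#'
#' @param cells per-cell ring records with columns `abs_pos_um` and the
#'   profiled variable.
#' @param bin_width_um bin width, um.
#' @param variable column to profile: `"density_g_cm3"` or `"L_r_um"`.
#' @param smooth logical; apply the 3-bin running mean.
#' @return A data frame: `bin_center` (um), `mean_value`, `n_cells`.
#' @export
absolute_profile <- function(cells, bin_width_um = 40,
                             variable = "density_g_cm3", smooth = TRUE) {
  if (is.null(cells) || nrow(cells) == 0) {
    return(data.frame(bin_center = numeric(0), mean_value = numeric(0),
                      n_cells = integer(0)))
  }
  if (!variable %in% names(cells)) {
    stop("no column '", variable, "' in cell records", call. = FALSE)
  }
  top <- max(cells$abs_pos_um)
  breaks <- seq(0, by = bin_width_um,
                length.out = ceiling(top / bin_width_um) + 1L)
  if (breaks[length(breaks)] < top) breaks <- c(breaks, top)
  pr <- profile_one(cells$abs_pos_um, cells[[variable]], breaks)
  m <- pr$mean
  if (smooth) m <- running_mean3(m)
  data.frame(
    bin_center = (breaks[-1] + breaks[-length(breaks)]) / 2,
    mean_value = m,
    n_cells = pr$n
  )
}

#' Summary metrics of one annual ring
#'
#' Ring width (sum of cell radial lengths), ring mass, volume-weighted mean
#' density, maximum density (the peak of the 40-um binned, 3-bin smoothed
#' density profile — the model analogue of maximum latewood density), cell
#' count, and the earlywood fraction (fraction of occupied profile bins with
#' smoothed density below `earlywood_threshold`).
#'
#' @param cells per-cell records of a single ring (one file-year).
#' @param earlywood_threshold density threshold, g cm^-3 (default 0.55); a
#'   package convention for the earlywood/latewood diagnostic.
#' @return One-row data frame: `ring_width_um`, `ring_mass_mg`, `n_cells`,
#'   `mean_density_g_cm3`, `max_density_g_cm3`, `earlywood_fraction`.
#' @export
summary_metrics <- function(cells, earlywood_threshold = 0.55) {
  if (is.null(cells) || nrow(cells) == 0) {
    stop("summary_metrics needs at least one cell", call. = FALSE)
  }
  V_c <- cell_volume(cells$L_r_um)
  prof <- absolute_profile(cells, bin_width_um = 40)
  dens <- prof$mean_value[prof$n_cells > 0 & !is.na(prof$mean_value)]
  data.frame(
    ring_width_um = sum(cells$L_r_um),
    ring_mass_mg = sum(cells$mass_mg),
    n_cells = nrow(cells),
    mean_density_g_cm3 = (sum(cells$mass_mg) / sum(V_c)) / 1000,
    max_density_g_cm3 = if (length(dens)) max(dens) else NA_real_,
    earlywood_fraction = if (length(dens)) mean(dens < earlywood_threshold)
      else NA_real_
  )
}

#' Smooth ensemble responses across a temperature-anomaly grid
#'
#' Running mean of each response variable over a 1.5 K-wide window (three
#' adjacent 0.5 K anomaly increments), the convention used for
#' temperature-sweep response curves.
#'
#' @param responses data frame with an `anomaly_K` column on a uniform 0.5 K
#'   grid plus one column per response variable.
#' @param step required grid spacing, K.
#' @return Data frame of the same shape with smoothed response columns.
#' @export
temperature_response <- function(responses, step = 0.5) {
  a <- responses$anomaly_K
  if (is.null(a)) stop("responses must have an 'anomaly_K' column", call. = FALSE)
  o <- order(a)
  responses <- responses[o, , drop = FALSE]
  if (length(a) > 1 && any(abs(diff(responses$anomaly_K) - step) > 1e-9)) {
    stop("anomaly grid must be uniform at ", step, " K", call. = FALSE)
  }
  out <- responses
  for (nm in setdiff(names(responses), "anomaly_K")) {
    out[[nm]] <- running_mean3(responses[[nm]])
  }
  out
}
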