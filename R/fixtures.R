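#' Deterministic two-block ring fixture
#'
#' Builds a synthetic annual-ring record of `n_early` identical earlywood
#' cells followed by `n_late` identical latewood cells with prescribed
#' densities and radial lengths. Used to test profile binning, smoothing
#' and summary metrics against hand-computable expectations.
#'
#' @param n_early,n_late cell counts of the two blocks (either may be 0, not
#'   both).
#' @param densities length-2 densities (g cm^-3) of the early/late blocks.
#' @param lengths length-2 radial lengths (um) of the early/late blocks.
#' @param year,file_id identifiers written into the record.
#' @param params a [model_params()] object (cell geometry).
#' @return A per-cell ring record data frame in the same layout as the
#'   `cells` element of a `xylo_sim`.
#' @export
make_two_block_ring <- function(n_early = 50, n_late = 50,
                                densities = c(0.4, 0.9),
                                lengths = c(30, 15), year = 1L, file_id = 1L,
                                params = model_params()) {
  if (n_early < 0 || n_late < 0 || n_early + n_late < 1) {
    stop("need a positive total number of cells", call. = FALSE)
  }
  if (any(lengths <= 0)) stop("cell lengths must be positive", call. = FALSE)
  L <- c(rep(lengths[1], n_early), rep(lengths[2], n_late))
  dens <- c(rep(densities[1], n_early), rep(densities[2], n_late))
  V_c <- cell_volume(L, params)
  M <- dens * 1000 * V_c
  abs_pos <- cumsum(L) - L / 2
  data.frame(
    year = year, file_id = file_id,
    cell_id = seq_along(L), birth_order = seq_along(L),
    L_r_um = L, mass_mg = M, density_g_cm3 = dens,
    abs_pos_um = abs_pos, norm_position = abs_pos / sum(L)
  )
}

#' Reproducible randomized wall-demand sets
#'
#' Draws `n` saturated wall demands spanning four orders of magnitude
#' (log-uniform), for transport solver/oracle equivalence tests at
#' engine-realistic scales.
#'
#' @param n number of cells (demands).
#' @param seed integer seed.
#' @param log10_range range of `log10(dM_max)` in mg cell^-1 day^-1.
#' @return Numeric vector of demands, ordered phloem-adjacent first.
#' @export
random_demand_set <- function(n, seed, log10_range = c(-7, -3)) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  local_rng(seed, 10^stats::runif(n, log10_range[1], log10_range[2]))
}
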