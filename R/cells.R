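# Boltzmann-Arrhenius factor exp((Ea/k_B) * (1/T0 - 1/T)); equals 1 at T0.
arrhenius_factor <- function(T_K, Ea, params) {
  if (any(T_K <= 0)) stop("temperature must be positive (kelvin)", call. = FALSE)
  exp((Ea / params$k_B) * (1 / params$T0 - 1 / T_K))
}

#' Temperature-dependent relative radial enlargement rate
#'
#' Boltzmann-Arrhenius kinetics for radial cell growth:
#' `mu = mu0 * exp((Ea/k_B) * (1/T0 - 1/T))`, so `mu(T0) = mu0` exactly and
#' `mu` is strictly increasing in temperature.
#'
#' @param T_K temperature, kelvin (vectorized).
#' @param params a [model_params()] object.
#' @return Relative growth rate, um um^-1 day^-1.
#' @examples
#' enlargement_rate(283.15)  # = mu0 = 0.0570
#' @export
enlargement_rate <- function(T_K, params = model_params()) {
  params$mu0 * arrhenius_factor(T_K, params$Ea, params)
}

#' Daily radial growth increment of a cell
#'
#' `dL = L_r * (exp(eps * mu) - 1)`: exponential relative growth at rate `mu`
#' modulated by the cell's birth-asymmetry factor `eps` (daughters born small
#' grow faster, `eps > 1`; daughters born large grow slower).
#'
#' @param L_r current radial length, um (vectorized).
#' @param mu relative growth rate, um um^-1 day^-1.
#' @param epsilon growth dependence on relative birth size (1 = symmetric).
#' @return Radial increment, um day^-1.
#' @examples
#' radial_increment(10, 0.0570, 1)
#' @export
radial_increment <- function(L_r, mu, epsilon = 1) {
  if (any(L_r <= 0)) stop("radial length must be positive", call. = FALSE)
  L_r * expm1(epsilon * mu)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Draw the division length for a cell of birth length L_r_b:
# L_r_d = f * L_r_b + chi_b * (2 - f + Z), Z ~ N(0, sigma) (unclamped).
# f = 0 is a pure sizer, f = 1 a pure adder. Floored at the birth length so a
# pathological draw divides at the next opportunity rather than instantly
# shrinking the target below the cell's size at birth.
draw_division_length <- function(L_r_b, params) {
  Z <- stats::rnorm(length(L_r_b), 0, params$sigma)
  pmax(params$f * L_r_b + params$chi_b * (2 - params$f + Z), L_r_b)
}

#' Divide a proliferating cell into two daughters
#'
#' Stochastic asymmetric division. The division asymmetry draw
#' `Z_a ~ N(0, sigma_a)` (clamped to +/-0.49 for numerical stability) splits
#' the mother's length `L` into birth lengths `L*(0.5 - Z_a)` and
#' `L*(0.5 + Z_a)` (their sum is exactly `L`). Each daughter receives a
#' growth factor `eps = 1 - g_asym * alpha_b`, where
#' `alpha_b = (L_b - L_b_sis)/(L_b + L_b_sis)` is its relative birth
#' asymmetry, and its own division length (sizer-adder rule,
#' `L_r_d = f*L_r_b + chi_b*(2 - f + Z)`). Wall mass is partitioned in
#' proportion to birth lengths; the carbohydrate concentration is inherited.
#' Uses the current RNG stream (the engine seeds one stream per radial file).
#'
#' @param mother list with at least `L_r`, `L_r_d`, `M`, `theta`.
#' @param params a [model_params()] object.
#' @return List of two daughter lists (`a`, `b`), each with `L_r`, `L_r_b`,
#'   `epsilon`, `L_r_d`, `M`, `theta`.
#' @export
divide_cell <- function(mother, params = model_params()) {
  if (mother$L_r < mother$L_r_d) {
    stop("division attempted below the division length", call. = FALSE)
  }
  Z_a <- clamp(stats::rnorm(1, 0, params$sigma_a), -0.49, 0.49)
  L <- mother$L_r
  s_a <- L * (0.5 - Z_a)
  s_b <- L - s_a                 # exact length conservation
  alpha_a <- -2 * Z_a            # (s_a - s_b) / (s_a + s_b)
  eps_a <- 1 - params$g_asym * alpha_a
  eps_b <- 1 + params$g_asym * alpha_a
  Ld <- draw_division_length(c(s_a, s_b), params)
  M_a <- mother$M * s_a / L
  mk <- function(s, eps, Ld1, M) {
    list(L_r = s, L_r_b = s, epsilon = eps, L_r_d = Ld1,
         M = M, theta = mother$theta)
  }
  list(a = mk(s_a, eps_a, Ld[1], M_a),
       b = mk(s_b, eps_b, Ld[2], mother$M - M_a))
}

#' Fate of the initial cell's non-initial daughter
#'
#' When the file's bifacial initial (stem) cell divides, one daughter remains
#' the initial and the other becomes a phloem mother (probability `f_phloem`)
#' or a xylem mother. Phloem mother cells are not tracked: a phloem fate
#' means the daughter (and its share of wall mass) leaves the simulated file.
#'
#' @param params a [model_params()] object.
#' @return `"phloem"` or `"xylem"`.
#' @export
initial_division_fate <- function(params = model_params()) {
  if (stats::runif(1) < params$f_phloem) "phloem" else "xylem"
}
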