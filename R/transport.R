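#' Equilibrium carbohydrate profile along a radial file
#'
#' Solves the daily source-sink diffusion equilibrium for the living cells of
#' one radial file. Carbohydrate flows from the phloem (constant
#' concentration `theta_p`) through the chain of living cells with a constant
#' inter-cell resistance `eta`; each cell consumes at its Michaelis-Menten
#' wall-growth rate. At equilibrium the flux into cell `i` equals the summed
#' wall growth of cell `i` and all cells further from the phloem, which pins
#' the whole profile once the innermost living cell's concentration `theta_n`
#' is known. `theta_n` is found with Brent's method ([stats::uniroot()]) on
#' the residual between the reconstructed and prescribed phloem boundary
#' concentration; the innermost cell's inner wall is impermeable (mature
#' cells are excluded from the domain).
#'
#' @param dM_max carbohydrate-saturated wall demands, mg cell^-1 day^-1,
#'   ordered from the cell adjacent to the phloem inward.
#' @param theta_p phloem carbohydrate concentration, mg ml^-1.
#' @param eta inter-cell diffusion resistance, day ml^-1.
#' @param params a [model_params()] object (supplies `Km`).
#' @param tol absolute residual tolerance on the phloem boundary, mg ml^-1.
#' @return A `xylo_transport` list: `theta` (per-cell concentrations),
#'   `dM` (realized wall growth, mg day^-1), `flux_in` (flux from the phloem,
#'   mg day^-1), `iterations` (solver function evaluations).
#' @examples
#' solve_equilibrium(c(1e-3, 5e-4), theta_p = 95, eta = 4360)
#' @export
solve_equilibrium <- function(dM_max, theta_p, eta, params = model_params(),
                              tol = 1e-8) {
  n <- length(dM_max)
  if (n < 1) stop("need at least one living cell", call. = FALSE)
  if (any(dM_max < 0)) stop("demands must be non-negative", call. = FALSE)
  if (theta_p <= 0) stop("theta_p must be positive", call. = FALSE)

  if (all(dM_max == 0)) {
    return(structure(list(theta = rep(theta_p, n), dM = numeric(n),
                          flux_in = 0, iterations = 0L),
                     class = "xylo_transport"))
  }
  resid <- function(tn) transport_theta0(tn, dM_max, params$Km, eta) - theta_p
  r_lo <- resid(0)     # = -theta_p < 0
  r_hi <- resid(theta_p)  # >= 0: demands only add to the boundary value
  if (r_lo > 0 || r_hi < 0) {
    stop("transport bracket failure (r(0) = ", format(r_lo), ", r(theta_p) = ",
         format(r_hi), "); demands: ",
         paste(signif(dM_max, 4), collapse = ", "), call. = FALSE)
  }
  root <- stats::uniroot(resid, lower = 0, upper = theta_p,
                         f.lower = r_lo, f.upper = r_hi,
                         tol = .Machine$double.eps^0.5)
  # the residual amplifies theta_n perturbations through the outward sweep;
  # polish the Brent root to the last representable double
  half <- max(4 * root$estim.prec, 1e-12, abs(root$root) * 1e-12)
  tn <- NA_real_
  while (is.na(tn)) {
    tn <- transport_polish(max(0, root$root - half),
                           min(theta_p, root$root + half),
                           dM_max, params$Km, eta, theta_p)
    half <- half * 32
    if (half > 32 * theta_p) {
      tn <- transport_polish(0, theta_p, dM_max, params$Km, eta, theta_p)
      break
    }
  }
  prof <- transport_profile(tn, dM_max, params$Km, eta)
  if (abs(prof$theta0 - theta_p) > tol) {
    stop("transport solver residual ", format(abs(prof$theta0 - theta_p)),
         " exceeds tolerance ", format(tol), call. = FALSE)
  }
  structure(list(theta = prof$theta, dM = prof$dM,
                 flux_in = (theta_p - prof$theta[1]) / eta,
                 iterations = root$iter + 2L),
            class = "xylo_transport")
}

#' Damped fixed-point reference solver for the transport equilibrium
#'
#' Independent verification oracle for [solve_equilibrium()]: iterates the
#' full concentration vector under the map
#' `theta_i <- theta_p - eta * cumsum_i(revcumsum(dM(theta)))` with adaptive
#' damping until the profile is stationary. Shares no code with the
#' production solver (which sweeps a scalar boundary value in C++).
#'
#' @inheritParams solve_equilibrium
#' @param damp initial damping factor in (0, 1].
#' @param tol convergence tolerance on the maximum per-cell change, mg ml^-1.
#' @param max_iter iteration cap; exceeding it is an error.
#' @return A `xylo_transport` list (see [solve_equilibrium()]).
#' @export
fixed_point_oracle <- function(dM_max, theta_p, eta, params = model_params(),
                               damp = 0.5, tol = 1e-10, max_iter = 1e5) {
  n <- length(dM_max)
  if (n < 1) stop("need at least one living cell", call. = FALSE)
  theta <- rep(theta_p, n)
  step_map <- function(theta) {
    dM <- wall_growth_rate(theta, dM_max, params)
    S <- rev(cumsum(rev(dM)))      # flux through the wall outward of cell i
    pmax(theta_p - eta * cumsum(S), 0)
  }
  d <- damp
  prev_delta <- Inf
  for (it in seq_len(max_iter)) {
    target <- step_map(theta)
    delta <- max(abs(target - theta))
    if (delta < tol) {
      dM <- wall_growth_rate(theta, dM_max, params)
      return(structure(list(theta = theta, dM = dM,
                            flux_in = (theta_p - theta[1]) / eta,
                            iterations = it),
                       class = "xylo_transport"))
    }
    if (delta > prev_delta) d <- max(d / 2, 1e-4)  # oscillating: damp harder
    prev_delta <- delta
    theta <- (1 - d) * theta + d * target
  }
  stop("fixed-point oracle failed to converge after ", max_iter,
       " iterations (last change ", format(prev_delta), ")", call. = FALSE)
}
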