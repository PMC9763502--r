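# Shared helpers for the xylosim test suite. Fixtures are built in code;
# heavy ensemble runs used by several acceptance checks are computed once and
# cached for the session.

default_p <- model_params()

# climate with a constant temperature, 365-day years
constant_climate <- function(t_C, years = 1995, latitude = 64.35) {
  cl <- synthesize_climate(latitude, years, seed = 1, mean_C = t_C,
                           amplitude_K = 0, ar1_phi = 0, noise_sd_K = 0)
  cl
}

# brute-force single-lineage oracle for the sizer-adder division rule:
# repeatedly draw division length and follow one daughter, using only the
# printed arithmetic (no divide_cell() code)
lineage_oracle <- function(n_div, params = default_p, seed = 1) {
  set.seed(seed)
  L_b <- params$chi_b
  L_d <- numeric(n_div)
  for (i in seq_len(n_div)) {
    Z <- rnorm(1, 0, params$sigma)
    L_d[i] <- params$f * L_b + params$chi_b * (2 - params$f + Z)
    Z_a <- max(min(rnorm(1, 0, params$sigma_a), 0.49), -0.49)
    L_b <- L_d[i] * (0.5 - Z_a)
  }
  L_d
}

acc_cache <- new.env(parent = emptyenv())

acc_run <- function(key, fun) {
  if (is.null(acc_cache[[key]])) acc_cache[[key]] <- fun()
  acc_cache[[key]]
}

# study-condition ensembles used by the acceptance checks (seed fixed at 1)
acc_default_run <- function() acc_run("default", function() {
  cl <- synthesize_climate(64.35, 1984:1995, seed = 1)
  suppressWarnings(run_ensemble(cl, n_files = 25, seed = 1))
})

acc_scenario_run <- function(name) acc_run(name, function() {
  cl <- synthesize_climate(64.35, 1991:1995, seed = 1)
  sc <- switch(name,
    paired_base = scenario_config(),
    plus2K = scenario_config(delta_T_K = 2,
      delta_T_targets = c("enlargement_rate", "thickening_rate")),
    sugar_saturation = scenario_config(sugar_saturation = TRUE),
    fixed_zw_no_dorm = scenario_config(fixed_zone_widths_doy = 171,
                                       autumn_dormancy = FALSE),
    fixed_temp = scenario_config(fixed_temp_C = 10))
  n <- if (name %in% c("paired_base", "plus2K")) 25 else 15
  suppressWarnings(run_ensemble(cl, n_files = n, scenario = sc, seed = 1))
})
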