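test_that("enlargement rate follows Boltzmann-Arrhenius kinetics", {
  expect_identical(enlargement_rate(283.15), model_params()$mu0)
  expect_equal(enlargement_rate(293.15), 0.0961529, tolerance = 1e-5)
  expect_equal(enlargement_rate(300, model_params(Ea = 0)), 0.0570)

  temps <- seq(263.15, 303.15, by = 5)
  mu <- enlargement_rate(temps)
  expect_true(all(diff(mu) > 0))
  # Arrhenius: the Q10-style ratio declines with temperature
  q10 <- enlargement_rate(temps + 10) / enlargement_rate(temps)
  expect_true(all(diff(q10) < 0))
  expect_error(enlargement_rate(-3), "positive")
})

test_that("radial increments are exponential-growth steps", {
  expect_equal(radial_increment(10, 0.0570, 1), 0.5866, tolerance = 1e-4)
  expect_equal(radial_increment(5, 0.1, 0), 0)
  # convexity: doubling eps*mu more than doubles the increment
  expect_gt(radial_increment(10, 0.2, 1), 2 * radial_increment(10, 0.1, 1))
  expect_error(radial_increment(0, 0.1, 1), "positive")
})

test_that("division conserves length and partitions mass by birth length", {
  set.seed(1)
  for (i in 1:100) {
    mother <- list(L_r = runif(1, 10, 30), L_r_d = 5, M = runif(1, 1e-4, 1e-2),
                   theta = 40)
    d <- divide_cell(mother)
    expect_identical(d$a$L_r + d$b$L_r, mother$L_r)    # exact conservation
    expect_equal(d$a$M + d$b$M, mother$M, tolerance = 1e-15)
    expect_equal(d$a$M / d$b$M, d$a$L_r / d$b$L_r, tolerance = 1e-12)
    expect_equal(d$a$epsilon + d$b$epsilon, 2, tolerance = 1e-12)
    expect_equal(d$a$theta, mother$theta)
  }
  expect_error(divide_cell(list(L_r = 4, L_r_d = 5, M = 1e-3, theta = 0)),
               "below the division length")
})

test_that("asymmetry noise is clamped and maps onto the growth factors", {
  # huge asymmetry SD forces the clamp at |Z_a| = 0.49 -> alpha = -/+0.98
  p <- model_params(sigma_a = 1e6)
  set.seed(2)
  for (i in 1:20) {
    d <- divide_cell(list(L_r = 20, L_r_d = 5, M = 1e-3, theta = 0), p)
    eps <- sort(c(d$a$epsilon, d$b$epsilon))
    expect_equal(eps, c(1 - 0.43 * 0.98, 1 + 0.43 * 0.98), tolerance = 1e-12)
    expect_equal(sort(c(d$a$L_r, d$b$L_r)) / 20, c(0.01, 0.99),
                 tolerance = 1e-12)
  }
  # symmetric division: equal daughters with unit growth factors
  p0 <- model_params(sigma_a = 1e-15, sigma = 1e-15)
  d <- divide_cell(list(L_r = 17.6, L_r_d = 17.6, M = 2e-3, theta = 0), p0)
  expect_equal(d$a$L_r, d$b$L_r, tolerance = 1e-9)
  expect_equal(d$a$epsilon, 1, tolerance = 1e-9)
  expect_equal(d$b$epsilon, 1, tolerance = 1e-9)
})

test_that("division length interpolates sizer and adder control", {
  # noise-free division length from mean birth size: f*chi_b + chi_b*(2 - f)
  p0 <- model_params(sigma_a = 1e-15, sigma = 1e-15)
  d <- divide_cell(list(L_r = 17.6, L_r_d = 17.6, M = 0, theta = 0), p0)
  expect_equal(d$a$L_r_d, 0.48 * 8.8 + 8.8 * (2 - 0.48), tolerance = 1e-9)

  division_lengths <- function(f, births) {
    p <- model_params(f = f, sigma = 1e-15, sigma_a = 1e-15)
    vapply(births, function(b) {
      d <- divide_cell(list(L_r = 2 * b, L_r_d = 2 * b, M = 0, theta = 0), p)
      d$a$L_r_d
    }, numeric(1))
  }
  births <- c(4, 8, 12)
  ld_sizer <- division_lengths(0, births)
  expect_lt(diff(range(ld_sizer)), 1e-6)            # size at division fixed
  ld_adder <- division_lengths(1, births)
  expect_lt(diff(range(ld_adder - births)), 1e-6)   # added increment fixed
})

test_that("the long-run mean division length settles at twice the birth size", {
  ld <- lineage_oracle(5000)
  expect_equal(mean(ld[-(1:50)]), 2 * default_p$chi_b, tolerance = 0.05)
})

test_that("initial-cell fate frequencies match the phloem probability", {
  set.seed(3)
  fates <- replicate(1e5, initial_division_fate())
  expect_equal(mean(fates == "phloem"), 0.315, tolerance = 0.005 / 0.315)
  expect_true(all(replicate(50, initial_division_fate(
    model_params(f_phloem = 0))) == "xylem"))
  expect_true(all(replicate(50, initial_division_fate(
    model_params(f_phloem = 1))) == "phloem"))
})
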