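test_that("cell density converts mass per volume into g per cm3", {
  p <- model_params()
  expect_equal(cell_density(p$rho * cell_volume(20), cell_volume(20)), 1.54)
  expect_equal(cell_density(0, 1e-6), 0)
  expect_equal(cell_density(2e-3, cell_volume(30)), 0.4965, tolerance = 1e-4)
  expect_error(cell_density(1, 0), "positive")
})

test_that("two-block rings produce step profiles with correct plateaus", {
  ring <- make_two_block_ring(50, 50, densities = c(0.4, 0.9),
                              lengths = c(30, 15))
  expect_equal(sum(ring$L_r_um), 50 * 30 + 50 * 15)
  pr <- normalized_profile(ring)
  expect_equal(nrow(pr), 50)
  # boundary at 1500/2250 of the ring; plateaus away from the smoothing seam
  early <- pr$mean_density[pr$bin_center < 1500 / 2250 - 0.05]
  late <- pr$mean_density[pr$bin_center > 1500 / 2250 + 0.05]
  expect_true(all(abs(early[!is.na(early)] - 0.4) < 1e-12))
  expect_true(all(abs(late[!is.na(late)] - 0.9) < 1e-12))
  expect_equal(sum(pr$n_cells), 100)

  ap <- absolute_profile(ring, bin_width_um = 40)
  expect_equal(sum(ap$n_cells), 100)
  expect_true(all(abs(ap$mean_value[ap$bin_center < 1400] - 0.4) < 1e-12))
})

test_that("single cells, uniform rings and empty rings are handled", {
  one <- make_two_block_ring(1, 0, densities = c(0.7, 0), lengths = c(25, 1))
  pr <- normalized_profile(one)
  expect_equal(sum(pr$n_cells), 1)
  expect_equal(pr$mean_density[!is.na(pr$mean_density)], 0.7)

  unif <- make_two_block_ring(40, 0, densities = c(0.5, 0), lengths = c(20, 1))
  pr <- normalized_profile(unif)
  occupied <- !is.na(pr$mean_density)
  expect_true(all(abs(pr$mean_density[occupied] - 0.5) < 1e-12))

  empty <- normalized_profile(data.frame())
  expect_equal(nrow(empty), 0)
  expect_equal(nrow(absolute_profile(NULL)), 0)
})

test_that("bin counts follow the binning conventions", {
  ring <- make_two_block_ring(50, 25, lengths = c(30, 20))  # width 2000
  ap <- absolute_profile(ring, bin_width_um = 40)
  expect_equal(nrow(ap), 50)
  # normalized and absolute binning agree on a single ring when the bin
  # widths correspond through the ring width
  pr <- normalized_profile(ring, bin_width = 0.02, smooth = FALSE)
  ap2 <- absolute_profile(ring, bin_width_um = 0.02 * 2000, smooth = FALSE)
  expect_equal(pr$mean_density, ap2$mean_value)
})

test_that("ring summaries aggregate width, mass and densities", {
  ring <- make_two_block_ring(50, 50, densities = c(0.4, 0.9),
                              lengths = c(30, 15))
  sm <- summary_metrics(ring)
  expect_equal(sm$ring_width_um, 2250)
  expect_equal(sm$n_cells, 100L)
  expect_equal(sm$max_density_g_cm3, 0.9, tolerance = 1e-12)
  # volume-weighted mean: (0.4*1500 + 0.9*750) / 2250
  expect_equal(sm$mean_density_g_cm3, (0.4 * 1500 + 0.9 * 750) / 2250,
               tolerance = 1e-12)
  expect_gt(sm$earlywood_fraction, 0.5)
  expect_lt(sm$earlywood_fraction, 0.8)

  low <- make_two_block_ring(20, 0, densities = c(0.3, 0), lengths = c(20, 1))
  expect_equal(summary_metrics(low)$earlywood_fraction, 1)

  one <- make_two_block_ring(1, 0, densities = c(0.7, 0), lengths = c(25, 1))
  sm1 <- summary_metrics(one)
  expect_equal(sm1$ring_width_um, 25)
  expect_equal(sm1$ring_mass_mg, one$mass_mg)
})

test_that("temperature-response smoothing is a three-point running mean", {
  grid <- seq(-2, 2, by = 0.5)
  lin <- data.frame(anomaly_K = grid, y = 3 + 2 * grid)
  sm <- temperature_response(lin)
  inner <- 2:(nrow(lin) - 1)
  expect_equal(sm$y[inner], lin$y[inner], tolerance = 1e-12)

  const <- data.frame(anomaly_K = grid, y = rep(7, length(grid)))
  expect_equal(temperature_response(const)$y, const$y)

  set.seed(1)
  noisy <- data.frame(anomaly_K = seq(-6, 8, by = 0.5))
  reps <- replicate(300, {
    noisy$y <- rnorm(nrow(noisy))
    temperature_response(noisy)$y[10]
  })
  expect_equal(var(reps), 1 / 3, tolerance = 0.25)

  bad <- data.frame(anomaly_K = c(0, 0.5, 1.2), y = 1:3)
  expect_error(temperature_response(bad), "uniform")
})
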