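dormant_zp <- unname(zone_widths(1, daylength_hours(64.35, 1), TRUE,
                                 64.35)["z_p"])

test_that("file initialization enacts the divide-once protocol", {
  fs <- initialize_file(1, dormant_zp, seed = 10)
  fs2 <- initialize_file(1, dormant_zp, seed = 10)
  expect_identical(fs, fs2)
  fs3 <- initialize_file(1, dormant_zp, seed = 11)
  expect_false(identical(fs$L, fs3$L))

  # retained cells: a prefix of daughters whose centres lie in the zone
  centre <- cumsum(fs$L) - fs$L / 2
  expect_true(all(centre <= dormant_zp))
  expect_gte(length(fs$L), 8)
  expect_lte(length(fs$L), 30)
  expect_true(all(fs$Ld >= fs$Lb))
  expect_true(all(fs$eps >= 1 - 0.98 * 0.43 & fs$eps <= 1 + 0.98 * 0.43))
  expect_true(all(fs$status == 1L))

  expect_error(initialize_file(1, 0.5, seed = 1), "too narrow")
})

test_that("dormant days change no lengths and no proliferation-zone mass", {
  fs <- initialize_file(1, dormant_zp, seed = 5)
  before <- fs
  fs2 <- step_day(fs, zw = c(dormant_zp, 500, 900), dormant = TRUE,
                  t_mean = 10)
  expect_identical(fs2$L, before$L)
  expect_identical(fs2$M, before$M)   # all cells proliferating: no deposition
  expect_equal(length(fs2$L), length(before$L))
})

test_that("daily mass gain equals the solver's phloem influx", {
  cl <- constant_climate(12, 1995)
  sched <- zone_schedule(cl, 64.35)
  fs <- initialize_file(1, sched$z_p[1], seed = 3)
  total_before <- sum(fs$M)
  for (i in 1:365) {
    fs <- step_day(fs, c(sched$z_p[i], sched$z_e[i], sched$z_t[i]),
                   sched$dormant[i], sched$t_mean[i])
  }
  # mass closure: cumulative influx = mass change + mass lost to phloem
  expect_equal(fs$flux_year + total_before,
               sum(fs$M) + fs$phloem_mass_out, tolerance = 1e-6 / sum(fs$M))
})

test_that("statuses stay ordered along the file and only move forward", {
  cl <- synthesize_climate(64.35, 1995, seed = 4)
  sched <- zone_schedule(cl, 64.35)
  fs <- initialize_file(1, sched$z_p[1], seed = 4)
  prev_status <- list()
  for (i in seq(1, 365, by = 1)) {
    fs <- step_day(fs, c(sched$z_p[i], sched$z_e[i], sched$z_t[i]),
                   sched$dormant[i], sched$t_mean[i])
    expect_true(all(diff(fs$status) >= 0))
    expect_true(fs$status[1] == 1L)
  }
  # ripeness for the ring: all lengths positive, masses below occlusion
  expect_true(all(fs$L > 0))
  expect_true(all(fs$M / cell_volume(fs$L) <= model_params()$rho))
})

test_that("year transitions partition cells into rings without overlap", {
  cl <- synthesize_climate(64.35, 1993:1995, seed = 9)
  sim <- suppressWarnings(run_ensemble(cl, n_files = 2, seed = 9))
  cells <- sim$cells
  # no cell id appears in two rings of the same file
  for (f in unique(cells$file_id)) {
    sub <- cells[cells$file_id == f, ]
    expect_false(any(duplicated(paste(sub$year, sub$cell_id))))
    # ring cell counts agree with the per-ring summaries
    r <- sim$rings[sim$rings$file_id == f & sim$rings$n_cells > 0, ]
    expect_equal(r$n_cells,
                 as.integer(table(factor(sub$year, levels = r$year))))
  }
  expect_true(all(cells$norm_position >= 0 & cells$norm_position <= 1))
  expect_true(all(cells$density_g_cm3 <= 1.54 + 1e-9))
})

test_that("a year without dormancy release produces an empty ring", {
  cl <- constant_climate(-5, 1995)   # permanently frozen
  sim <- run_ensemble(cl, n_files = 1, seed = 2)
  expect_equal(nrow(sim$cells), 0)
  expect_true(all(sim$rings$n_cells == 0))
  expect_true(all(sim$zones$dormant))
})

test_that("ensembles are bit-reproducible under a fixed master seed", {
  cl <- synthesize_climate(64.35, 1994:1995, seed = 6)
  a <- suppressWarnings(run_ensemble(cl, n_files = 3, seed = 123))
  b <- suppressWarnings(run_ensemble(cl, n_files = 3, seed = 123))
  expect_identical(a$cells, b$cells)
  expect_identical(a$rings, b$rings)
  d <- suppressWarnings(run_ensemble(cl, n_files = 3, seed = 124))
  expect_false(identical(a$cells, d$cells))
})

test_that("boreal forcing yields rings of realistic size and anatomy", {
  run <- acc_default_run()
  r <- run$rings[run$rings$year >= 1986, ]
  expect_true(all(r$n_cells > 0))
  expect_gt(mean(r$n_cells), 25)
  expect_lt(mean(r$n_cells), 75)
  expect_gt(mean(r$ring_width_um), 800)
  expect_lt(mean(r$ring_width_um), 2600)
  # latewood is denser than earlywood in every simulated year
  cells <- run$cells[run$cells$year >= 1986, ]
  for (y in unique(cells$year)) {
    pr <- normalized_profile(cells[cells$year == y, ])
    m <- pr$mean_density
    expect_gt(max(m[pr$bin_center > 2 / 3], na.rm = TRUE),
              mean(m[pr$bin_center < 0.4], na.rm = TRUE))
  }
})
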