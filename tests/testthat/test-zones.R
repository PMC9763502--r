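test_that("zone widths follow the daylength regressions with regime rules", {
  # direct evaluation with the regression coefficients, before ordering
  raw <- zone_widths(200, 20, dormant = FALSE, latitude = 64.35, raw = TRUE)
  expect_equal(unname(raw["z_p"]), -50.9 + 7.47 * 20)   # 98.5
  expect_equal(unname(raw["z_t"]), -427 + 68.8 * 20)    # 949
  expect_equal(unname(raw["z_e"]), -744 + 51.7 * 20)

  # pre-DOY-185 proliferation width is pinned to its DOY-185 value
  dl185 <- daylength_hours(64.35, 185)
  raw2 <- zone_widths(100, 15, dormant = FALSE, latitude = 64.35, raw = TRUE)
  expect_equal(unname(raw2["z_p"]), -50.9 + 7.47 * dl185)
  # pre-DOY-185 enlargement-only width is the temporal extension in DOY
  expect_equal(unname(raw2["z_e"]), min(1257 - 5.01 * 100, -744 + 51.7 * 24))

  # dormant proliferation width is pinned to its DOY-231 value
  dl231 <- daylength_hours(64.35, 231)
  rawd <- zone_widths(300, 8, dormant = TRUE, latitude = 64.35, raw = TRUE)
  expect_equal(unname(rawd["z_p"]), -50.9 + 7.47 * dl231)

  # ordering: z_t >= z_e >= z_p, outer raised to inner
  z <- zone_widths(200, 14, dormant = FALSE, latitude = 64.35)
  expect_equal(unname(z["z_e"]), unname(z["z_p"]))  # raw z_e < z_p here
  expect_true(z["z_t"] >= z["z_e"] && z["z_e"] >= z["z_p"])

  # polar-day cap
  zc <- zone_widths(200, 24, dormant = FALSE, latitude = 70, raw = TRUE)
  expect_equal(unname(zc["z_t"]), -427 + 68.8 * 24)
  expect_error(zone_widths(200, 25, FALSE, 64.35), "daylength")
})

test_that("zone widths are affine in daylength with the fitted slopes", {
  h <- 0.5
  for (dl in c(14, 16, 18)) {
    z1 <- zone_widths(200, dl, FALSE, 64.35, raw = TRUE)
    z2 <- zone_widths(200, dl + h, FALSE, 64.35, raw = TRUE)
    expect_equal(unname((z2 - z1) / h), c(7.47, 51.7, 68.8), tolerance = 1e-10)
  }
})

test_that("the chilling-conditioned degree-day requirement behaves", {
  expect_equal(dormancy_release_threshold(0), 4416.8)
  expect_equal(dormancy_release_threshold(50), 15 + 4401.8 * exp(-2.1),
               tolerance = 1e-12)
  expect_lt(abs(dormancy_release_threshold(600) - 15), 1e-6)
  cd <- seq(0, 300, by = 10)
  expect_true(all(diff(dormancy_release_threshold(cd)) < 0))
  expect_error(dormancy_release_threshold(-1), "non-negative")
})

test_that("dormancy release follows day-by-day accumulation", {
  p <- default_p
  # chill bank of 100 days, then constant +10 C from the forcing start:
  # requirement 15 + 4401.8*exp(-4.2) = 81.55 is met through DOY 40,
  # so release happens on DOY 41
  st <- dormancy_state(TRUE)
  st$cd <- 100
  for (doy in 32:60) st <- update_dormancy(st, doy, 10, p)
  expect_equal(st$release_doy, 41L)
  expect_false(st$dormant)

  # permanently freezing: degree-days never accumulate, never released
  st <- dormancy_state(TRUE)
  for (doy in 1:365) st <- update_dormancy(st, doy, -5, p)
  expect_true(st$dormant)
  expect_true(is.na(st$release_doy))

  # DOY 231 re-imposes dormancy regardless of temperature
  st <- dormancy_state(FALSE)
  st <- update_dormancy(st, 231, 25, p)
  expect_true(st$dormant)
  st <- dormancy_state(FALSE)
  st <- update_dormancy(st, 231, 25, p, autumn_dormancy = FALSE)
  expect_false(st$dormant)
})

test_that("release day is monotone non-increasing in added chill days", {
  p <- default_p
  release_for <- function(extra_chill) {
    st <- dormancy_state(TRUE)
    st$cd <- extra_chill
    # mild spring: 3 C from the forcing start
    for (doy in 33:182) {
      st <- update_dormancy(st, doy, 3, p)
      if (!st$dormant) break
    }
    if (is.na(st$release_doy)) 999L else st$release_doy
  }
  rel <- vapply(seq(0, 150, by = 15), release_for, integer(1))
  expect_true(all(diff(rel) <= 0))
})

test_that("the schedule has at most one release per year, in the first half", {
  cl <- synthesize_climate(64.35, 1991:1994, seed = 3)
  s <- zone_schedule(cl, 64.35)
  rel <- s[s$release, ]
  expect_true(all(rel$doy <= 182))
  expect_true(all(table(rel$year) <= 1))
  expect_true(all(s$z_t >= s$z_e & s$z_e >= s$z_p))
  expect_true(all(s$dormant[s$doy >= 231]))
  # frozen zone widths are constant over the year
  sfz <- zone_schedule(cl, 64.35,
                       scenario = scenario_config(fixed_zone_widths_doy = 171))
  expect_equal(length(unique(sfz$z_e)), 1L)
  expect_equal(unique(sfz$z_p),
               unname(zone_widths(171, daylength_hours(64.35, 171),
                                  FALSE, 64.35)["z_p"]))
})
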