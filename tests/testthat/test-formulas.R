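test_that("residual volume inverts the indicator-dilution mixing relation", {
  # no marker in the mixed fluid means no residual volume
  expect_equal(residual_volume(2000, 0, 2.5), 0)
  # 300 mL at 2.3 g/L diluted into 2000 mL gives 0.3 g/L; inversion is exact
  expect_equal(residual_volume(2000, 0.3, 2.3), 300)
  # randomized mixing oracle: construct the mixed concentration from a known
  # residual volume and demand exact inversion
  withr::with_seed(11, {
    for (i in 1:50) {
      rv <- runif(1, 0, 800)
      v_in <- runif(1, 1000, 3000)
      c_res <- runif(1, 0.5, 5)
      c_t0 <- rv * c_res / (v_in + rv)
      expect_equal(residual_volume(v_in, c_t0, c_res), rv, tolerance = 1e-10)
    }
  })
})

test_that("marker failures are errors, never silently clamped", {
  expect_error(residual_volume(2000, 1, 1),
               class = "spakit_error_indicator_dilution")
  expect_error(residual_volume(2000, 2.5, 2.3),
               class = "spakit_error_indicator_dilution")
  expect_error(residual_volume(0, 0.3, 2.3), class = "spakit_error_input")
})

test_that("net ultrafiltration is the dwell volume balance", {
  expect_equal(net_ultrafiltration(2300, 0, 0, 2300), 0)
  expect_equal(net_ultrafiltration(2200, 150, 40, 2300), 90)
  # net absorption shows up as a negative balance
  expect_lt(net_ultrafiltration(2000, 100, 35, 2300), 0)
  expect_error(net_ultrafiltration(-1, 0, 0, 2300), class = "spakit_error_input")
})

test_that("Garred estimator recovers the generating MTAC from the closed form", {
  # no concentration change at constant volume: MTAC is exactly zero
  expect_equal(mtac_garred(2000, 2000, 240, 3, 3, 5), 0)
  # D(t) = P (1 - exp(-K t / V)) with K = 5 is inverted exactly
  d_t <- closed_form_dialysate(240, 5, 2000, 10)
  expect_equal(mtac_garred(2000, 2000, 240, 0, d_t, 10), 5, tolerance = 1e-12)
  # glucose runs the same closed form backwards (negative gradient)
  g_t <- closed_form_dialysate(240, 3.9, 2000, 5, d0 = 75)
  expect_equal(mtac_garred(2000, 2000, 240, 75, g_t, 5), 3.9, tolerance = 1e-12)
  # randomized sweep over the physiological range
  withr::with_seed(23, {
    for (i in 1:60) {
      k <- runif(1, 0.5, 30)
      v <- runif(1, 1000, 3000)
      p <- runif(1, 1, 20)
      t <- runif(1, 60, 360)
      d_t <- closed_form_dialysate(t, k, v, p)
      expect_equal(mtac_garred(v, v, t, 0, d_t, p), k, tolerance = 1e-9)
    }
  })
})

test_that("Garred estimator is invariant under gradient reflection", {
  # replacing (P, D0, Dt) by (2c - P, 2c - D0, 2c - Dt) flips both gradients
  # and leaves the log ratio unchanged
  withr::with_seed(31, {
    for (i in 1:20) {
      k <- runif(1, 1, 20)
      p <- runif(1, 5, 15)
      d_t <- closed_form_dialysate(240, k, 2000, p)
      cc <- runif(1, -10, 30)
      a <- mtac_garred(2000, 1900, 240, 0, d_t, p)
      b <- mtac_garred(2000, 1900, 240, 2 * cc - 0, 2 * cc - d_t, 2 * cc - p)
      expect_equal(a, b, tolerance = 1e-12)
    }
  })
})

test_that("gradient crossover during the dwell is flagged non-computable", {
  expect_error(mtac_garred(2000, 2000, 240, 2, 8, 5),
               class = "spakit_error_gradient_crossover")
  expect_error(mtac_garred(2000, 2000, 240, 2, 5, 5),
               class = "spakit_error_gradient_crossover")
})

test_that("total solute removal is the dialysate mass difference", {
  expect_equal(total_solute_removal(0, 2100, 0, 2000), 0)
  expect_equal(total_solute_removal(4, 2100, 0, 2000), 8.4)
  # glucose: absorbed mass is negative
  expect_lt(total_solute_removal(50, 2100, 75, 2000), 0)
})

test_that("clearance converts removal and mean plasma level to mL/min", {
  expect_equal(clearance(0, 6, 240), 0)
  # 8.4 mmol over 240 min against 6 mM: 8400 umol / (6 umol/mL * 240 min)
  expect_equal(clearance(8.4, 6, 240), 8400 / (6 * 240))
  expect_error(clearance(8.4, 0, 240), class = "spakit_error_no_plasma")
})

test_that("mean plasma concentration interpolates and carries as specified", {
  expect_equal(as.numeric(mean_plasma(c(6, 6, 6))), 6)
  expect_equal(as.numeric(mean_plasma(c(4, 5, 9))), 6)
  # a single interior gap is linearly interpolated
  m <- mean_plasma(c(4, NA, 8))
  expect_equal(as.numeric(m), 6)
  expect_match(attr(m, "imputed"), "t120_interpolated")
  # missing endpoints carry the nearest available value
  m0 <- mean_plasma(c(NA, 5, 9))
  expect_equal(as.numeric(m0), mean(c(5, 5, 9)))
  expect_match(attr(m0, "imputed"), "carried")
  m240 <- mean_plasma(c(4, 6, NA))
  expect_equal(as.numeric(m240), mean(c(4, 6, 6)))
  expect_error(mean_plasma(c(NA, NA, NA)), class = "spakit_error_no_plasma")
})

test_that("transport ratios follow their definitions", {
  expect_equal(dp_ratio(5, 5), 1)
  expect_equal(dp_ratio(2.05, 5), 0.41)
  expect_equal(dp_ratio(0, 5), 0)
  expect_error(dp_ratio(2, 0), class = "spakit_error_no_plasma")
  expect_equal(dd0_ratio(75, 75), 1)
  expect_equal(dd0_ratio(48.75, 75), 0.65)
  expect_equal(dd0_ratio(0, 75), 0)
  expect_error(dd0_ratio(10, 0), class = "spakit_error_input")
})

test_that("body surface area is an allometric power law", {
  # doubling weight scales BSA by 2^a
  expect_equal(body_surface_area(80) / body_surface_area(40), 2^0.656)
  # identity coefficients pass weight through
  expect_equal(body_surface_area(1.73, k = 1, a = 1), 1.73)
  expect_gt(body_surface_area(100), body_surface_area(40))
  expect_error(body_surface_area(0), class = "spakit_error_input")
})
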