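test_that("noiseless melt curves recover the programmed midpoints", {
  for (tm_true in c(66.8, 83.2)) {
    mc <- simulate_melt_curve(tm = tm_true, noise_sd = 0)
    est <- fit_tm(mc)
    expect_equal(est$tm, tm_true, tolerance = 0.25)
    expect_gt(est$derivative_peak_value, 0)
  }
})

test_that("baseline drift does not displace the recovered Tm materially", {
  mc <- simulate_melt_curve(tm = 70, pre_drift = -2, post_drift = -3,
                            noise_sd = 0)
  expect_equal(fit_tm(mc)$tm, 70, tolerance = 0.5)
})

test_that("featureless curves raise an ambiguous-peak error", {
  flat <- data.frame(temperature = seq(25, 99, 0.5), signal = 1000)
  expect_error(fit_tm(flat), "ambiguous derivative peak")
  noise_only <- simulate_melt_curve(tm = 60, pre_level = 1000,
                                    post_level = 1000, noise_sd = 5, seed = 2)
  expect_error(fit_tm(noise_only), "ambiguous derivative peak")
})

test_that("fit_tm validates its inputs", {
  mc <- simulate_melt_curve(noise_sd = 0)
  expect_error(fit_tm(mc[1:3, ]), "at least 5")
  expect_error(fit_tm(mc, window = 4L), "odd")
  bad <- mc; bad$temperature[10L] <- bad$temperature[9L]
  expect_error(fit_tm(bad), "strictly increasing")
  bad2 <- mc; bad2$signal[5L] <- NA
  expect_error(fit_tm(bad2), "finite")
  expect_error(fit_tm(data.frame(x = 1:10)), "columns temperature and signal")
})

test_that("melt-curve CSV round-trips into fit_tm", {
  mc <- simulate_melt_curve(tm = 75, noise_sd = 0)
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(mc, f, row.names = FALSE)
  expect_equal(fit_tm(read_melt_curve(f))$tm, fit_tm(mc)$tm)
})

test_that("crystallinity reproduces hand-computed values", {
  expect_equal(crystallinity(50, 20), (50 - 20) / 140.1 * 100)
  expect_equal(round(crystallinity(50, 20), 2), 21.41)
  expect_equal(crystallinity(140.1, 0), 100)
  expect_equal(crystallinity(30, 30), 0)
  # scale invariance: doubling all enthalpies including the reference
  expect_equal(crystallinity(100, 40, 280.2), crystallinity(50, 20, 140.1))
  expect_warning(x <- crystallinity(10, 30), "negative")
  expect_equal(x, (10 - 30) / 140.1 * 100)
  expect_error(crystallinity(50, 20, 0), "positive")
  expect_error(crystallinity(-1, 0), "nonnegative")
})

test_that("calibration inverts a known linear response", {
  std <- data.frame(analyte = rep(c("tpa", "mhet"), each = 4L),
                    concentration = rep(c(0.1, 0.2, 0.5, 1.0), 2L))
  std$area <- ifelse(std$analyte == "tpa",
                     50 + 1200 * std$concentration,
                     20 + 800 * std$concentration)
  samples <- data.frame(analyte = c("tpa", "mhet"),
                        area = c(50 + 1200 * 0.42, 20 + 800 * 0.33))
  q <- calibrate_and_quantify(std, samples)
  expect_equal(q$concentration, c(0.42, 0.33), tolerance = 1e-9)
  # dilution factor scales the result
  q2 <- calibrate_and_quantify(std, samples, dilution_factor = 2)
  expect_equal(q2$concentration, 2 * q$concentration)
})

test_that("calibration agrees with a normal-equations oracle on noisy data", {
  set.seed(81)
  conc <- c(0.05, 0.1, 0.2, 0.5, 1, 2)
  area <- 10 + 950 * conc + rnorm(6, 0, 5)
  std <- data.frame(analyte = "tpa", concentration = conc, area = area)
  X <- cbind(1, conc)
  beta <- solve(t(X) %*% X, t(X) %*% area)
  samp <- data.frame(analyte = "tpa", area = c(300, 700))
  q <- calibrate_and_quantify(std, samp)
  expect_equal(q$concentration, (samp$area - beta[1L]) / beta[2L],
               tolerance = 1e-9)
})

test_that("calibration rejects singular or missing standards", {
  std <- data.frame(analyte = "tpa", concentration = c(1, 1, 1),
                    area = c(5, 5, 5))
  samp <- data.frame(analyte = "tpa", area = 4)
  expect_error(calibrate_and_quantify(std, samp), "2 distinct")
  std2 <- data.frame(analyte = "tpa", concentration = c(1, 2), area = c(5, 5))
  expect_error(calibrate_and_quantify(std2, samp), "singular")
  std3 <- data.frame(analyte = "tpa", concentration = c(1, 2), area = c(5, 9))
  expect_error(calibrate_and_quantify(std3,
                                      data.frame(analyte = "bhet", area = 1)),
               "no standards")
  expect_warning(q <- calibrate_and_quantify(std3,
                                             data.frame(analyte = "tpa",
                                                        area = 0)),
                 "clipped")
  expect_equal(q$concentration, 0)
  expect_error(calibrate_and_quantify(std3, samp, dilution_factor = 0),
               "positive")
})

test_that("full conversion of the PET charge reads as 100 percent", {
  pet_load <- 3.75
  mol_total <- pet_load / 192.17
  tc <- product_time_course(times = c(0, 12),
                            tpa = c(0, 0.6 * mol_total),
                            mhet = c(0, 0.4 * mol_total),
                            pet_load = pet_load, volume = 0.150)
  e <- depolymerization_extent(tc)
  expect_equal(e$extent, c(0, 100), tolerance = 1e-9)
  expect_false(attr(e, "capped"))
})

test_that("extent is linear in products and excludes BHET by default", {
  tc <- product_time_course(times = 1, tpa = 2e-3, mhet = 1e-3, bhet = 5e-4,
                            pet_load = 3.75)
  e0 <- depolymerization_extent(tc)
  expect_equal(e0$extent, 100 * 3e-3 * 192.17 / 3.75, tolerance = 1e-12)
  e1 <- depolymerization_extent(tc, include_bhet = TRUE)
  expect_equal(e1$extent, 100 * 3.5e-3 * 192.17 / 3.75, tolerance = 1e-12)
  tc2 <- product_time_course(times = 1, tpa = 4e-3, mhet = 2e-3,
                             pet_load = 3.75)
  expect_equal(depolymerization_extent(tc2)$extent, 2 * e0$extent)
})

test_that("super-stoichiometric products are flagged as capped", {
  tc <- product_time_course(times = 1, tpa = 0.05, mhet = 0, pet_load = 3.75)
  expect_warning(e <- depolymerization_extent(tc), "exceeds 100")
  expect_true(attr(e, "capped"))
})

test_that("product_time_course validates inputs", {
  expect_error(product_time_course(c(1, 0), tpa = c(0, 0), mhet = c(0, 0),
                                   pet_load = 1), "nondecreasing")
  expect_error(product_time_course(1, tpa = -1, mhet = 0, pet_load = 1),
               "nonnegative")
  expect_error(product_time_course(1, tpa = 0, mhet = 0, pet_load = 0),
               "positive")
  expect_error(product_time_course(1:2, tpa = 0, mhet = c(0, 0),
                                   pet_load = 1), "equal length")
})

test_that("titrant accounting multiplies molarity by cumulative volume", {
  eq <- base_to_acid_equivalents(times = c(0, 1), cumulative_volume = c(0, 1e-3),
                                 molarity = 0.3575)
  expect_equal(eq$equivalents, c(0, 3.575e-4))
  expect_error(base_to_acid_equivalents(c(0, 1), c(1e-3, 0), 0.3575),
               "nondecreasing")
  expect_error(base_to_acid_equivalents(0, 0, -1), "positive")
})

test_that("expected equivalents follow TPA:2, MHET:1, BHET:0", {
  expect_equal(expected_base_equivalents(1e-3, 1e-3, 1e-3), 3e-3)
  expect_equal(expected_base_equivalents(0, 2e-3), 2e-3)
  expect_equal(expected_base_equivalents(5e-4, 0, 10), 1e-3)
  expect_error(expected_base_equivalents(-1, 0), "nonnegative")
})

test_that("consistent titration and product data agree on equivalents", {
  tc <- simulate_depolymerization()
  expected <- expected_base_equivalents(tc$tpa, tc$mhet, tc$bhet)
  molarity <- 0.3575
  vol <- expected / molarity
  eq <- base_to_acid_equivalents(tc$times, vol, molarity)
  expect_equal(eq$equivalents, expected, tolerance = 1e-12)
})
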