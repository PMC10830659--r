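test_that("compute_bsa matches the Dubois power law and is monotone", {
  expect_equal(compute_bsa(180, 75), 1.943, tolerance = 0.001)
  # log-space re-evaluation as an independent oracle
  h <- 100; w <- 25.46
  expect_equal(compute_bsa(h, w),
               exp(log(0.007184) + 0.725 * log(h) + 0.425 * log(w)),
               tolerance = 1e-12)
  expect_gt(compute_bsa(180, 75), compute_bsa(170, 75))
  expect_gt(compute_bsa(180, 80), compute_bsa(180, 75))
  expect_error(compute_bsa(-180, 75), "cm")
  expect_error(compute_bsa(170, 0), "positive")
})

test_that("estimate_vo2 reproduces the published expressions", {
  expect_equal(estimate_vo2("dehmer", "male", 40, 2.0), 250)
  expect_equal(estimate_vo2("dehmer", "female", 80, 2.0), 250)
  expect_equal(estimate_vo2("krakau", "male", 60, 2.0), 257.2)
  expect_equal(estimate_vo2("krakau", "female", 60, 2.0),
               2.0 * (147.5 - 60 * 0.47))
  expect_equal(estimate_vo2("lafarge", "female", 60, 1.8, heart_rate = 70),
               1.8 * (138.1 - 17.04 * log(60) + 0.378 * 70))
  expect_equal(estimate_vo2("bergstra", "male", 50, 1.9),
               1.9 * 157.3 + 10 - 10.5 * log(50) + 4.8)
  expect_equal(estimate_vo2("bergstra", "female", 50, 1.9),
               1.9 * 157.3 - 10.5 * log(50) + 4.8)
})

test_that("estimate_vo2 rejects invalid input", {
  expect_error(estimate_vo2("lafarge", "male", 60, 1.9), "heart_rate")
  expect_error(estimate_vo2("krakau", "male", -5, 1.9), "age")
  expect_error(estimate_vo2("krakau", "x", 60, 1.9), "sex")
  expect_error(estimate_vo2("smith", "male", 60, 1.9))
})

test_that("VO2 formulas are age-monotone and BSA-homogeneous", {
  ages <- seq(18, 95, by = 1)
  for (sex in c("male", "female")) {
    for (f in c("krakau", "lafarge", "bergstra")) {
      v <- estimate_vo2(f, sex, ages, bsa = 1.9, heart_rate = 75)
      expect_true(all(diff(v) < 0), info = paste(f, sex))
      expect_true(all(v > 0), info = paste(f, sex))
    }
    expect_true(all(diff(estimate_vo2("dehmer", sex, ages, 1.9)) == 0))
  }
  # krakau and dehmer exactly linear in BSA
  for (f in c("krakau", "dehmer")) {
    expect_equal(estimate_vo2(f, "male", 60, 2 * 1.3),
                 2 * estimate_vo2(f, "male", 60, 1.3))
  }
  # bergstra affine in BSA with slope exactly 157.3
  b1 <- estimate_vo2("bergstra", "female", 60, 1.4)
  b2 <- estimate_vo2("bergstra", "female", 60, 2.4)
  expect_equal(b2 - b1, 157.3 * (2.4 - 1.4))
  # positivity over the stated envelope
  grid <- expand.grid(age = c(18, 50, 95), bsa = c(1.2, 2.6),
                      hr = c(40, 140), sex = c("male", "female"))
  for (f in vo2_formulas()) {
    v <- estimate_vo2(f, grid$sex, grid$age, grid$bsa, heart_rate = grid$hr)
    expect_true(all(v > 0), info = f)
  }
})

test_that("compute_avdo2 follows the 1.34 mL/g relation", {
  expect_equal(compute_avdo2(15, 0.98, 0.68), 6.03)
  # linearity in hemoglobin and in the saturation gap
  expect_equal(compute_avdo2(30, 0.98, 0.68), 2 * compute_avdo2(15, 0.98, 0.68))
  expect_equal(compute_avdo2(14, 0.95, 0.55),
               14 * 1.34 * 0.40, tolerance = 1e-12)
  # percent mode
  expect_equal(compute_avdo2(15, 98, 68, saturation_mode = "percent"), 6.03)
})

test_that("compute_avdo2 rejects bad saturations", {
  expect_error(compute_avdo2(15, 0.68, 0.68), "exceed")
  expect_error(compute_avdo2(15, 0.60, 0.70), "0.7")
  expect_error(compute_avdo2(15, 98, 68), "percent")
  expect_error(compute_avdo2(15, 1.2, 0.68), "ambiguous")
  expect_error(compute_avdo2(0, 0.98, 0.68), "hemoglobin")
})

test_that("compute_fick_co converts units correctly", {
  expect_equal(compute_fick_co(250, 5), 5)
  expect_equal(compute_fick_co(257.2, 6.03), 4.265, tolerance = 0.001)
  # reciprocal scaling
  expect_equal(compute_fick_co(250, 2.5), 2 * compute_fick_co(250, 5))
  expect_error(compute_fick_co(250, 0), "avdo2")
  expect_error(compute_fick_co(-1, 5), "vo2")
})

test_that("fick round trip recovers cardiac output algebraically", {
  set.seed(42)
  for (i in 1:200) {
    hb <- runif(1, 8, 18)
    sv <- runif(1, 0.35, 0.80)
    sa <- runif(1, sv + 0.05, 1.0)
    co <- runif(1, 1.5, 12)
    av <- compute_avdo2(hb, sa, sv)
    expect_equal(compute_fick_co(av * 10 * co, av), co, tolerance = 1e-12)
  }
})

test_that("compute_pvr uses the standard 80x conversion", {
  expect_equal(compute_pvr(22, 13, 5.4), 80 * 9 / 5.4)
  expect_equal(compute_pvr(20, 20, 5), 0)
  expect_equal(compute_pvr(30, 10, 8), compute_pvr(30, 10, 4) / 2)
  expect_true(is.na(compute_pvr(NA, 13, 5.4)))
  expect_error(compute_pvr(10, 15, 5), "mpap")
  expect_error(compute_pvr(22, 13, 0), "cardiac output")
})

test_that("derive_all populates every derived quantity", {
  d <- derive_all(toy_cohort())
  expect_s3_class(d, "hemo_derived")
  expect_equal(nrow(d), 4)
  for (f in vo2_formulas()) {
    expect_true(all(c(paste0("vo2_", f), paste0("ifm_co_", f),
                      paste0("ifm_ci_", f)) %in% names(d)))
  }
  # identity invariants on complete rows
  for (f in vo2_formulas()) {
    co <- d[[paste0("ifm_co_", f)]]
    ok <- !is.na(co)
    expect_equal(d[[paste0("ifm_ci_", f)]][ok] * d$bsa[ok], co[ok])
    expect_equal(co[ok], d[[paste0("vo2_", f)]][ok] / (10 * d$avdo2[ok]))
  }
  expect_equal(d$td_ci, toy_cohort()$td_co_l_min / d$bsa)
  # P4 has no heart rate: lafarge absent, others present; no pressures: pvr NA
  expect_true(is.na(d$ifm_co_lafarge[4]))
  expect_false(any(is.na(d$ifm_co_krakau)))
  expect_true(is.na(d$pvr[4]))
  expect_false(any(is.na(d$pvr[1:3])))
})

test_that("derive_all is deterministic and attaches patient ids to errors", {
  expect_identical(derive_all(toy_cohort()), derive_all(toy_cohort()))
  bad <- toy_cohort()
  bad$svo2[2] <- 0.99  # above sao2
  expect_error(derive_all(bad), "P2")
  neg <- toy_cohort()
  neg$height_cm[3] <- -170
  expect_error(derive_all(neg), "P3")
})

test_that("percent saturation mode flows through derive_all", {
  pc <- toy_cohort()
  pc$sao2 <- pc$sao2 * 100
  pc$svo2 <- pc$svo2 * 100
  expect_equal(derive_all(pc, saturation_mode = "percent"),
               derive_all(toy_cohort()))
})
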