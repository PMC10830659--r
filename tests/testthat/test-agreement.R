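test_that("classify_ratio partitions with inclusive boundaries", {
  expect_equal(as.character(classify_ratio(4.0, 5.0)), "concordant")
  expect_equal(as.character(classify_ratio(6.0, 5.0)), "concordant")  # 1.2
  expect_equal(as.character(classify_ratio(3.0, 3.0)), "concordant")
  expect_equal(as.character(classify_ratio(6.3, 5.0)), "over")
  expect_equal(as.character(classify_ratio(3.9, 5.0)), "under")
  # partition property: exactly one class per positive ratio
  set.seed(11)
  r <- exp(rnorm(500, 0, 0.5))
  cls <- classify_ratio(r, rep(1, 500))
  expect_false(any(is.na(cls)))
  expect_equal(sum(table(cls)), 500)
  expect_error(classify_ratio(4, 0), "reference")
  expect_error(classify_ratio(-4, 5), "method")
})

test_that("bland_altman matches hand computation", {
  ba <- bland_altman(c(5, 6, 7), c(4, 6, 8))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_low, -1.96)
  expect_equal(ba$loa_high, 1.96)
  expect_equal(ba$points$mean, c(4.5, 6, 7.5))
  expect_equal(ba$points$diff, c(1, 0, -1))
  # degenerate agreement
  same <- bland_altman(c(5, 6, 7), c(5, 6, 7))
  expect_equal(c(same$mean_diff, same$loa_low, same$loa_high), c(0, 0, 0))
  off <- bland_altman(c(5, 6, 7) + 1, c(5, 6, 7))
  expect_equal(c(off$mean_diff, off$loa_low, off$loa_high), c(1, 1, 1))
  expect_error(bland_altman(5, 4), "2 complete pairs")
})

test_that("bland_altman is antisymmetric; percentage error symmetric", {
  set.seed(21)
  a <- runif(30, 3, 8); b <- runif(30, 3, 8)
  f <- bland_altman(a, b); g <- bland_altman(b, a)
  expect_equal(g$mean_diff, -f$mean_diff)
  expect_equal(g$loa_low, -f$loa_high)
  expect_equal(g$loa_high, -f$loa_low)
  expect_equal(percentage_error(a, b), percentage_error(b, a))
})

test_that("percentage_error matches hand computation and scales exactly", {
  expect_equal(percentage_error(c(5, 6, 7), c(4, 6, 8)), 100 * 1.96 / 6)
  expect_equal(round(percentage_error(c(5, 6, 7), c(4, 6, 8)), 2), 32.67)
  expect_equal(percentage_error(c(5, 6, 7), c(5, 6, 7)), 0)
  set.seed(31)
  a <- runif(20, 3, 8); b <- runif(20, 3, 8)
  for (c_scale in c(0.1, 3, 17)) {
    expect_equal(percentage_error(c_scale * a, c_scale * b),
                 percentage_error(a, b))
  }
  # multiplier switch
  expect_equal(percentage_error(a, b, multiplier = 2),
               percentage_error(a, b) * 2 / 1.96)
})

test_that("deviation_table counts ratio classes per method", {
  td <- rep(1, 5)
  derived <- data.frame(
    patient_id = paste0("T", 1:5),
    ifm_co_krakau = c(0.5, 0.79, 0.8, 1.0, 1.3),
    ifm_co_dehmer = rep(1, 5),
    td_co = td
  )
  tab <- deviation_table(derived, formulas = c("krakau", "dehmer"))
  k <- tab[tab$method == "krakau", ]
  expect_equal(c(k$under_n, k$concordant_n, k$over_n), c(2, 2, 1))
  expect_equal(k$under_n + k$concordant_n + k$over_n, k$n)
  d <- tab[tab$method == "dehmer", ]
  expect_equal(d$concordant_pct, 100)
})

test_that("pearson_with_ci matches the definitional oracle and cor.test", {
  set.seed(41)
  a <- rnorm(10); b <- 0.6 * a + rnorm(10, 0, 0.5)
  got <- pearson_with_ci(a, b)
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
    ((length(a) - 1) * sd(a) * sd(b))
  expect_equal(got$r, r_oracle, tolerance = 1e-12)
  ct <- cor.test(a, b)
  expect_equal(got$ci_low, unname(ct$conf.int[1]), tolerance = 1e-10)
  expect_equal(got$ci_high, unname(ct$conf.int[2]), tolerance = 1e-10)
  # exact linear relations
  expect_equal(pearson_with_ci(a, 2 * a + 1)$r, 1)
  expect_equal(pearson_with_ci(a, -a)$r, -1)
  expect_error(pearson_with_ci(a[1:3], b[1:3]), "at least 4")
  expect_error(pearson_with_ci(rep(1, 10), b), "constant")
})

test_that("cohen_kappa matches the definitional oracle on a printed table", {
  tab <- matrix(c(40, 5, 0,
                  0, 50, 0,
                  0, 0, 5), nrow = 3, byrow = TRUE)
  cls <- table_to_classes(tab)
  got <- cohen_kappa(cls$a, cls$b)
  expect_equal(got$kappa, kappa_oracle(tab), tolerance = 1e-12)
  expect_equal(sum(got$contingency), 100)
  expect_false(got$degenerate)
  expect_true(got$ci_low <= got$kappa && got$kappa <= got$ci_high)
})

test_that("cohen_kappa handles perfect, independent, degenerate cases", {
  x <- factor(c("under", "concordant", "over", "concordant"),
              levels = ratio_classes())
  expect_equal(cohen_kappa(x, x)$kappa, 1)
  # independence by construction: kappa ~ 0 in a large sample
  set.seed(51)
  a <- sample(ratio_classes(), 20000, replace = TRUE, prob = c(.3, .5, .2))
  b <- sample(ratio_classes(), 20000, replace = TRUE, prob = c(.2, .6, .2))
  k <- cohen_kappa(a, b)
  expect_lt(abs(k$kappa), 0.02)
  # both raters constant and identical -> degenerate, not NaN
  const <- rep("concordant", 10)
  dk <- cohen_kappa(const, const)
  expect_true(dk$degenerate)
  expect_true(is.na(dk$kappa))
})

test_that("kappa stays in [-1, 1] over random classification pairs", {
  set.seed(61)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    a <- sample(ratio_classes(), n, replace = TRUE)
    b <- if (i %% 3 == 0) a else sample(ratio_classes(), n, replace = TRUE)
    k <- cohen_kappa(a, b)
    if (k$degenerate) next
    expect_gte(k$kappa, -1)
    expect_lte(k$kappa, 1)
    if (identical(a, b) && length(unique(a)) > 1) expect_equal(k$kappa, 1)
  }
})

test_that("compare_all produces the full report structure", {
  syn <- generate_cohort(synth_config(n = 120, seed = 5, noise_sd = 0.15))
  d <- derive_all(syn$records)
  cmp <- compare_all(d)
  expect_s3_class(cmp, "fick_comparison")
  expect_named(cmp$vs_reference, vo2_formulas())
  expect_length(cmp$vs_krakau, 3)
  expect_length(cmp$kappa, 3)
  # deviation table proportions equal row-wise classification
  for (f in vo2_formulas()) {
    r <- cmp$vs_reference[[f]]
    row <- cmp$deviation[cmp$deviation$method == f, ]
    cls <- classify_ratio(d[[paste0("ifm_co_", f)]], d$td_co)
    expect_equal(row$under_n, sum(cls == "under", na.rm = TRUE))
    expect_equal(row$concordant_n, sum(cls == "concordant", na.rm = TRUE))
    expect_equal(sum(r$class_counts), r$n)
  }
  # medians match a sorting oracle
  s <- cmp$summary
  med <- s[s$quantity == "co_l_min" & s$method == "krakau", "median"]
  x <- sort(d$ifm_co_krakau)
  expect_equal(med, median(x))
  expect_equal(med, unname(quantile(x, 0.5)))
})

test_that("compare_all marks impossible comparisons unavailable", {
  syn <- generate_cohort(synth_config(n = 10, seed = 6))
  rec <- syn$records
  rec$heart_rate <- NA_real_  # lafarge impossible for everyone
  cmp <- compare_all(derive_all(rec), formulas = c("krakau", "lafarge"))
  expect_true(isTRUE(cmp$vs_reference$lafarge$unavailable))
  expect_false(isTRUE(cmp$vs_reference$krakau$unavailable))
})
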