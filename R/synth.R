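# Synthetic RHC cohort generator with a known-truth disagreement model.
#
# The latent true CO of each patient is the indirect-Fick CO under a chosen
# "truth" formula; the thermodilution reading is that CO perturbed by a
# multiplicative log-normal factor, td_co = true_co * exp(log_bias + eps),
# eps ~ N(0, noise_sd^2). The iFM/TD ratio is then exp(-log_bias - eps), so
# every ratio-based statistic has a closed-form companion.

# per-variable substream seeds: adding a new variable (new index) never
# perturbs columns drawn from earlier indices
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + k * 7919) %% 2147483647)
}

# truncated-normal sampling by redraw (never clipped); lower/upper may be
# vectors (per-row bounds)
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  if (sd < 0) stop_config("rnorm_trunc: sd must be >= 0")
  if (sd == 0) {
    if (any(mean < lower | mean > upper)) {
      stop_config("degenerate (sd = 0) value %.4g outside truncation bounds",
                  mean)
    }
    return(rep(mean, n))
  }
  mass <- pnorm(upper, mean, sd) - pnorm(lower, mean, sd)
  if (any(mass < 1e-12)) {
    stop_config("infeasible truncation bounds [%.4g, %.4g] for N(%.4g, %.4g)",
                min(lower), max(upper), mean, sd)
  }
  x <- rnorm(n, mean, sd)
  bad <- x < lower | x > upper
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- x < lower | x > upper
  }
  x
}

#' Configuration for the synthetic cohort generator
#'
#' Marginal distributions default to a cohort resembling a contemporary
#' adult RHC population: age 63 +/- 14.4 years truncated to \[18, 95\], 30%
#' women, hemoglobin 13.7 +/- 1.8 g/dL, sex-specific height and weight, and
#' truncated-normal oximetry with arterial saturation forced above
#' mixed-venous. The disagreement model is controlled by `truth_formula`
#' (whose indirect-Fick CO defines the latent true CO), a multiplicative
#' bias `log_bias` and a log-normal noise SD `noise_sd`.
#'
#' @param n Cohort size (>= 1).
#' @param seed Integer seed; all draws derive substreams from it.
#' @param prop_female Proportion of women (default 0.30).
#' @param age_mean,age_sd,age_range Age distribution in years (default
#'   63, 14.4, truncated to 18-95).
#' @param height_mean,height_sd Named vectors (`male`, `female`), cm.
#' @param weight_mean,weight_sd Named vectors (`male`, `female`), kg.
#' @param height_range,weight_range Truncation bounds.
#' @param hb_mean,hb_sd,hb_range Hemoglobin, g/dL.
#' @param hr_mean,hr_sd,hr_range Heart rate, beats/min.
#' @param sao2_mean,sao2_sd,sao2_range Arterial saturation (fractions).
#' @param svo2_mean,svo2_sd,svo2_range Mixed-venous saturation (fractions).
#' @param mpawp_mean,mpawp_sd,mpawp_range Wedge pressure, mm Hg.
#' @param papgrad_mean,papgrad_sd,papgrad_range Transpulmonary gradient
#'   (mPAP - mPAWP), mm Hg; mPAP is wedge + gradient so mPAP >= mPAWP holds
#'   by construction.
#' @param truth_formula Formula defining the latent true CO (default
#'   `"krakau"`).
#' @param log_bias Multiplicative bias beta: `td_co = true_co * exp(beta +
#'   eps)` (default 0).
#' @param noise_sd SD sigma of `eps ~ N(0, sigma^2)` (default 0.15).
#' @return A validated list of class `"synth_config"`.
#' @export
synth_config <- function(n,
                         seed = 1L,
                         prop_female = 0.30,
                         age_mean = 63, age_sd = 14.4, age_range = c(18, 95),
                         height_mean = c(male = 176, female = 163),
                         height_sd = c(male = 7, female = 6.5),
                         height_range = c(140, 210),
                         weight_mean = c(male = 84, female = 72),
                         weight_sd = c(male = 14, female = 14),
                         weight_range = c(40, 160),
                         hb_mean = 13.7, hb_sd = 1.8, hb_range = c(7, 20),
                         hr_mean = 75, hr_sd = 15, hr_range = c(40, 140),
                         sao2_mean = 0.96, sao2_sd = 0.02,
                         sao2_range = c(0.85, 1.0),
                         svo2_mean = 0.65, svo2_sd = 0.07,
                         svo2_range = c(0.30, 0.85),
                         mpawp_mean = 14, mpawp_sd = 7,
                         mpawp_range = c(2, 40),
                         papgrad_mean = 10, papgrad_sd = 6,
                         papgrad_range = c(1, 60),
                         truth_formula = "krakau",
                         log_bias = 0,
                         noise_sd = 0.15) {
  if (length(n) != 1 || is.na(n) || n < 1) {
    stop_config("synth_config: n must be >= 1")
  }
  if (length(seed) != 1 || is.na(seed)) {
    stop_config("synth_config: seed must be a single integer")
  }
  if (prop_female < 0 || prop_female > 1) {
    stop_config("synth_config: prop_female must be in [0, 1]")
  }
  truth_formula <- match.arg(truth_formula, vo2_formulas())
  if (noise_sd < 0) {
    stop_config("synth_config: noise_sd must be >= 0")
  }
  sds <- c(age_sd, height_sd, weight_sd, hb_sd, hr_sd, sao2_sd, svo2_sd,
           mpawp_sd, papgrad_sd)
  if (any(sds < 0)) {
    stop_config("synth_config: all SDs must be >= 0")
  }
  # sex-specific parameters may arrive as lists (e.g. from a JSON config)
  height_mean <- unlist(height_mean)
  height_sd <- unlist(height_sd)
  weight_mean <- unlist(weight_mean)
  weight_sd <- unlist(weight_sd)
  for (nm in c("height_mean", "height_sd", "weight_mean", "weight_sd")) {
    v <- get(nm)
    if (!all(c("male", "female") %in% names(v))) {
      stop_config("synth_config: %s must be named with 'male' and 'female'",
                  nm)
    }
  }
  cfg <- list(n = as.integer(n), seed = as.integer(seed),
              prop_female = prop_female,
              age_mean = age_mean, age_sd = age_sd, age_range = age_range,
              height_mean = height_mean, height_sd = height_sd,
              height_range = height_range,
              weight_mean = weight_mean, weight_sd = weight_sd,
              weight_range = weight_range,
              hb_mean = hb_mean, hb_sd = hb_sd, hb_range = hb_range,
              hr_mean = hr_mean, hr_sd = hr_sd, hr_range = hr_range,
              sao2_mean = sao2_mean, sao2_sd = sao2_sd,
              sao2_range = sao2_range,
              svo2_mean = svo2_mean, svo2_sd = svo2_sd,
              svo2_range = svo2_range,
              mpawp_mean = mpawp_mean, mpawp_sd = mpawp_sd,
              mpawp_range = mpawp_range,
              papgrad_mean = papgrad_mean, papgrad_sd = papgrad_sd,
              papgrad_range = papgrad_range,
              truth_formula = truth_formula,
              log_bias = log_bias, noise_sd = noise_sd)
  class(cfg) <- "synth_config"
  cfg
}

# draw one variable inside its own substream, leaving the global RNG state
# as it was
draw_in_substream <- function(seed, k, fun) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, k))
  fun()
}

#' Generate a synthetic RHC cohort with known ground truth
#'
#' Draws demographics and oximetry from the truncated distributions in the
#' configuration, computes each patient's latent true CO as the
#' indirect-Fick CO under `truth_formula`, and sets the thermodilution
#' reading to `true_co * exp(log_bias + eps)` with `eps ~ N(0, noise_sd^2)`.
#' Out-of-bound draws are redrawn, never clipped; mixed-venous saturation is
#' redrawn until strictly below the patient's arterial saturation. The
#' generator is deterministic given the seed, and each variable uses its own
#' seed substream.
#'
#' @param config A [synth_config()].
#' @return List of class `"synth_cohort"` with `records` (a cohort data
#'   frame in the [cohort_columns()] schema), `truth` (per-patient
#'   `true_co`, `epsilon`, `vo2_truth`), and the `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synth_config")) {
    config <- do.call(synth_config, as.list(config))
  }
  n <- config$n
  seed <- config$seed

  sex <- draw_in_substream(seed, 1L, function() {
    ifelse(runif(n) < config$prop_female, "female", "male")
  })
  female <- sex == "female"
  age <- draw_in_substream(seed, 2L, function() {
    rnorm_trunc(n, config$age_mean, config$age_sd,
                config$age_range[1], config$age_range[2])
  })
  height <- draw_in_substream(seed, 3L, function() {
    x <- numeric(n)
    x[!female] <- rnorm_trunc(sum(!female), config$height_mean[["male"]],
                              config$height_sd[["male"]],
                              config$height_range[1], config$height_range[2])
    x[female] <- rnorm_trunc(sum(female), config$height_mean[["female"]],
                             config$height_sd[["female"]],
                             config$height_range[1], config$height_range[2])
    x
  })
  weight <- draw_in_substream(seed, 4L, function() {
    x <- numeric(n)
    x[!female] <- rnorm_trunc(sum(!female), config$weight_mean[["male"]],
                              config$weight_sd[["male"]],
                              config$weight_range[1], config$weight_range[2])
    x[female] <- rnorm_trunc(sum(female), config$weight_mean[["female"]],
                             config$weight_sd[["female"]],
                             config$weight_range[1], config$weight_range[2])
    x
  })
  hb <- draw_in_substream(seed, 5L, function() {
    rnorm_trunc(n, config$hb_mean, config$hb_sd,
                config$hb_range[1], config$hb_range[2])
  })
  hr <- draw_in_substream(seed, 6L, function() {
    rnorm_trunc(n, config$hr_mean, config$hr_sd,
                config$hr_range[1], config$hr_range[2])
  })
  sao2 <- draw_in_substream(seed, 7L, function() {
    rnorm_trunc(n, config$sao2_mean, config$sao2_sd,
                config$sao2_range[1], config$sao2_range[2])
  })
  svo2 <- draw_in_substream(seed, 8L, function() {
    # per-row upper bound keeps svo2 strictly below sao2
    rnorm_trunc(n, config$svo2_mean, config$svo2_sd,
                config$svo2_range[1],
                pmin(config$svo2_range[2], sao2 - 0.02))
  })
  mpawp <- draw_in_substream(seed, 9L, function() {
    rnorm_trunc(n, config$mpawp_mean, config$mpawp_sd,
                config$mpawp_range[1], config$mpawp_range[2])
  })
  papgrad <- draw_in_substream(seed, 10L, function() {
    rnorm_trunc(n, config$papgrad_mean, config$papgrad_sd,
                config$papgrad_range[1], config$papgrad_range[2])
  })
  eps <- draw_in_substream(seed, 11L, function() {
    if (config$noise_sd == 0) rep(0, n) else rnorm(n, 0, config$noise_sd)
  })

  bsa <- compute_bsa(height, weight)
  vo2_truth <- estimate_vo2(config$truth_formula, sex, age, bsa,
                            heart_rate = hr)
  avdo2 <- compute_avdo2(hb, sao2, svo2)
  true_co <- compute_fick_co(vo2_truth, avdo2)
  td_co <- true_co * exp(config$log_bias + eps)

  records <- data.frame(
    patient_id = sprintf("SYN%05d", seq_len(n)),
    age = age, sex = sex, height_cm = height, weight_kg = weight,
    heart_rate = hr, hemoglobin_g_dl = hb, sao2 = sao2, svo2 = svo2,
    td_co_l_min = td_co, mpap_mmhg = mpawp + papgrad, mpawp_mmhg = mpawp,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    patient_id = records$patient_id,
    true_co = true_co, epsilon = eps, vo2_truth = vo2_truth,
    stringsAsFactors = FALSE
  )
  out <- list(records = records, truth = truth, config = config)
  class(out) <- "synth_cohort"
  out
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic RHC cohort: n = %d, truth formula %s, log-bias %.3f, noise SD %.3f, seed %d\n",
    x$config$n, x$config$truth_formula, x$config$log_bias,
    x$config$noise_sd, x$config$seed))
  invisible(x)
}

#' Closed-form discordance probability of the disagreement model
#'
#' Under the generator's model, the ratio of the truth-formula Fick CO to
#' the thermodilution reading is `exp(-beta - eps)` with
#' `eps ~ N(0, sigma^2)`. The probability that the ratio falls outside the
#' concordant band \[0.8, 1.2\] is
#' `pnorm((log(0.8) + beta) / sigma) + 1 - pnorm((log(1.2) + beta) / sigma)`.
#' For `sigma = 0` it is the indicator of `exp(-beta)` lying outside the
#' band.
#'
#' @param noise_sd Noise SD sigma (>= 0).
#' @param log_bias Bias beta (default 0).
#' @return Discordance probability in \[0, 1\].
#' @export
expected_discordance <- function(noise_sd, log_bias = 0) {
  if (any(noise_sd < 0)) stop_config("expected_discordance: noise_sd must be >= 0")
  ifelse(noise_sd == 0,
         as.numeric(exp(-log_bias) < 0.8 | exp(-log_bias) > 1.2),
         pnorm((log(0.8) + log_bias) / noise_sd) +
           1 - pnorm((log(1.2) + log_bias) / noise_sd))
}
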