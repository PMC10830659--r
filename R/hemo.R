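# Per-patient hemodynamic computations: BSA, VO2 estimation formulas,
# arteriovenous oxygen content difference, indirect-Fick CO and derived
# indices.

#' Names of the supported VO2 estimation formulas
#'
#' The closed set of oxygen-consumption approximation formulas implemented by
#' [estimate_vo2()]. Every operation that iterates "all formulas" iterates
#' this vector, in this order.
#'
#' @return Character vector `c("krakau", "lafarge", "dehmer", "bergstra")`.
#' @export
vo2_formulas <- function() c("krakau", "lafarge", "dehmer", "bergstra")

#' Body surface area (Dubois & Dubois)
#'
#' BSA = 0.007184 * height^0.725 * weight^0.425 with height in centimetres
#' and weight in kilograms (the canonical 1916 constants).
#'
#' @param height_cm Height in cm (> 0). Vectorized.
#' @param weight_kg Weight in kg (> 0). Vectorized.
#' @return Body surface area in m^2.
#' @examples
#' compute_bsa(180, 75)  # 1.943 m^2
#' @export
compute_bsa <- function(height_cm, weight_kg) {
  if (any(!is.na(height_cm) & height_cm <= 0) ||
      any(!is.na(weight_kg) & weight_kg <= 0)) {
    stop_data("compute_bsa: height and weight must be strictly positive (height in cm, weight in kg)")
  }
  0.007184 * height_cm^0.725 * weight_kg^0.425
}

# canonical sex coding: accepts "m"/"f"/"male"/"female" (any case)
normalize_sex <- function(sex) {
  s <- tolower(as.character(sex))
  s[s == "m"] <- "male"
  s[s == "f"] <- "female"
  bad <- !is.na(s) & !(s %in% c("male", "female"))
  if (any(bad)) {
    stop_data("sex must be one of m/f/male/female; got: %s",
              paste(unique(s[bad]), collapse = ", "))
  }
  s
}

#' Estimate oxygen consumption (VO2) under a named formula
#'
#' Implements the four published VO2 approximation formulas used for
#' indirect-Fick cardiac output, in mL/min:
#' \describe{
#'   \item{krakau}{men: `BSA * (161 - 0.54 * age)`;
#'     women: `BSA * (147.5 - 0.47 * age)`}
#'   \item{lafarge}{men: `BSA * (138.1 - 11.49 * ln(age) + 0.378 * HR)`;
#'     women: `BSA * (138.1 - 17.04 * ln(age) + 0.378 * HR)`}
#'   \item{dehmer}{`BSA * 125` (sex-invariant)}
#'   \item{bergstra}{men: `BSA * 157.3 + 10 - 10.5 * ln(age) + 4.8`;
#'     women: `BSA * 157.3 - 10.5 * ln(age) + 4.8`. The `+10` is an additive
#'     male term, not multiplied by BSA.}
#' }
#' `ln` is the natural logarithm of age in years.
#'
#' @param formula One of [vo2_formulas()].
#' @param sex "male"/"female" (or "m"/"f"). Vectorized.
#' @param age Age in years (> 0). Vectorized.
#' @param bsa Body surface area in m^2. Vectorized.
#' @param heart_rate Heart rate in beats/min; required only for `"lafarge"`.
#' @return Estimated VO2 in mL/min.
#' @examples
#' estimate_vo2("krakau", "male", age = 60, bsa = 2.0)  # 257.2
#' estimate_vo2("dehmer", "female", age = 40, bsa = 2.0)  # 250
#' @export
estimate_vo2 <- function(formula, sex, age, bsa, heart_rate = NULL) {
  formula <- match.arg(formula, vo2_formulas())
  sex <- normalize_sex(sex)
  if (any(!is.na(age) & age <= 0)) {
    stop_data("estimate_vo2: age must be > 0 years (formulas take ln(age))")
  }
  male <- sex == "male"
  switch(formula,
    krakau = bsa * ifelse(male, 161 - 0.54 * age, 147.5 - 0.47 * age),
    lafarge = {
      if (is.null(heart_rate)) {
        stop_data("estimate_vo2: the LaFarge formula requires heart_rate")
      }
      bsa * (138.1 - ifelse(male, 11.49, 17.04) * log(age) +
               0.378 * heart_rate)
    },
    dehmer = bsa * 125,
    bergstra = bsa * 157.3 + ifelse(male, 10, 0) - 10.5 * log(age) + 4.8
  )
}

#' Arteriovenous oxygen content difference
#'
#' avDO2 = hemoglobin (g/dL) * 1.34 mL/g * (SaO2 - SvO2), in mL O2 per dL
#' blood. The Huefner constant is fixed at 1.34 mL/g. Saturations are
#' fractions in \[0, 1\]; pass `saturation_mode = "percent"` for 0-100
#' inputs. In fraction mode, values above 1 are rejected (values above 1.5
#' look like the percent scale; values in (1, 1.5\] are ambiguous either way).
#'
#' @param hemoglobin Hemoglobin in g/dL (> 0). Vectorized.
#' @param sao2 Arterial oxygen saturation. Vectorized.
#' @param svo2 Mixed-venous oxygen saturation; must satisfy `svo2 < sao2`.
#' @param saturation_mode `"fraction"` (default) or `"percent"`.
#' @return avDO2 in mL O2/dL.
#' @examples
#' compute_avdo2(15, 0.98, 0.68)  # 6.03
#' @export
compute_avdo2 <- function(hemoglobin, sao2, svo2,
                          saturation_mode = c("fraction", "percent")) {
  saturation_mode <- match.arg(saturation_mode)
  if (saturation_mode == "percent") {
    sao2 <- sao2 / 100
    svo2 <- svo2 / 100
  } else {
    big <- c(sao2[!is.na(sao2) & sao2 > 1], svo2[!is.na(svo2) & svo2 > 1])
    if (length(big)) {
      hint <- if (any(big > 1.5)) {
        "values look like the 0-100 scale; use saturation_mode = \"percent\""
      } else {
        "values in (1, 1.5] are ambiguous between scales"
      }
      stop_data("compute_avdo2: saturations must be fractions in [0,1] (%s)",
                hint)
    }
  }
  if (any(!is.na(hemoglobin) & hemoglobin <= 0)) {
    stop_data("compute_avdo2: hemoglobin must be > 0 g/dL")
  }
  bad <- !is.na(sao2) & !is.na(svo2) & sao2 <= svo2
  if (any(bad)) {
    i <- which(bad)[1]
    stop_data("compute_avdo2: sao2 (%.4g) must exceed svo2 (%.4g)",
              sao2[i], svo2[i])
  }
  if (any(!is.na(sao2) & (sao2 < 0)) || any(!is.na(svo2) & (svo2 < 0))) {
    stop_data("compute_avdo2: saturations must be non-negative")
  }
  hemoglobin * 1.34 * (sao2 - svo2)
}

#' Indirect-Fick cardiac output
#'
#' CO = VO2 / (10 * avDO2). The factor 10 converts the per-dL oxygen content
#' to per-L so that mL/min divided by mL/L gives L/min.
#'
#' @param vo2 Oxygen consumption in mL/min (> 0). Vectorized.
#' @param avdo2 Arteriovenous O2 content difference in mL/dL (> 0).
#' @return Cardiac output in L/min.
#' @examples
#' compute_fick_co(250, 5)  # 5 L/min
#' @export
compute_fick_co <- function(vo2, avdo2) {
  if (any(!is.na(avdo2) & avdo2 <= 0)) {
    stop_data("compute_fick_co: avdo2 must be > 0 mL/dL (CO undefined at 0)")
  }
  if (any(!is.na(vo2) & vo2 <= 0)) {
    stop_data("compute_fick_co: vo2 must be > 0 mL/min")
  }
  vo2 / (10 * avdo2)
}

#' Pulmonary vascular resistance
#'
#' PVR = 80 * (mPAP - mPAWP) / CO, in dyn*s/cm^5. Missing pressures yield
#' `NA`, never zero.
#'
#' @param mpap Mean pulmonary artery pressure, mm Hg. Vectorized.
#' @param mpawp Mean pulmonary artery wedge pressure, mm Hg; `mpap >= mpawp`.
#' @param co Cardiac output in L/min (> 0).
#' @return PVR in dyn*s/cm^5, `NA` where either pressure is missing.
#' @examples
#' compute_pvr(22, 13, 5.4)  # 133.3
#' @export
compute_pvr <- function(mpap, mpawp, co) {
  if (any(!is.na(co) & co <= 0)) {
    stop_data("compute_pvr: cardiac output must be > 0 L/min")
  }
  bad <- !is.na(mpap) & !is.na(mpawp) & mpap < mpawp
  if (any(bad)) {
    i <- which(bad)[1]
    stop_data("compute_pvr: mpap (%.4g) must be >= mpawp (%.4g)",
              mpap[i], mpawp[i])
  }
  80 * (mpap - mpawp) / co
}

#' Derive all hemodynamic quantities for a cohort
#'
#' Runs every per-patient computation over a cohort table: BSA, VO2 under all
#' four formulas, avDO2, indirect-Fick CO and CI per formula, thermodilution
#' CI, and PVR where pressures are present. Patients missing `heart_rate`
#' get `NA` for the LaFarge columns only; patients missing pressures get `NA`
#' PVR. Nothing is imputed.
#'
#' @param cohort A data frame with the cohort schema of [read_cohort()]
#'   (columns `patient_id, age, sex, height_cm, weight_kg, heart_rate,
#'   hemoglobin_g_dl, sao2, svo2, td_co_l_min, mpap_mmhg, mpawp_mmhg`;
#'   pressure columns optional).
#' @param saturation_mode `"fraction"` (default) or `"percent"` for 0-100
#'   saturation inputs.
#' @return A data frame of class `"hemo_derived"`: one row per patient with
#'   columns `patient_id`, `bsa`, `avdo2`, `vo2_<formula>`,
#'   `ifm_co_<formula>`, `ifm_ci_<formula>` for each formula, plus `td_co`,
#'   `td_ci` and `pvr`.
#' @export
derive_all <- function(cohort, saturation_mode = c("fraction", "percent")) {
  saturation_mode <- match.arg(saturation_mode)
  cohort <- validate_cohort(cohort, saturation_mode = saturation_mode)

  # validate_cohort already normalized saturations to fractions and rejected
  # invalid rows with their patient ids
  bsa <- compute_bsa(cohort$height_cm, cohort$weight_kg)
  avdo2 <- compute_avdo2(cohort$hemoglobin_g_dl, cohort$sao2, cohort$svo2)

  out <- data.frame(patient_id = cohort$patient_id, bsa = bsa,
                    avdo2 = avdo2, stringsAsFactors = FALSE)
  for (f in vo2_formulas()) {
    hr <- if (f == "lafarge") cohort$heart_rate else NULL
    vo2 <- if (f == "lafarge") {
      # NA heart rate -> NA vo2, other formulas unaffected
      estimate_vo2(f, cohort$sex, cohort$age, bsa, heart_rate = hr)
    } else {
      estimate_vo2(f, cohort$sex, cohort$age, bsa)
    }
    out[[paste0("vo2_", f)]] <- vo2
    out[[paste0("ifm_co_", f)]] <- compute_fick_co(vo2, avdo2)
    out[[paste0("ifm_ci_", f)]] <- out[[paste0("ifm_co_", f)]] / bsa
  }
  out$td_co <- cohort$td_co_l_min
  out$td_ci <- cohort$td_co_l_min / bsa
  out$pvr <- if (all(c("mpap_mmhg", "mpawp_mmhg") %in% names(cohort))) {
    compute_pvr(cohort$mpap_mmhg, cohort$mpawp_mmhg, cohort$td_co_l_min)
  } else {
    NA_real_
  }
  class(out) <- c("hemo_derived", "data.frame")
  out
}
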