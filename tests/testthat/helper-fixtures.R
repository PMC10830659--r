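# Shared fixtures: a tiny hand-written cohort and an independent VO2
# evaluator used as the oracle against estimate_vo2().

toy_cohort <- function() {
  data.frame(
    patient_id = c("P1", "P2", "P3", "P4"),
    age = c(60, 45, 72, 55),
    sex = c("m", "f", "m", "f"),
    height_cm = c(180, 165, 175, 160),
    weight_kg = c(80, 62, 90, 70),
    heart_rate = c(70, 80, 65, NA),
    hemoglobin_g_dl = c(14.5, 12.8, 15.2, 13.0),
    sao2 = c(0.97, 0.98, 0.95, 0.96),
    svo2 = c(0.68, 0.72, 0.60, 0.65),
    td_co_l_min = c(5.2, 4.6, 6.1, 4.9),
    mpap_mmhg = c(22, 18, 30, NA),
    mpawp_mmhg = c(12, 9, 16, NA),
    stringsAsFactors = FALSE
  )
}

# independently written brute-force evaluator of the four VO2 expressions;
# deliberately structured differently from estimate_vo2 (scalar, explicit
# branches) so it can serve as an oracle
vo2_oracle <- function(formula, sex, age, bsa, hr = NA) {
  if (formula == "krakau") {
    if (sex == "male") return(bsa * (161 - age * 0.54))
    return(bsa * (147.5 - age * 0.47))
  }
  if (formula == "lafarge") {
    coef <- if (sex == "male") 11.49 else 17.04
    return(bsa * (138.1 - coef * log(age) + 0.378 * hr))
  }
  if (formula == "dehmer") return(bsa * 125)
  if (formula == "bergstra") {
    base <- bsa * 157.3 - 10.5 * log(age) + 4.8
    return(if (sex == "male") base + 10 else base)
  }
  stop("unknown formula")
}

# all 3x3 nonnegative integer contingency tables with total count <= `total`,
# one table per row (cells in row-major order), built by vectorized growth
all_small_tables <- function(total = 12L) {
  M <- matrix(integer(0), nrow = 1, ncol = 0)
  for (cell in 1:9) {
    r <- total - (if (ncol(M)) rowSums(M) else 0L)
    idx <- rep(seq_len(nrow(M)), r + 1L)
    val <- sequence(r + 1L) - 1L
    M <- cbind(M[idx, , drop = FALSE], val)
  }
  M[rowSums(M) > 0L, , drop = FALSE]
}

# definitional kappa oracle straight from a 3x3 count table
kappa_oracle <- function(tab) {
  n <- sum(tab)
  p <- tab / n
  p_o <- p[1, 1] + p[2, 2] + p[3, 3]
  p_e <- sum(rowSums(p) * colSums(p))
  if (1 - p_e == 0) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

# expand a count table into the paired class vectors it summarizes
table_to_classes <- function(tab, levels = ratio_classes()) {
  a <- character(0); b <- character(0)
  for (i in 1:3) for (j in 1:3) {
    if (tab[i, j] > 0) {
      a <- c(a, rep(levels[i], tab[i, j]))
      b <- c(b, rep(levels[j], tab[i, j]))
    }
  }
  list(a = factor(a, levels = levels), b = factor(b, levels = levels))
}
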