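# Pairwise method-comparison statistics: ratio classification, Bland-Altman,
# percentage error, Pearson correlation, Cohen's kappa, and the full-study
# driver.

#' Ratio concordance classes
#'
#' The three-way classification of a method ratio `co_ifm / co_ref`:
#' `under` (< 0.8), `concordant` (0.8 to 1.2, boundaries inclusive), `over`
#' (> 1.2). A deviation of more than 20% from the reference means a ratio
#' outside the closed interval \[0.8, 1.2\].
#'
#' @return Character vector of the class labels, in order.
#' @export
ratio_classes <- function() c("under", "concordant", "over")

# pairwise-complete mask shared by all paired statistics
pair_complete <- function(a, b) !is.na(a) & !is.na(b)

#' Classify a cardiac-output ratio against a reference
#'
#' @param co_ifm Indirect-Fick CO, L/min (> 0). Vectorized.
#' @param co_ref Reference CO, L/min (> 0). Vectorized.
#' @return Factor with levels [ratio_classes()]; `NA` where either input is
#'   missing.
#' @examples
#' classify_ratio(4.0, 5.0)  # ratio exactly 0.8 -> concordant
#' @export
classify_ratio <- function(co_ifm, co_ref) {
  if (any(!is.na(co_ref) & co_ref <= 0)) {
    stop_data("classify_ratio: reference CO must be > 0")
  }
  if (any(!is.na(co_ifm) & co_ifm <= 0)) {
    stop_data("classify_ratio: method CO must be > 0")
  }
  ratio <- co_ifm / co_ref
  cls <- ifelse(ratio < 0.8, "under", ifelse(ratio > 1.2, "over",
                                             "concordant"))
  factor(cls, levels = ratio_classes())
}

#' Bland-Altman analysis of a method pair
#'
#' Mean difference and 95% limits of agreement, `mean_diff +/- 1.96 * SD` of
#' the paired differences `a - b` (sample SD, n-1 denominator), computed over
#' pairwise-complete rows. Per-pair `(mean, diff)` coordinates are returned
#' for plotting.
#'
#' @param a,b Paired CO series, L/min.
#' @param ids Optional identifiers carried into the plotting coordinates.
#' @return List of class `"bland_altman"` with `n`, `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, and a `points` data frame.
#' @examples
#' bland_altman(c(5, 6, 7), c(4, 6, 8))  # mean_diff 0, LoA -1.96 / +1.96
#' @export
bland_altman <- function(a, b, ids = NULL) {
  keep <- pair_complete(a, b)
  if (sum(keep) < 2) {
    stop_data("bland_altman: need at least 2 complete pairs (got %d)",
              sum(keep))
  }
  a <- a[keep]; b <- b[keep]
  d <- a - b
  m <- mean(d)
  s <- sd(d)
  out <- list(
    n = length(d),
    mean_diff = m,
    sd_diff = s,
    loa_low = m - 1.96 * s,
    loa_high = m + 1.96 * s,
    points = data.frame(
      patient_id = if (is.null(ids)) seq_along(d) else ids[keep],
      mean = (a + b) / 2,
      diff = d,
      stringsAsFactors = FALSE
    )
  )
  class(out) <- "bland_altman"
  out
}

#' Critchley percentage error between two CO methods
#'
#' `100 * multiplier * SD(a - b) / (0.5 * (mean(a) + mean(b)))`, over
#' pairwise-complete rows, with sample SD. The default multiplier is 1.96;
#' `multiplier = 2` is available as a sensitivity switch. Values below 30%
#' are conventionally regarded as clinically acceptable.
#'
#' @param a,b Paired CO series, L/min.
#' @param multiplier SD multiplier, 1.96 (default) or 2.0.
#' @return Percentage error in percent (a scalar >= 0).
#' @examples
#' percentage_error(c(5, 6, 7), c(4, 6, 8))  # 32.67%
#' @export
percentage_error <- function(a, b, multiplier = 1.96) {
  keep <- pair_complete(a, b)
  if (sum(keep) < 2) {
    stop_data("percentage_error: need at least 2 complete pairs")
  }
  a <- a[keep]; b <- b[keep]
  denom <- (mean(a) + mean(b)) / 2
  if (denom <= 0) {
    stop_data("percentage_error: combined mean must be > 0")
  }
  100 * multiplier * sd(a - b) / denom
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' Sample Pearson r over pairwise-complete rows and its 95% confidence
#' interval via the Fisher z-transform, `atanh(r) +/- 1.96 / sqrt(n - 3)`.
#'
#' @param a,b Paired numeric series.
#' @param conf Confidence level (default 0.95).
#' @return List with `r`, `ci_low`, `ci_high`, `n`.
#' @export
pearson_with_ci <- function(a, b, conf = 0.95) {
  keep <- pair_complete(a, b)
  n <- sum(keep)
  if (n < 4) {
    stop_data("pearson_with_ci: need at least 4 complete pairs (got %d)", n)
  }
  a <- a[keep]; b <- b[keep]
  if (sd(a) == 0 || sd(b) == 0) {
    stop_data("pearson_with_ci: correlation undefined for a constant series")
  }
  r <- cor(a, b)
  z <- atanh(r)
  crit <- qnorm(1 - (1 - conf) / 2)
  half <- crit / sqrt(n - 3)
  list(r = r, ci_low = tanh(z - half), ci_high = tanh(z + half), n = n)
}

#' Cohen's kappa between two three-category classifications
#'
#' Unweighted kappa `(p_o - p_e) / (1 - p_e)` from the contingency table of
#' two paired classifications, with chance agreement `p_e` from the marginal
#' products. The 95% confidence interval uses the asymptotic
#' (Fleiss-Cohen-Everitt) standard error. If both raters are constant and
#' identical (`p_e = 1`), kappa is undefined: the result carries
#' `degenerate = TRUE` and `NA` estimates rather than propagating NaN.
#'
#' @param class_a,class_b Paired factors (coerced to factors over `levels`).
#' @param levels Category levels; defaults to [ratio_classes()].
#' @param conf Confidence level (default 0.95).
#' @return List of class `"kappa_result"` with `kappa`, `se`, `ci_low`,
#'   `ci_high`, `n`, `contingency` (counts, rows = `class_a`), `p_o`, `p_e`,
#'   `degenerate`.
#' @export
cohen_kappa <- function(class_a, class_b, levels = ratio_classes(),
                        conf = 0.95) {
  class_a <- factor(class_a, levels = levels)
  class_b <- factor(class_b, levels = levels)
  keep <- pair_complete(class_a, class_b)
  class_a <- class_a[keep]; class_b <- class_b[keep]
  n <- length(class_a)
  if (n < 1) {
    stop_data("cohen_kappa: no complete pairs")
  }
  tab <- table(class_a, class_b)
  p <- tab / n
  p_row <- rowSums(p)
  p_col <- colSums(p)
  p_o <- sum(diag(p))
  p_e <- sum(p_row * p_col)

  out <- list(n = n, contingency = tab, p_o = p_o, p_e = p_e,
              degenerate = FALSE)
  if (isTRUE(all.equal(p_e, 1)) && p_e >= 1 - 1e-12) {
    out$degenerate <- TRUE
    out$kappa <- NA_real_
    out$se <- NA_real_
    out$ci_low <- NA_real_
    out$ci_high <- NA_real_
    class(out) <- "kappa_result"
    return(out)
  }
  k <- (p_o - p_e) / (1 - p_e)

  # Fleiss, Cohen & Everitt large-sample variance of kappa-hat
  idx <- seq_along(levels)
  term1 <- sum(vapply(idx, function(i) {
    p[i, i] * (1 - (p_row[i] + p_col[i]) * (1 - k))^2
  }, numeric(1)))
  term2 <- 0
  for (i in idx) for (j in idx) {
    if (i != j) term2 <- term2 + p[i, j] * (p_col[i] + p_row[j])^2
  }
  term2 <- (1 - k)^2 * term2
  term3 <- (k - p_e * (1 - k))^2
  se <- sqrt(max(0, (term1 + term2 - term3))) / ((1 - p_e) * sqrt(n))

  crit <- qnorm(1 - (1 - conf) / 2)
  out$kappa <- k
  out$se <- se
  out$ci_low <- max(-1, k - crit * se)
  out$ci_high <- min(1, k + crit * se)
  class(out) <- "kappa_result"
  out
}

#' @export
print.kappa_result <- function(x, ...) {
  if (isTRUE(x$unavailable)) {
    cat("Cohen's kappa: unavailable (no complete pairs)\n")
  } else if (x$degenerate) {
    cat("Cohen's kappa: degenerate (both classifications constant and identical)\n")
  } else {
    cat(sprintf("Cohen's kappa: %.3f (95%% CI %.3f to %.3f), n = %d\n",
                x$kappa, x$ci_low, x$ci_high, x$n))
  }
  invisible(x)
}

#' Agreement report for one method pair
#'
#' Bundles every agreement statistic for one comparison `a` (test method)
#' versus `b` (reference): Bland-Altman mean difference and limits of
#' agreement, percentage error with the < 30% acceptability flag, Pearson r
#' with its 95% CI, and the ratio-class counts of `a / b`.
#'
#' @param a,b Paired CO series, L/min (test, reference).
#' @param label_a,label_b Method names for reporting.
#' @param ids Optional patient identifiers for the Bland-Altman coordinates.
#' @param pe_multiplier Percentage-error SD multiplier (1.96 or 2.0).
#' @return List of class `"agreement_report"`.
#' @export
agreement_report <- function(a, b, label_a = "method", label_b = "reference",
                             ids = NULL, pe_multiplier = 1.96) {
  keep <- pair_complete(a, b)
  n <- sum(keep)
  if (n < 2) {
    stop_data("agreement_report (%s vs %s): need at least 2 complete pairs",
              label_a, label_b)
  }
  ba <- bland_altman(a, b, ids = ids)
  pe <- percentage_error(a, b, multiplier = pe_multiplier)
  pr <- if (n >= 4 && sd(a[keep]) > 0 && sd(b[keep]) > 0) {
    pearson_with_ci(a, b)
  } else {
    list(r = NA_real_, ci_low = NA_real_, ci_high = NA_real_, n = n)
  }
  cls <- classify_ratio(a[keep], b[keep])
  counts <- table(cls)
  out <- list(
    label_a = label_a, label_b = label_b, n = n,
    mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
    loa_low = ba$loa_low, loa_high = ba$loa_high,
    percentage_error = pe, pe_multiplier = pe_multiplier,
    acceptable = pe < 30,
    pearson = pr,
    class_counts = as.integer(counts),
    class_props = as.numeric(counts) / n,
    classes = ratio_classes(),
    bland_altman = ba
  )
  names(out$class_counts) <- names(counts)
  names(out$class_props) <- names(counts)
  class(out) <- "agreement_report"
  out
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement: %s vs %s (n = %d)\n", x$label_a, x$label_b, x$n))
  cat(sprintf("  mean difference %.3f L/min, LoA %.3f to %.3f\n",
              x$mean_diff, x$loa_low, x$loa_high))
  cat(sprintf("  percentage error %.1f%% (%s; multiplier %.2f)\n",
              x$percentage_error,
              if (x$acceptable) "acceptable, < 30%" else "not acceptable",
              x$pe_multiplier))
  if (!is.na(x$pearson$r)) {
    cat(sprintf("  Pearson r %.3f (95%% CI %.3f to %.3f)\n",
                x$pearson$r, x$pearson$ci_low, x$pearson$ci_high))
  }
  cat(sprintf("  ratio classes: %s\n",
              paste(sprintf("%s %d (%.1f%%)", names(x$class_counts),
                            x$class_counts, 100 * x$class_props),
                    collapse = ", ")))
  invisible(x)
}

#' Ratio-deviation table for several methods against a reference
#'
#' Counts and percentages of patients in each ratio class (`under`,
#' `concordant`, `over`) for each indirect-Fick method against the reference
#' series, using each method's own pairwise-complete n.
#'
#' @param derived Output of [derive_all()] (must carry `td_co`).
#' @param formulas Methods to tabulate (default all four).
#' @param reference Reference series; defaults to `derived$td_co`.
#' @return Data frame with one row per method: `method`, `n`, and count and
#'   percent columns per class.
#' @export
deviation_table <- function(derived, formulas = vo2_formulas(),
                            reference = derived$td_co) {
  rows <- lapply(formulas, function(f) {
    a <- derived[[paste0("ifm_co_", f)]]
    keep <- pair_complete(a, reference)
    if (!any(keep)) {
      stop_data("deviation_table: no complete pairs for %s", f)
    }
    cls <- classify_ratio(a[keep], reference[keep])
    counts <- table(cls)
    n <- sum(keep)
    data.frame(method = f, n = n,
               under_n = as.integer(counts["under"]),
               under_pct = 100 * as.integer(counts["under"]) / n,
               concordant_n = as.integer(counts["concordant"]),
               concordant_pct = 100 * as.integer(counts["concordant"]) / n,
               over_n = as.integer(counts["over"]),
               over_pct = 100 * as.integer(counts["over"]) / n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# median (25th; 75th percentile) rows for CO / CI / VO2 per method
method_summary <- function(derived, formulas = vo2_formulas()) {
  qfun <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(NA_real_, NA_real_, NA_real_, 0))
    c(median(x), quantile(x, 0.25, names = FALSE),
      quantile(x, 0.75, names = FALSE), length(x))
  }
  rows <- list()
  add <- function(quantity, method, x) {
    q <- qfun(x)
    rows[[length(rows) + 1]] <<- data.frame(
      quantity = quantity, method = method, n = as.integer(q[4]),
      median = q[1], q25 = q[2], q75 = q[3], stringsAsFactors = FALSE)
  }
  add("co_l_min", "td", derived$td_co)
  add("ci_l_min_m2", "td", derived$td_ci)
  for (f in formulas) {
    add("co_l_min", f, derived[[paste0("ifm_co_", f)]])
    add("ci_l_min_m2", f, derived[[paste0("ifm_ci_", f)]])
    add("vo2_ml_min", f, derived[[paste0("vo2_", f)]])
  }
  do.call(rbind, rows)
}

#' Full method-comparison report for a derived cohort
#'
#' Drives every comparison in the study design: an [agreement_report()] for
#' each formula against the thermodilution reference, an agreement report
#' for each other formula against the Krakau formula, Cohen's kappa between
#' the Krakau-vs-reference ratio classification and each other formula's
#' classification, the per-method deviation table, and median/quartile
#' summaries of CO, CI and VO2 per method. Comparisons with fewer than 2
#' complete pairs are marked unavailable rather than failing the run.
#'
#' @param derived Output of [derive_all()] (must carry `td_co`).
#' @param pe_multiplier Percentage-error SD multiplier (1.96 or 2.0).
#' @param formulas Formulas to compare (default all four).
#' @return List of class `"fick_comparison"` with elements `vs_reference`,
#'   `vs_krakau`, `kappa`, `deviation`, `summary`, `n_total`.
#' @export
compare_all <- function(derived, pe_multiplier = 1.96,
                        formulas = vo2_formulas()) {
  stopifnot(all(formulas %in% vo2_formulas()))
  td <- derived$td_co
  ids <- derived$patient_id

  try_report <- function(a, b, la, lb) {
    tryCatch(agreement_report(a, b, label_a = la, label_b = lb, ids = ids,
                              pe_multiplier = pe_multiplier),
             fickco_data_error = function(e) {
               structure(list(label_a = la, label_b = lb,
                              unavailable = TRUE,
                              reason = conditionMessage(e)),
                         class = "agreement_report")
             })
  }

  vs_reference <- lapply(formulas, function(f) {
    try_report(derived[[paste0("ifm_co_", f)]], td, f, "td")
  })
  names(vs_reference) <- formulas

  vs_krakau <- list()
  kappas <- list()
  if ("krakau" %in% formulas) {
    krakau_co <- derived$ifm_co_krakau
    others <- setdiff(formulas, "krakau")
    vs_krakau <- lapply(others, function(f) {
      try_report(derived[[paste0("ifm_co_", f)]], krakau_co, f, "krakau")
    })
    names(vs_krakau) <- others

    # interrater agreement between the krakau-vs-reference classification
    # and each other formula's classification, on shared complete rows
    kappas <- lapply(others, function(f) {
      a <- krakau_co
      b <- derived[[paste0("ifm_co_", f)]]
      keep <- pair_complete(a, b) & !is.na(td)
      if (sum(keep) < 1) {
        return(structure(list(unavailable = TRUE), class = "kappa_result"))
      }
      cohen_kappa(classify_ratio(a[keep], td[keep]),
                  classify_ratio(b[keep], td[keep]))
    })
    names(kappas) <- others
  }

  # tabulate only methods with at least one complete pair; the others are
  # already flagged unavailable above
  dev_formulas <- formulas[vapply(formulas, function(f) {
    any(pair_complete(derived[[paste0("ifm_co_", f)]], td))
  }, logical(1))]
  out <- list(
    n_total = nrow(derived),
    pe_multiplier = pe_multiplier,
    formulas = formulas,
    vs_reference = vs_reference,
    vs_krakau = vs_krakau,
    kappa = kappas,
    deviation = deviation_table(derived, formulas = dev_formulas),
    summary = method_summary(derived, formulas = formulas)
  )
  class(out) <- "fick_comparison"
  out
}

#' @export
print.fick_comparison <- function(x, ...) {
  cat(sprintf("Indirect-Fick method comparison (n = %d patients)\n\n",
              x$n_total))
  for (r in x$vs_reference) {
    if (isTRUE(r$unavailable)) {
      cat(sprintf("Agreement: %s vs %s — unavailable (%s)\n",
                  r$label_a, r$label_b, r$reason))
    } else {
      print(r)
    }
  }
  if (length(x$kappa)) {
    cat("\nKappa vs krakau classification:\n")
    for (f in names(x$kappa)) {
      cat(sprintf("  %s: ", f))
      print(x$kappa[[f]])
    }
  }
  invisible(x)
}
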