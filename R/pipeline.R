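# Command-line orchestration: validate a cohort, run every derivation and
# comparison, write tables / plot coordinates / a JSON summary; generate
# synthetic cohorts from a config file.

report_as_list <- function(r) {
  if (isTRUE(r$unavailable)) {
    return(list(label_a = r$label_a, label_b = r$label_b,
                unavailable = TRUE, reason = r$reason))
  }
  counts <- as.list(as.integer(r$class_counts))
  names(counts) <- names(r$class_counts)
  props <- as.list(as.numeric(r$class_props))
  names(props) <- names(r$class_props)
  list(
    label_a = r$label_a, label_b = r$label_b, n = r$n,
    mean_diff = r$mean_diff, sd_diff = r$sd_diff,
    loa_low = r$loa_low, loa_high = r$loa_high,
    percentage_error = r$percentage_error,
    pe_multiplier = r$pe_multiplier,
    acceptable = r$acceptable,
    pearson_r = r$pearson$r,
    pearson_ci_low = r$pearson$ci_low,
    pearson_ci_high = r$pearson$ci_high,
    class_counts = counts,
    class_props = props
  )
}

kappa_as_list <- function(k) {
  if (isTRUE(k$unavailable)) return(list(unavailable = TRUE))
  list(kappa = k$kappa, se = k$se, ci_low = k$ci_low, ci_high = k$ci_high,
       n = k$n, degenerate = k$degenerate,
       contingency = unclass(unname(as.matrix(k$contingency))))
}

comparison_as_list <- function(cmp) {
  list(
    n_total = cmp$n_total,
    pe_multiplier = cmp$pe_multiplier,
    formulas = cmp$formulas,
    vs_reference = lapply(cmp$vs_reference, report_as_list),
    vs_krakau = lapply(cmp$vs_krakau, report_as_list),
    kappa_vs_krakau = lapply(cmp$kappa, kappa_as_list)
  )
}

round_df <- function(df, digits = 4) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Run the full cohort analysis pipeline
#'
#' Validates the cohort, derives every hemodynamic quantity, runs all
#' method comparisons and writes the artifact files to `out_dir`:
#' `derived.csv` (wide per-patient table), `method_summary.csv`
#' (median/quartiles of CO, CI, VO2 per method), `deviation_table.csv`
#' (ratio-class counts per method), `bland_altman_<a>_vs_<b>.csv`
#' (plot coordinates per comparison), `summary.json` (every statistic, full
#' precision) and `run_log.txt` (n, per-comparison exclusions with reasons,
#' and every configuration value). The run is deterministic and idempotent
#' for fixed inputs.
#'
#' @param input Path to a cohort CSV, or a cohort data frame.
#' @param out_dir Output directory (created if absent).
#' @param saturation_mode `"fraction"` (default) or `"percent"`.
#' @param pe_multiplier Percentage-error SD multiplier (1.96 or 2.0).
#' @param formulas Formulas to include (default all four).
#' @return The `"fick_comparison"` object, invisibly.
#' @export
run_analysis <- function(input, out_dir,
                         saturation_mode = c("fraction", "percent"),
                         pe_multiplier = 1.96,
                         formulas = vo2_formulas()) {
  saturation_mode <- match.arg(saturation_mode)
  if (!pe_multiplier %in% c(1.96, 2.0)) {
    stop_config("pe_multiplier must be 1.96 or 2.0")
  }
  if (!all(formulas %in% vo2_formulas())) {
    stop_config("unknown formula(s): %s",
                paste(setdiff(formulas, vo2_formulas()), collapse = ", "))
  }
  cohort <- if (is.character(input)) {
    read_cohort(input, saturation_mode = saturation_mode)
  } else {
    validate_cohort(input, saturation_mode = saturation_mode)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # saturations already normalized to fractions by validation
  derived <- derive_all(cohort, saturation_mode = "fraction")
  cmp <- compare_all(derived, pe_multiplier = pe_multiplier,
                     formulas = formulas)

  write_derived(derived, file.path(out_dir, "derived.csv"))
  write.csv(round_df(method_summary(derived, formulas = formulas)),
            file.path(out_dir, "method_summary.csv"), row.names = FALSE)
  write.csv(round_df(cmp$deviation),
            file.path(out_dir, "deviation_table.csv"), row.names = FALSE)
  for (r in c(cmp$vs_reference, cmp$vs_krakau)) {
    if (isTRUE(r$unavailable)) next
    write.csv(round_df(r$bland_altman$points),
              file.path(out_dir, sprintf("bland_altman_%s_vs_%s.csv",
                                         r$label_a, r$label_b)),
              row.names = FALSE)
  }
  jsonlite::write_json(comparison_as_list(cmp),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # exclusion accounting per comparison: a patient is excluded only from
  # comparisons for which a required field is missing
  log_lines <- c(
    "fickco run log",
    sprintf("patients_total: %d", nrow(cohort)),
    sprintf("saturation_mode: %s", saturation_mode),
    sprintf("pe_multiplier: %g", pe_multiplier),
    sprintf("formulas: %s", paste(formulas, collapse = ","))
  )
  for (f in formulas) {
    a <- derived[[paste0("ifm_co_", f)]]
    n_pair <- sum(!is.na(a) & !is.na(derived$td_co))
    excl <- nrow(cohort) - n_pair
    reason <- if (f == "lafarge") "missing heart_rate or td_co" else
      "missing td_co or inputs"
    log_lines <- c(log_lines,
                   sprintf("comparison %s vs td: n = %d, excluded = %d (%s)",
                           f, n_pair, excl,
                           if (excl > 0) reason else "none"))
  }
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(cmp)
}

#' Generate a synthetic cohort and write it to disk
#'
#' Delegates to [generate_cohort()] and writes `cohort.csv` (standard
#' schema), `truth.csv` (`patient_id, true_co, epsilon, vo2_truth`) and
#' `config.json` (the configuration echoed back) into `out_dir`.
#'
#' @param config A [synth_config()], a plain list of its arguments, or a
#'   path to a JSON file of them.
#' @param out_dir Output directory (created if absent).
#' @return The `"synth_cohort"` object, invisibly.
#' @export
run_generate <- function(config, out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop_config("config file not found: %s", config)
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!inherits(config, "synth_config")) {
    config <- tryCatch(do.call(synth_config, as.list(config)),
                       error = function(e) {
                         if (inherits(e, "fickco_config_error")) stop(e)
                         stop_config("invalid synthetic config: %s",
                                     conditionMessage(e))
                       })
  }
  cohort <- generate_cohort(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(cohort$records, file.path(out_dir, "cohort.csv"))
  truth <- round_df(cohort$truth, digits = 6)
  write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE,
            na = "")
  # named vectors become JSON objects so the echoed config reads back intact
  cfg_json <- lapply(unclass(cohort$config), function(x) {
    if (!is.null(names(x)) && length(x) > 1) as.list(x) else x
  })
  jsonlite::write_json(cfg_json,
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cohort)
}

#' Command-line entry point
#'
#' Implements `analyze` and `generate` subcommands:
#' \preformatted{
#' fickco analyze --input cohort.csv --out DIR [--saturation-mode percent]
#'                [--pe-multiplier 1.96] [--formulas krakau,dehmer,...]
#' fickco generate --config synth.json --out DIR
#' }
#' Exit codes: 0 success, 1 data error, 2 config/usage error. A wrapper
#' script is installed under `inst/cli/fickco`.
#'
#' @param args Command-line arguments (default `commandArgs(trailingOnly =
#'   TRUE)`).
#' @return Integer exit status, invisibly.
#' @export
fickco_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: fickco <analyze|generate> [options]",
    "  analyze  --input cohort.csv --out DIR [--saturation-mode fraction|percent]",
    "           [--pe-multiplier 1.96|2.0] [--formulas krakau,lafarge,dehmer,bergstra]",
    "  generate --config synth.json --out DIR",
    sep = "\n")
  if (length(args) < 1 || !args[1] %in% c("analyze", "generate")) {
    message(usage)
    return(invisible(2L))
  }
  sub <- args[1]
  rest <- args[-1]
  status <- tryCatch({
    if (sub == "analyze") {
      opts <- optparse::parse_args(optparse::OptionParser(
        option_list = list(
          optparse::make_option("--input", type = "character"),
          optparse::make_option("--out", type = "character"),
          optparse::make_option("--saturation-mode", type = "character",
                                default = "fraction", dest = "saturation_mode"),
          optparse::make_option("--pe-multiplier", type = "double",
                                default = 1.96, dest = "pe_multiplier"),
          optparse::make_option("--formulas", type = "character",
                                default = paste(vo2_formulas(),
                                                collapse = ","))
        )), args = rest)
      if (is.null(opts$input) || is.null(opts$out)) {
        stop_config("analyze requires --input and --out")
      }
      run_analysis(opts$input, opts$out,
                   saturation_mode = opts$saturation_mode,
                   pe_multiplier = opts$pe_multiplier,
                   formulas = strsplit(opts$formulas, ",")[[1]])
      0L
    } else {
      opts <- optparse::parse_args(optparse::OptionParser(
        option_list = list(
          optparse::make_option("--config", type = "character"),
          optparse::make_option("--out", type = "character")
        )), args = rest)
      if (is.null(opts$config) || is.null(opts$out)) {
        stop_config("generate requires --config and --out")
      }
      run_generate(opts$config, opts$out)
      0L
    }
  },
  fickco_config_error = function(e) {
    message("config error: ", conditionMessage(e)); 2L
  },
  fickco_data_error = function(e) {
    message("data error: ", conditionMessage(e)); 1L
  },
  error = function(e) {
    message("error: ", conditionMessage(e)); 1L
  })
  invisible(status)
}
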