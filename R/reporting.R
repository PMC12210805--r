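#' Planning configuration
#'
#' Bundles everything needed to run the two planning directions: the
#' population specification, the thresholds and measures of interest, the
#' precision targets for the threshold-based measures and for the four
#' established criteria, and the interval method.
#'
#' @param pop a [pop_spec()].
#' @param thresholds probability thresholds to evaluate.
#' @param ciw global target confidence-interval width(s) for the
#'   threshold-based measures; a vector builds a grid (the first entry is
#'   the primary target used for the binding criterion). The default 0.1
#'   reflects the usual recommendation that a 95% interval width of 0.1 or
#'   less represents good precision on the proportion scale.
#' @param measures measures to include (default all six).
#' @param level confidence level.
#' @param method `"wald"` (closed forms) or `"agresti_coull"` (iterative).
#' @param c_statistic anticipated c-statistic (NULL to skip the criterion).
#' @param c_ciw target CI width for the c-statistic (default 0.1).
#' @param oe_ciw target CI width for the O/E ratio (NULL to skip).
#' @param slope_ciw target CI width for the calibration slope (NULL to skip).
#' @param snb_ciw target CI width for standardised net benefit (NULL to
#'   skip); evaluated at each threshold in `thresholds`.
#' @param n_max bound for the iterative searches.
#' @return an object of class `plan_config`.
#' @export
plan_config <- function(pop, thresholds, ciw = 0.1,
                        measures = MEASURES, level = 0.95,
                        method = c("wald", "agresti_coull"),
                        c_statistic = NULL, c_ciw = 0.1, oe_ciw = NULL,
                        slope_ciw = NULL, snb_ciw = NULL,
                        n_max = 1e6) {
  stopifnot(inherits(pop, "pop_spec"),
            all(thresholds >= 0), all(thresholds <= 1),
            all(ciw > 0), all(ciw < 2))
  method <- match.arg(method)
  measures <- vapply(measures, match_measure, character(1), USE.NAMES = FALSE)
  if (length(measures) == 0L && is.null(c_statistic) && is.null(oe_ciw) &&
      is.null(slope_ciw) && is.null(snb_ciw)) {
    stop("at least one measure or criterion must be requested.", call. = FALSE)
  }
  structure(list(pop = pop, thresholds = thresholds, ciw = ciw,
                 measures = measures, level = level, method = method,
                 c_statistic = c_statistic, c_ciw = c_ciw, oe_ciw = oe_ciw,
                 slope_ciw = slope_ciw, snb_ciw = snb_ciw, n_max = n_max),
            class = "plan_config")
}

#' Read a planning configuration from JSON
#'
#' Flat JSON with the population fields of [write_pop_spec()] under `pop`
#' and the remaining [plan_config()] fields at the top level.
#'
#' @param path JSON file path.
#' @return a [plan_config()].
#' @export
read_plan_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x$pop, tmp, auto_unbox = TRUE, digits = NA)
  pop <- read_pop_spec(tmp)
  args <- x[setdiff(names(x), "pop")]
  do.call(plan_config, c(list(pop = pop), args))
}

#' Minimum required sample size for every requested criterion
#'
#' Runs the target-width-to-minimum-N planning direction: derives the
#' anticipated true performance at each threshold from the population
#' specification (by simulation, reproducible under the spec's seed),
#' inverts the standard-error formulas (or runs the iterative searches) for
#' each measure and CI-width in the grid, computes the four established
#' criteria where requested, and identifies the binding criterion — the
#' maximum N at the primary CI width.
#'
#' @param config a [plan_config()].
#' @return an object of class `samplesize_report`: list with
#'   `measure_table` (one row per threshold x measure, one `N (events)`
#'   column per CI width), `criteria_table` (established criteria),
#'   `results` (all [samplesize_result()] objects at the primary width),
#'   `binding`, `profiles`, and the `config`.
#' @export
#' @examples
#' cfg <- plan_config(pop_spec(beta_risk(1.33, 1.75), n_sim = 1e5),
#'                    thresholds = 0.1, ciw = 0.1)
#' run_min_samplesize(cfg)
run_min_samplesize <- function(config) {
  stopifnot(inherits(config, "plan_config"))
  sim <- simulate_population(config$pop)
  profiles <- lapply(config$thresholds, function(t) {
    true_performance(config$pop, t, population = sim)
  })
  names(profiles) <- as.character(config$thresholds)
  primary <- config$ciw[1]

  rows <- list(); results <- list()
  for (k in seq_along(config$thresholds)) {
    prof <- profiles[[k]]
    for (ms in config$measures) {
      cells <- character(length(config$ciw))
      for (j in seq_along(config$ciw)) {
        tgt <- precision_target(ms, ciw = config$ciw[j], level = config$level)
        res <- if (ms == "f1") {
          n_f1(prof, tgt, n_max = config$n_max)
        } else if (config$method == "agresti_coull") {
          n_measure_ac(ms, prof, tgt, n_max = config$n_max)
        } else {
          n_threshold_measure(ms, prof, tgt)
        }
        cells[j] <- format(res)
        if (j == 1L) results[[paste(ms, config$thresholds[k], sep = "@")]] <- res
      }
      row <- data.frame(threshold = config$thresholds[k], measure = ms,
                        value = round(prof[[ms]], 3))
      for (j in seq_along(config$ciw)) {
        row[[paste0("ciw_", config$ciw[j])]] <- cells[j]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  measure_table <- do.call(rbind, rows)

  crit_rows <- list()
  phi_sim <- mean(sim$y)
  if (!is.null(config$oe_ciw)) {
    res <- n_oe(phi_sim, precision_target("oe", ciw = config$oe_ciw,
                                          level = config$level))
    results[["oe"]] <- res
    crit_rows[[length(crit_rows) + 1L]] <-
      data.frame(criterion = "oe", threshold = NA_real_, value = 1,
                 ciw = config$oe_ciw, n = format(res))
  }
  if (!is.null(config$slope_ciw)) {
    info <- fisher_information(sim$lp)
    res <- n_calibration_slope(info,
                               precision_target("calibration_slope",
                                                ciw = config$slope_ciw,
                                                level = config$level),
                               phi = phi_sim)
    results[["calibration_slope"]] <- res
    crit_rows[[length(crit_rows) + 1L]] <-
      data.frame(criterion = "calibration_slope", threshold = NA_real_,
                 value = 1, ciw = config$slope_ciw, n = format(res))
  }
  if (!is.null(config$c_statistic)) {
    res <- n_cstatistic(config$c_statistic, phi_sim,
                        precision_target("c_statistic", ciw = config$c_ciw,
                                         level = config$level),
                        n_max = config$n_max, search = "bisect")
    results[["c_statistic"]] <- res
    crit_rows[[length(crit_rows) + 1L]] <-
      data.frame(criterion = "c_statistic", threshold = NA_real_,
                 value = config$c_statistic, ciw = config$c_ciw,
                 n = format(res))
  }
  if (!is.null(config$snb_ciw)) {
    for (k in seq_along(config$thresholds)) {
      t <- config$thresholds[k]
      res <- n_snb(profiles[[k]], t,
                   precision_target("snb", ciw = config$snb_ciw,
                                    level = config$level))
      results[[paste0("snb@", t)]] <- res
      crit_rows[[length(crit_rows) + 1L]] <-
        data.frame(criterion = "snb", threshold = t,
                   value = round(res$assumptions$snb, 3),
                   ciw = config$snb_ciw, n = format(res))
    }
  }
  criteria_table <- if (length(crit_rows)) do.call(rbind, crit_rows) else NULL

  structure(list(measure_table = measure_table,
                 criteria_table = criteria_table,
                 results = results,
                 binding = binding_criterion(results),
                 profiles = profiles,
                 primary_ciw = primary,
                 config = config),
            class = "samplesize_report")
}

#' @export
print.samplesize_report <- function(x, ...) {
  cat("Minimum required sample size, N (events)\n\n")
  print(x$measure_table, row.names = FALSE)
  if (!is.null(x$criteria_table)) {
    cat("\nEstablished criteria\n")
    print(x$criteria_table, row.names = FALSE)
  }
  cat(sprintf("\nBinding criterion at primary CI width %g: %s, N = %d (%d events)\n",
              x$primary_ciw, x$binding$criterion, x$binding$n_required,
              x$binding$events_required))
  invisible(x)
}

#' Expected confidence intervals at a given sample size
#'
#' The reverse planning direction: given a candidate sample size, reports
#' each measure's anticipated estimate with its Wald confidence interval at
#' that size, flagging any interval wider than `max_ciw`.
#'
#' @param config a [plan_config()].
#' @param n total sample size (>= 1).
#' @param max_ciw width above which an interval is flagged (default 0.1).
#' @return data.frame with columns `threshold`, `measure`, `estimate`,
#'   `ci_low`, `ci_high`, `ciw`, `exceeds_max`.
#' @export
#' @examples
#' cfg <- plan_config(pop_spec(beta_risk(1.33, 1.75), n_sim = 1e5),
#'                    thresholds = c(0.1, 0.3))
#' run_expected_ciw(cfg, n = 949)
run_expected_ciw <- function(config, n, max_ciw = 0.1) {
  stopifnot(inherits(config, "plan_config"), n >= 1)
  sim <- simulate_population(config$pop)
  z <- z_level(config$level)
  rows <- list()
  for (t in config$thresholds) {
    prof <- true_performance(config$pop, t, population = sim)
    for (ms in config$measures) {
      v <- prof[[ms]]
      se <- if (ms == "f1") {
        se_f1(prof$ppv, prof$sensitivity, prof$specificity, prof$phi, n)
      } else {
        se_proportion(v, n * denominator_fraction(ms, prof))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        threshold = t, measure = ms, estimate = v,
        ci_low = v - z * se, ci_high = v + z * se, ciw = 2 * z * se,
        exceeds_max = 2 * z * se > max_ciw)
    }
  }
  do.call(rbind, rows)
}

#' Write a sample-size report to CSV or JSON
#'
#' @param report a `samplesize_report` from [run_min_samplesize()] or a
#'   data.frame from [run_expected_ciw()]/[expected_ciw_simulation()].
#' @param path output file; the extension (`.csv` or `.json`) selects the
#'   dialect unless `format` is given.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  tab <- if (inherits(report, "samplesize_report")) {
    report$measure_table
  } else {
    report
  }
  if (format == "csv") {
    utils::write.csv(tab, path, row.names = FALSE)
    if (inherits(report, "samplesize_report") &&
        !is.null(report$criteria_table)) {
      crit_path <- sub("(\\.csv)$", "_criteria\\1", path, ignore.case = TRUE)
      utils::write.csv(report$criteria_table, crit_path, row.names = FALSE)
    }
  } else {
    payload <- if (inherits(report, "samplesize_report")) {
      list(measures = report$measure_table,
           criteria = report$criteria_table,
           binding = list(criterion = report$binding$criterion,
                          n = report$binding$n_required,
                          events = report$binding$events_required))
    } else {
      report
    }
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(path)
}
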