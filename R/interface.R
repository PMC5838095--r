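#' Read a per-line screen table
#'
#' CSV schema (RFC 4180): columns `line_id`, `n_f1_females`, `n_f1_males`,
#' `neonates_per_female` (either a single count or a semicolon-joined list
#' of per-female counts), `control_mortality`; optional `region`.
#' Validation errors name the offending row and column.
#'
#' @param path path to the CSV file.
#' @return A list of [line_record()] objects.
#' @export
read_line_table <- function(path) {
  if (!file.exists(path)) stop_input("no such line table: ", path)
  header <- names(read.csv(path, nrows = 1L, check.names = FALSE))
  required <- c("line_id", "n_f1_females", "n_f1_males",
                "neonates_per_female", "control_mortality")
  missing_cols <- setdiff(required, header)
  if (length(missing_cols) > 0L) {
    stop_input("line table is missing column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(neonates_per_female = "character"))
  has_region <- "region" %in% names(tab)
  lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    k <- suppressWarnings(
      as.numeric(strsplit(as.character(row$neonates_per_female), ";",
                          fixed = TRUE)[[1L]]))
    if (anyNA(k) || any(k < 0)) {
      stop_input("row ", i, ", column neonates_per_female: ",
                 "must be non-negative numbers joined by ';'")
    }
    tryCatch(
      line_record(row$line_id, row$n_f1_females, row$n_f1_males, k,
                  row$control_mortality,
                  region = if (has_region) row$region else NA_character_),
      f2screen_input_error = function(e) {
        stop_input("row ", i, ": ", conditionMessage(e))
      }
    )
  })
}

#' Write a per-line screen table
#'
#' Inverse of [read_line_table()]: serialises per-female neonate counts as
#' a semicolon-joined field. Output is deterministic, so a
#' write-read-write round trip is byte-identical.
#'
#' @param lines a list of [line_record()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_line_table <- function(lines, path) {
  if (inherits(lines, "line_record")) lines <- list(lines)
  if (!is.list(lines) || length(lines) == 0L ||
      !all(vapply(lines, inherits, logical(1), "line_record"))) {
    stop_input("lines must be a non-empty list of line_record objects")
  }
  tab <- data.frame(
    line_id = vapply(lines, function(l) l$line_id, character(1)),
    region = vapply(lines, function(l) l$region, character(1)),
    n_f1_females = vapply(lines, function(l) l$n_f1_females, integer(1)),
    n_f1_males = vapply(lines, function(l) l$n_f1_males, integer(1)),
    neonates_per_female = vapply(
      lines, function(l) paste(format(l$neonates_per_female, trim = TRUE,
                                      scientific = FALSE), collapse = ";"),
      character(1)),
    control_mortality = vapply(lines, function(l) l$control_mortality,
                               numeric(1)),
    stringsAsFactors = FALSE
  )
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full F2-screen analysis pipeline
#'
#' Executes the analysis stages of the screen in order — allele-frequency
#' estimation, detection power, optional campaign comparison, optional
#' resistance-evolution forecast — and assembles a self-describing report.
#' All stochastic stages are driven by the seeds recorded in the report.
#'
#' @param config a list (or path to a YAML file) with blocks:
#' \describe{
#'   \item{estimate}{required: `positives`, `lines`; optional
#'     `alleles_per_line` (4), `level` (0.95), `method` ("beta_approx").}
#'   \item{detection}{optional: `table` (line-table CSV path) or `lines`
#'     (list of [line_record()]); optional `thresholds`.}
#'   \item{compare}{optional: `b_positives`, `b_lines`; optional
#'     `b_alleles_per_line`, `method`, `n_samples`, plus `power = list(
#'     mult_a, mult_b, n_reps, alpha)` for the replication simulation.}
#'   \item{evolution}{optional: arguments for [evolution_scenario()] with
#'     `adoption` inline or as a CSV path; `use_posterior = TRUE` forwards
#'     the estimation posterior as the initial frequency (stochastic mode),
#'     otherwise the posterior mean seeds a deterministic forecast.}
#'   \item{seed}{optional integer; per-stage seeds are derived from it.}
#' }
#' @return An object of class `analysis_report`.
#' @examples
#' rep <- run_full_pipeline(list(estimate = list(positives = 1, lines = 137)))
#' rep$estimate$expected_q
#' @export
run_full_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$estimate)) {
    stop_input("config must at least contain an 'estimate' block")
  }
  seed <- config$seed
  report <- list(
    schema_version = "1.0",
    provenance = list(
      package = "f2screen",
      package_version = as.character(packageVersion("f2screen")),
      r_version = as.character(getRversion()),
      created = format(Sys.time(), tz = "UTC", usetz = TRUE),
      seed = seed,
      config = config
    )
  )

  est <- config$estimate
  if (is.null(est$positives) || is.null(est$lines)) {
    stop_input("stage 'estimate': needs 'positives' and 'lines'")
  }
  post <- tryCatch(
    posterior_q(est$positives, est$lines,
                a = est$alleles_per_line %||% 4L,
                method = est$method %||% "beta_approx"),
    error = function(e) stop_state("stage 'estimate' failed: ",
                                   conditionMessage(e))
  )
  level <- est$level %||% 0.95
  ci <- credibility_interval(post, level)
  report$estimate <- list(
    s = post$s, n = post$n, alleles_per_line = post$a, method = post$method,
    expected_q = expected_q(post), level = level,
    ci_low = unname(ci[1L]), ci_high = unname(ci[2L])
  )

  if (!is.null(config$detection)) {
    det_cfg <- config$detection
    lines <- if (!is.null(det_cfg$table)) read_line_table(det_cfg$table)
             else det_cfg$lines
    if (is.null(lines)) {
      stop_input("stage 'detection': needs 'table' or 'lines'")
    }
    ds <- tryCatch(
      detection_summary(lines,
                        thresholds = unlist(det_cfg$thresholds %||%
                                              c(0.80, 0.95))),
      error = function(e) stop_state("stage 'detection' failed: ",
                                     conditionMessage(e))
    )
    report$detection <- list(
      n_lines = length(ds$per_line),
      experiment_wise = ds$experiment_wise,
      fraction_above = as.list(ds$fraction_above),
      fraction_below = as.list(ds$fraction_below)
    )
  }

  if (!is.null(config$compare)) {
    cmp <- config$compare
    if (is.null(cmp$b_positives) || is.null(cmp$b_lines)) {
      stop_input("stage 'compare': needs 'b_positives' and 'b_lines'")
    }
    post_b <- posterior_q(cmp$b_positives, cmp$b_lines,
                          a = cmp$b_alleles_per_line %||% post$a,
                          method = post$method)
    pe <- tryCatch(
      prob_equal(post, post_b, method = cmp$method %||% "quadrature",
                 n_samples = cmp$n_samples %||% 1e5,
                 seed = if (!is.null(seed)) seed + 1L),
      error = function(e) stop_state("stage 'compare' failed: ",
                                     conditionMessage(e))
    )
    report$comparison <- list(
      b_s = post_b$s, b_n = post_b$n, p = pe$p, p_a_less = pe$p_a_less,
      p_a_greater = pe$p_a_greater, method = pe$method,
      seed = if (!is.null(seed)) seed + 1L
    )
    if (!is.null(cmp$power)) {
      pw <- cmp$power
      rp <- replication_power(post, post_b,
                              n_multiplier_a = pw$mult_a %||% 1,
                              n_multiplier_b = pw$mult_b %||% 1,
                              n_reps = pw$n_reps %||% 10000L,
                              alpha = pw$alpha %||% 0.05,
                              seed = if (!is.null(seed)) seed + 2L)
      report$comparison$power <- list(
        power = rp$power, se = rp$se, n_reps = rp$n_reps, alpha = rp$alpha,
        multipliers = as.list(rp$multipliers),
        seed = if (!is.null(seed)) seed + 2L
      )
    }
  }

  if (!is.null(config$evolution)) {
    ev <- config$evolution
    if (is.null(ev$adoption)) stop_input("stage 'evolution': needs 'adoption'")
    use_post <- isTRUE(ev$use_posterior)
    adoption <- ev$adoption
    if (is.list(adoption) && !is.data.frame(adoption)) {
      adoption <- data.frame(year = as.integer(names(adoption)),
                             proportion = unlist(adoption, use.names = FALSE))
    }
    scen <- tryCatch(
      evolution_scenario(
        initial_q = if (use_post) post else expected_q(post),
        adoption = adoption,
        generations_per_year = ev$generations_per_year %||% 2L,
        bt_survival = unlist(ev$bt_survival %||%
                               c(ss = 0.01, rs = 0.02, rr = 1)),
        refuge_survival = unlist(ev$refuge_survival %||%
                                   c(ss = 1, rs = 1, rr = 1)),
        threshold_q = ev$threshold_q %||% 0.5,
        horizon_years = ev$horizon_years %||% 100L,
        start_year = ev$start_year,
        n_runs = ev$n_runs %||% 10000L,
        population_size = ev$population_size,
        seed = if (!is.null(seed)) seed + 3L
      ),
      error = function(e) stop_state("stage 'evolution' failed: ",
                                     conditionMessage(e))
    )
    report$evolution <- if (use_post) {
      st <- run_stochastic(scen, init = ev$init %||% "sample")
      list(mode = "stochastic", init = st$init, n_runs = st$n_runs,
           fraction_reached = st$fraction_reached,
           mean_final_q = st$mean_final_q,
           final_q_quantiles = as.list(st$final_q_quantiles),
           seed = scen$seed)
    } else {
      fc <- years_to_resistance(scen)
      list(mode = "deterministic", initial_q = expected_q(post),
           years_to_resistance = if (fc$reached) fc$years else NA,
           reached = fc$reached, final_q = fc$final_q,
           threshold_q = fc$threshold_q)
    }
  }

  structure(report, class = "analysis_report")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.analysis_report <- function(x, ...) {
  cat("F2 screen analysis report (schema", x$schema_version, ")\n")
  e <- x$estimate
  cat(sprintf("  E(q) = %.4f, %d%% CI (%.4f, %.4f)  [S = %d, N = %d, %s]\n",
              e$expected_q, round(100 * e$level), e$ci_low, e$ci_high,
              e$s, e$n, e$method))
  if (!is.null(x$detection)) {
    cat(sprintf("  experiment-wise detection: %.1f%% over %d lines\n",
                100 * x$detection$experiment_wise, x$detection$n_lines))
  }
  if (!is.null(x$comparison)) {
    cat(sprintf("  comparison vs (S = %d, N = %d): p = %.4f\n",
                x$comparison$b_s, x$comparison$b_n, x$comparison$p))
  }
  if (!is.null(x$evolution)) {
    if (identical(x$evolution$mode, "deterministic")) {
      cat(sprintf("  evolution: %s\n",
                  if (x$evolution$reached)
                    sprintf("threshold reached after %d years",
                            x$evolution$years_to_resistance)
                  else sprintf("threshold not reached (final q = %.4g)",
                               x$evolution$final_q)))
    } else {
      cat(sprintf("  evolution (stochastic, %d runs): %.1f%% reached threshold\n",
                  x$evolution$n_runs, 100 * x$evolution$fraction_reached))
    }
  }
  invisible(x)
}

#' Serialise an analysis report to JSON
#'
#' Probabilities are written at full precision; rounding to 4 decimal
#' places happens only in the printed human-readable summary.
#'
#' @param report an `analysis_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "analysis_report")) {
    stop_input("report must be an analysis_report")
  }
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
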