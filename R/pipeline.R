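#' Write a cohort table to CSV
#'
#' Writes the standard cohort schema: `patient_id, age, sepsis, icu_death,
#' icu_los, overall_event, followup_time`, then one column per panel marker
#' (exact miR names). Booleans are encoded 0/1, times are in days, the
#' decimal separator is a point, line endings are LF, encoding UTF-8.
#'
#' @param cohort Cohort data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cols <- cohort_columns()
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols)) {
    stop_schema(sprintf("cohort is missing column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  out <- cohort[, cols, drop = FALSE]
  for (b in c("sepsis", "icu_death", "overall_event")) {
    out[[b]] <- as.integer(as.logical(out[[b]]))
  }
  con <- file(path, open = "wb")  # binary: force LF on every platform
  on.exit(close(con))
  writeLines(paste(cols, collapse = ","), con, sep = "\n", useBytes = TRUE)
  if (nrow(out)) {
    body <- do.call(paste, c(lapply(out, function(col) {
      if (is.numeric(col)) format(col, digits = 15, trim = TRUE,
                                   scientific = FALSE)
      else as.character(col)
    }), sep = ","))
    writeLines(body, con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' Read and validate a cohort CSV
#'
#' Reads the schema written by [write_cohort()]. Every validation failure
#' names the offending row (1-based data row) and field: missing columns,
#' non-0/1 booleans, non-positive marker levels or follow-up times, and
#' ICU deaths not flagged as overall events are schema errors.
#'
#' @param path CSV path.
#' @return A validated cohort data frame of class `mirna_cohort`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_schema(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_columns(), names(raw))
  if (length(missing_cols)) {
    stop_schema(sprintf("missing column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  raw <- raw[, cohort_columns(), drop = FALSE]

  fail <- function(row, msg) {
    stop_schema(sprintf("row %d: %s", row, msg))
  }
  num_fields <- c("age", "icu_los", "followup_time", mirna_panel())
  for (f in num_fields) {
    v <- suppressWarnings(as.numeric(raw[[f]]))
    bad <- which(is.na(v))
    if (length(bad)) fail(bad[1], sprintf("field '%s' is not numeric", f))
    raw[[f]] <- v
  }
  for (b in c("sepsis", "icu_death", "overall_event")) {
    v <- raw[[b]]
    bad <- which(!(v %in% c(0, 1, TRUE, FALSE)))
    if (length(bad)) fail(bad[1], sprintf("field '%s' must be 0/1", b))
    raw[[b]] <- as.logical(as.integer(v))
  }
  for (m in mirna_panel()) {
    bad <- which(raw[[m]] <= 0)
    if (length(bad)) {
      fail(bad[1], sprintf("field '%s' must be a positive level (AU)", m))
    }
  }
  bad <- which(raw$followup_time <= 0)
  if (length(bad)) fail(bad[1], "field 'followup_time' must be > 0")
  bad <- which(raw$icu_los <= 0)
  if (length(bad)) fail(bad[1], "field 'icu_los' must be > 0")
  bad <- which(raw$icu_death & !raw$overall_event)
  if (length(bad)) {
    fail(bad[1], "overall_event=0 but icu_death=1 (ICU death implies overall event)")
  }
  class(raw) <- c("mirna_cohort", "data.frame")
  raw
}

# Pearson chi-square test of independence on a 2-way count table; small
# self-contained helper so the manifest never depends on warning behaviour
# of stats::chisq.test with sparse strata.
chisq_independence <- function(tab) {
  tab <- as.matrix(tab)
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  tab <- tab[keep_r, keep_c, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    return(list(chi_square = 0, df = 0L, p_value = 1))
  }
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi <- sum((tab - exp_tab)^2 / exp_tab)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(chi_square = chi, df = df,
       p_value = stats::pchisq(chi, df, lower.tail = FALSE))
}

endpoint_time_event <- function(cohort, outcome) {
  # ICU analyses run on days in ICU / ICU death; overall analyses on total
  # follow-up time / death during observation
  if (outcome == "icu_death") {
    list(times = cohort$icu_los, events = as.logical(cohort$icu_death))
  } else {
    list(times = cohort$followup_time,
         events = as.logical(cohort$overall_event))
  }
}

pipeline_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[mirscore] ", fmt), ...))
}

analyse_definition <- function(cohort, definition, outcome, grouping,
                               verbose) {
  scores <- score_cohort(definition, cohort)
  grouping <- grouping %||% default_grouping(definition)
  # extend the top stratum if derived definitions have more items than the
  # supplied grouping anticipates
  mx <- nrow(definition$items)
  if (max(unlist(grouping)) < mx) {
    grouping[[length(grouping)]] <-
      sort(unique(c(grouping[[length(grouping)]],
                    seq(max(unlist(grouping)) + 1L, mx))))
  }
  te <- endpoint_time_event(cohort, outcome)
  strata_tab <- stratum_mortality(scores, te$events, grouping)

  labels <- vapply(grouping, function(set) {
    paste0("{", paste(sort(set), collapse = ","), "}")
  }, character(1))
  stratum_of <- labels[vapply(scores, function(s) {
    which(vapply(grouping, function(set) s %in% set, logical(1)))[1]
  }, numeric(1))]

  present <- unique(stratum_of)
  lr <- if (length(present) >= 2L) {
    logrank_test(te$times, te$events, stratum_of)
  } else NULL

  km <- lapply(split(seq_along(scores), stratum_of), function(idx) {
    fit <- km_fit(te$times[idx], te$events[idx])
    list(event_times = fit$event_times, survival = fit$survival,
         at_risk = fit$at_risk, events = fit$events,
         greenwood_var = fit$greenwood_var, n = fit$n)
  })

  sepsis_tab <- table(factor(cohort$sepsis, levels = c(FALSE, TRUE),
                             labels = c("non_sepsis", "sepsis")),
                      factor(stratum_of, levels = labels))
  contingency <- chisq_independence(sepsis_tab)
  contingency$counts <- as.data.frame.matrix(sepsis_tab)

  pipeline_log(verbose, "  %s: cut-offs {%s}; strata %s; log-rank p = %s",
               definition$name,
               paste(sprintf("%s %.3g", definition$items$marker,
                             definition$items$cutoff), collapse = ", "),
               paste(strata_tab$n, collapse = "/"),
               if (is.null(lr)) "NA" else format(lr$p_value, digits = 3))

  list(definition = list(name = definition$name,
                         includes_age = definition$includes_age,
                         items = definition$items),
       scores = scores,
       grouping = labels,
       strata = as.data.frame(strata_tab),
       logrank = if (is.null(lr)) NULL else
         list(chi_square = lr$chi_square, df = lr$df, p_value = lr$p_value,
              observed = as.list(lr$observed),
              expected = as.list(lr$expected)),
       km = km,
       sepsis_contingency = contingency)
}

#' Run the full scoring pipeline
#'
#' Orchestrates simulate (unless a cohort is supplied) -> per-marker
#' contrast comparisons -> marker selection -> Youden cut-off derivation ->
#' score construction (each endpoint with and without the age item) ->
#' stratified mortality tables -> Kaplan-Meier / log-rank evaluation, and
#' assembles a deterministic run manifest. Any stage hitting degenerate
#' input aborts with the stage name.
#'
#' @param config A [sim_config()]; used to simulate when `cohort` is `NULL`
#'   and recorded (hashed) in the manifest.
#' @param cohort Optional cohort data frame; `NULL` simulates from `config`.
#' @param control Optional control cohort (same schema) enabling the
#'   patients-vs-control contrast.
#' @param alpha Significance level for marker selection.
#' @param groupings Optional named list (`icu_survival`,
#'   `icu_survival_age`, `overall_survival`, `overall_survival_age`) of
#'   stratum groupings; defaults per [default_grouping()].
#' @param out_dir Optional output directory for the manifest and CSV/JSON
#'   artifacts.
#' @param verbose Log stages to stderr?
#' @return The run manifest (a nested list), invisibly carrying the cohort
#'   as attribute `"cohort"`.
#' @export
run_pipeline <- function(config = default_study_config(), cohort = NULL,
                         control = NULL, alpha = 0.05, groupings = NULL,
                         out_dir = NULL, verbose = TRUE) {
  config <- validate_sim_config(config)
  t0 <- proc.time()[["elapsed"]]
  if (is.null(cohort)) {
    cohort <- simulate_cohort(config)
    pipeline_log(verbose, "simulate: %d patients (seed %d)", nrow(cohort),
                 config$seed)
  } else {
    pipeline_log(verbose, "cohort supplied: %d patients", nrow(cohort))
  }
  if (nrow(cohort) == 0L) stop_degenerate("stage simulate: empty cohort")

  # stage: per-contrast comparison tables (the Table-3 analogue)
  contrasts <- list()
  stage_wrap <- function(stage, expr) {
    tryCatch(expr, mirscore_degenerate_error = function(e) {
      stop_degenerate(sprintf(
        "stage %s: %s (check that both outcome classes are present)",
        stage, conditionMessage(e)))
    })
  }
  sepsis <- as.logical(cohort$sepsis)
  if (any(sepsis) && !all(sepsis)) {
    rows <- lapply(mirna_panel(), function(m) {
      mw <- mann_whitney_u(cohort[[m]][!sepsis], cohort[[m]][sepsis],
                           alpha = alpha)
      data.frame(marker = m, statistic_u = mw$statistic_u,
                 p_value = mw$p_value, direction = mw$direction)
    })
    contrasts$sepsis_vs_nonsepsis <- do.call(rbind, rows)
  }
  contrasts$icu_death <- stage_wrap("compare",
    compare_markers(cohort, "icu_death", alpha))
  contrasts$overall_death <- stage_wrap("compare",
    compare_markers(cohort, "overall_event", alpha))
  if (!is.null(control)) {
    rows <- lapply(mirna_panel(), function(m) {
      mw <- mann_whitney_u(control[[m]], cohort[[m]], alpha = alpha)
      data.frame(marker = m, statistic_u = mw$statistic_u,
                 p_value = mw$p_value, direction = mw$direction)
    })
    contrasts$patients_vs_control <- do.call(rbind, rows)
  }
  pipeline_log(verbose, "compare: %d contrast tables", length(contrasts))

  endpoints <- c(icu_survival = "icu_death",
                 overall_survival = "overall_event")
  analyses <- list()
  selections <- list()
  for (nm in names(endpoints)) {
    outcome <- endpoints[[nm]]
    sel <- stage_wrap("select_markers",
                      select_markers(cohort, outcome, alpha))
    if (nrow(sel) == 0L) {
      stop_degenerate(sprintf(
        "stage select_markers: no marker significant at alpha = %g for %s; supply a larger cohort or raise alpha",
        alpha, outcome))
    }
    selections[[nm]] <- sel
    pipeline_log(verbose, "select (%s): %s", outcome,
                 paste(sel$marker, collapse = ", "))
    for (with_age in c(FALSE, TRUE)) {
      key <- if (with_age) paste0(nm, "_age") else nm
      def <- stage_wrap("build_score",
        build_score(cohort, sel, outcome, include_age = with_age,
                    name = key))
      analyses[[key]] <- stage_wrap("survive",
        analyse_definition(cohort, def, outcome,
                           groupings[[key]], verbose))
    }
  }

  manifest <- list(
    tool = "mirscore",
    version = as.character(utils::packageVersion("mirscore")),
    seed = config$seed,
    config_hash = config_hash(config),
    alpha = alpha,
    n_patients = nrow(cohort),
    contrast_tests = contrasts,
    selections = selections,
    analyses = analyses
  )
  pipeline_log(verbose, "done in %.2f s",
               proc.time()[["elapsed"]] - t0)

  if (!is.null(out_dir)) {
    write_pipeline_artifacts(manifest, cohort, config, out_dir)
    pipeline_log(verbose, "artifacts written to %s", out_dir)
  }
  attr(manifest, "cohort") <- cohort
  invisible(manifest)
}

write_pipeline_artifacts <- function(manifest, cohort, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  m <- manifest
  attr(m, "cohort") <- NULL
  jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  config_to_json(config, file.path(out_dir, "config.json"))
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))
  for (ct in names(manifest$contrast_tests)) {
    utils::write.csv(manifest$contrast_tests[[ct]],
                     file.path(out_dir, sprintf("contrast_%s.csv", ct)),
                     row.names = FALSE)
  }
  summary_lines <- character(0)
  for (key in names(manifest$analyses)) {
    an <- manifest$analyses[[key]]
    utils::write.csv(an$strata,
                     file.path(out_dir, sprintf("strata_%s.csv", key)),
                     row.names = FALSE)
    for (s in names(an$km)) {
      kmc <- an$km[[s]]
      steps <- data.frame(time = c(0, kmc$event_times),
                          survival = c(1, kmc$survival))
      safe <- gsub("[^0-9A-Za-z]+", "_", paste(key, s))
      utils::write.csv(steps,
                       file.path(out_dir, sprintf("km_%s.csv", safe)),
                       row.names = FALSE)
    }
    summary_lines <- c(
      summary_lines, sprintf("== %s ==", key),
      utils::capture.output(print(an$strata, row.names = FALSE)),
      sprintf("log-rank: chi2 = %s, df = %s, p = %s",
              format(an$logrank$chi_square %||% NA, digits = 4),
              an$logrank$df %||% NA,
              format(an$logrank$p_value %||% NA, digits = 4)),
      sprintf("sepsis contingency: chi2 = %.4g, df = %d, p = %.4g",
              an$sepsis_contingency$chi_square,
              an$sepsis_contingency$df,
              an$sepsis_contingency$p_value),
      "")
  }
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}
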