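outcome_column <- function(outcome) {
  match.arg(outcome, c("icu_death", "overall_event"))
}

score_direction_to_roc <- function(direction) {
  switch(direction,
         high_scores = "high_is_positive",
         low_scores = "low_is_positive",
         stop_input(sprintf("unknown score direction '%s'", direction)))
}

#' Per-marker two-group comparison table
#'
#' Runs the rank-sum comparison of every panel marker between patients with
#' and without the outcome (non-survivors vs survivors) — the in-cohort
#' analogue of the published dysregulation table.
#'
#' @param cohort A cohort data frame (see [simulate_cohort()] /
#'   [read_cohort()]).
#' @param outcome `"icu_death"` or `"overall_event"`.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Data frame with one row per marker: `marker`, `statistic_u`,
#'   `p_value`, `median_survivor`, `median_nonsurvivor`, `direction`
#'   (median shift in non-survivors when `p < alpha`, else `"none"`).
#' @export
compare_markers <- function(cohort, outcome = c("icu_death", "overall_event"),
                            alpha = 0.05) {
  outcome <- outcome_column(outcome[1])
  out <- as.logical(cohort[[outcome]])
  if (!any(out) || all(out)) {
    stop_degenerate(sprintf("cohort has a single %s class", outcome))
  }
  rows <- lapply(mirna_panel(), function(m) {
    mw <- mann_whitney_u(cohort[[m]][!out], cohort[[m]][out], alpha = alpha)
    data.frame(marker = m, statistic_u = mw$statistic_u,
               p_value = mw$p_value, median_survivor = mw$median1,
               median_nonsurvivor = mw$median2, direction = mw$direction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select significantly dysregulated markers for an outcome
#'
#' Markers whose rank-sum comparison between non-survivors and survivors
#' reaches `p < alpha` are returned with the direction of their median
#' shift in non-survivors (`up` -> `high_scores`, `down` -> `low_scores`).
#'
#' @inheritParams compare_markers
#' @return Data frame with columns `marker`, `direction`
#'   (`"high_scores"`/`"low_scores"`) and `p_value`; zero rows if nothing
#'   is significant.
#' @export
select_markers <- function(cohort, outcome = c("icu_death", "overall_event"),
                           alpha = 0.05) {
  tab <- compare_markers(cohort, outcome, alpha)
  keep <- tab$p_value < alpha & tab$direction != "none"
  data.frame(
    marker = tab$marker[keep],
    direction = ifelse(tab$direction[keep] == "up", "high_scores",
                       "low_scores"),
    p_value = tab$p_value[keep],
    stringsAsFactors = FALSE
  )
}

new_score_definition <- function(name, items, includes_age,
                                 cutpoints = NULL) {
  structure(
    list(name = name, items = items, includes_age = includes_age,
         cutpoints = cutpoints),
    class = "score_definition"
  )
}

#' Build an additive dichotomized score definition
#'
#' Derives one Youden-index cut-off per selected marker against the outcome
#' (on the same cohort the score will be applied to, as in the original
#' analysis) and assembles them into an additive score: one point per
#' marker strictly above (`high_scores`) or strictly below (`low_scores`)
#' its cut-off. With `include_age = TRUE` an `AGE` item with its own Youden
#' cut-off (higher age scores) is appended.
#'
#' @param cohort Cohort data frame.
#' @param selected Data frame with `marker` and `direction` columns, as
#'   returned by [select_markers()].
#' @param outcome `"icu_death"` or `"overall_event"`.
#' @param include_age Append the age item?
#' @param name Optional score name; defaults to `icu_survival` /
#'   `overall_survival` according to the outcome.
#' @return A `score_definition`: `name`, `items` (data frame of `marker`,
#'   `cutoff`, `direction`), `includes_age`, and the full
#'   `cutpoint_result` list.
#' @export
build_score <- function(cohort, selected,
                        outcome = c("icu_death", "overall_event"),
                        include_age = FALSE, name = NULL) {
  outcome <- outcome_column(outcome[1])
  if (is.null(selected) || nrow(as.data.frame(selected)) == 0L) {
    stop_input("selected marker list must be non-empty")
  }
  selected <- as.data.frame(selected)
  out <- as.logical(cohort[[outcome]])
  cps <- list()
  for (i in seq_len(nrow(selected))) {
    m <- selected$marker[i]
    if (!m %in% names(cohort)) {
      stop_input(sprintf("marker '%s' not present in cohort", m))
    }
    cps[[m]] <- youden_cutpoint(
      cohort[[m]], out,
      direction = score_direction_to_roc(selected$direction[i]),
      marker = m
    )
  }
  items <- data.frame(
    marker = selected$marker,
    cutoff = vapply(cps, function(cp) cp$cutoff, numeric(1)),
    direction = selected$direction,
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (include_age) {
    cp_age <- youden_cutpoint(cohort$age, out,
                              direction = "high_is_positive",
                              marker = "AGE")
    cps[["AGE"]] <- cp_age
    items <- rbind(items, data.frame(marker = "AGE", cutoff = cp_age$cutoff,
                                     direction = "high_scores"))
  }
  if (is.null(name)) {
    name <- if (outcome == "icu_death") "icu_survival" else "overall_survival"
  }
  new_score_definition(name, items, include_age, cps)
}

#' Reference overall-survival score definition
#'
#' The published two-item overall score: one point if miR-133a exceeds
#' 4.3 AU, one point if miR-150 falls below 22.7 AU, and (optionally) one
#' point if age exceeds 68.5 years.
#'
#' @param include_age Append the age item (cut-off 68.5 years)?
#' @return A `score_definition`.
#' @export
reference_overall_definition <- function(include_age = TRUE) {
  items <- data.frame(
    marker = c("miR-133a", "miR-150"),
    cutoff = c(4.3, 22.7),
    direction = c("high_scores", "low_scores"),
    stringsAsFactors = FALSE
  )
  if (include_age) {
    items <- rbind(items, data.frame(marker = "AGE", cutoff = 68.5,
                                     direction = "high_scores"))
  }
  new_score_definition("overall_survival", items, include_age)
}

#' Reference ICU-survival score definition
#'
#' The three-item ICU score (miR-133a up, miR-143 down, miR-223 down) with
#' configuration-supplied miRNA cut-offs — the original analysis reports
#' them only graphically — and the published age cut-off of 72.5 years.
#'
#' @param cutoffs Named numeric vector supplying cut-offs for `miR-133a`,
#'   `miR-143` and `miR-223` (AU).
#' @param include_age Append the age item?
#' @param age_cutoff Age cut-off in years (published: 72.5).
#' @return A `score_definition`.
#' @export
reference_icu_definition <- function(cutoffs, include_age = TRUE,
                                     age_cutoff = 72.5) {
  need <- c("miR-133a", "miR-143", "miR-223")
  if (!all(need %in% names(cutoffs))) {
    stop_input(sprintf("cutoffs must name %s", paste(need, collapse = ", ")))
  }
  items <- data.frame(
    marker = need,
    cutoff = as.numeric(cutoffs[need]),
    direction = c("high_scores", "low_scores", "low_scores"),
    stringsAsFactors = FALSE
  )
  if (include_age) {
    items <- rbind(items, data.frame(marker = "AGE", cutoff = age_cutoff,
                                     direction = "high_scores"))
  }
  new_score_definition("icu_survival", items, include_age)
}

#' Apply a score definition to a single patient record
#'
#' One point per item satisfied with strict inequality: `value > cutoff`
#' for `high_scores` items, `value < cutoff` for `low_scores` items; a
#' value exactly at the cut-off never scores. The `AGE` item reads the
#' record's `age` field.
#'
#' @param definition A `score_definition`.
#' @param record Named list or one-row data frame carrying all markers
#'   named by the definition (and `age` if the definition includes it).
#' @return Integer score in `[0, number of items]`.
#' @examples
#' apply_score(reference_overall_definition(),
#'             list(`miR-133a` = 5, `miR-150` = 10, age = 70))
#' @export
apply_score <- function(definition, record) {
  if (!inherits(definition, "score_definition")) {
    stop_input("definition must be a score_definition")
  }
  record <- as.list(record)
  pts <- 0L
  for (i in seq_len(nrow(definition$items))) {
    m <- definition$items$marker[i]
    field <- if (m == "AGE") "age" else m
    v <- record[[field]]
    if (is.null(v) || is.na(v)) {
      stop_input(sprintf("record is missing '%s'", field))
    }
    hit <- if (definition$items$direction[i] == "high_scores") {
      v > definition$items$cutoff[i]
    } else {
      v < definition$items$cutoff[i]
    }
    pts <- pts + as.integer(hit)
  }
  pts
}

#' Apply a score definition to a whole cohort
#'
#' @inheritParams apply_score
#' @param cohort Cohort data frame.
#' @return Integer vector of scores, one per row of `cohort`.
#' @export
score_cohort <- function(definition, cohort) {
  if (!inherits(definition, "score_definition")) {
    stop_input("definition must be a score_definition")
  }
  pts <- integer(nrow(cohort))
  for (i in seq_len(nrow(definition$items))) {
    m <- definition$items$marker[i]
    field <- if (m == "AGE") "age" else m
    if (!field %in% names(cohort)) {
      stop_input(sprintf("cohort is missing column '%s'", field))
    }
    v <- cohort[[field]]
    hit <- if (definition$items$direction[i] == "high_scores") {
      v > definition$items$cutoff[i]
    } else {
      v < definition$items$cutoff[i]
    }
    pts <- pts + as.integer(hit)
  }
  pts
}

#' Mortality by score stratum
#'
#' Partitions patients by score value sets and tabulates deaths, with the
#' mortality percentage rounded half-up to one decimal (the convention of
#' the published tables).
#'
#' @param scores Integer scores.
#' @param deaths Logical death indicators, aligned with `scores`.
#' @param grouping List of numeric vectors of score values; the sets must
#'   be disjoint and cover every observed score.
#' @return Data frame of class `stratum_table` with `stratum` (label), `n`,
#'   `deaths`, `mortality_percent` (NA for strata with `n = 0`).
#' @examples
#' stratum_mortality(c(0, 0, 1, 3, 3, 3),
#'                   c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE),
#'                   list(0, c(1, 2), 3))
#' @export
stratum_mortality <- function(scores, deaths, grouping) {
  if (length(scores) != length(deaths)) {
    stop_input("scores and deaths must have equal length")
  }
  if (!is.list(grouping) || length(grouping) == 0L) {
    stop_input("grouping must be a non-empty list of score-value sets")
  }
  all_vals <- unlist(grouping)
  if (anyDuplicated(all_vals)) {
    stop_input("grouping sets must be disjoint")
  }
  outside <- setdiff(unique(scores), all_vals)
  if (length(outside)) {
    stop_input(sprintf("observed score(s) outside grouping: %s",
                       paste(sort(outside), collapse = ", ")))
  }
  deaths <- as.logical(deaths)
  rows <- lapply(grouping, function(set) {
    in_set <- scores %in% set
    n <- sum(in_set)
    d <- sum(deaths[in_set])
    data.frame(
      stratum = paste0("{", paste(sort(set), collapse = ","), "}"),
      n = n, deaths = d,
      mortality_percent = if (n > 0) round_half_up(100 * d / n, 1L)
                          else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  class(tab) <- c("stratum_table", "data.frame")
  tab
}

#' Default stratum grouping for a score definition
#'
#' Extremes kept apart, middle pooled: `{0}`, `{1, ..., max-1}`, `{max}`
#' (for the three-item ICU score this is the published `{0}`, `{1,2}`,
#' `{3}` pooling; a two-item score keeps each value separate).
#'
#' @param definition A `score_definition`.
#' @return List of numeric vectors usable as `grouping`.
#' @export
default_grouping <- function(definition) {
  m <- nrow(definition$items)
  if (m < 2L) return(list(0, seq_len(m)))
  if (m == 2L) return(list(0, 1, 2))
  list(0, seq_len(m - 1L), m)
}

#' Serialize / restore a score definition as JSON
#'
#' @param definition A `score_definition`.
#' @param path Output file; `NULL` returns the JSON string.
#' @return JSON string, or a `score_definition` for `score_from_json`.
#' @export
score_to_json <- function(definition, path = NULL) {
  x <- list(name = definition$name,
            includes_age = definition$includes_age,
            items = definition$items)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(as.character(js))
}

#' @rdname score_to_json
#' @param json JSON string (used when `path` is `NULL`).
#' @export
score_from_json <- function(path = NULL, json = NULL) {
  x <- if (!is.null(path)) jsonlite::fromJSON(path)
       else jsonlite::fromJSON(json)
  new_score_definition(x$name, as.data.frame(x$items), x$includes_age)
}
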