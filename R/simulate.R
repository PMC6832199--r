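# Draw layout per patient (15 uniforms, consumed patient-major so that
# cohorts of different sizes generated from the same seed share a prefix):
#   1 sepsis  2 icu death  3 late death  4 age  5 shared factor
#   6-12 marker noise (panel order)  13 icu los  14 death time  15 censoring
N_DRAWS_PER_PATIENT <- 15L

#' Simulate a synthetic ICU cohort
#'
#' Generates `config$n_patients` patient records with the statistical
#' structure the scoring workflow assumes. Outcome flags are Bernoulli with
#' the configured probabilities; marker levels are log-normal with log-mean
#' `log_mu + ` the sum of the applicable contrast shifts (sepsis shift for
#' septic patients, ICU-death shift for ICU deaths, overall-death shift for
#' late deaths, plus the patients-vs-control shift unless
#' `control = TRUE`); all seven log-levels share a patient-level factor
#' carrying `marker_correlation` of their variance. Ages are truncated
#' normal with outcome-dependent mean. ICU length of stay is exponential;
#' late deaths occur at `icu_los` plus a truncated-exponential residual
#' time; survivors are censored at `icu_los` plus an exponential
#' loss-to-follow-up time, truncated at the administrative horizon.
#'
#' The generator is deterministic given `config` (including its seed), and
#' all draws for patient `i` precede those for patient `i + 1`.
#'
#' @param config A [sim_config()] object.
#' @param control If `TRUE`, simulate a healthy-control-like panel: the
#'   `patients_vs_control` shift and all outcome/sepsis shifts are omitted
#'   (outcome columns are still emitted so the schema is unchanged).
#' @return A `data.frame` of class `mirna_cohort` with columns
#'   `patient_id`, `age`, `sepsis`, `icu_death`, `icu_los`,
#'   `overall_event`, `followup_time`, then the seven marker columns (AU).
#' @examples
#' cohort <- simulate_cohort(default_study_config(seed = 7))
#' nrow(cohort)
#' @export
simulate_cohort <- function(config, control = FALSE) {
  config <- validate_sim_config(config)
  n <- config$n_patients
  markers <- mirna_panel()

  if (n == 0L) {
    empty <- data.frame(
      patient_id = character(0), age = numeric(0), sepsis = logical(0),
      icu_death = logical(0), icu_los = numeric(0),
      overall_event = logical(0), followup_time = numeric(0),
      check.names = FALSE
    )
    for (m in markers) empty[[m]] <- numeric(0)
    class(empty) <- c("mirna_cohort", "data.frame")
    return(empty)
  }

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)
  u <- matrix(stats::runif(N_DRAWS_PER_PATIENT * n),
              nrow = N_DRAWS_PER_PATIENT)

  sepsis <- u[1L, ] < config$sepsis_fraction
  icu_death <- u[2L, ] < config$p_icu_death
  late_death <- !icu_death &
    (u[3L, ] < config$p_late_death_given_icu_survival)
  overall_event <- icu_death | late_death

  mu_age <- ifelse(overall_event, config$age_mean_nonsurvivor,
                   config$age_mean_survivor)
  plo <- stats::pnorm(18, mu_age, config$age_sd)
  phi <- stats::pnorm(95, mu_age, config$age_sd)
  age <- stats::qnorm(plo + u[4L, ] * (phi - plo), mu_age, config$age_sd)

  factor_z <- stats::qnorm(u[5L, ])
  lambda <- sqrt(config$marker_correlation)
  resid_scale <- sqrt(1 - config$marker_correlation)

  em <- config$effect_matrix
  levels <- matrix(NA_real_, nrow = n, ncol = length(markers),
                   dimnames = list(NULL, markers))
  for (k in seq_along(markers)) {
    m <- markers[k]
    pm <- config$marker_params[[m]]
    shift <- if (control) 0 else {
      em[m, "patients_vs_control"] +
        sepsis * em[m, "sepsis_vs_nonsepsis"] +
        icu_death * em[m, "icu_death"] +
        late_death * em[m, "overall_death"]
    }
    eps <- stats::qnorm(u[5L + k, ])
    levels[, k] <- exp(pm[1] + shift +
                         pm[2] * (lambda * factor_z + resid_scale * eps))
  }

  icu_los <- stats::qexp(u[13L, ], rate = config$icu_los_rate)
  fmax <- config$followup_max_days

  followup <- numeric(n)
  # ICU deaths: death at the end of the ICU stay
  followup[icu_death] <- icu_los[icu_death]
  # late deaths: residual time drawn from an exponential truncated at the
  # remaining window, so the configured late-death probability is exact
  if (any(late_death)) {
    w <- pmax(fmax - icu_los[late_death], 1e-8)
    pw <- stats::pexp(w, rate = config$late_death_rate)
    followup[late_death] <- icu_los[late_death] +
      stats::qexp(u[14L, late_death] * pw, rate = config$late_death_rate)
  }
  surv <- !overall_event
  if (any(surv)) {
    cens <- icu_los[surv] +
      stats::qexp(u[15L, surv], rate = config$censor_rate)
    followup[surv] <- pmin(cens, fmax)
  }

  cohort <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    age = age,
    sepsis = sepsis,
    icu_death = icu_death,
    icu_los = icu_los,
    overall_event = overall_event,
    followup_time = followup,
    check.names = FALSE
  )
  for (m in markers) cohort[[m]] <- levels[, m]
  class(cohort) <- c("mirna_cohort", "data.frame")
  cohort
}
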