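#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf(
    "Youden cut-point%s: %.4g (%s)\n  J = %.3f (sens %.3f, spec %.3f), AUC = %.3f\n",
    if (is.na(x$marker)) "" else paste0(" for ", x$marker),
    x$cutoff, x$direction, x$youden_j, x$sensitivity, x$specificity,
    x$auc))
  invisible(x)
}

#' @export
print.score_definition <- function(x, ...) {
  cat(sprintf("Score '%s' (%d items%s):\n", x$name, nrow(x$items),
              if (x$includes_age) ", incl. age" else ""))
  for (i in seq_len(nrow(x$items))) {
    op <- if (x$items$direction[i] == "high_scores") ">" else "<"
    cat(sprintf("  +1 if %s %s %.4g\n", x$items$marker[i], op,
                x$items$cutoff[i]))
  }
  invisible(x)
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon rank-sum (%s): U = %.4g, n = %d/%d, p = %.4g, direction: %s\n",
    x$method, x$statistic_u, x$n1, x$n2, x$p_value, x$direction))
  invisible(x)
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d event times\n", x$n,
              length(x$event_times)))
  if (length(x$event_times)) {
    print(data.frame(time = x$event_times, at_risk = x$at_risk,
                     events = x$events, survival = round(x$survival, 4)),
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi2 = %.4g on %d df, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  invisible(x)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf(
    "Cox PH (Breslow): beta = %.4g (se %.4g), HR = %.4g, p = %.4g%s\n",
    x$beta, x$se, x$hazard_ratio, x$p_value,
    if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}
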