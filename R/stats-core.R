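#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Two-sided two-group comparison by the midrank method. When both groups
#' have at most 10 observations and there are no ties, the p-value is exact
#' (full enumeration of the U null distribution); otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @param alpha Significance level used only to set the `direction` field.
#' @return A list of class `mw_test` with `statistic_u` (U of `group_a`),
#'   `p_value`, `n1`, `n2`, `median1`, `median2`, `direction` (`"up"` /
#'   `"down"` / `"none"`: sign of `median2 - median1` when `p < alpha`)
#'   and `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney_u <- function(group_a, group_b, alpha = 0.05) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop_input("both groups must be non-empty")
  }
  if (anyNA(group_a) || anyNA(group_b)) stop_input("missing values in input")
  n1 <- length(group_a)
  n2 <- length(group_b)
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  u_a <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  tie_counts <- table(pooled)
  has_ties <- any(tie_counts > 1L)

  if (n1 <= 10L && n2 <= 10L && !has_ties) {
    # exact: every assignment of n1 ranks out of N is equally likely
    combs <- utils::combn(n1 + n2, n1)
    u_all <- colSums(combs) - n1 * (n1 + 1) / 2
    dev <- abs(u_all - n1 * n2 / 2)
    p <- mean(dev >= abs(u_a - n1 * n2 / 2) - 1e-9)
    method <- "exact"
  } else {
    nn <- n1 + n2
    mu <- n1 * n2 / 2
    tie_term <- sum(tie_counts^3 - tie_counts)
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term / (nn * (nn - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- max(0, (abs(u_a - mu) - 0.5) / sqrt(sigma2))
      p <- min(1, 2 * stats::pnorm(-z))
    }
    method <- "normal_approximation"
  }

  med1 <- stats::median(group_a)
  med2 <- stats::median(group_b)
  direction <- if (p < alpha && med2 != med1) {
    if (med2 > med1) "up" else "down"
  } else "none"

  structure(
    list(statistic_u = u_a, p_value = p, n1 = n1, n2 = n2,
         median1 = med1, median2 = med2, direction = direction,
         method = method),
    class = "mw_test"
  )
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks, with a two-sided p-value from the t
#' approximation on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop_input("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop_input("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop_input("missing values in input")
  rx <- rank(x)
  ry <- rank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sx <- sum(dx^2)
  sy <- sum(dy^2)
  if (sx == 0 || sy == 0) stop_degenerate("constant input: rho undefined")
  rho <- sum(dx * dy) / sqrt(sx * sy)
  rho <- max(-1, min(1, rho))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

# Internal: sensitivity/specificity over candidate thresholds in a
# canonical frame where high values are test-positive (the low_is_positive
# direction is handled by negation so direction symmetry holds exactly).
# Candidate thresholds: midpoints of consecutive distinct values plus one
# sentinel below the minimum and one above the maximum; a case is
# test-positive iff value > threshold (strict).
roc_canonical <- function(values, is_positive) {
  sv <- sort(unique(values))
  thr <- if (length(sv) == 1L) c(sv - 1, sv + 1) else {
    c(sv[1] - 1, (sv[-length(sv)] + sv[-1]) / 2, sv[length(sv)] + 1)
  }
  pos <- values[is_positive]
  neg <- values[!is_positive]
  sens <- 1 - stats::ecdf(pos)(thr)   # P(pos > thr)
  spec <- stats::ecdf(neg)(thr)       # P(neg <= thr)
  # trapezoid over (1 - spec, sens); with thr ascending both decrease
  x <- rev(1 - spec)
  y <- rev(sens)
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  list(thresholds = thr, sensitivity = sens, specificity = spec, auc = auc)
}

check_two_classes <- function(values, is_positive) {
  if (length(values) != length(is_positive)) {
    stop_input("values and labels must have equal length")
  }
  if (anyNA(values) || anyNA(is_positive) || any(!is.finite(values))) {
    stop_input("missing or non-finite values in input")
  }
  is_positive <- as.logical(is_positive)
  if (!any(is_positive) || all(is_positive)) {
    stop_degenerate("both classes must be represented")
  }
  is_positive
}

#' ROC curve over midpoint thresholds
#'
#' Builds the empirical ROC curve of a marker for a binary state. Candidate
#' thresholds are the midpoints between consecutive distinct observed
#' values, plus one sentinel below the minimum and one above the maximum,
#' so a reported threshold never coincides with an observed value. A case
#' is test-positive iff its value is strictly above (`high_is_positive`) or
#' strictly below (`low_is_positive`) the threshold. The AUC is the
#' trapezoid area over (1 - specificity, sensitivity) and equals the
#' tie-adjusted Mann-Whitney pair-counting AUC.
#'
#' @param values Numeric marker levels (AU) or ages (years).
#' @param is_positive Logical event labels.
#' @param direction `"high_is_positive"` or `"low_is_positive"`.
#' @return List of class `roc_curve` with `thresholds` (ascending, original
#'   scale), aligned `sensitivity` and `specificity`, `auc` and
#'   `positive_direction`.
#' @export
roc_curve <- function(values, is_positive,
                      direction = c("high_is_positive", "low_is_positive")) {
  direction <- match.arg(direction)
  is_positive <- check_two_classes(values, is_positive)
  v <- if (direction == "low_is_positive") -values else values
  rc <- roc_canonical(v, is_positive)
  if (direction == "low_is_positive") {
    ord <- rev(seq_along(rc$thresholds))
    rc$thresholds <- -rc$thresholds[ord]
    rc$sensitivity <- rc$sensitivity[ord]
    rc$specificity <- rc$specificity[ord]
  }
  structure(
    list(thresholds = rc$thresholds, sensitivity = rc$sensitivity,
         specificity = rc$specificity, auc = rc$auc,
         positive_direction = direction),
    class = "roc_curve"
  )
}

#' Youden-index optimal cut-point
#'
#' Evaluates Youden's J = sensitivity + specificity - 1 at every candidate
#' threshold of [roc_curve()] and returns the maximizer. Ties on J are
#' broken by higher sensitivity, then by the lower threshold in the
#' canonical high-is-positive frame (for `low_is_positive` the values are
#' negated before the scan, so the direction-symmetry identity
#' `cutpoint(v, low) == -cutpoint(-v, high)` holds exactly).
#'
#' @inheritParams roc_curve
#' @param marker Optional marker name carried into the result.
#' @return List of class `cutpoint_result` with `marker`, `cutoff`,
#'   `direction`, `youden_j`, `sensitivity`, `specificity`, `auc`.
#' @examples
#' youden_cutpoint(c(1, 2, 3, 5, 6, 7),
#'                 c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
#' @export
youden_cutpoint <- function(values, is_positive,
                            direction = c("high_is_positive",
                                          "low_is_positive"),
                            marker = NA_character_) {
  direction <- match.arg(direction)
  is_positive <- check_two_classes(values, is_positive)
  v <- if (direction == "low_is_positive") -values else values
  rc <- roc_canonical(v, is_positive)
  j <- rc$sensitivity + rc$specificity - 1
  tol <- 1e-12
  best <- which(j >= max(j) - tol)
  best <- best[rc$sensitivity[best] >= max(rc$sensitivity[best]) - tol]
  pick <- best[which.min(rc$thresholds[best])]
  cutoff <- rc$thresholds[pick]
  if (direction == "low_is_positive") cutoff <- -cutoff
  structure(
    list(marker = marker, cutoff = cutoff, direction = direction,
         youden_j = rc$sensitivity[pick] + rc$specificity[pick] - 1,
         sensitivity = rc$sensitivity[pick],
         specificity = rc$specificity[pick],
         auc = rc$auc),
    class = "cutpoint_result"
  )
}
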