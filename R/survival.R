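#' Kaplan-Meier product-limit estimator
#'
#' Right-censored survival function with Greenwood variance. Subjects
#' censored at an event time are counted as at risk at that time (deaths
#' precede censoring).
#'
#' @param times Positive follow-up times (days).
#' @param events Logical (or 0/1) event indicators.
#' @return List of class `km_curve` with `event_times` (sorted distinct
#'   times with at least one event), `survival`, `at_risk`, `events`,
#'   `greenwood_var` (NA once the estimate reaches 0) and `n`.
#' @examples
#' km_fit(c(1, 2, 3), c(TRUE, FALSE, TRUE))
#' @export
km_fit <- function(times, events) {
  if (length(times) != length(events)) {
    stop_input("times and events must have equal length")
  }
  if (anyNA(times) || anyNA(events)) stop_input("missing values in input")
  if (any(times <= 0)) stop_input("times must be > 0")
  events <- as.logical(events)

  et <- sort(unique(times[events]))
  n_risk <- vapply(et, function(t) sum(times >= t), numeric(1))
  d <- vapply(et, function(t) sum(events & times == t), numeric(1))
  surv <- cumprod(1 - d / n_risk)
  gterm <- ifelse(n_risk > d, d / (n_risk * (n_risk - d)), NA_real_)
  gvar <- surv^2 * cumsum(gterm)
  gvar[surv == 0] <- NA_real_

  structure(
    list(event_times = et, survival = surv, at_risk = n_risk, events = d,
         greenwood_var = gvar, n = length(times)),
    class = "km_curve"
  )
}

#' Step-function coordinates of a Kaplan-Meier curve
#'
#' @param fit A [km_fit()] result.
#' @return Data frame with `time` and `survival` columns (starting at
#'   `time = 0`, `survival = 1`) suitable for step plotting or CSV export.
#' @export
km_steps <- function(fit) {
  if (!inherits(fit, "km_curve")) stop_input("fit must be a km_curve")
  data.frame(time = c(0, fit$event_times), survival = c(1, fit$survival))
}

#' k-group log-rank test
#'
#' Standard log-rank test: at each distinct event time the expected number
#' of events in group g is `d * n_g / n`; the chi-square statistic uses the
#' hypergeometric covariance of the observed-minus-expected vector, with
#' `df = k - 1`.
#'
#' @param times Positive follow-up times.
#' @param events Logical event indicators.
#' @param groups Group labels (coerced to factor); at least 2 non-empty
#'   groups.
#' @return List of class `logrank_result` with `chi_square`, `df`,
#'   `p_value`, and per-group `observed` / `expected`.
#' @export
logrank_test <- function(times, events, groups) {
  if (length(times) != length(events) || length(times) != length(groups)) {
    stop_input("times, events and groups must have equal length")
  }
  if (anyNA(times) || anyNA(events) || anyNA(groups)) {
    stop_input("missing values in input")
  }
  groups <- factor(groups)
  groups <- droplevels(groups)
  k <- nlevels(groups)
  if (k < 2L) stop_input("need at least 2 non-empty groups")
  events <- as.logical(events)

  et <- sort(unique(times[events]))
  obs <- stats::setNames(numeric(k), levels(groups))
  expd <- obs
  V <- matrix(0, k, k, dimnames = list(levels(groups), levels(groups)))

  for (t in et) {
    at_risk <- times >= t
    n_t <- sum(at_risk)
    d_t <- sum(events & times == t)
    n_gt <- vapply(levels(groups),
                   function(g) sum(at_risk & groups == g), numeric(1))
    d_gt <- vapply(levels(groups),
                   function(g) sum(events & times == t & groups == g),
                   numeric(1))
    obs <- obs + d_gt
    p_g <- n_gt / n_t
    expd <- expd + d_t * p_g
    if (n_t > 1L) {
      w <- d_t * (n_t - d_t) / (n_t - 1)
      V <- V + w * (diag(p_g, k) - tcrossprod(p_g))
    }
  }

  oe <- (obs - expd)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  chi <- if (length(et) == 0L || sum(abs(oe)) < 1e-12) {
    0
  } else {
    qr_v <- qr(Vk)
    if (qr_v$rank < ncol(Vk)) {
      sv <- svd(Vk)
      pos <- sv$d > max(sv$d) * 1e-12
      pinv <- sv$v[, pos, drop = FALSE] %*%
        (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
      drop(t(oe) %*% pinv %*% oe)
    } else {
      drop(t(oe) %*% solve(qr_v, oe))
    }
  }
  chi <- max(0, chi)

  structure(
    list(chi_square = chi, df = k - 1L,
         p_value = stats::pchisq(chi, df = k - 1L, lower.tail = FALSE),
         observed = obs, expected = expd),
    class = "logrank_result"
  )
}

# Breslow partial log-likelihood, score and information at beta for
# right-censored data; covariate centred by the caller for stability.
cox_breslow_derivs <- function(beta, times, events, x) {
  ord <- order(times, decreasing = TRUE)
  t_o <- times[ord]
  e_o <- events[ord]
  x_o <- x[ord]
  w <- exp(beta * x_o)
  s0 <- cumsum(w)
  s1 <- cumsum(w * x_o)
  s2 <- cumsum(w * x_o^2)
  # positions of the last tied observation per time = full risk set
  last_of_time <- c(t_o[-length(t_o)] != t_o[-1], TRUE)
  et <- unique(t_o[e_o])
  score <- 0
  info <- 0
  loglik <- 0
  for (t in et) {
    idx <- max(which(t_o == t & last_of_time))
    d_t <- sum(e_o & t_o == t)
    sx <- sum(x_o[e_o & t_o == t])
    m1 <- s1[idx] / s0[idx]
    m2 <- s2[idx] / s0[idx]
    loglik <- loglik + beta * sx - d_t * log(s0[idx])
    score <- score + sx - d_t * m1
    info <- info + d_t * (m2 - m1^2)
  }
  list(loglik = loglik, score = score, info = info)
}

#' Univariate Cox proportional-hazards regression
#'
#' Maximizes the Breslow-ties partial likelihood by Newton's method started
#' at `beta = 0`; convergence when the absolute score falls below `tol`
#' (default 1e-8) within `max_iter` iterations. A monotone likelihood
#' (complete separation) is flagged through `converged = FALSE` rather than
#' failing silently.
#'
#' @param times Positive follow-up times.
#' @param events Logical event indicators (at least one event).
#' @param covariate Numeric covariate; must not be constant.
#' @param max_iter,tol Newton iteration controls.
#' @return List of class `cox_fit` with `beta`, `se`, `hazard_ratio`,
#'   `p_value`, `n_iter`, `converged`.
#' @export
cox_univariate <- function(times, events, covariate,
                           max_iter = 50L, tol = 1e-8) {
  if (length(times) != length(events) ||
      length(times) != length(covariate)) {
    stop_input("times, events and covariate must have equal length")
  }
  if (anyNA(times) || anyNA(events) || anyNA(covariate)) {
    stop_input("missing values in input")
  }
  events <- as.logical(events)
  if (!any(events)) stop_degenerate("no events observed")
  if (length(unique(covariate)) < 2L) {
    stop_degenerate("constant covariate carries no information")
  }

  xc <- covariate - mean(covariate)
  beta <- 0
  converged <- FALSE
  n_iter <- 0L
  dv <- NULL
  for (it in seq_len(max_iter)) {
    n_iter <- it
    dv <- cox_breslow_derivs(beta, times, events, xc)
    if (abs(dv$score) < tol) {
      converged <- TRUE
      break
    }
    if (dv$info <= 1e-12) break  # flat likelihood: separation
    step <- dv$score / dv$info
    step <- sign(step) * min(abs(step), 5)  # damp huge steps
    beta <- beta + step
    if (abs(beta) > 200) break  # diverging: monotone likelihood
  }
  # scale-invariant separation check: with a monotone likelihood the score
  # only vanishes because the risk-set weights saturate, which drives the
  # standardized estimate beyond any plausible effect and collapses the
  # observed information (exploding standardized SE)
  sdx <- stats::sd(xc)
  se_raw <- if (!is.null(dv) && dv$info > 0) 1 / sqrt(dv$info) else Inf
  if (converged && (abs(beta) * sdx > 10 || se_raw * sdx > 50)) {
    converged <- FALSE
  }

  se <- if (dv$info > 0) 1 / sqrt(dv$info) else NA_real_
  p <- if (converged && is.finite(se)) {
    2 * stats::pnorm(-abs(beta / se))
  } else NA_real_

  structure(
    list(beta = beta, se = se, hazard_ratio = exp(beta), p_value = p,
         n_iter = n_iter, converged = converged),
    class = "cox_fit"
  )
}
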