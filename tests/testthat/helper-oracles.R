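# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check.

# tie-adjusted pair-counting AUC: P(pos beats neg) + 0.5 P(tie)
oracle_auc_paircount <- function(values, is_positive, direction) {
  pos <- values[as.logical(is_positive)]
  neg <- values[!as.logical(is_positive)]
  cmp <- outer(pos, neg, `-`)
  if (direction == "low_is_positive") cmp <- -cmp
  (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (length(pos) * length(neg))
}

# exhaustive Youden scan in the canonical high-is-positive frame:
# midpoint thresholds plus sentinels, strict '>' positivity, ties on J
# broken by higher sensitivity then lower canonical threshold
oracle_youden_scan <- function(values, is_positive, direction) {
  v <- if (direction == "low_is_positive") -values else values
  lab <- as.logical(is_positive)
  sv <- sort(unique(v))
  thr <- c(sv[1] - 1,
           if (length(sv) > 1) (sv[-length(sv)] + sv[-1]) / 2,
           sv[length(sv)] + 1)
  best <- NULL
  for (t in thr) {
    sens <- sum(v > t & lab) / sum(lab)
    spec <- sum(v <= t & !lab) / sum(!lab)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && sens > best$sens + 1e-12)) {
      best <- list(t = t, j = j, sens = sens, spec = spec)
    }
  }
  cutoff <- if (direction == "low_is_positive") -best$t else best$t
  list(cutoff = cutoff, j = best$j, sens = best$sens, spec = best$spec)
}

# independent midrank computation
oracle_midrank <- function(x) {
  vapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2, numeric(1))
}

# exact two-sided Mann-Whitney p by direct enumeration of label
# arrangements over the observed values (works with ties too)
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  mid <- n1 * length(b) / 2
  combs <- utils::combn(length(pooled), n1)
  u_all <- apply(combs, 2, u_of)
  mean(abs(u_all - mid) >= abs(u_obs - mid) - 1e-9)
}

# two-group log-rank chi-square, computed independently (plain loops)
oracle_logrank_chisq <- function(times, events, g01) {
  et <- sort(unique(times[events]))
  oe <- 0
  v <- 0
  for (t in et) {
    at <- times >= t
    n_t <- sum(at)
    d_t <- sum(events & times == t)
    n1 <- sum(at & g01 == 1)
    d1 <- sum(events & times == t & g01 == 1)
    oe <- oe + d1 - d_t * n1 / n_t
    if (n_t > 1) {
      v <- v + d_t * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  if (v <= 0) 0 else oe^2 / v
}

# Monte-Carlo permutation reference for the two-group log-rank p-value:
# permutes group labels, recomputing the same chi-square statistic for
# every permutation (vectorised over permutations via matrix algebra)
oracle_logrank_perm_p <- function(times, events, g01, B = 10000) {
  et <- sort(unique(times[events]))
  n <- length(times)
  R <- outer(et, times, function(t, x) as.numeric(x >= t))   # at risk
  D <- outer(et, times, function(t, x) as.numeric(x == t)) *
    rep(as.numeric(events), each = length(et))               # events
  n_t <- rowSums(R)
  d_t <- rowSums(D)
  L <- vapply(seq_len(B), function(b) sample(g01), numeric(n))
  n1t <- R %*% L
  d1t <- D %*% L
  E <- d_t * n1t / n_t
  Vt <- d_t * (n1t / n_t) * (1 - n1t / n_t) *
    ifelse(n_t > 1, (n_t - d_t) / (n_t - 1), 0)
  chi_perm <- colSums(d1t - E)^2 / pmax(colSums(Vt), 1e-300)
  chi_obs <- oracle_logrank_chisq(times, events, g01)
  mean(chi_perm >= chi_obs - 1e-9)
}

# Breslow partial log-likelihood by direct loops, and a coarse-to-fine
# grid search at 1e-4 resolution over [-5, 5]
oracle_breslow_loglik <- function(beta, times, events, x) {
  ll <- 0
  for (t in unique(times[events])) {
    dead <- which(events & times == t)
    risk <- which(times >= t)
    ll <- ll + beta * sum(x[dead]) -
      length(dead) * log(sum(exp(beta * x[risk])))
  }
  ll
}

oracle_cox_grid <- function(times, events, x, lo = -5, hi = 5) {
  coarse <- seq(lo, hi, by = 0.01)
  ll <- vapply(coarse, oracle_breslow_loglik, numeric(1),
               times = times, events = events, x = x)
  b0 <- coarse[which.max(ll)]
  fine <- seq(max(lo, b0 - 0.02), min(hi, b0 + 0.02), by = 1e-4)
  llf <- vapply(fine, oracle_breslow_loglik, numeric(1),
                times = times, events = events, x = x)
  fine[which.max(llf)]
}

# small random labelled instance, optionally on a coarse grid (forces ties)
random_roc_instance <- function(n_pos, n_neg, tied = FALSE) {
  v <- if (tied) {
    sample(seq(0, 5, by = 0.5), n_pos + n_neg, replace = TRUE)
  } else {
    stats::rnorm(n_pos + n_neg)
  }
  list(values = v,
       labels = sample(c(rep(TRUE, n_pos), rep(FALSE, n_neg))))
}

# default-config cohort shorthand for tests
test_cohort <- function(seed = 1L, n = NULL) {
  cfg <- default_study_config(seed = seed)
  if (!is.null(n)) cfg$n_patients <- as.integer(n)
  simulate_cohort(cfg)
}

zero_shift_config <- function(seed) {
  cfg <- default_study_config(seed = seed)
  cfg$effect_matrix[] <- 0
  cfg
}
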