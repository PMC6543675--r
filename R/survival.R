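#' Survival core
#'
#' Self-contained Kaplan-Meier, log-rank and single-binary-covariate Cox
#' routines. The combination screen calls these millions of times, so they
#' are written as lean vectorized paths over a precomputed sort order; the
#' test suite cross-validates them against the reference survival package.
#'
#' @name survival_core
NULL

# Precompute sort order, distinct-time boundaries and the Efron tie
# expansion for a set of (time, event) pairs. Everything here depends only
# on times/events, not on group labels, so a screen computes it once per
# cohort and reuses it for every combination.
surv_precompute <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1)
  if (anyNA(time) || anyNA(event)) stop_secepr("survival data contain NA")
  if (any(time < 0)) stop_secepr("survival times must be >= 0")
  if (any(time == 0)) {
    pos <- time[time > 0]
    if (!length(pos)) stop_secepr("all survival times are zero")
    rlang::warn("zero survival times shifted to half the smallest positive time")
    time[time == 0] <- min(pos) / 2
  }
  n <- length(time)
  o <- order(time)
  t_s <- time[o]
  e_s <- as.integer(event[o])
  first <- which(!duplicated(t_s))
  last <- c(first[-1L] - 1L, n)
  cs_e <- cumsum(e_s)
  d_all <- cs_e[last] - c(0L, cs_e[head(last, -1L)])
  nrisk_all <- n - first + 1L
  ev <- d_all > 0L
  d <- d_all[ev]
  # Efron expansion: event time index repeated d_i times with j/d fractions
  rep_i <- rep.int(seq_along(d), d)
  frac <- unlist(lapply(d, function(dd) seq.int(0L, dd - 1L) / dd), use.names = FALSE)
  list(
    n = n, o = o, t_sorted = t_s, e_sorted = e_s,
    first = first, last = last, ev = ev,
    times = t_s[first][ev], d = d, nrisk = nrisk_all[ev],
    n_events = sum(e_s), rep_i = rep_i, frac = frac
  )
}

# at-risk and event counts for group 1 at each event time
group_counts <- function(pre, group) {
  g_s <- as.integer(group[pre$o])
  n1risk <- rev(cumsum(rev(g_s)))[pre$first][pre$ev]
  cs <- cumsum(pre$e_sorted * g_s)
  d1 <- (cs[pre$last] - c(0L, cs[head(pre$last, -1L)]))[pre$ev]
  list(n1risk = n1risk, d1 = d1)
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survivor function, optionally by group.
#' Censored observations reduce the risk set without a survival drop.
#'
#' @param data Data frame with columns `time` (months > 0), `event`
#'   (logical/0-1) and optionally `group`.
#' @param time,event,group Column names (tidy-select strings).
#' @return A `secep_km` object; its `steps` tibble has one row per distinct
#'   event time and group: `group`, `time`, `n_risk`, `n_event`, `survival`.
#' @examples
#' km_fit(data.frame(time = c(1, 2, 3), event = c(TRUE, TRUE, TRUE)))
#' @export
km_fit <- function(data, time = "time", event = "event", group = NULL) {
  tt <- data[[time]]
  ee <- as.logical(data[[event]])
  if (!length(tt)) stop_secepr("no samples")
  grp <- if (is.null(group) || !group %in% names(data)) {
    rep("all", length(tt))
  } else {
    as.character(data[[group]])
  }
  steps <- purrr::map_dfr(split(seq_along(tt), grp), function(idx) {
    pre <- surv_precompute(tt[idx], ee[idx])
    if (!length(pre$times)) {
      return(tibble::tibble(group = grp[idx[1]], time = numeric(),
                            n_risk = integer(), n_event = integer(),
                            survival = numeric()))
    }
    s <- cumprod(1 - pre$d / pre$nrisk)
    tibble::tibble(group = grp[idx[1]], time = pre$times,
                   n_risk = pre$nrisk, n_event = pre$d, survival = s)
  })
  structure(
    list(
      steps = steps,
      n = tapply(tt, grp, length),
      n_events = tapply(ee, grp, sum)
    ),
    class = "secep_km"
  )
}

#' @export
print.secep_km <- function(x, ...) {
  cat("<secep_km> groups:", paste(names(x$n), collapse = ", "), "\n")
  print(x$steps, n = 10)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard unweighted log-rank test over pooled event times with the
#' hypergeometric variance; chi-square statistic on 1 df.
#'
#' @param data Data frame with `time`, `event` and a two-level `group`
#'   column (logical or two unique values; the "altered" group is `TRUE`
#'   or the second sorted level).
#' @inheritParams km_fit
#' @return A `secep_logrank` object: `chi_square`, `p`, `observed`,
#'   `expected` (per group), `n`, `n_events`.
#' @export
logrank_test <- function(data, time = "time", event = "event", group = "group") {
  g <- to_binary_group(data[[group]])
  pre <- surv_precompute(data[[time]], as.logical(data[[event]]))
  res <- logrank_core(pre, g)
  structure(c(res, list(n = pre$n)), class = "secep_logrank")
}

to_binary_group <- function(g) {
  if (is.logical(g)) return(as.integer(g))
  lev <- sort(unique(g))
  if (length(lev) != 2) stop_secepr("group must have exactly two levels")
  as.integer(g == lev[2])
}

logrank_core <- function(pre, g) {
  if (all(g == 0L) || all(g == 1L)) stop_secepr("both groups must be non-empty")
  if (pre$n_events == 0) stop_secepr("no events")
  gc <- group_counts(pre, g)
  nr <- pre$nrisk
  d <- pre$d
  p1 <- gc$n1risk / nr
  e1 <- d * p1
  v <- ifelse(nr > 1, d * p1 * (1 - p1) * (nr - d) / (nr - 1), 0)
  o1 <- sum(gc$d1)
  V <- sum(v)
  chi <- if (V > 0) (o1 - sum(e1))^2 / V else 0
  list(
    chi_square = chi,
    p = pchisq(chi, df = 1, lower.tail = FALSE),
    observed = c(group0 = pre$n_events - o1, group1 = o1),
    expected = c(group0 = pre$n_events - sum(e1), group1 = sum(e1)),
    n_events = pre$n_events
  )
}

#' Cox proportional hazards for one binary covariate
#'
#' Maximizes the partial likelihood with Efron handling of tied event times
#' by Newton-Raphson, and reports the hazard ratio with its 95% Wald
#' confidence interval on the log scale (z = 1.959964). A monotone partial
#' likelihood (e.g. all events confined to one group) is reported as
#' `converged = FALSE` with the hazard ratio at the boundary direction, not
#' as an error.
#'
#' @inheritParams logrank_test
#' @return A `secep_cox` object: `log_hr`, `se`, `hr`, `ci_low`, `ci_high`,
#'   `p` (Wald), `converged`, `n`, `n_events`.
#' @export
cox_binary <- function(data, time = "time", event = "event", group = "group") {
  g <- to_binary_group(data[[group]])
  pre <- surv_precompute(data[[time]], as.logical(data[[event]]))
  res <- cox_core(pre, g)
  structure(c(res, list(n = pre$n)), class = "secep_cox")
}

cox_core <- function(pre, g, z_crit = 1.959964, max_iter = 25, tol = 1e-9) {
  if (all(g == 0L) || all(g == 1L)) stop_secepr("no contrast: single group")
  if (pre$n_events < 2) stop_secepr("need >= 2 events")
  gc <- group_counts(pre, g)
  r1 <- gc$n1risk
  r0 <- pre$nrisk - r1
  d1 <- gc$d1
  d0 <- pre$d - d1
  rep_i <- pre$rep_i
  frac <- pre$frac
  sum_d1 <- sum(d1)
  b <- 0
  converged <- FALSE
  info <- NA_real_
  for (iter in seq_len(max_iter)) {
    eb <- exp(b)
    s_risk <- r0 + r1 * eb
    s_ev <- d0 + d1 * eb
    x_risk <- r1 * eb
    x_ev <- d1 * eb
    den <- s_risk[rep_i] - frac * s_ev[rep_i]
    num <- x_risk[rep_i] - frac * x_ev[rep_i]
    mu <- num / den
    score <- sum_d1 - sum(mu)
    info <- sum(mu * (1 - mu))
    if (!is.finite(info) || info <= 1e-12 || abs(b) > 15) break
    step <- score / info
    if (abs(step) > 2) step <- sign(step) * 2 # dampen early overshoot
    b <- b + step
    if (abs(step) < tol) {
      converged <- TRUE
      break
    }
  }
  if (abs(b) > 15) converged <- FALSE
  se <- if (converged && info > 0) 1 / sqrt(info) else NA_real_
  list(
    log_hr = b,
    se = se,
    hr = exp(b),
    ci_low = if (converged) exp(b - z_crit * se) else NA_real_,
    ci_high = if (converged) exp(b + z_crit * se) else NA_real_,
    p = if (converged) 2 * pnorm(-abs(b / se)) else NA_real_,
    converged = converged,
    n_events = pre$n_events
  )
}

#' @export
print.secep_logrank <- function(x, ...) {
  cat(sprintf("<secep_logrank> chi^2 = %.4g (1 df), p = %.4g\n",
              x$chi_square, x$p))
  invisible(x)
}

#' @export
print.secep_cox <- function(x, ...) {
  cat(sprintf("<secep_cox> HR = %.3f [%.3f, %.3f], p = %.3g%s\n",
              x$hr, x$ci_low, x$ci_high, x$p,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Export a Kaplan-Meier curve as a tibble
#'
#' @param x A `secep_km` object.
#' @param ... Unused.
#' @return Tibble of survival steps (`group`, `time`, `n_risk`, `n_event`,
#'   `survival`).
#' @method tidy secep_km
#' @export
tidy.secep_km <- function(x, ...) x$steps

#' @method glance secep_km
#' @export
glance.secep_km <- function(x, ...) {
  tibble::tibble(
    group = names(x$n),
    n = as.integer(x$n),
    n_events = as.integer(x$n_events)
  )
}

#' @method tidy secep_logrank
#' @export
tidy.secep_logrank <- function(x, ...) {
  tibble::tibble(
    group = names(x$observed),
    observed = as.numeric(x$observed),
    expected = as.numeric(x$expected)
  )
}

#' @method glance secep_logrank
#' @export
glance.secep_logrank <- function(x, ...) {
  tibble::tibble(chi_square = x$chi_square, p = x$p,
                 n = x$n, n_events = x$n_events)
}

#' @method tidy secep_cox
#' @export
tidy.secep_cox <- function(x, ...) {
  tibble::tibble(
    term = "group", estimate = x$log_hr, std_error = x$se,
    hr = x$hr, ci_low = x$ci_low, ci_high = x$ci_high, p = x$p
  )
}

#' @method glance secep_cox
#' @export
glance.secep_cox <- function(x, ...) {
  tibble::tibble(hr = x$hr, ci_low = x$ci_low, ci_high = x$ci_high,
                 p = x$p, converged = x$converged,
                 n = x$n, n_events = x$n_events)
}
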