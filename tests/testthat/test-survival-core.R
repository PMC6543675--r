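test_that("Kaplan-Meier matches hand-computed product limits", {
  km <- km_fit(data.frame(time = c(1, 2, 3), event = c(TRUE, TRUE, TRUE)))
  expect_equal(tidy(km)$survival, c(2 / 3, 1 / 3, 0))
  # all censored: no drops
  km0 <- km_fit(data.frame(time = c(1, 2, 3), event = c(FALSE, FALSE, FALSE)))
  expect_equal(nrow(tidy(km0)), 0)
  expect_equal(glance(km0)$n_events, 0L)
  # censoring reduces the risk set without a drop: events at 1 and 3,
  # censored at 2 -> S = 2/3 then 2/3 * 0 = 0 with a risk set of 1 at t = 3
  km1 <- km_fit(data.frame(time = c(1, 2, 3), event = c(TRUE, FALSE, TRUE)))
  s <- tidy(km1)
  expect_equal(s$survival, c(2 / 3, 0))
  expect_equal(s$n_risk, c(3L, 1L))
})

test_that("KM without censoring equals the empirical survivor function", {
  d <- random_surv_data(200, seed = 10, cens_rate = 1e-9)
  km <- km_fit(d)
  s <- tidy(km)
  emp <- vapply(s$time, function(t) mean(d$time > t), numeric(1))
  expect_equal(s$survival, emp, tolerance = 1e-12)
})

test_that("log-rank matches the O/E/V hand computation on a toy table", {
  # group1 events at 1, 2; group2 events at 3, 4; n = 2 each, no censoring
  d <- data.frame(time = 1:4, event = TRUE, group = c(TRUE, TRUE, FALSE, FALSE))
  # hand: at t=1 n=4 n1=2 -> e1=0.5 v=(1*0.5*0.5*3/3)=0.25
  #       t=2 n=3 n1=1 -> e1=1/3 v=(1/3)(2/3)=2/9
  #       t=3 n=2 n1=0 -> e1=0 v=0; t=4: n=1 -> v=0
  lr <- logrank_test(d)
  e1 <- 0.5 + 1 / 3
  v <- 0.25 + 2 / 9
  expect_equal(unname(lr$expected["group1"]), e1, tolerance = 1e-12)
  expect_equal(lr$chi_square, (2 - e1)^2 / v, tolerance = 1e-12)
  # identical multisets in the two groups: chi = 0, p = 1
  d2 <- data.frame(time = rep(c(2, 5, 9), 2), event = rep(c(TRUE, TRUE, FALSE), 2),
                   group = rep(c(TRUE, FALSE), each = 3))
  lr2 <- logrank_test(d2)
  expect_equal(lr2$chi_square, 0)
  expect_equal(lr2$p, 1)
})

test_that("log-rank is invariant to label swaps and monotone time transforms", {
  d <- random_surv_data(60, seed = 11)
  lr <- logrank_test(d)
  d_swap <- d
  d_swap$group <- !d$group
  expect_equal(logrank_test(d_swap)$chi_square, lr$chi_square, tolerance = 1e-12)
  d_mono <- d
  d_mono$time <- exp(d$time / 20) # strictly increasing
  expect_equal(logrank_test(d_mono)$p, lr$p, tolerance = 1e-12)
})

test_that("log-rank p agrees with its permutation null on toy data", {
  d <- random_surv_data(20, seed = 12, rate = 0.08)
  p_perm <- logrank_perm_p(d, n_perm = 2000, seed = 13)
  expect_lt(abs(logrank_test(d)$p - p_perm), 0.05)
})

test_that("survival routines refuse degenerate inputs", {
  d <- data.frame(time = c(1, 2), event = c(FALSE, FALSE), group = c(TRUE, FALSE))
  expect_error(logrank_test(d), "no events")
  d1 <- data.frame(time = 1:4, event = TRUE, group = TRUE)
  expect_error(cox_binary(d1), "single group")
  d2 <- data.frame(time = 1:4, event = c(TRUE, FALSE, FALSE, FALSE),
                   group = c(TRUE, TRUE, FALSE, FALSE))
  expect_error(cox_binary(d2), "2 events")
  expect_error(km_fit(data.frame(time = numeric(), event = logical())), "no samples")
  expect_warning(
    km_fit(data.frame(time = c(0, 1, 2), event = TRUE)),
    "shifted"
  )
})

test_that("Cox flags the monotone-likelihood boundary instead of erroring", {
  # every event happens in group 1 while group 0 only gets censored
  d <- data.frame(
    time = c(1, 2, 3, 4, 50, 60, 70, 80),
    event = c(rep(TRUE, 4), rep(FALSE, 4)),
    group = c(rep(TRUE, 4), rep(FALSE, 4))
  )
  cx <- cox_binary(d)
  expect_false(cx$converged)
  expect_gt(cx$log_hr, 5) # driven toward +infinity
})

test_that("Cox on null labels covers HR 1 and matches the reference Efron fit", {
  d <- random_surv_data(1000, seed = 14, round_digits = 0) # heavy ties
  cx <- cox_binary(d)
  expect_true(cx$converged)
  expect_gt(cx$hr, 0.8)
  expect_lt(cx$hr, 1.25)
  expect_true(cx$ci_low < 1 && cx$ci_high > 1)
  ref <- survival::coxph(survival::Surv(time, event) ~ group, data = d,
                         ties = "efron")
  expect_equal(cx$log_hr, unname(stats::coef(ref)), tolerance = 1e-6)
  expect_equal(cx$se, sqrt(unname(stats::vcov(ref)[1, 1])), tolerance = 1e-6)
  # KM and log-rank cross-checks on the same heavily tied data
  sf <- summary(survival::survfit(survival::Surv(time, event) ~ 1, data = d))
  expect_equal(tidy(km_fit(d))$survival, unname(sf$surv), tolerance = 1e-12)
  sd2 <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  expect_equal(logrank_test(d)$chi_square, unname(sd2$chisq), tolerance = 1e-9)
})

test_that("Cox recovers a planted hazard ratio from exponential data", {
  n <- 1000
  d <- withr::with_seed(15, {
    group <- rep(c(TRUE, FALSE), each = n / 2)
    t_ev <- rexp(n, 0.02 * ifelse(group, 2, 1))
    cens <- runif(n, 0, 160) # ~20% censoring at these rates
    data.frame(time = pmin(t_ev, cens), event = t_ev <= cens, group = group)
  })
  expect_lt(abs(mean(!d$event) - 0.2), 0.1)
  cx <- cox_binary(d)
  expect_lt(abs(cx$hr - 2) / 2, 0.15)
  expect_true(cx$ci_low < 2 && cx$ci_high > 2)
})

test_that("two-sample exponential HR approaches the rate ratio as censoring vanishes", {
  n <- 2000
  d <- withr::with_seed(16, {
    group <- rep(c(TRUE, FALSE), each = n / 2)
    data.frame(time = rexp(n, 0.01 * ifelse(group, 3, 1)),
               event = TRUE, group = group)
  })
  cx <- cox_binary(d)
  expect_lt(abs(cx$hr - 3) / 3, 0.10)
})

test_that("log-rank and Cox Wald p land on the same side of 0.05 for a planted effect", {
  d <- withr::with_seed(17, {
    group <- rep(c(TRUE, FALSE), each = 60)
    t_ev <- rexp(120, 0.02 * ifelse(group, 3, 1))
    cens <- runif(120, 0, 150)
    data.frame(time = pmin(t_ev, cens), event = t_ev <= cens, group = group)
  })
  p_lr <- logrank_test(d)$p
  p_cox <- cox_binary(d)$p
  expect_true((p_lr < 0.05) == (p_cox < 0.05))
  expect_lt(p_lr, 0.05)
})
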