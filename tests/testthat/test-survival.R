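test_that("endpoint construction applies exclusions, causes and the cap", {
  co <- simulate_cohort(cohort_config(), seed = 81)
  css <- make_endpoint(co, "css")
  os <- make_endpoint(co, "os")
  expect_identical(nrow(css), 219L)
  expect_identical(attr(css, "n_excluded"), 2L)

  toy <- tiny_cohort(3)
  toy$time_months <- c(40, 130, 25)
  toy$cancer_death <- c(0L, 0L, 1L)
  toy$any_death <- c(1L, 0L, 1L)
  css <- make_endpoint(toy, "css")
  os <- make_endpoint(toy, "os")
  # other-cause death at 40: censored for CSS, event for OS
  expect_identical(css$event[1], 0L)
  expect_identical(os$event[1], 1L)
  expect_identical(css$time_months[1], 40)
  # 130 months of potential follow-up -> capped at 120, censored
  expect_identical(os$time_months[2], 120)
  expect_identical(os$event[2], 0L)
  expect_identical(css$event[3], 1L)

  bad <- toy
  bad$cancer_death[1] <- 1L
  bad$any_death[1] <- 0L
  expect_error(make_endpoint(bad, "css"), "requires any_death")
})

test_that("Kaplan-Meier estimates match hand product-limit computations", {
  no_events <- data.frame(time_months = c(5, 10, 15), event = 0L)
  expect_true(all(km_estimate(no_events)$survival == 1))

  all_events <- data.frame(time_months = c(1, 2, 3), event = 1L)
  expect_equal(km_estimate(all_events)$survival, c(2/3, 1/3, 0))

  mixed <- data.frame(time_months = c(1, 2, 3), event = c(1L, 0L, 1L))
  km <- km_estimate(mixed)
  expect_equal(km$survival[km$time == 1], 2/3)
  expect_equal(km$survival[km$time == 3], 0)  # 2/3 * (1 - 1/1)

  expect_error(km_estimate(data.frame(time_months = c(0, 1),
                                      event = c(1L, 1L))), "positive")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(82)
  t <- round(rexp(40, 0.1), 1) + 0.1
  rec <- data.frame(time_months = t, event = 1L)
  km <- km_estimate(rec)
  ecdf_surv <- sapply(km$time, function(u) mean(t > u))
  expect_equal(km$survival, ecdf_surv, tolerance = 1e-12)
})

# hand log-rank for two groups: loop over distinct event times
brute_logrank <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- sort(unique(group))[1]
  o_minus_e <- 0
  v <- 0
  for (u in sort(unique(time[event == 1]))) {
    at_risk <- time >= u
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(event == 1 & time == u)
    d1 <- sum(event == 1 & time == u & group == g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

test_that("log-rank matches a hand risk-set evaluation and behaves at nulls", {
  # 6-patient toy with an exactly enumerable risk-set history
  time <- c(2, 4, 5, 7, 8, 11)
  event <- c(1L, 1L, 0L, 1L, 1L, 0L)
  group <- factor(c("a", "b", "a", "b", "a", "b"))
  rec <- data.frame(time_months = time, event = event)
  lr <- log_rank(rec, group)
  expect_equal(lr$statistic, brute_logrank(time, event, group),
               tolerance = 1e-8)
  expect_identical(lr$df, 1L)

  # two identical groups -> statistic ~ 0
  rec2 <- data.frame(time_months = rep(c(3, 6, 9), 2),
                     event = rep(c(1L, 0L, 1L), 2))
  lr2 <- log_rank(rec2, factor(rep(c("a", "b"), each = 3)))
  expect_lt(lr2$statistic, 1e-10)
  expect_equal(lr2$p_value, 1, tolerance = 1e-6)

  # complete separation -> significant
  rec3 <- data.frame(time_months = c(1, 2, 3, 10, 10, 10),
                     event = c(1L, 1L, 1L, 0L, 0L, 0L))
  lr3 <- log_rank(rec3, factor(rep(c("a", "b"), each = 3)))
  expect_lt(lr3$p_value, 0.05)

  expect_error(log_rank(rec3, factor(rep("a", 6))), "at least 2")
})

test_that("2-group log-rank equals the Cox score test on tie-free data", {
  set.seed(83)
  t <- sort(rexp(30, 0.1)) + seq(0.001, 0.03, length.out = 30)  # no ties
  rec <- data.frame(time_months = t,
                    event = rbinom(30, 1, 0.8),
                    grp = factor(rep(c("a", "b"), 15)))
  lr <- log_rank(rec, rec$grp)
  cox <- survival::coxph(survival::Surv(time_months, event) ~ grp,
                         data = rec, ties = "breslow")
  expect_equal(lr$statistic, unname(cox$score), tolerance = 1e-6)
})

# brute-force Breslow partial log-likelihood for one binary covariate
brute_pl <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

test_that("Cox estimates match brute-force partial-likelihood maximization", {
  time <- c(3, 5, 6, 8, 10, 12, 14, 17)
  event <- c(1L, 1L, 0L, 1L, 1L, 0L, 1L, 1L)
  x <- c(1, 0, 1, 0, 1, 0, 1, 0)
  rec <- data.frame(time_months = time, event = event, x = x)
  fit <- cox_fit(rec, "x", ties = "breslow")
  beta_hat <- fit$table$coef[fit$table$term == "x"]
  opt <- stats::optimize(function(b) -brute_pl(b, time, event, x),
                         c(-10, 10), tol = 1e-10)
  expect_equal(beta_hat, opt$minimum, tolerance = 1e-6)
  expect_identical(fit$n, 8L)
  expect_identical(fit$n_events, 6)
  expect_true(fit$converged)
})

test_that("Cox inference has the reporting structure of an HR table", {
  set.seed(84)
  n <- 800
  grp <- factor(sample(score_group_levels(), n, TRUE),
                levels = score_group_levels())
  t <- rexp(n, 0.01)
  rec <- data.frame(time_months = pmin(t, 120),
                    event = as.integer(t <= 120), grp = grp)
  fit <- cox_fit(rec, "grp")
  tab <- fit$table
  expect_identical(tab$level, score_group_levels())
  expect_true(tab$referent[1])
  expect_identical(tab$hr[1], 1)
  # covariate independent of hazard: log-HRs within 3.5 SEs of zero
  expect_true(all(abs(tab$coef[-1] / tab$se[-1]) < 3.5))
  expect_true(all(tab$ci_lower[-1] <= tab$hr[-1] &
                  tab$hr[-1] <= tab$ci_upper[-1]))
})

test_that("Cox estimates are invariant to time units and tie method agrees", {
  set.seed(85)
  n <- 300
  x <- rnorm(n)
  t <- rexp(n, 0.02 * exp(0.5 * x)) + seq(1e-5, 3e-3, length.out = n)
  rec <- data.frame(time_months = t, event = rep(1L, n), x = x)
  fit_m <- cox_fit(rec, "x")
  rec_days <- transform(rec, time_months = time_months * 30.44)
  fit_d <- cox_fit(rec_days, "x")
  expect_equal(fit_m$table$coef, fit_d$table$coef, tolerance = 1e-8)

  fit_b <- cox_fit(rec, "x", ties = "breslow")
  expect_lt(abs(fit_b$table$hr / fit_m$table$hr - 1), 0.01)
})

test_that("Cox recovers true hazard ratios across replicates", {
  # mean of beta-hat over seeded replicates within 3 MC standard errors
  set.seed(86)
  for (hr in c(0.5, 1, 2)) {
    betas <- replicate(60, {
      n <- 800
      g <- rbinom(n, 1, 0.5)
      t <- rexp(n, 0.01 * hr^g)
      rec <- data.frame(time_months = pmin(t, 120),
                        event = as.integer(t <= 120), g = g)
      fit <- cox_fit(rec, "g")
      fit$table$coef[fit$table$term == "g"]
    })
    mc_se <- sd(betas) / sqrt(length(betas))
    expect_lt(abs(mean(betas) - log(hr)), 3 * mc_se + 1e-8)
  }
})

test_that("trend test recovers a log-linear effect and detects power", {
  set.seed(87)
  n <- 5000
  grp <- factor(sample(score_group_levels(), n, TRUE),
                levels = score_group_levels())
  code <- as.numeric(grp) - 1
  t <- rexp(n, 0.01 * 0.5^code)  # HR halves per level: exactly log-linear
  rec <- data.frame(time_months = pmin(t, 240),
                    event = as.integer(t <= 240), grp = grp)
  tr <- p_trend(rec, rec$grp)
  expect_lt(tr$p_value, 0.001)
  expect_equal(tr$coef, log(0.5), tolerance = 0.05)

  cat_fit <- cox_fit(rec, "grp")
  expect_equal(cat_fit$table$coef[2], log(0.5), tolerance = 0.1)
  expect_equal(cat_fit$table$coef[3], log(0.25), tolerance = 0.1)
})

test_that("monotone likelihood is flagged as non-convergence", {
  rec <- data.frame(time_months = c(1, 2, 3, 10, 11, 12),
                    event = c(1L, 1L, 1L, 1L, 1L, 1L),
                    x = c(1, 1, 1, 0, 0, 0))
  fit <- suppressWarnings(cox_fit(rec, "x"))
  expect_false(fit$converged)
})
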