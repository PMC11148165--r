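# longsurv: LMM, Kaplan-Meier / log-rank, Cox with brute-force oracle,
# Fisher 2x2, joint model coverage and sign recovery.

test_that("LMM collapses to OLS with no between-subject variance", {
  dat <- withr::with_seed(51, {
    d <- expand.grid(subject_id = paste0("s", 1:30), day = c(1, 5, 9))
    d$y <- 2 - 0.1 * d$day + rnorm(nrow(d), 0, 0.4)  # no subject effect
    d
  })
  fit <- fit_lmm(dat, "y", "day", "subject_id")
  ols <- lm(y ~ day, dat)
  expect_equal(fit$fixed$estimate, unname(coef(ols)), tolerance = 1e-5)
  # unbalanced panels fit without error
  fit2 <- fit_lmm(dat[-c(3, 10, 44, 70), ], "y", "day", "subject_id")
  expect_s3_class(fit2, "lmm_fit")
})

test_that("LMM recovers a longitudinal decline with subject heterogeneity", {
  seeds <- split_seed(52, 10)
  cover <- vapply(seq_len(10), function(r) withr::with_seed(seeds[r], {
    n <- 100
    b <- rnorm(n, 0, 1)
    d <- expand.grid(subject_id = paste0("s", 1:n), day = c(1, 5, 9))
    d$y <- 2 - 0.05 * d$day + b[match(d$subject_id, paste0("s", 1:n))] +
      rnorm(nrow(d), 0, 0.5)
    fit <- fit_lmm(d, "y", "day", "subject_id")
    slope <- fit$fixed[fit$fixed$term == "day", ]
    abs(slope$estimate - (-0.05)) <= 1.96 * slope$se
  }), logical(1))
  expect_gte(mean(cover), 0.8)
})

test_that("Kaplan-Meier matches hand computation and the no-event limit", {
  rec <- data.frame(time = c(1, 2), event = c(1, 1))
  km <- kaplan_meier(rec)
  expect_equal(km$curves$surv, c(0.5, 0))
  rec0 <- data.frame(time = rep(60, 5), event = 0)
  km0 <- kaplan_meier(rec0)
  expect_true(all(km0$curves$surv == 1))
  # no censoring: KM equals the empirical survival function
  tt <- c(5, 10, 20, 40)
  kme <- kaplan_meier(data.frame(time = tt, event = 1))
  expect_equal(kme$curves$surv, 1 - seq_along(tt) / 4)
})

test_that("KM tracks the true exponential curve on simulated data", {
  rec <- withr::with_seed(53, {
    lam <- 0.02; n <- 400
    t_lat <- rexp(n, lam)
    data.frame(time = pmin(t_lat, 60), event = as.integer(t_lat <= 60))
  })
  km <- kaplan_meier(rec)
  s_true <- exp(-0.02 * km$curves$time)
  inside <- s_true >= km$curves$lower & s_true <= km$curves$upper
  expect_gte(mean(inside), 0.9)
})

test_that("log-rank p-values are null-uniform for identical hazards", {
  seeds <- split_seed(54, 200)
  ps <- vapply(seq_len(200), function(r) withr::with_seed(seeds[r], {
    n <- 60
    t_lat <- rexp(n, 0.02)
    rec <- data.frame(time = pmin(t_lat, 60), event = as.integer(t_lat <= 60))
    kaplan_meier(rec, rep(c("a", "b"), each = n / 2))$logrank_p
  }), numeric(1))
  rate <- mean(ps <= 0.05)
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.10)
})

test_that("Cox coefficient matches a brute-force partial-likelihood oracle", {
  # 6 subjects, one binary covariate, no ties
  rec <- data.frame(time = c(2, 4, 6, 8, 10, 12),
                    event = c(1, 1, 0, 1, 1, 0),
                    x = c(1, 1, 0, 0, 1, 0))
  fit <- fit_cox(rec, "x")
  # oracle: maximise the (no-ties) partial likelihood on a fine grid
  pl <- function(beta) {
    ll <- 0
    for (i in which(rec$event == 1)) {
      risk <- rec$time >= rec$time[i]
      ll <- ll + beta * rec$x[i] - log(sum(exp(beta * rec$x[risk])))
    }
    ll
  }
  beta_hat <- stats::optimize(pl, c(-5, 5), maximum = TRUE)$maximum
  expect_equal(fit$coefficients$coef[1], beta_hat, tolerance = 1e-4)
})

test_that("Cox recovers a true hazard ratio of 3 and covers the null", {
  rec <- withr::with_seed(55, {
    n <- 400
    x <- rep(c(0, 1), each = n / 2)
    t_lat <- rexp(n, 0.01 * 3^x)
    data.frame(time = pmin(t_lat, 60), event = as.integer(t_lat <= 60), x = x)
  })
  fit <- fit_cox(rec, "x")
  hr <- fit$coefficients$HR[1]
  expect_gte(hr, 2.0); expect_lte(hr, 4.5)
  expect_true(fit$coefficients$lower[1] < hr & hr < fit$coefficients$upper[1])

  # null covariate: Wald CI covers 1 most of the time
  seeds <- split_seed(56, 40)
  cover <- vapply(seq_len(40), function(r) withr::with_seed(seeds[r], {
    n <- 100
    t_lat <- rexp(n, 0.02)
    rec0 <- data.frame(time = pmin(t_lat, 60),
                       event = as.integer(t_lat <= 60), x = rnorm(n))
    cf <- fit_cox(rec0, "x")$coefficients
    cf$lower[1] < 1 & 1 < cf$upper[1]
  }), logical(1))
  expect_gte(mean(cover), 0.85)
  expect_error(fit_cox(data.frame(time = 1:3, event = 0), "x"), "event")
})

test_that("Fisher association gives sample ORs, Woolf CIs, exact enumeration p", {
  res <- fisher_association(matrix(c(30, 10, 10, 30), 2, byrow = TRUE))
  expect_equal(res$odds_ratio, 9)
  null <- fisher_association(matrix(c(10, 10, 10, 10), 2))
  expect_equal(null$odds_ratio, 1)
  expect_equal(null$p, 1)
  # enumeration oracle for [[8,2],[1,5]]: hypergeometric tail sum
  tab <- matrix(c(8, 2, 1, 5), 2, byrow = TRUE)
  res2 <- fisher_association(tab)
  m <- 8 + 2; n_ <- 1 + 5; k <- 8 + 1
  probs <- dhyper(0:k, m, n_, k)
  p_oracle <- sum(probs[probs <= dhyper(8, m, n_, k) * (1 + 1e-7)])
  expect_equal(res2$p, p_oracle, tolerance = 1e-12)
  # zero cell triggers the Haldane-Anscombe correction
  resz <- fisher_association(matrix(c(5, 0, 2, 7), 2, byrow = TRUE))
  expect_equal(resz$odds_ratio, (5.5 * 7.5) / (0.5 * 2.5))
  expect_error(fisher_association(matrix(1:6, 2)), "2x2")
})

simulate_joint_cohort <- function(n, nu, seed, slope = -0.05, lam0 = 0.01) {
  withr::with_seed(seed, {
    b <- rnorm(n, 0, 1)
    long <- expand.grid(subject_id = paste0("s", 1:n), day = c(1, 5, 9))
    idx <- match(long$subject_id, paste0("s", 1:n))
    long$y <- 2 + slope * long$day + b[idx] + rnorm(nrow(long), 0, 0.5)
    t_lat <- rexp(n, lam0 * exp(nu * b))
    surv <- data.frame(subject_id = paste0("s", 1:n),
                       time = pmin(t_lat, 60),
                       event = as.integer(t_lat <= 60))
    list(long = long, surv = surv)
  })
}

test_that("joint likelihood separates exactly at nu = 0", {
  dat <- simulate_joint_cohort(80, nu = 0, seed = 61)
  jf0 <- fit_joint(dat$long, dat$surv, "y", "day", "subject_id",
                   boot_ci = FALSE)
  # refit with nu pinned to zero via the internal single fit
  pd <- icudysbiosis:::prepare_joint_data(dat$long, dat$surv, "y", "day",
                                          "subject_id", character())
  gh <- icudysbiosis:::gh_nodes(15L)
  f0 <- icudysbiosis:::fit_joint_once(pd, nu_fixed = 0, gh = gh)
  lmm <- fit_lmm(dat$long, "y", "day", "subject_id")
  # exponential survival ML: rate = events / total time (no covariates)
  lam_hat <- sum(dat$surv$event) / sum(dat$surv$time)
  ll_surv <- sum(dat$surv$event * log(lam_hat) - lam_hat * dat$surv$time)
  expect_equal(f0$log_lik, lmm$log_lik + ll_surv, tolerance = 1e-3)
})

test_that("joint model bootstrap CI covers nu = 0 and finds nu = 0.8", {
  seeds <- split_seed(62, 12)
  cover <- vapply(seq_len(12), function(r) {
    dat <- simulate_joint_cohort(120, nu = 0, seed = seeds[r])
    jf <- fit_joint(dat$long, dat$surv, "y", "day", "subject_id",
                    n_boot = 40, seed = seeds[r])
    jf$nu_ci[1] <= 0 && 0 <= jf$nu_ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.8)

  signs <- vapply(seq_len(8), function(r) {
    dat <- simulate_joint_cohort(150, nu = 0.8, seed = 7000 + r)
    jf <- fit_joint(dat$long, dat$surv, "y", "day", "subject_id",
                    boot_ci = FALSE)
    jf$nu > 0
  }, logical(1))
  expect_true(all(signs))
})

test_that("joint fits are reproducible under a fixed seed", {
  dat <- simulate_joint_cohort(60, nu = 0.5, seed = 63)
  j1 <- fit_joint(dat$long, dat$surv, "y", "day", "subject_id",
                  n_boot = 10, seed = 9)
  j2 <- fit_joint(dat$long, dat$surv, "y", "day", "subject_id",
                  n_boot = 10, seed = 9)
  expect_identical(j1$nu, j2$nu)
  expect_identical(j1$nu_ci, j2$nu_ci)
})

test_that("persister contrast feeds an age-adjusted Cox model", {
  rec <- withr::with_seed(64, {
    n <- 120
    persist <- rbinom(n, 1, 0.3)
    t_lat <- rexp(n, 0.008 * exp(log(2.5) * persist))
    data.frame(subject_id = paste0("s", 1:n),
               time = pmin(t_lat, 60), event = as.integer(t_lat <= 60),
               age = round(rnorm(n, 60, 10)),
               label_baseline = ifelse(persist == 1, "Low",
                                       sample(c("High", "Intermediate"), n,
                                              replace = TRUE)),
               label_middle = ifelse(persist == 1, "Low",
                                     sample(c("High", "Intermediate", "Low"),
                                            n, replace = TRUE, prob = c(.45, .45, .1))))
  })
  fit <- persister_cox(rec)
  hr <- fit$coefficients$HR[fit$coefficients$term == "persister"]
  expect_gt(hr, 1)
})
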