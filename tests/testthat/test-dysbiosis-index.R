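# Dysbiosis Index: closed-form prediction against the published models,
# feature selection, multinomial fitting, accuracy evaluation.

test_that("closed-form prediction reproduces direct evaluation of the logits", {
  oral <- load_paper_model("oral")
  # all features zero: X = e^b10, Y = e^b20 directly
  f0 <- setNames(rep(0, length(oral$feature_names)), oral$feature_names)
  pr <- predict(oral, f0)
  X <- exp(3.639385); Y <- exp(15.535322)
  expect_equal(pr$P_low, Y / (1 + X + Y), tolerance = 1e-12)
  expect_equal(pr$P_high, 1 / (1 + X + Y), tolerance = 1e-12)
  expect_gt(pr$P_low, 0.99999)
  expect_identical(pr$label, "Low")

  lung <- load_paper_model("lung")
  fl <- setNames(rep(0, length(lung$feature_names)), lung$feature_names)
  fl["ShannonIndex"] <- 4
  prl <- predict(lung, fl)
  Xl <- exp(6.314866 - 2.064372 * 4); Yl <- exp(11.631919 - 3.663621 * 4)
  expect_equal(prl$P_high, 1 / (1 + Xl + Yl), tolerance = 1e-12)
  expect_equal(prl$P_high, 0.839, tolerance = 0.001)
  expect_identical(prl$label, "High")
})

test_that("probabilities normalise and agree with brute-force logits on random inputs", {
  seeds <- split_seed(99, 3L)
  for (comp in c("oral", "lung", "gut")) {
    m <- load_paper_model(comp)
    n_f <- length(m$feature_names)
    F_ <- withr::with_seed(seeds[match(comp, c("oral", "lung", "gut"))], {
      M <- matrix(runif(200 * n_f, -5, 5), 200, n_f,
                  dimnames = list(NULL, m$feature_names))
      if ("ShannonIndex" %in% m$feature_names)
        M[, "ShannonIndex"] <- runif(200, 0, 5)
      M
    })
    pr <- predict(m, F_)
    expect_true(all(abs(pr$P_high + pr$P_intermediate + pr$P_low - 1) < 1e-12))
    # independent brute-force arithmetic, no log-sum-exp
    b1 <- m$b1; b2 <- m$b2
    X <- exp(b1[["Intercept"]] + F_ %*% b1[m$feature_names])
    Y <- exp(b2[["Intercept"]] + F_ %*% b2[m$feature_names])
    expect_equal(pr$P_low, drop(Y / (1 + X + Y)), tolerance = 1e-12)
    expect_equal(pr$P_intermediate, drop(X / (1 + X + Y)), tolerance = 1e-12)
  }
})

test_that("prediction is pure, name-matched, and strict about inputs", {
  m <- load_paper_model("gut")
  f <- setNames(seq_along(m$feature_names) / 10, m$feature_names)
  p1 <- predict(m, f)
  p2 <- predict(m, rev(f))          # reordering with names is irrelevant
  expect_identical(p1, p2)
  expect_error(predict(m, f[-1]), "missing model feature")
  expect_equal(predict(m, f[-1], fill_missing = TRUE),
               predict(m, replace(f, 1, 0)), tolerance = 1e-15)
  f_bad <- f; f_bad[2] <- NaN
  expect_error(predict(m, f_bad), "NaN")
  # extreme logits do not overflow
  f_big <- setNames(rep(1e4, length(f)), names(f))
  pr <- predict(m, f_big)
  expect_true(all(is.finite(as.matrix(pr[1:3]))))
  expect_equal(sum(pr[1, 1:3]), 1, tolerance = 1e-12)
})

test_that("monotonicity: raising a feature with b2 > b1 > 0 raises P(L)/P(H)", {
  b1 <- c(Intercept = 0.2, f1 = 0.5, f2 = -0.3)
  b2 <- c(Intercept = -0.1, f1 = 1.5, f2 = 0.2)
  m <- new_dysbiosis_index_model("lung", c("f1", "f2"), b1, b2)
  grid <- seq(-3, 3, length.out = 25)
  pr <- predict(m, cbind(f1 = grid, f2 = 0))
  ratio <- pr$P_low / pr$P_high
  expect_true(all(diff(ratio) > 0))
})

test_that("stability selection keeps separating features and drops noise", {
  n <- 120
  labels <- rep(c("High", "Intermediate", "Low"), each = n / 3)
  F_ <- withr::with_seed(314, {
    signal <- rep(c(-3, 0, 3), each = n / 3) + rnorm(n, 0, 0.3)
    noise <- matrix(rnorm(n * 20), n)
    colnames(noise) <- paste0("noise", 1:20)
    cbind(signal = signal, noise)
  })
  sel1 <- select_features(F_, labels, seed = 5)
  sel2 <- select_features(F_, labels, seed = 5)
  expect_identical(sel1, sel2)                   # deterministic given seed
  expect_true("signal" %in% sel1)                # perfect separator always kept
  n_noise <- sum(grepl("^noise", sel1))
  expect_lte(n_noise, 2L)                        # false positives are rare
  expect_error(select_features(F_, rep("a", n)), "3 classes")
})

test_that("fit_mlr recovers known coefficients and validates its design", {
  # simulate from a known 3-class multinomial logit; average estimates over
  # replicates so Monte-Carlo error shrinks below the check tolerance
  b1 <- c(0.5, 1.0, -0.5)   # intercept, f1, f2 (Intermediate vs High)
  b2 <- c(-0.5, -1.0, 1.5)  # Low vs High
  sim_one <- function(seed, n = 1000) withr::with_seed(seed, {
    F_ <- cbind(f1 = rnorm(n), f2 = rnorm(n))
    eta1 <- b1[1] + F_ %*% b1[2:3]
    eta2 <- b2[1] + F_ %*% b2[2:3]
    P <- cbind(1, exp(eta1), exp(eta2))
    P <- P / rowSums(P)
    y <- apply(P, 1, function(p) sample(c("High", "Intermediate", "Low"), 1,
                                        prob = p))
    list(F_ = F_, y = y)
  })
  ests <- vapply(1:10, function(r) {
    dat <- sim_one(2700 + r)
    m <- fit_mlr(dat$F_, dat$y, compartment = "oral")
    c(m$b1[c("f1", "f2")], m$b2[c("f1", "f2")])
  }, numeric(4))
  expect_equal(unname(rowMeans(ests)), c(b1[2:3], b2[2:3]), tolerance = 0.1)

  dat <- sim_one(2718)
  expect_error(fit_mlr(dat$F_, rep("High", 1000)), "3 classes")
  F_bad <- cbind(dat$F_, f3 = dat$F_[, "f1"] * 2)
  expect_error(fit_mlr(F_bad, dat$y), "collinear.*f3")
})

test_that("uninformative features give intercept-only class frequencies", {
  n <- 300
  y <- rep(c("High", "Intermediate", "Low"), times = c(150, 100, 50))
  F_ <- withr::with_seed(11, cbind(f1 = rnorm(n)))
  m <- fit_mlr(F_, y)
  pr <- predict(m, F_)
  freq <- colMeans(as.matrix(pr[, 1:3]))
  expect_equal(unname(freq[c("P_high", "P_intermediate", "P_low")]),
               c(150, 100, 50) / n, tolerance = 0.02)
})

test_that("accuracy evaluation gives exact binomial CIs and confusion matrices", {
  m <- load_paper_model("lung")
  F_ <- matrix(0, 4, length(m$feature_names),
               dimnames = list(NULL, m$feature_names))
  F_[, "ShannonIndex"] <- c(5, 5, 0, 0)   # two clear High, two clear Low
  res <- evaluate_accuracy(m, F_, c("High", "High", "Low", "Low"))
  expect_equal(res$accuracy, 1)
  expect_equal(res$ci[2], 1)
  res0 <- evaluate_accuracy(m, F_, c("Low", "Low", "High", "High"))
  expect_equal(res0$accuracy, 0)
  expect_error(evaluate_accuracy(m, F_[0, ], character()), "empty")
})

test_that("train/test split is stratified and reproducible", {
  labels <- rep(c("High", "Intermediate", "Low"), times = c(100, 60, 40))
  s1 <- split_train_test(labels, 0.2, seed = 4)
  s2 <- split_train_test(labels, 0.2, seed = 4)
  expect_identical(s1, s2)
  expect_length(s1$test, 40L)
  expect_equal(as.numeric(table(labels[s1$test])), c(20, 12, 8))
  expect_length(intersect(s1$train, s1$test), 0L)
})
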