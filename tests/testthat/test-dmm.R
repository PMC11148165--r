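# DMM: EM fitting, parameter recovery, Laplace evidence, K selection,
# diversity labeling.

test_that("fit_dmm recovers a single symmetric Dirichlet component", {
  al <- matrix(5, 1, 10, dimnames = list("c1", paste0("t", 1:10)))
  sim <- simulate_dmm_counts(al, 1, 500, c(5000, 5000), seed = 11)
  fit <- fit_dmm(sim$table, 1, n_init = 1, seed = 2)
  expect_true(fit$fit_info$converged)
  # each alpha within 10% relative error
  expect_true(all(abs(fit$alpha - 5) / 5 < 0.10))
  # mean relative abundance near 1/10 by symmetry
  expect_true(all(abs(colMeans(relative_abundance(sim$table)) - 0.1) < 0.01))
})

test_that("fit_dmm is deterministic and its EM log-likelihood is monotone", {
  sim <- fixture_sep3()
  expect_no_warning(f1 <- fit_dmm(sim$table, 3, n_init = 2, seed = 5))
  f2 <- fit_dmm(sim$table, 3, n_init = 2, seed = 5)
  expect_identical(f1$alpha, f2$alpha)
  expect_identical(f1$responsibilities, f2$responsibilities)
  expect_equal(sum(f1$weights), 1, tolerance = 1e-9)
  expect_true(all(abs(rowSums(f1$responsibilities) - 1) < 1e-9))
  expect_error(fit_dmm(sim$table, nrow(sim$table) + 1), "exceeds")
})

test_that("separated 3-component fixture is recovered almost perfectly", {
  sim <- fixture_sep3()
  fit <- fit_dmm(sim$table, 3, n_init = 2, seed = 5)
  hard <- dmm_assignments(fit)
  expect_gt(rand_index(hard, sim$labels), 0.95)
  # responsibilities are confident for >95% of samples
  expect_gt(mean(apply(fit$responsibilities, 1, max) > 0.95), 0.95)
})

test_that("Laplace evidence matches a numerical-Hessian oracle at K = 1", {
  skip_if_not_installed("pracma")
  al <- matrix(c(4, 2, 1, 0.5, 0.5), 1, 5,
               dimnames = list("c1", paste0("t", 1:5)))
  sim <- simulate_dmm_counts(al, 1, 40, c(200, 400), seed = 21)
  fit <- fit_dmm(sim$table, 1, n_init = 1, seed = 3, tol = 1e-10)
  ev_analytic <- laplace_log_evidence(fit, sim$table)
  # oracle: numerically differentiate the log posterior in log-alpha space
  X <- unclass(sim$table); storage.mode(X) <- "double"
  f <- function(eta) {
    a <- matrix(exp(eta), 1)
    sum(icudysbiosis:::dirmult_loglik_matrix(X, a)) +
      sum(dnorm(eta, 0, 3, log = TRUE))
  }
  eta_hat <- log(fit$alpha[1, ])
  H_num <- pracma::hessian(f, eta_hat)
  ld <- determinant(-H_num, logarithm = TRUE)
  ev_num <- f(eta_hat) + (5 / 2) * log(2 * pi) - as.numeric(ld$modulus) / 2
  expect_equal(ev_analytic, ev_num, tolerance = 1e-4)
})

test_that("evidence is invariant to component relabeling and peaks at K_true", {
  sim <- fixture_sep3()
  fit3 <- fit_dmm(sim$table, 3, n_init = 2, seed = 5)
  ev3 <- laplace_log_evidence(fit3, sim$table)
  perm <- c(3, 1, 2)
  fit_perm <- fit3
  fit_perm$alpha <- fit3$alpha[perm, ]
  fit_perm$weights <- fit3$weights[perm]
  fit_perm$responsibilities <- fit3$responsibilities[, perm]
  expect_equal(laplace_log_evidence(fit_perm, sim$table), ev3,
               tolerance = 1e-6)
  fit1 <- fit_dmm(sim$table, 1, n_init = 1, seed = 5)
  ev1 <- laplace_log_evidence(fit1, sim$table)
  fit5 <- suppressWarnings(fit_dmm(sim$table, 5, n_init = 2, seed = 5))
  ev5 <- tryCatch(laplace_log_evidence(fit5, sim$table),
                  error = function(e) -Inf)  # singular Hessian = overfit
  expect_gt(ev3, ev1)
  expect_gt(ev3, ev5)
})

test_that("select_k applies evidence and the 10% prevalence rule", {
  sim <- fixture_sep3()
  best <- select_k(sim$table, K_max = 4, seed = 7, n_init = 2)
  expect_identical(best$K, 3L)
  expect_true(all(best$selection$min_prevalence[best$selection$admissible] >= 0.10))

  # 1-component data select K = 1
  al1 <- matrix(3, 1, 20, dimnames = list("c1", paste0("t", 1:20)))
  sim1 <- simulate_dmm_counts(al1, 1, 120, c(1000, 3000), seed = 31)
  best1 <- suppressWarnings(select_k(sim1$table, K_max = 3, seed = 7, n_init = 2))
  expect_identical(best1$K, 1L)

  # a 5%-weight component cannot support its own cluster under the rule
  al2 <- separated_alpha_matrix(2, 20, block_mass = 0.8)
  sim2 <- simulate_dmm_counts(al2, c(0.95, 0.05), 200, c(1000, 3000), seed = 41)
  fit2 <- fit_dmm(sim2$table, 2, n_init = 2, seed = 7)
  prev2 <- min(tabulate(dmm_assignments(fit2), 2)) / 200
  expect_lt(prev2, 0.10)
})

test_that("model selection recovers K_true across replicate cohorts", {
  for (K_true in 1:3) {
    hits <- vapply(1:4, function(r) {
      al <- separated_alpha_matrix(max(K_true, 1), 20, block_mass = 0.7)
      w <- rep(1 / K_true, K_true)
      sim <- simulate_dmm_counts(al[seq_len(K_true), , drop = FALSE], w, 120,
                                 c(1000, 3000), seed = 500 + 10 * K_true + r)
      best <- suppressWarnings(
        select_k(sim$table, K_max = 4, seed = r, n_init = 2))
      best$K == K_true
    }, logical(1))
    expect_true(all(hits), label = paste("K_true =", K_true))
  }
})

test_that("label_clusters orders components by member diversity", {
  sim <- fixture_graded3()
  fit <- fit_dmm(sim$table, 3, n_init = 2, seed = 9)
  sh <- shannon_table(sim$table, reps = 20, seed = 13)
  shv <- setNames(sh$mean_shannon, sh$sample_id)
  lab <- label_clusters(fit, shv)
  expect_setequal(unname(lab$component_labels), c("High", "Intermediate", "Low"))
  m <- lab$mean_shannon
  expect_identical(names(which.max(m)),
                   names(lab$component_labels)[lab$component_labels == "High"])
  # permuting component indices leaves sample labels unchanged
  perm <- c(2, 3, 1)
  fitp <- fit
  fitp$alpha <- fit$alpha[perm, ]
  fitp$weights <- fit$weights[perm]
  fitp$responsibilities <- fit$responsibilities[, perm]
  labp <- label_clusters(fitp, shv)
  expect_identical(labp$sample_labels, lab$sample_labels)
  # graded fixture: Low cluster is dominated by the last (pathogen) block
  low_samples <- names(lab$sample_labels)[lab$sample_labels == "Low"]
  rel <- relative_abundance(sim$table)
  block_low <- paste0(sprintf("taxon_%02d", 11:15))
  high_samples <- names(lab$sample_labels)[lab$sample_labels == "High"]
  expect_gt(mean(rel[low_samples, block_low]), mean(rel[high_samples, block_low]))
})

test_that("hand-set component means map to High/Intermediate/Low", {
  R <- diag(3)[rep(1:3, each = 2), ]
  rownames(R) <- paste0("s", 1:6)
  fake <- structure(list(K = 3L, alpha = matrix(1, 3, 4), weights = rep(1/3, 3),
                         responsibilities = R,
                         fit_info = list(converged = TRUE)),
                    class = "dmm_model")
  shannon <- c(3.1, 3.1, 2.0, 2.0, 0.8, 0.8)
  names(shannon) <- paste0("s", 1:6)
  lab <- label_clusters(fake, shannon)
  expect_identical(unname(lab$component_labels),
                   c("High", "Intermediate", "Low"))
})
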