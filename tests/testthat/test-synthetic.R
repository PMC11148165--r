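# synthetic_cohort: generative contracts, determinism, convergence to the
# configured mixture, outcome and dropout structure.

test_that("symmetric single-component counts have uniform mean composition", {
  al <- matrix(50, 1, 10, dimnames = list("c1", paste0("t", 1:10)))
  sim <- simulate_dmm_counts(al, 1, 200, c(5000, 5000), seed = 71)
  expect_true(all(abs(colMeans(relative_abundance(sim$table)) - 0.1) < 0.01))
})

test_that("identical seeds give bit-identical tables, different seeds differ", {
  al <- separated_alpha_matrix(2, 12)
  s1 <- simulate_dmm_counts(al, c(0.5, 0.5), 50, c(1000, 2000), seed = 72)
  s2 <- simulate_dmm_counts(al, c(0.5, 0.5), 50, c(1000, 2000), seed = 72)
  s3 <- simulate_dmm_counts(al, c(0.5, 0.5), 50, c(1000, 2000), seed = 73)
  expect_identical(unclass(s1$table), unclass(s2$table))
  expect_identical(s1$labels, s2$labels)
  expect_false(identical(unclass(s1$table), unclass(s3$table)))
})

test_that("generator rejects invalid parameters", {
  al <- separated_alpha_matrix(2, 12)
  expect_error(simulate_dmm_counts(al * -1, c(0.5, 0.5), 10, c(100, 200)),
               "positive")
  expect_error(simulate_dmm_counts(al[0, , drop = FALSE], numeric(0), 10,
                                   c(100, 200)), "at least one component")
  expect_error(simulate_dmm_counts(al, c(0.6, 0.6), 10, c(100, 200)),
               "simplex")
  expect_error(simulate_dmm_counts(al, c(0.5, 0.5), 10, c(0, 200)), "depth")
})

test_that("component frequencies and compositions converge to the configuration", {
  al <- separated_alpha_matrix(3, 20, block_mass = 0.7)
  w <- c(0.5, 0.3, 0.2)
  sim <- simulate_dmm_counts(al, w, 1000, c(2000, 4000), seed = 74)
  freq <- tabulate(sim$labels, 3) / 1000
  se <- sqrt(w * (1 - w) / 1000)
  expect_true(all(abs(freq - w) <= 3 * se))
  # per-component mean composition near alpha_k / sum(alpha_k)
  rel <- relative_abundance(sim$table)
  for (k in 1:3) {
    target <- al[k, ] / sum(al[k, ])
    got <- colMeans(rel[sim$labels == k, , drop = FALSE])
    expect_lt(max(abs(got - target)), 0.02)
  }
})

test_that("outcome generator honors hazards, censoring and dropout", {
  # zero hazard: everyone censored at day 60, all visits attendable
  out0 <- simulate_outcomes(rep(1:3, 50), 0, c(1, 1, 1), seed = 75)
  expect_true(all(out0$time == 60) && all(out0$event == 0))
  expect_true(all(out0$attend_baseline))

  # hazard multiplier 3: Cox recovers an HR in [2, 4.5]
  labels <- rep(c(1, 2), each = 200)
  out <- simulate_outcomes(labels, 0.01, c(1, 3), seed = 76)
  rec <- data.frame(time = out$time, event = out$event,
                    x = as.integer(out$cluster == 2))
  hr <- fit_cox(rec, "x")$coefficients$HR[1]
  expect_gte(hr, 2.0); expect_lte(hr, 4.5)
  expect_error(simulate_outcomes(1:3, -0.1, c(1, 1, 1)), "non-negative")

  # informative dropout: high-risk cluster loses more follow-up visits
  outd <- simulate_outcomes(rep(1:2, each = 300), 0.005, c(1, 4),
                            dropout_logit = list(intercept = -1.5,
                                                 cluster = c(0, 0.8),
                                                 latent_time = 1.5),
                            seed = 77)
  attend_mid <- tapply(outd$attend_middle, outd$cluster, mean)
  expect_lt(attend_mid[["2"]], attend_mid[["1"]])
})

test_that("log-rank rejection rate is nominal when multipliers are equal", {
  seeds <- split_seed(78, 100)
  ps <- vapply(seq_len(100), function(r) {
    out <- simulate_outcomes(rep(1:2, each = 100), 0.01, c(1, 1),
                             seed = seeds[r])
    kaplan_meier(data.frame(time = out$time, event = out$event),
                 out$cluster)$logrank_p
  }, numeric(1))
  rate <- mean(ps <= 0.05)
  expect_gte(rate, 0.01); expect_lte(rate, 0.11)
})

test_that("KM of the all-ones cohort tracks exp(-hazard * t)", {
  out <- simulate_outcomes(rep(1, 500), 0.01, 1, seed = 79)
  km <- kaplan_meier(data.frame(time = out$time, event = out$event))
  s_true <- exp(-0.01 * km$curves$time)
  inside <- s_true >= km$curves$lower & s_true <= km$curves$upper
  expect_gte(mean(inside), 0.9)
})

test_that("simulate_cohort writes all structural invariants", {
  cfg <- sim_config(seed = 80, n_subjects = 40, depth_range = c(1000, 3000))
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$tables$lung, co2$tables$lung)   # end-to-end reproducible
  expect_identical(co1$outcomes$gut, co2$outcomes$gut)

  md <- co1$metadata
  expect_true(all(md$sample_id %in% names(co1$true_labels)))
  expect_true(all(co1$true_labels %in% 1:3))
  expect_true(all(md$interval %in% c("baseline", "middle", "late")))
  for (comp in c("oral", "lung", "gut")) {
    tab <- co1$tables[[comp]]
    expect_true(all(rownames(tab) %in% md$sample_id))
    # every sample references an existing subject
    subj <- md$subject_id[match(rownames(tab), md$sample_id)]
    expect_true(all(subj %in% co1$outcomes[[comp]]$subject_id))
    # sample count = attended visits
    att <- paste0("attend_", c("baseline", "middle", "late"))
    expect_identical(nrow(tab), sum(as.matrix(co1$outcomes[[comp]][, att])))
    # depth_range min 1000: every sample passes the >= 1000-read QC
    expect_true(all(rowSums(tab) >= 1000))
  }
})

test_that("zero dropout and zero hazard give subjects x visits samples", {
  cfg <- sim_config(seed = 81, n_subjects = 30, baseline_hazard = 0,
                    dropout_logit = NULL)
  co <- simulate_cohort(cfg)
  for (comp in c("oral", "lung", "gut"))
    expect_identical(nrow(co$tables[[comp]]), 90L)
})

test_that("biomarkers correlate with pathogen-class abundance as loaded", {
  cfg <- sim_config(seed = 82, n_subjects = 80, noise_sd = 0.5)
  co <- simulate_cohort(cfg)
  base_ids <- co$metadata$sample_id[co$metadata$compartment == "lung" &
                                    co$metadata$interval == "baseline"]
  counts <- unclass(co$tables$lung)[base_ids, ]
  pathogens <- co$annotations$taxon_id[co$annotations$pathogenicity_class ==
                                         "respiratory_pathogen"]
  clr_path <- icudysbiosis:::clr_class_pathogen(counts, pathogens)
  subj <- co$metadata$subject_id[match(base_ids, co$metadata$sample_id)]
  bm <- co$biomarkers[subj, "sTNFR1"]
  expect_gt(cor(clr_path, bm), 0.8)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(mixing_weights = c(0.5, 0.5)), "simplex")
  expect_error(sim_config(depth_range = c(0, 100)), "depth_range")
  expect_error(sim_config(censor_day = 0), "censor_day")
  al <- separated_alpha_matrix(3, 50)
  al[1, 1] <- -1
  expect_error(sim_config(alpha_matrix = al), "> 0")
})
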