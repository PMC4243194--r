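test_that("site summaries reproduce counts, continuity and weights", {
  # a 139/508 site: prevalence is exactly n1/n
  rows <- c(lapply(1:139, function(i) new_rec(cc_other_partner = "yes",
                                              sex = "male")),
            lapply(1:369, function(i) new_rec(cc_other_partner = "no",
                                              sex = "male")),
            lapply(1:50, function(i) new_rec(site_id = "sB", arm = "control",
                                             ea_id = "sB_ea1", sex = "male",
                                             cc_other_partner = "no")),
            list(new_rec(site_id = "sB", arm = "control", ea_id = "sB_ea1",
                         sex = "male", cc_other_partner = "yes")))
  ds <- crt_dataset(make_records(rows))
  s <- summarize_sites(ds, default_outcome_specs()$concurrency)
  sA <- s[s$site_id == "sA", ]
  expect_equal(sA$n1, 139)
  expect_equal(sA$n, 508)
  expect_equal(sA$p, 139 / 508)
  expect_equal(round(sA$p, 4), 0.2736)
  expect_false(sA$continuity_applied)
  # weight = n p / (1 - p), computed independently
  expect_equal(sA$weight, 508 * (139 / 508) / (1 - 139 / 508))
})

test_that("zero-event sites get the 0.5 continuity correction", {
  rows <- c(lapply(1:100, function(i) new_rec(pv_slap = "no", pv_push = "no",
    pv_fist = "no", pv_kick = "no", pv_choke = "no", pv_weapon = "no",
    pv_panga = "no")),
    lapply(1:20, function(i) new_rec(site_id = "sB", arm = "control",
      ea_id = "sB_ea1", pv_slap = if (i == 1) "yes" else "no",
      pv_push = "no", pv_fist = "no", pv_kick = "no", pv_choke = "no",
      pv_weapon = "no", pv_panga = "no")))
  ds <- crt_dataset(make_records(rows))
  s <- summarize_sites(ds, default_outcome_specs()$physical_ipv)
  sA <- s[s$site_id == "sA", ]
  expect_true(sA$continuity_applied)
  expect_equal(sA$n1, 0)
  expect_equal(sA$log_prev, log(0.5 / 100))
})

test_that("degenerate sites are reported by name", {
  rows <- list(new_rec(sex = "female"),
               new_rec(site_id = "sB", arm = "control", ea_id = "sB_ea1",
                       sex = "male", cc_other_partner = "yes"))
  ds <- crt_dataset(make_records(rows))
  expect_error(summarize_sites(ds, default_outcome_specs()$concurrency),
               "degenerate site.*sA")
})

test_that("compute_weight formula and error cases", {
  expect_equal(compute_weight(100, 0.5), 100)
  expect_equal(compute_weight(508, 0.2736), 508 * 0.2736 / (1 - 0.2736),
               tolerance = 1e-12)
  expect_equal(round(compute_weight(508, 0.2736), 1), 191.3)
  expect_error(compute_weight(100, 1), "outside \\(0, 1\\)")
  expect_error(compute_weight(100, 0), "outside \\(0, 1\\)")
})

test_that("crude effect matches the brute-force WLS oracle (2- and 3-pair)", {
  # fixed 2-pair toy
  s <- toy_summaries(p = c(0.2, 0.4, 0.1, 0.3), n = rep(100, 4),
                     pair_id = c("p1", "p1", "p2", "p2"),
                     arm = rep(c("intervention", "control"), 2))
  eff <- crude_effect(s)
  o <- wls_oracle(s$log_prev, s$arm, s$pair_id, s$weight)
  expect_equal(eff$rr, o$rr, tolerance = 1e-10)
  expect_equal(eff$ci_low, o$ci_low, tolerance = 1e-10)
  expect_equal(eff$ci_high, o$ci_high, tolerance = 1e-10)
  expect_equal(eff$df, o$df)
  # randomized instances, 2 and 3 pairs
  set.seed(99)
  for (P in c(2, 3)) {
    for (rep in 1:10) {
      p <- runif(2 * P, 0.05, 0.9)
      n <- sample(50:500, 2 * P, replace = TRUE)
      s <- toy_summaries(p, n, pair_id = rep(paste0("p", 1:P), each = 2),
                         arm = rep(c("intervention", "control"), P))
      eff <- crude_effect(s)
      o <- wls_oracle(s$log_prev, s$arm, s$pair_id, s$weight)
      expect_equal(eff$rr, o$rr, tolerance = 1e-10)
      expect_equal(eff$ci_low, o$ci_low, tolerance = 1e-10)
      expect_equal(eff$residual_variance, o$sigma2, tolerance = 1e-10)
    }
  }
})

test_that("identical sites give rr = 1 with zero residual variance", {
  s <- toy_summaries(p = rep(0.3, 8), n = rep(200, 8),
                     pair_id = rep(paste0("p", 1:4), each = 2),
                     arm = rep(c("intervention", "control"), 4))
  eff <- crude_effect(s)
  expect_equal(eff$rr, 1, tolerance = 1e-12)
  expect_equal(eff$residual_variance, 0, tolerance = 1e-12)
  expect_equal(eff$df, 3)  # 2P - P - 1 with P = 4
})

test_that("fewer than two pairs is an error", {
  s <- toy_summaries(p = c(0.2, 0.3), n = c(100, 100),
                     pair_id = c("p1", "p1"),
                     arm = c("intervention", "control"))
  expect_error(crude_effect(s), "insufficient pairs")
})

test_that("estimator invariances: pair relabeling, arm swap, weight scale", {
  set.seed(7)
  p <- runif(8, 0.1, 0.6)
  s <- toy_summaries(p, n = sample(100:400, 8, replace = TRUE),
                     pair_id = rep(paste0("p", 1:4), each = 2),
                     arm = rep(c("intervention", "control"), 4))
  base <- crude_effect(s)
  # permute pair labels
  s2 <- s
  s2$pair_id <- c(p1 = "zz", p2 = "aa", p3 = "mm", p4 = "bb")[s2$pair_id]
  eff2 <- crude_effect(s2)
  expect_equal(eff2$rr, base$rr, tolerance = 1e-12)
  expect_equal(eff2$ci_low, base$ci_low, tolerance = 1e-12)
  # swap arms: rr -> 1/rr, CI reverses
  s3 <- s
  s3$arm <- ifelse(s3$arm == "intervention", "control", "intervention")
  eff3 <- crude_effect(s3)
  expect_equal(eff3$rr, 1 / base$rr, tolerance = 1e-12)
  expect_equal(eff3$ci_low, 1 / base$ci_high, tolerance = 1e-12)
  expect_equal(eff3$ci_high, 1 / base$ci_low, tolerance = 1e-12)
  # rescale all weights
  s4 <- s
  s4$weight <- s4$weight * 7.3
  eff4 <- crude_effect(s4)
  expect_equal(eff4$rr, base$rr, tolerance = 1e-12)
  expect_equal(eff4$ci_low, base$ci_low, tolerance = 1e-12)
  expect_equal(eff4$ci_high, base$ci_high, tolerance = 1e-12)
})

test_that("control model: intercept-only behaviour and coefficient recovery", {
  set.seed(21)
  n <- 2000
  age <- sample(18:49, n, replace = TRUE)
  # outcome generated from a known logistic model with beta_age = 0.05
  eta <- -2 + 0.05 * age
  y <- runif(n) < plogis(eta)
  rows <- lapply(seq_len(n), function(i) {
    new_rec(arm = "control", site_id = "sB", ea_id = "sB_ea1",
            age = age[i], rs_refuse = ifelse(y[i], "yes", "no"))
  })
  rows[[n + 1]] <- new_rec(rs_refuse = "no")  # completes the pair
  ds <- crt_dataset(make_records(rows))
  bp <- c(sA_ea1 = 0.3, sB_ea1 = 0.3)
  m <- fit_control_model(ds, default_outcome_specs()$accept_refuse_sex, bp)
  expect_equal(unname(m$coef["age"]), 0.05, tolerance = 0.02)
  # outcome independent of covariates: predictions sit near the prevalence
  y2 <- runif(n) < 0.3
  rows2 <- lapply(seq_len(n), function(i) {
    new_rec(arm = "control", site_id = "sB", ea_id = "sB_ea1",
            age = age[i], rs_refuse = ifelse(y2[i], "yes", "no"))
  })
  rows2[[n + 1]] <- new_rec(rs_refuse = "no")
  ds2 <- crt_dataset(make_records(rows2))
  m2 <- fit_control_model(ds2, default_outcome_specs()$accept_refuse_sex, bp)
  preds <- m2$predict(as.data.frame(ds2)[ds2$arm == "control", ])
  expect_true(all(abs(preds - mean(y2)) < 0.08))
  # a constant EA baseline prevalence (0.57 everywhere) is accepted as a
  # continuous covariate and behaves as intercept-only for that term
  m3 <- fit_control_model(ds2, default_outcome_specs()$accept_refuse_sex,
                          c(sA_ea1 = 0.57, sB_ea1 = 0.57))
  preds3 <- m3$predict(as.data.frame(ds2)[ds2$arm == "control", ])
  expect_true(all(is.finite(preds3)))
  expect_true(all(abs(preds3 - mean(y2)) < 0.08))
})

test_that("control model rejects constant outcomes (separation)", {
  rows <- lapply(1:50, function(i) {
    new_rec(arm = "control", site_id = "sB", ea_id = "sB_ea1",
            rs_refuse = "yes")
  })
  rows[[51]] <- new_rec(rs_refuse = "no")
  ds <- crt_dataset(make_records(rows))
  expect_error(
    fit_control_model(ds, default_outcome_specs()$accept_refuse_sex,
                      c(sA_ea1 = 0.3, sB_ea1 = 0.3)),
    "separation")
})

test_that("adjusted effect agrees with the WLS oracle on its own O/E table", {
  ds <- simulate_trial(sim_config(n_followup = 80, n_baseline = 60,
                                  outcomes = default_sim_outcomes()["physical_ipv"]),
                       13)
  eff <- adjusted_effect(ds, default_outcome_specs()$physical_ipv)
  oe <- attr(eff, "oe")
  o <- wls_oracle(oe$log_ratio, oe$arm, oe$pair_id, oe$weight)
  expect_equal(eff$rr, o$rr, tolerance = 1e-10)
  expect_equal(eff$ci_low, o$ci_low, tolerance = 1e-10)
  expect_equal(eff$ci_high, o$ci_high, tolerance = 1e-10)
  expect_equal(eff$df, 3)
  expect_true(all(oe$ratio == ifelse(oe$continuity_applied, 0.5, oe$observed) /
                    oe$expected))
})

test_that("null effect with a calibrated model gives rr near 1", {
  cfg <- sim_config(n_followup = 400, n_baseline = 100,
                    outcomes = list(physical_ipv = list(
                      control_prev = 0.25, rr = 1, k = 0,
                      baseline_prev = 0.25, baseline_k = 0)),
                    beta_age = 0, ea_sd = 0)
  ds <- simulate_trial(cfg, 31)
  eff <- adjusted_effect(ds, default_outcome_specs()$physical_ipv)
  expect_true(abs(log(eff$rr)) < 0.25)
  oe <- attr(eff, "oe")
  expect_true(all(abs(oe$ratio - 1) < 0.35))
})

test_that("unpaired t-test matches base R's pooled-variance t oracle", {
  set.seed(5)
  s <- toy_summaries(p = runif(8, 0.1, 0.5), n = rep(150, 8),
                     pair_id = rep(paste0("p", 1:4), each = 2),
                     arm = rep(c("intervention", "control"), 4))
  eff <- unpaired_ttest_effect(s)
  tt <- t.test(s$log_prev[s$arm == "intervention"],
               s$log_prev[s$arm == "control"], var.equal = TRUE)
  expect_equal(eff$rr, exp(unname(tt$estimate[1] - tt$estimate[2])),
               tolerance = 1e-12)
  expect_equal(eff$ci_low, exp(tt$conf.int[1]), tolerance = 1e-12)
  expect_equal(eff$ci_high, exp(tt$conf.int[2]), tolerance = 1e-12)
  expect_equal(eff$df, 6)
})

test_that("paired analysis beats the unpaired under strong pair effects", {
  cfg <- sim_config(n_followup = 150, n_baseline = 20,
                    outcomes = list(physical_ipv = list(
                      control_prev = 0.25, rr = 1, k = 0.35,
                      baseline_prev = 0.25, baseline_k = 0.35)),
                    pair_share = 0.95)
  narrower <- 0
  reps <- 20
  for (r in seq_len(reps)) {
    ds <- simulate_trial(cfg, 100 + r)
    s <- summarize_sites(ds, default_outcome_specs()$physical_ipv)
    paired <- crude_effect(s)
    unpaired <- unpaired_ttest_effect(s)
    if (log(paired$ci_high / paired$ci_low) <
        log(unpaired$ci_high / unpaired$ci_low)) narrower <- narrower + 1
  }
  expect_gt(narrower, reps / 2)
})

test_that("k estimation: exact-zero cases and undefined case", {
  s <- toy_summaries(p = rep(0.3, 4), n = rep(1e6, 4),
                     pair_id = c("p1", "p1", "p2", "p2"),
                     arm = rep("control", 4))
  expect_equal(estimate_cv(s)$k, 0)
  s0 <- toy_summaries(p = rep(0, 4), n = rep(100, 4),
                      pair_id = c("p1", "p1", "p2", "p2"),
                      arm = rep("control", 4))
  expect_error(estimate_cv(s0), "undefined")
  expect_error(estimate_cv(s[1, , drop = FALSE]), "at least 2 sites")
})

test_that("k estimation recovers the generating CV", {
  # site prevalences drawn from the calibrated logit-normal, binomial counts
  set.seed(2024)
  for (k_true in c(0.25)) {
    cal <- crtpair:::calibrate_logitnormal(0.3, k_true)
    khat <- replicate(200, {
      p_sites <- plogis(rnorm(8, cal$mu, cal$sigma))
      n1 <- rbinom(8, 500, p_sites)
      s <- toy_summaries(n1 / 500, rep(500, 8),
                         pair_id = rep(paste0("p", 1:4), each = 2),
                         arm = rep("control", 8))
      estimate_cv(s)$k
    })
    mcse <- sd(khat) / sqrt(length(khat))
    expect_lt(abs(mean(khat) - k_true), 4 * mcse + 0.015)
  }
  # sampling-only variation truncates to zero in most replicates
  khat0 <- replicate(100, {
    n1 <- rbinom(8, 500, 0.3)
    s <- toy_summaries(n1 / 500, rep(500, 8),
                       pair_id = rep(paste0("p", 1:4), each = 2),
                       arm = rep("control", 8))
    estimate_cv(s)$k
  })
  expect_gt(mean(khat0 == 0), 0.5)
})
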