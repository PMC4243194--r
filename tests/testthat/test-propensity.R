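test_that("identical score lists match at zero total distance", {
  e <- data.frame(respondent_id = paste0("e", 1:4), score = c(.1, .2, .3, .4),
                  pair_id = "p1", stringsAsFactors = FALSE)
  c_ <- data.frame(respondent_id = paste0("c", 1:4), score = c(.1, .2, .3, .4),
                   pair_id = "p1", stringsAsFactors = FALSE)
  mr <- match_exposed(e, c_)
  expect_equal(mr$total_distance, 0)
  expect_equal(nrow(mr$matches), 4)
  expect_equal(length(mr$unmatched_exposed), 0)
})

test_that("3x3 toy matching equals exhaustive enumeration", {
  e <- data.frame(respondent_id = paste0("e", 1:3), score = c(.1, .2, .9),
                  stringsAsFactors = FALSE)
  c_ <- data.frame(respondent_id = paste0("c", 1:3), score = c(.15, .85, .5),
                   stringsAsFactors = FALSE)
  mr <- match_exposed(e, c_)
  expect_equal(mr$total_distance, brute_assignment_cost(e$score, c_$score),
               tolerance = 1e-12)
  # optimal pairing: .1-.15, .2-.5, .9-.85
  got <- setNames(mr$matches$control_id, mr$matches$exposed_id)
  expect_equal(got[["e1"]], "c1")
  expect_equal(got[["e2"]], "c3")
  expect_equal(got[["e3"]], "c2")
})

test_that("DP matching equals the exhaustive optimum on random instances", {
  set.seed(314)
  for (rep in 1:30) {
    n <- sample(1:5, 1); m <- sample(n:6, 1)
    e <- data.frame(respondent_id = paste0("e", 1:n),
                    score = round(runif(n), 3), stringsAsFactors = FALSE)
    c_ <- data.frame(respondent_id = paste0("c", 1:m),
                     score = round(runif(m), 3), stringsAsFactors = FALSE)
    mr <- match_exposed(e, c_)
    expect_equal(mr$total_distance, brute_assignment_cost(e$score, c_$score),
                 tolerance = 1e-12, info = paste("instance", rep))
    expect_true(all(!duplicated(mr$matches$control_id)))
  }
})

test_that("matching beats random permutations on larger instances", {
  set.seed(99)
  e <- data.frame(respondent_id = sprintf("e%03d", 1:40), score = runif(40),
                  stringsAsFactors = FALSE)
  c_ <- data.frame(respondent_id = sprintf("c%03d", 1:60), score = runif(60),
                   stringsAsFactors = FALSE)
  mr <- match_exposed(e, c_)
  for (i in 1:1000) {
    rnd <- sum(abs(e$score - c_$score[sample(60, 40)]))
    expect_gte(rnd, mr$total_distance - 1e-12)
  }
})

test_that("surplus exposed respondents are reported and warned about", {
  e <- data.frame(respondent_id = paste0("e", 1:5), score = c(.1, .2, .3, .8, .9),
                  stringsAsFactors = FALSE)
  c_ <- data.frame(respondent_id = paste0("c", 1:2), score = c(.12, .31),
                   stringsAsFactors = FALSE)
  expect_warning(mr <- match_exposed(e, c_), "partial")
  expect_equal(nrow(mr$matches), 2)
  expect_equal(length(mr$unmatched_exposed), 3)
  expect_equal(mr$total_distance,
               brute_assignment_cost(e$score, c_$score), tolerance = 1e-12)
})

test_that("within-pair matching never crosses pairs", {
  e <- data.frame(respondent_id = paste0("e", 1:4), score = c(.1, .2, .3, .4),
                  pair_id = c("p1", "p1", "p2", "p2"), stringsAsFactors = FALSE)
  c_ <- data.frame(respondent_id = paste0("c", 1:4), score = c(.4, .3, .2, .1),
                   pair_id = c("p1", "p1", "p2", "p2"), stringsAsFactors = FALSE)
  mr <- match_exposed(e, c_, within_pair = TRUE)
  pair_of <- setNames(c(e$pair_id, c_$pair_id),
                      c(e$respondent_id, c_$respondent_id))
  expect_true(all(pair_of[mr$matches$exposed_id] ==
                    pair_of[mr$matches$control_id]))
  # global matching does better or equal on total distance
  mr_global <- match_exposed(e, c_, within_pair = FALSE)
  expect_lte(mr_global$total_distance, mr$total_distance)
})

test_that("caliper drops distant matches into unmatched", {
  e <- data.frame(respondent_id = c("e1", "e2"), score = c(.1, .9),
                  stringsAsFactors = FALSE)
  c_ <- data.frame(respondent_id = c("c1", "c2"), score = c(.12, .3),
                   stringsAsFactors = FALSE)
  mr <- match_exposed(e, c_, caliper = 0.1)
  expect_equal(nrow(mr$matches), 1)
  expect_equal(mr$unmatched_exposed, "e2")
})

test_that("propensity model recovers a known exposure mechanism", {
  set.seed(88)
  n <- 2000
  age <- sample(18:49, n, replace = TRUE)
  p_thr <- plogis(-3 + 0.1 * age)
  thr <- runif(n) < p_thr
  rows <- lapply(seq_len(n), function(i) {
    new_rec(age = age[i],
            exp_materials = if (thr[i]) "once" else "never",
            exp_activities = if (thr[i]) "few_times" else "never",
            exp_multimedia = "never")
  })
  rows[[n + 1]] <- new_rec(site_id = "sB", arm = "control", ea_id = "sB_ea1")
  ds <- crt_dataset(make_records(rows))
  pm <- fit_propensity(ds, covariates = c("age"))
  expect_lt(abs(unname(pm$coef["age"]) - 0.1), 0.02)  # ~3 SE at n = 2000
  # scores on control records are finite logits; probabilities in (0,1)
  ctl <- as.data.frame(ds)[ds$arm == "control", ]
  pr <- pm$prob(ctl)
  expect_true(all(pr > 0 & pr < 1))
})

test_that("propensity fit fails cleanly on empty exposure classes", {
  rows <- lapply(1:30, function(i) new_rec())  # nobody exposed
  rows[[31]] <- new_rec(site_id = "sB", arm = "control", ea_id = "sB_ea1")
  ds <- crt_dataset(make_records(rows))
  expect_error(fit_propensity(ds, covariates = "age"),
               "empty or universal")
  expect_error(fit_propensity(ds, covariates = "shoe_size"),
               "unknown propensity covariate")
})

test_that("matching improves balance on the covariate driving exposure", {
  set.seed(12)
  n <- 600
  mk_side <- function(arm, site, offset) {
    age <- sample(18:49, n, replace = TRUE)
    thr <- runif(n) < plogis(-6 + 0.15 * age + offset)
    lapply(seq_len(n), function(i) {
      new_rec(arm = arm, site_id = site, ea_id = paste0(site, "_ea1"),
              age = age[i],
              exp_materials = if (thr[i] && arm == "intervention") "once" else "never",
              exp_activities = if (thr[i] && arm == "intervention") "few_times" else "never",
              exp_multimedia = "never")
    })
  }
  ds <- crt_dataset(make_records(c(mk_side("intervention", "sA", 0),
                                   mk_side("control", "sB", 0))))
  pm <- fit_propensity(ds, covariates = "age")
  fu <- as.data.frame(ds)
  cls <- classify_exposure(fu)
  score <- pm$score(fu)
  exposed <- cbind(fu, score = score)[fu$arm == "intervention" &
                                        cls == "threshold", ]
  controls <- cbind(fu, score = score)[fu$arm == "control", ]
  mr <- match_exposed(exposed, controls)
  bal <- match_balance(exposed, controls, mr, c("age"))
  expect_lte(abs(bal$smd_after), abs(bal$smd_before))
  expect_gt(abs(bal$smd_before), 0.1)  # exposure really was age-driven
})

test_that("a full-coverage match reproduces the adjusted ITT effect exactly", {
  ds <- simulate_trial(sim_config(n_followup = 60, n_baseline = 40,
                                  outcomes = default_sim_outcomes()["physical_ipv"]),
                       17)
  fu <- as.data.frame(ds)[ds$round == "followup", ]
  int_ids <- fu$respondent_id[fu$arm == "intervention"]
  ctl_ids <- fu$respondent_id[fu$arm == "control"]
  n <- min(length(int_ids), length(ctl_ids))
  expect_equal(length(int_ids), length(ctl_ids))  # balanced design
  mr <- structure(list(
    matches = data.frame(exposed_id = int_ids[1:n], control_id = ctl_ids[1:n],
                         distance = 0, stringsAsFactors = FALSE),
    unmatched_exposed = character(), total_distance = 0),
    class = "match_result")
  spec <- default_outcome_specs()$physical_ipv
  eff_m <- matched_effect(ds, spec, mr)
  eff_a <- adjusted_effect(ds, spec)
  expect_equal(eff_m$rr, eff_a$rr, tolerance = 1e-12)
  expect_equal(eff_m$ci_low, eff_a$ci_low, tolerance = 1e-12)
  expect_equal(eff_m$scale, "matched")
})

test_that("empty matches are an error, not a silent null effect", {
  mr <- structure(list(matches = data.frame(exposed_id = character(),
                                            control_id = character(),
                                            distance = numeric()),
                       unmatched_exposed = character(), total_distance = 0),
                  class = "match_result")
  ds <- simulate_trial(fast_cfg(), 3)
  expect_error(matched_effect(ds, default_outcome_specs()$physical_ipv, mr),
               "empty match")
})
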