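# Synthetic trial generator.
#
# Emulates the repeat cross-sectional structure the analysis assumes: 8
# sites in 4 matched pairs, a fixed number of respondents per sex per site
# per round, binary composite outcomes with logit-normal between-cluster
# variation moment-matched to a target coefficient of variation k, a
# site-level risk-ratio intervention effect at follow-up, item-level
# responses back-filled to reproduce each composite value exactly, and
# route-level intervention-exposure counts with arm- and sex-specific
# target rates.

default_sim_outcomes <- function() {
  list(
    accept_violence = list(
      control_prev = c(female = 0.59, male = 0.86),
      rr = c(female = 0.54, male = 0.13),
      k = c(female = 0.20, male = 0.045),
      baseline_prev = c(female = 0.58, male = 0.26),
      baseline_k = c(female = 0.098, male = 0.46)),
    accept_refuse_sex = list(
      control_prev = c(female = 0.73, male = 0.75),
      rr = c(female = 1.28, male = 1.31),
      k = c(female = 0.14, male = 0.14),
      baseline_prev = c(female = 0.38, male = 0.54),
      baseline_k = c(female = 0.18, male = 0.16)),
    physical_ipv = list(control_prev = 0.22, rr = 0.48, k = 0.45,
                        baseline_prev = 0.23, baseline_k = 0.0),
    sexual_ipv = list(control_prev = 0.20, rr = 0.76, k = 0.33,
                      baseline_prev = 0.12, baseline_k = 0.19),
    community_response = list(control_prev = 0.13, rr = 2.11, k = 0.38,
                              baseline_prev = 0.13, baseline_k = 0.38),
    concurrency = list(control_prev = 0.45, rr = 0.57, k = 0.0,
                       baseline_prev = 0.38, baseline_k = 0.21)
  )
}

default_sim_covariates <- function() {
  list(
    age_mean = c(female = 28.7, male = 29.2), age_sd = 7.8,
    married = c(female = 0.58, male = 0.51),
    polygamous_given_married = c(female = 0.20, male = 0.10),
    ever_regular = c(female = 0.92, male = 0.76),
    regular_past_year = c(female = 0.79, male = 0.70),
    partnered_past_year = c(female = 0.83, male = 0.82),
    works_outside = c(female = 0.25, male = 0.40),
    stayed_elsewhere = 0.15
  )
}

default_sim_exposure <- function() {
  list(intervention_any = c(female = 0.68, male = 0.91),
       intervention_threshold = c(female = 0.53, male = 0.85),
       control_any = c(female = 0.01, male = 0.02))
}

#' Simulation configuration
#'
#' Defaults reproduce the trial's stated world: 4 matched pairs of sites,
#' 150 respondents per sex per site at follow-up and 100 at baseline,
#' follow-up control prevalences, risk ratios and between-cluster CVs per
#' outcome taken from the trial's reported values, covariate marginals from
#' the respondent characteristics table, and exposure rates of 91%/68%
#' (men/women, any route, intervention arm) and 85%/53% (threshold) versus
#' 2%/1% in the control arm.
#'
#' @param pairs number of matched pairs (default 4).
#' @param n_followup respondents per sex per site at follow-up (default 150).
#' @param n_baseline respondents per sex per site at baseline (default 100).
#' @param outcomes named list of per-outcome parameter lists with elements
#'   `control_prev`, `rr`, `k`, `baseline_prev`, `baseline_k`; each element
#'   may be a scalar or a `c(female=, male=)` pair. Subset the list to
#'   generate only some outcomes.
#' @param covariates covariate marginals; see `default_sim_covariates()`.
#' @param exposure exposure target rates; see `default_sim_exposure()`.
#' @param beta_age,beta_married individual-level log-odds effects on every
#'   outcome (age centered at its mean; marital status centered at its
#'   rate), used to give the control-arm adjustment model something real to
#'   adjust for.
#' @param pair_share fraction of the between-site logit variance shared
#'   within a matched pair (default 0.5).
#' @param round_cor correlation of the site-specific (non-pair) logit
#'   effects across survey rounds (default 0.7), which is what makes
#'   baseline EA prevalence an informative covariate.
#' @param ea_sd SD of an enumeration-area logit effect shared across rounds
#'   (default 0.1).
#' @param eas_per_site enumeration areas per site (default 4).
#' @return a `sim_config` list.
#' @export
sim_config <- function(pairs = 4, n_followup = 150, n_baseline = 100,
                       outcomes = default_sim_outcomes(),
                       covariates = default_sim_covariates(),
                       exposure = default_sim_exposure(),
                       beta_age = 0.02, beta_married = 0,
                       pair_share = 0.5, round_cor = 0.7, ea_sd = 0.1,
                       eas_per_site = 4) {
  for (o in names(outcomes)) {
    oc <- outcomes[[o]]
    stopifnot(all(oc$control_prev > 0), all(oc$control_prev < 1),
              all(oc$rr > 0), all(oc$k >= 0))
  }
  structure(list(pairs = pairs, n_followup = n_followup,
                 n_baseline = n_baseline, outcomes = outcomes,
                 covariates = covariates, exposure = exposure,
                 beta_age = beta_age, beta_married = beta_married,
                 pair_share = pair_share, round_cor = round_cor,
                 ea_sd = ea_sd, eas_per_site = eas_per_site),
            class = "sim_config")
}

by_sex <- function(x, sex) {
  if (length(x) == 1) unname(x) else unname(x[[sex]])
}

# Draw true site prevalences for one outcome/sex across both rounds.
# Returns a list of two named vectors (baseline, followup), site_id ->
# prevalence in the *absence* of intervention; the risk-ratio effect is
# applied later to follow-up intervention sites.
draw_site_prevalences <- function(st, p_bl, k_bl, p_fu, k_fu, pair_share,
                                  round_cor) {
  n_sites <- nrow(st)
  a_pair <- stats::rnorm(length(unique(st$pair_id)))
  names(a_pair) <- unique(st$pair_id)
  e_bl <- stats::rnorm(n_sites)
  e_fu <- round_cor * e_bl + sqrt(1 - round_cor^2) * stats::rnorm(n_sites)
  zs <- function(e) sqrt(pair_share) * a_pair[st$pair_id] +
    sqrt(1 - pair_share) * e
  mk <- function(p, k, z) {
    cal <- calibrate_logitnormal(p, k)
    stats::setNames(invlogit(cal$mu + cal$sigma * z), st$site_id)
  }
  list(baseline = mk(p_bl, k_bl, zs(e_bl)),
       followup = mk(p_fu, k_fu, zs(e_fu)))
}

# Back-fill item responses consistent with a drawn composite value:
# TRUE -> one uniformly chosen item yes, the rest no; FALSE -> all no.
# `values` is a logical vector over the selected rows.
fill_any_yes_items <- function(records, rows, values, codes) {
  for (code in codes) records[[code]][rows] <- "no"
  pos <- rows[values]
  if (length(pos) > 0) {
    pick <- sample.int(length(codes), length(pos), replace = TRUE)
    for (j in seq_along(codes)) {
      records[[codes[j]]][pos[pick == j]] <- "yes"
    }
  }
  records
}

#' Generate a synthetic pair-matched trial
#'
#' Produces a complete two-round dataset (baseline + follow-up) under the
#' configuration's stated world. Site-level true prevalences follow a
#' logit-normal model moment-matched to the target between-cluster CV k
#' (with a fraction of the logit variance shared within matched pairs);
#' intervention sites' follow-up prevalences are scaled by the target risk
#' ratio (capped at 0.995); individual outcome probabilities add centered
#' age and marital-status effects plus an enumeration-area effect; item
#' responses are back-filled so that re-evaluating the composite outcomes
#' reproduces the drawn values exactly; exposure counts hit the arm- and
#' sex-specific target rates.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; the dataset is a pure function of `cfg` and
#'   `seed`.
#' @return a [crt_dataset()] with both rounds.
#' @export
simulate_trial <- function(cfg, seed) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(seed, simulate_trial_impl(cfg))
}

simulate_trial_impl <- function(cfg) {
  P <- cfg$pairs
  st <- data.frame(
    site_id = sprintf("site%02d", seq_len(2 * P)),
    pair_id = paste0("p", rep(seq_len(P), each = 2)),
    stringsAsFactors = FALSE)
  # blind draw within each pair
  flip <- stats::runif(P) < 0.5
  st$arm <- ifelse(rep(flip, each = 2) == c(TRUE, FALSE),
                   "intervention", "control")
  ea_tab <- data.frame(
    site_id = rep(st$site_id, each = cfg$eas_per_site),
    ea_id = paste0(rep(st$site_id, each = cfg$eas_per_site), "_ea",
                   seq_len(cfg$eas_per_site)),
    pct_gated = round(stats::runif(nrow(st) * cfg$eas_per_site, 0.1, 0.6), 3),
    n_households = round(stats::runif(nrow(st) * cfg$eas_per_site, 200, 800)),
    ea_effect = stats::rnorm(nrow(st) * cfg$eas_per_site, 0, cfg$ea_sd),
    stringsAsFactors = FALSE)

  # site-level true prevalences per outcome x sex
  prevs <- list()
  for (o in names(cfg$outcomes)) {
    oc <- cfg$outcomes[[o]]
    for (sx in c("female", "male")) {
      prevs[[paste(o, sx)]] <- draw_site_prevalences(
        st, by_sex(oc$baseline_prev, sx), by_sex(oc$baseline_k, sx),
        by_sex(oc$control_prev, sx), by_sex(oc$k, sx),
        cfg$pair_share, cfg$round_cor)
    }
  }

  blocks <- list()
  for (round in c("baseline", "followup")) {
    n_per <- if (round == "baseline") cfg$n_baseline else cfg$n_followup
    for (i in seq_len(nrow(st))) {
      for (sx in c("female", "male")) {
        blocks[[length(blocks) + 1]] <-
          simulate_block(cfg, st[i, ], ea_tab, round, sx, n_per, prevs)
      }
    }
  }
  records <- do.call(rbind, blocks)
  rownames(records) <- NULL
  crt_dataset(records, sites = st[, c("site_id", "pair_id", "arm")])
}

simulate_block <- function(cfg, site, ea_tab, round, sx, n, prevs) {
  cov <- cfg$covariates
  eas <- ea_tab[ea_tab$site_id == site$site_id, , drop = FALSE]
  ea_idx <- sample.int(nrow(eas), n, replace = TRUE)

  ages <- 18:49
  age <- sample(ages, n, replace = TRUE,
                prob = stats::dnorm(ages, by_sex(cov$age_mean, sx), cov$age_sd))
  married <- stats::runif(n) < by_sex(cov$married, sx)
  polygamous <- married & (stats::runif(n) < by_sex(cov$polygamous_given_married, sx))
  ever_reg <- stats::runif(n) < by_sex(cov$ever_regular, sx)
  p_reg <- by_sex(cov$regular_past_year, sx) / by_sex(cov$ever_regular, sx)
  regular_py <- ever_reg & (stats::runif(n) < min(p_reg, 1))
  p_part <- by_sex(cov$partnered_past_year, sx)
  p_extra <- max(0, min(1, (p_part - by_sex(cov$regular_past_year, sx)) /
                          max(1e-9, 1 - by_sex(cov$regular_past_year, sx))))
  partnered <- regular_py | (stats::runif(n) < p_extra)

  rec <- data.frame(
    respondent_id = sprintf("%s_%s_%s_%04d", site$site_id,
                            substr(round, 1, 2), substr(sx, 1, 1), seq_len(n)),
    household_id = sprintf("%s_%s_%s_h%04d", site$site_id,
                           substr(round, 1, 2), substr(sx, 1, 1), seq_len(n)),
    site_id = site$site_id, ea_id = eas$ea_id[ea_idx],
    pair_id = site$pair_id, arm = site$arm, round = round, sex = sx,
    age = as.integer(age),
    marital_status = ifelse(married, "married_cohabiting", "other"),
    polygamous = polygamous, ever_regular_partner = ever_reg,
    partnered_past_year = partnered, regular_partner_past_year = regular_py,
    relationship_duration = round(stats::rexp(n, 1 / 6), 1),
    residence_duration = 1 + round(stats::rexp(n, 1 / 8), 1),
    stayed_elsewhere_past_year = stats::runif(n) < cov$stayed_elsewhere,
    works_outside_community = stats::runif(n) < by_sex(cov$works_outside, sx),
    time_out_in_community = sample(0:3, n, replace = TRUE),
    gated_compound = stats::runif(n) < eas$pct_gated[ea_idx],
    ea_pct_gated = eas$pct_gated[ea_idx],
    ea_n_households = eas$n_households[ea_idx],
    stringsAsFactors = FALSE)
  for (code in all_item_codes()) rec[[code]] <- NA_character_
  for (col in exposure_columns()) rec[[col]] <- "never"

  ic <- item_codes()
  age_c <- age - by_sex(cov$age_mean, sx)
  mar_c <- as.numeric(married) - by_sex(cov$married, sx)
  lp_shift <- cfg$beta_age * age_c + cfg$beta_married * mar_c +
    eas$ea_effect[ea_idx]

  draw_outcome <- function(o, eligible) {
    pr <- prevs[[paste(o, sx)]][[round]][[site$site_id]]
    if (round == "followup" && site$arm == "intervention") {
      pr <- min(by_sex(cfg$outcomes[[o]]$rr, sx) * pr, 0.995)
    }
    p_i <- invlogit(logit(pr) + lp_shift)
    out <- rep(NA, n)
    out[eligible] <- stats::runif(sum(eligible)) < p_i[eligible]
    out
  }

  have <- function(o) o %in% names(cfg$outcomes)
  everyone <- rep(TRUE, n)

  if (have("accept_violence")) {
    v <- draw_outcome("accept_violence", everyone)
    rec <- fill_any_yes_items(rec, which(everyone), v, ic$accept_violence)
  }
  if (have("accept_refuse_sex")) {
    v <- draw_outcome("accept_refuse_sex", everyone)
    rec <- fill_any_yes_items(rec, which(everyone), v, ic$refuse_sex)
  }
  ipv_any <- rep(FALSE, n)
  if (have("physical_ipv")) {
    elig <- sx == "female" & partnered
    v <- draw_outcome("physical_ipv", elig)
    rec <- fill_any_yes_items(rec, which(elig), v[elig], ic$physical)
    ipv_any <- ipv_any | (!is.na(v) & v)
  }
  if (have("sexual_ipv")) {
    elig <- sx == "female" & partnered
    v <- draw_outcome("sexual_ipv", elig)
    rec <- fill_any_yes_items(rec, which(elig), v[elig], ic$sexual)
    ipv_any <- ipv_any | (!is.na(v) & v)
  }
  if (have("community_response")) {
    elig <- ipv_any
    if (any(elig)) {
      v <- draw_outcome("community_response", elig)
      rows <- which(elig)
      vals <- v[elig]
      rec$cr_helped[rows] <- ifelse(vals, "yes", "no")
      rec <- fill_any_yes_items(rec, rows, vals, ic$response)
    }
  }
  if (have("concurrency")) {
    elig <- sx == "male" & !polygamous & regular_py
    v <- draw_outcome("concurrency", elig)
    rec <- fill_any_yes_items(rec, which(elig), v[elig], ic$concurrency)
  }

  if (round == "followup") {
    rec <- assign_exposure(rec, cfg$exposure, site$arm, sx)
  }
  rec
}

assign_exposure <- function(rec, exp_cfg, arm, sx) {
  n <- nrow(rec)
  if (arm == "intervention") {
    p_any <- by_sex(exp_cfg$intervention_any, sx)
    p_thr <- by_sex(exp_cfg$intervention_threshold, sx)
  } else {
    p_any <- by_sex(exp_cfg$control_any, sx)
    p_thr <- p_any / 2
  }
  r <- stats::runif(n)
  cls <- ifelse(r < p_thr, "threshold", ifelse(r < p_any, "any", "unexposed"))
  routes <- exposure_columns()
  thr <- which(cls == "threshold")
  if (length(thr) > 0) {
    # two distinct routes: the first at >= a few times, the second once
    r1 <- sample.int(3, length(thr), replace = TRUE)
    r2 <- ((r1 + sample.int(2, length(thr), replace = TRUE) - 1) %% 3) + 1
    lvl1 <- ifelse(stats::runif(length(thr)) < 0.5, "few_times", "many_times")
    for (j in 1:3) {
      rec[[routes[j]]][thr[r1 == j]] <- lvl1[r1 == j]
      rec[[routes[j]]][thr[r2 == j]] <- "once"
    }
  }
  anyx <- which(cls == "any")
  if (length(anyx) > 0) {
    pick <- sample.int(3, length(anyx), replace = TRUE)
    for (j in 1:3) {
      rec[[routes[j]]][anyx[pick == j]] <- "once"
    }
  }
  rec
}

#' Summarize replicated effect estimates
#'
#' @param estimates data.frame with columns `rr`, `ci_low`, `ci_high` and
#'   optionally `estimator`; one row per replicate.
#' @param true_rr the generating risk ratio.
#' @return data.frame per estimator: `n_reps`, mean log-RR `bias`,
#'   empirical SE of the log-RR (`emp_se`), Monte-Carlo SE of the bias
#'   (`mc_se`), and `coverage` of the nominal CI.
#' @export
summarize_simulation <- function(estimates, true_rr) {
  stopifnot(nrow(estimates) >= 2)
  if (is.null(estimates$estimator)) estimates$estimator <- "estimate"
  rows <- lapply(split(estimates, estimates$estimator), function(d) {
    lrr <- log(d$rr)
    data.frame(estimator = d$estimator[1], n_reps = nrow(d),
               bias = mean(lrr) - log(true_rr),
               emp_se = stats::sd(lrr),
               mc_se = stats::sd(lrr) / sqrt(nrow(d)),
               coverage = mean(d$ci_low <= true_rr & true_rr <= d$ci_high),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run repeated simulate-and-analyze replicates
#'
#' @param cfg a [sim_config()]; subset `cfg$outcomes` to the outcome of
#'   interest for speed.
#' @param reps number of replicates.
#' @param seed base seed; replicate r uses `seed + r`.
#' @param outcome_id which outcome to analyze.
#' @param estimators subset of `c("crude", "adjusted", "ttest")`.
#' @param sex optional sex restriction for the analysis.
#' @return data.frame with one row per replicate x estimator: `rep`,
#'   `estimator`, `rr`, `ci_low`, `ci_high`.
#' @export
replicate_trials <- function(cfg, reps, seed, outcome_id = "physical_ipv",
                             estimators = c("crude", "adjusted"),
                             sex = NULL) {
  spec <- default_outcome_specs()[[outcome_id]]
  rows <- vector("list", reps * length(estimators))
  idx <- 0
  for (r in seq_len(reps)) {
    ds <- simulate_trial(cfg, seed + r)
    summ <- if (any(c("crude", "ttest") %in% estimators)) {
      summarize_sites(ds, spec, sex = sex)
    }
    for (est in estimators) {
      eff <- switch(est,
                    crude = crude_effect(summ),
                    adjusted = adjusted_effect(ds, spec, sex = sex),
                    ttest = unpaired_ttest_effect(summ))
      idx <- idx + 1
      rows[[idx]] <- data.frame(rep = r, estimator = est, rr = eff$rr,
                                ci_low = eff$ci_low, ci_high = eff$ci_high,
                                stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
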