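# Two-stage cluster-level analysis for the pair-matched trial.
#
# Stage one reduces individual records to one summary per site (prevalence,
# or observed/expected counts under a control-arm model). Stage two enters
# the log site measures into a weighted analysis of variance with terms for
# intervention arm and site pair; the intervention coefficient, back on the
# natural scale, is the risk ratio. With P pairs the residual degrees of
# freedom are 2P - P - 1 = P - 1 (3 for the 4-pair design), so confidence
# intervals use t quantiles on few df.

new_effect <- function(outcome_id, rr, ci_low, ci_high, scale, df,
                       residual_variance, se_log) {
  structure(list(outcome_id = outcome_id, rr = rr, ci_low = ci_low,
                 ci_high = ci_high, scale = scale, df = df,
                 residual_variance = residual_variance, se_log = se_log),
            class = "crt_effect")
}

#' @export
print.crt_effect <- function(x, ...) {
  cat(sprintf("<crt_effect> %s [%s]: RR %.3f (95%% CI %.3f to %.3f), df = %d\n",
              x$outcome_id %||% "?", x$scale, x$rr, x$ci_low, x$ci_high,
              x$df))
  invisible(x)
}

#' Per-site summaries of a composite outcome
#'
#' Counts, for each site, the respondents in the outcome's denominator with
#' a non-missing value (n) and those with the outcome (n1), and computes the
#' site prevalence, its log, and the analysis weight. When a site records no
#' events, 0.5 is added to the numerator (denominator unchanged) so a log
#' prevalence exists; the flag `continuity_applied` records this.
#'
#' @param ds a [crt_dataset()].
#' @param spec an [outcome_spec()].
#' @param round `"followup"` (default) or `"baseline"`.
#' @param sex optional sex restriction on top of the spec's denominator.
#' @return data.frame of class `site_summary`, one row per site:
#'   `site_id`, `pair_id`, `arm`, `outcome_id`, `n1`, `n`, `p`,
#'   `continuity_applied`, `log_prev`, `weight`.
#' @export
summarize_sites <- function(ds, spec, round = "followup", sex = NULL) {
  stopifnot(inherits(ds, "crt_dataset"))
  st <- sites(ds)
  recs <- ds[ds$round == round, , drop = FALSE]
  if (!is.null(sex)) recs <- recs[recs$sex == sex, , drop = FALSE]
  ov <- evaluate_outcome(recs, spec)
  keep <- ov$in_denominator & !is.na(ov$value)
  out <- lapply(seq_len(nrow(st)), function(i) {
    sid <- st$site_id[i]
    sel <- keep & recs$site_id == sid
    n <- sum(sel)
    if (n == 0) {
      stop("degenerate site: no eligible respondents with a non-missing '",
           spec$outcome_id, "' value in site '", sid, "' at ", round)
    }
    n1 <- sum(ov$value[sel])
    cc <- n1 == 0
    n1c <- if (cc) 0.5 else n1
    p <- n1c / n
    data.frame(site_id = sid, pair_id = st$pair_id[i], arm = st$arm[i],
               outcome_id = spec$outcome_id, n1 = n1, n = n, p = p,
               continuity_applied = cc, log_prev = log(p),
               weight = compute_weight(n, p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("site_summary", "data.frame")
  out
}

#' Analysis weight for a site prevalence
#'
#' Weights are inversely proportional to the (delta-method) variance of the
#' log site prevalence: var(log p-hat) ~ (1 - p) / (n p), hence
#' w = n p / (1 - p). The weighted ANOVA is invariant to rescaling all
#' weights, so the proportionality constant is irrelevant.
#'
#' @param n site denominator.
#' @param p site prevalence (after any continuity correction), in (0, 1).
#' @return positive weight(s).
#' @export
compute_weight <- function(n, p) {
  if (any(p <= 0) || any(p >= 1)) {
    stop("weight undefined for site prevalence outside (0, 1): ",
         "the log-scale variance is zero or infinite")
  }
  n * p / (1 - p)
}

# Weighted ANOVA of log site measures on arm + pair; the engine behind the
# crude, adjusted and matched estimators.
wls_pair_anova <- function(log_measure, arm, pair_id, weight, outcome_id,
                           scale, conf_level = 0.95) {
  pairs <- unique(pair_id)
  P <- length(pairs)
  if (P < 2) {
    stop("insufficient pairs: the pair + arm ANOVA has no residual degrees ",
         "of freedom with fewer than 2 pairs")
  }
  d <- data.frame(y = log_measure,
                  arm01 = as.numeric(arm == "intervention"),
                  pair = factor(pair_id), w = weight)
  fit <- stats::lm(y ~ arm01 + pair, data = d, weights = w)
  df <- fit$df.residual
  res <- stats::residuals(fit)
  rss <- sum(d$w * res^2)
  sigma2 <- rss / df
  xw <- stats::model.matrix(fit) * sqrt(d$w)
  vc <- sigma2 * solve(crossprod(xw))
  beta <- stats::coef(fit)[["arm01"]]
  se <- sqrt(vc["arm01", "arm01"])
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  new_effect(outcome_id, exp(beta), exp(beta - tq * se), exp(beta + tq * se),
             scale, df, sigma2, se)
}

#' Crude cluster-level risk ratio
#'
#' Weighted least-squares fit of the log site prevalences on an intervention
#' indicator plus site-pair indicators. The exponentiated arm coefficient is
#' the prevalence (risk) ratio, intervention versus control; the CI uses the
#' t distribution on the ANOVA's residual df.
#'
#' @param summaries a `site_summary` from [summarize_sites()]; both arms of
#'   every pair must be present.
#' @param conf_level confidence level (default 0.95).
#' @return a `crt_effect` with `scale = "crude"`.
#' @export
crude_effect <- function(summaries, conf_level = 0.95) {
  wls_pair_anova(summaries$log_prev, summaries$arm, summaries$pair_id,
                 summaries$weight, summaries$outcome_id[1], "crude",
                 conf_level)
}

#' Baseline enumeration-area prevalence of an outcome
#'
#' Computes, from the baseline round, the prevalence of `spec` (or of a
#' proxy outcome when the follow-up measure was revised between rounds)
#' within each enumeration area, for use as a continuous individual-level
#' covariate in the control-arm model.
#'
#' @param ds a [crt_dataset()] containing baseline records.
#' @param spec the outcome whose baseline prevalence is wanted; pass the
#'   proxy spec when the outcome itself was not measured at baseline.
#' @param sex optional sex restriction, matching the analysis stratum.
#' @return named numeric vector, `ea_id` -> prevalence fraction.
#' @export
baseline_ea_prevalence <- function(ds, spec, sex = NULL) {
  recs <- ds[ds$round == "baseline", , drop = FALSE]
  if (!is.null(sex)) recs <- recs[recs$sex == sex, , drop = FALSE]
  ov <- evaluate_outcome(recs, spec)
  keep <- ov$in_denominator & !is.na(ov$value)
  ea <- recs$ea_id[keep]
  val <- ov$value[keep]
  tapply(val, ea, mean)
}

#' Fit the control-arm prediction model
#'
#' Individual-level logistic regression of the outcome on age, marital
#' status and the baseline enumeration-area prevalence of the outcome (or
#' its closest baseline proxy), fitted to control-arm follow-up respondents,
#' complete-case on the three covariates. The fitted model predicts, for any
#' respondent, the probability of the outcome in the absence of the
#' intervention.
#'
#' @param ds a [crt_dataset()].
#' @param spec an [outcome_spec()].
#' @param baseline_prev named vector `ea_id` -> baseline prevalence, e.g.
#'   from [baseline_ea_prevalence()].
#' @param sex optional sex restriction.
#' @return object of class `control_model` with a `$predict(records)`
#'   method returning probabilities (`NA` where covariates are missing).
#' @export
fit_control_model <- function(ds, spec, baseline_prev, sex = NULL) {
  recs <- ds[ds$round == "followup" & ds$arm == "control", , drop = FALSE]
  if (!is.null(sex)) recs <- recs[recs$sex == sex, , drop = FALSE]
  ov <- evaluate_outcome(recs, spec)
  keep <- ov$in_denominator & !is.na(ov$value)
  d <- data.frame(y = as.numeric(ov$value[keep]),
                  age = recs$age[keep],
                  married = as.numeric(recs$marital_status[keep] ==
                                         "married_cohabiting"),
                  bprev = as.numeric(baseline_prev[recs$ea_id[keep]]))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) == 0) stop("no complete-case control records to fit on")
  if (all(d$y == 0) || all(d$y == 1)) {
    stop("separation: control-arm outcome '", spec$outcome_id,
         "' is constant; the logistic model is not identifiable")
  }
  fit <- suppressWarnings(stats::glm(y ~ age + married + bprev, data = d,
                                     family = stats::binomial()))
  coefs <- stats::coef(fit)
  # constant covariates (e.g. a single-valued baseline prevalence) are
  # aliased with the intercept; R drops them, which is the intended
  # intercept-only behaviour for that term
  coefs[is.na(coefs)] <- 0
  if (!fit$converged) {
    warning("control model for '", spec$outcome_id,
            "' did not converge; refitting with a ridge penalty (1e-4)")
    X <- cbind(1, d$age, d$married, d$bprev)
    coefs <- ridge_logistic(X, d$y, lambda = 1e-4)
    names(coefs) <- c("(Intercept)", "age", "married", "bprev")
  }
  structure(list(
    outcome_id = spec$outcome_id,
    coef = coefs,
    predict = function(records) {
      eta <- coefs[1] + coefs[2] * records$age +
        coefs[3] * as.numeric(records$marital_status == "married_cohabiting") +
        coefs[4] * as.numeric(baseline_prev[records$ea_id])
      invlogit(eta)
    }), class = "control_model")
}

# Ridge-penalized logistic regression by IRLS; fallback when glm fails to
# converge. The intercept is penalized too: with lambda = 1e-4 the
# difference is immaterial and the system stays full rank.
ridge_logistic <- function(X, y, lambda = 1e-4, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- invlogit(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    A <- crossprod(X * sqrt(w)) + diag(lambda, ncol(X))
    beta_new <- solve(A, crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < 1e-10) { beta <- beta_new; break }
    beta <- beta_new
  }
  drop(beta)
}

#' Observed and expected events per site
#'
#' For every site (both arms), sums the control-model predicted
#' probabilities over that site's eligible follow-up respondents (E) and
#' counts the observed events (O). Respondents with missing covariates or a
#' missing outcome are excluded from both O and E. A zero observed count is
#' continuity-corrected to 0.5.
#'
#' @inheritParams fit_control_model
#' @param model a `control_model` from [fit_control_model()].
#' @return data.frame of class `oe_summary`: `site_id`, `pair_id`, `arm`,
#'   `observed`, `expected`, `ratio`, `log_ratio`, `weight`,
#'   `continuity_applied`.
#' @export
observed_expected <- function(ds, spec, model, sex = NULL) {
  st <- sites(ds)
  recs <- ds[ds$round == "followup", , drop = FALSE]
  if (!is.null(sex)) recs <- recs[recs$sex == sex, , drop = FALSE]
  ov <- evaluate_outcome(recs, spec)
  pred <- model$predict(recs)
  keep <- ov$in_denominator & !is.na(ov$value) & !is.na(pred)
  out <- lapply(seq_len(nrow(st)), function(i) {
    sid <- st$site_id[i]
    sel <- keep & recs$site_id == sid
    if (sum(sel) == 0) {
      stop("degenerate site: no usable respondents for '", spec$outcome_id,
           "' in site '", sid, "'")
    }
    O <- sum(ov$value[sel])
    E <- sum(pred[sel])
    if (E <= 0) stop("degenerate expected count (E = 0) in site '", sid, "'")
    cc <- O == 0
    Oc <- if (cc) 0.5 else O
    data.frame(site_id = sid, pair_id = st$pair_id[i], arm = st$arm[i],
               outcome_id = spec$outcome_id, observed = O, expected = E,
               ratio = Oc / E, log_ratio = log(Oc / E), weight = Oc,
               continuity_applied = cc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("oe_summary", "data.frame")
  out
}

#' Adjusted cluster-level risk ratio (observed/expected)
#'
#' Two-stage covariate adjustment: a logistic model fitted to control-arm
#' individuals predicts each site's expected number of events in the
#' absence of the intervention; the log site O/E ratios then enter the same
#' weighted pair + arm ANOVA as the crude analysis. Site weights are the
#' (continuity-corrected) observed counts, the delta-method inverse
#' variance of log O with E treated as fixed.
#'
#' @inheritParams fit_control_model
#' @param model optional prefitted `control_model`; fitted internally when
#'   `NULL`.
#' @param baseline_prev optional `ea_id` -> baseline prevalence vector;
#'   computed from the baseline round of `ds` (using `proxy_spec` when
#'   given) when `NULL`.
#' @param proxy_spec outcome spec to use as the baseline proxy measure when
#'   the outcome itself is not comparable across rounds.
#' @param conf_level confidence level.
#' @return a `crt_effect` with `scale = "adjusted"` and the per-site O/E
#'   table in attribute `"oe"`.
#' @export
adjusted_effect <- function(ds, spec, model = NULL, baseline_prev = NULL,
                            proxy_spec = NULL, sex = NULL,
                            conf_level = 0.95) {
  if (is.null(baseline_prev)) {
    baseline_prev <- baseline_ea_prevalence(ds, proxy_spec %||% spec, sex)
  }
  if (is.null(model)) {
    model <- fit_control_model(ds, spec, baseline_prev, sex)
  }
  oe <- observed_expected(ds, spec, model, sex)
  eff <- wls_pair_anova(oe$log_ratio, oe$arm, oe$pair_id, oe$weight,
                        spec$outcome_id, "adjusted", conf_level)
  attr(eff, "oe") <- oe
  eff
}

#' Unpaired t-test sensitivity analysis
#'
#' Ignores the pair matching and compares the site-level log measures (log
#' prevalence for a `site_summary`, log O/E for an `oe_summary`) between
#' arms with an equal-variance two-sample t-test on 2P - 2 df, trading the
#' pairing for extra residual degrees of freedom.
#'
#' @param x a `site_summary` or `oe_summary`.
#' @param conf_level confidence level.
#' @return a `crt_effect` with `scale = "ttest"`.
#' @export
unpaired_ttest_effect <- function(x, conf_level = 0.95) {
  y <- if (inherits(x, "oe_summary")) x$log_ratio else x$log_prev
  gi <- x$arm == "intervention"
  ni <- sum(gi); nc <- sum(!gi)
  if (ni < 2 || nc < 2) stop("need at least 2 sites per arm for the t-test")
  md <- mean(y[gi]) - mean(y[!gi])
  sp2 <- (sum((y[gi] - mean(y[gi]))^2) + sum((y[!gi] - mean(y[!gi]))^2)) /
    (ni + nc - 2)
  se <- sqrt(sp2 * (1 / ni + 1 / nc))
  df <- ni + nc - 2
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  new_effect(x$outcome_id[1], exp(md), exp(md - tq * se), exp(md + tq * se),
             "ttest", df, sp2, se)
}

#' Between-cluster coefficient of variation
#'
#' Estimates k, the coefficient of variation of the true outcome prevalence
#' between clusters, from site-level summaries of one arm (or all sites at
#' baseline). The empirical variance of the site prevalences is corrected
#' for within-site binomial sampling noise and truncated at zero:
#' k-hat^2 = max(0, (s^2 - pbar (1 - pbar) / n-tilde) / pbar^2), with
#' n-tilde the harmonic mean site denominator.
#'
#' @param summaries a `site_summary` (typically restricted to one arm).
#' @param round label stored on the estimate (`"baseline"`/`"followup"`).
#' @param arm_set label: `"all"` or `"control_only"`.
#' @return object of class `cv_estimate` with elements `outcome_id`,
#'   `round`, `arm_set`, `k`.
#' @export
estimate_cv <- function(summaries, round = "followup", arm_set = "all") {
  if (nrow(summaries) < 2) stop("need at least 2 sites to estimate k")
  # use raw prevalences (undo the continuity correction)
  p <- ifelse(summaries$continuity_applied, 0, summaries$n1 / summaries$n)
  pbar <- mean(p)
  if (pbar == 0) stop("k undefined: outcome prevalence is zero in every site")
  s2 <- stats::var(p)
  ntilde <- 1 / mean(1 / summaries$n)
  k2 <- max(0, (s2 - pbar * (1 - pbar) / ntilde) / pbar^2)
  structure(list(outcome_id = summaries$outcome_id[1], round = round,
                 arm_set = arm_set, k = sqrt(k2)), class = "cv_estimate")
}

#' @export
print.cv_estimate <- function(x, ...) {
  cat(sprintf("<cv_estimate> %s (%s, %s): k = %.3f\n", x$outcome_id,
              x$round, x$arm_set, x$k))
  invisible(x)
}
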