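# Secondary exposure analysis: model the propensity for threshold-level
# intervention exposure among intervention-arm respondents, match exposed
# respondents 1:1 without replacement to control respondents on the logit
# propensity, and rerun the adjusted cluster-level pipeline on the matched
# subset.

#' Default propensity-model covariates
#'
#' Age, marital status, relationship duration, duration living in the
#' community, whether the respondent stayed elsewhere in the past year,
#' work outside the community, time spent out in the community, living in a
#' gated compound, the community pair, and two enumeration-area summaries
#' (fraction of gated households, number of households).
#'
#' @return character vector of covariate names.
#' @export
default_propensity_covariates <- function() {
  c("age", "marital_status", "relationship_duration", "residence_duration",
    "stayed_elsewhere_past_year", "works_outside_community",
    "time_out_in_community", "gated_compound", "pair_id", "ea_pct_gated",
    "ea_n_households")
}

propensity_design <- function(records, covariates) {
  cols <- list()
  for (cv in covariates) {
    v <- records[[cv]]
    if (cv == "marital_status") {
      cols[[cv]] <- as.numeric(v == "married_cohabiting")
    } else if (cv == "pair_id") {
      f <- factor(v)
      if (nlevels(f) > 1) {
        mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(mm) <- paste0("pair_", levels(f)[-1])
        for (j in seq_len(ncol(mm))) cols[[colnames(mm)[j]]] <- mm[, j]
      }
    } else if (is.logical(v)) {
      cols[[cv]] <- as.numeric(v)
    } else {
      cols[[cv]] <- as.numeric(v)
    }
  }
  X <- do.call(cbind, cols)
  cbind(`(Intercept)` = 1, X)
}

#' Fit the exposure propensity model
#'
#' Logistic regression of threshold-level intervention exposure (vs any
#' lower exposure) on the covariates, fitted to intervention-arm follow-up
#' respondents, complete-case on the covariates. The returned scorer can be
#' applied to any records (in particular control-arm respondents) and
#' returns the propensity on the logit (linear-predictor) scale, the scale
#' used for matching.
#'
#' @param ds a [crt_dataset()].
#' @param covariates covariate names; default
#'   [default_propensity_covariates()].
#' @return object of class `propensity_model` with `$coef` and
#'   `$score(records)` (logit scale) / `$prob(records)` (probability scale).
#' @export
fit_propensity <- function(ds, covariates = default_propensity_covariates()) {
  known <- c(covariate_columns(), "age", "marital_status", "pair_id")
  unknown <- setdiff(covariates, known)
  if (length(unknown) > 0) stop("unknown propensity covariate: ", unknown[1])
  recs <- ds[ds$round == "followup" & ds$arm == "intervention", , drop = FALSE]
  if (nrow(recs) == 0) stop("no intervention-arm follow-up records")
  y <- as.numeric(classify_exposure(recs) == "threshold")
  X <- propensity_design(recs, covariates)
  cc <- stats::complete.cases(X)
  X <- X[cc, , drop = FALSE]
  y <- y[cc]
  if (length(unique(y)) < 2) {
    stop("cannot fit propensity model: exposure class is empty or universal")
  }
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0  # aliased (constant) covariates drop out
  if (!fit$converged) {
    warning("propensity model did not converge; using ridge penalty (1e-4)")
    coefs <- ridge_logistic(X, y, lambda = 1e-4)
    names(coefs) <- colnames(X)
  }
  p <- invlogit(drop(X %*% coefs))
  if (max(p) > 1 - 1e-8 || min(p) < 1e-8) {
    stop("separation in propensity model: fitted probabilities at 0/1")
  }
  score_fn <- function(records) {
    Xn <- propensity_design(records, covariates)
    Xn <- Xn[, names(coefs), drop = FALSE]
    drop(Xn %*% coefs)
  }
  structure(list(coef = coefs, covariates = covariates, score = score_fn,
                 prob = function(records) invlogit(score_fn(records))),
            class = "propensity_model")
}

# Exact 1:1 assignment minimizing total |a - b| for scalar scores.
# For one-dimensional points under L1 cost the optimal assignment respects
# the sort order, so a dynamic program over (sorted a) x (sorted b) finds
# the global optimum of the assignment problem: f[i, j] = best cost of
# matching the first i of a within the first j of b,
# f[i, j] = min(f[i-1, j-1] + |a_i - b_j|, f[i, j-1]).
# Requires length(a) <= length(b); every a is matched.
assign_sorted_1d <- function(a, b) {
  n <- length(a); m <- length(b)
  stopifnot(n <= m)
  INF <- Inf
  f <- matrix(INF, n + 1, m + 1)
  f[1, ] <- 0
  for (i in seq_len(n)) {
    for (j in i:m) {
      f[i + 1, j + 1] <- min(f[i, j] + abs(a[i] - b[j]), f[i + 1, j])
    }
  }
  # reconstruct, preferring the earliest control on ties (deterministic)
  match_j <- integer(n)
  i <- n; j <- m
  while (i >= 1) {
    if (f[i + 1, j + 1] == f[i + 1, j]) {
      j <- j - 1
    } else {
      match_j[i] <- j
      i <- i - 1; j <- j - 1
    }
  }
  match_j
}

#' Optimal 1:1 propensity matching without replacement
#'
#' Matches exposed respondents to controls minimizing the total absolute
#' difference in propensity score (the assignment problem). Each control is
#' used at most once. When `within_pair = TRUE`, matches are restricted to
#' the control site of the exposed respondent's own pair. If a stratum
#' holds more exposed than controls, as many as possible are matched (again
#' cost-optimally) and the remainder reported in `unmatched_exposed` with a
#' warning. Ties are broken deterministically by respondent id order.
#'
#' @param exposed data.frame with `respondent_id`, `score` and (if
#'   `within_pair`) `pair_id`.
#' @param controls data.frame of candidate controls, same columns.
#' @param within_pair restrict matches to the same pair (default `FALSE`).
#' @param caliper optional maximum allowed score distance; matched pairs
#'   farther apart are dropped into `unmatched_exposed`.
#' @return object of class `match_result`: `matches` (data.frame
#'   `exposed_id`, `control_id`, `distance`), `unmatched_exposed`,
#'   `total_distance`.
#' @export
match_exposed <- function(exposed, controls, within_pair = FALSE,
                          caliper = NULL) {
  if (nrow(exposed) == 0 || nrow(controls) == 0) {
    stop("matching needs at least one exposed and one control respondent")
  }
  strata <- if (within_pair) {
    lapply(intersect(unique(exposed$pair_id), unique(controls$pair_id)),
           function(p) list(e = exposed[exposed$pair_id == p, , drop = FALSE],
                            c = controls[controls$pair_id == p, , drop = FALSE]))
  } else {
    list(list(e = exposed, c = controls))
  }
  matches <- list()
  unmatched <- character()
  if (within_pair) {
    lost <- setdiff(exposed$pair_id, controls$pair_id)
    unmatched <- exposed$respondent_id[exposed$pair_id %in% lost]
  }
  for (s in strata) {
    e <- s$e[order(s$e$score, s$e$respondent_id), , drop = FALSE]
    c_ <- s$c[order(s$c$score, s$c$respondent_id), , drop = FALSE]
    if (nrow(e) == 0) next
    if (nrow(c_) == 0) { unmatched <- c(unmatched, e$respondent_id); next }
    swap <- nrow(e) > nrow(c_)
    if (swap) {
      warning("more exposed (", nrow(e), ") than controls (", nrow(c_),
              ") in a stratum; matching is partial")
      mj <- assign_sorted_1d(c_$score, e$score)
      mdf <- data.frame(exposed_id = e$respondent_id[mj],
                        control_id = c_$respondent_id,
                        distance = abs(e$score[mj] - c_$score),
                        stringsAsFactors = FALSE)
      unmatched <- c(unmatched, setdiff(e$respondent_id, mdf$exposed_id))
    } else {
      mj <- assign_sorted_1d(e$score, c_$score)
      mdf <- data.frame(exposed_id = e$respondent_id,
                        control_id = c_$respondent_id[mj],
                        distance = abs(e$score - c_$score[mj]),
                        stringsAsFactors = FALSE)
    }
    matches[[length(matches) + 1]] <- mdf
  }
  matches <- if (length(matches)) do.call(rbind, matches) else
    data.frame(exposed_id = character(), control_id = character(),
               distance = numeric(), stringsAsFactors = FALSE)
  if (!is.null(caliper)) {
    wide <- matches$distance > caliper
    unmatched <- c(unmatched, matches$exposed_id[wide])
    matches <- matches[!wide, , drop = FALSE]
  }
  matches <- matches[order(matches$exposed_id), , drop = FALSE]
  rownames(matches) <- NULL
  structure(list(matches = matches, unmatched_exposed = sort(unmatched),
                 total_distance = sum(matches$distance)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> ", nrow(x$matches), " matched pairs, ",
      length(x$unmatched_exposed), " unmatched exposed; total distance ",
      signif(x$total_distance, 4), "\n", sep = "")
  invisible(x)
}

#' Covariate balance before and after matching
#'
#' Standardized mean differences (exposed minus control over the pooled
#' standard deviation) for each numeric covariate, before matching (all
#' exposed vs all candidate controls) and after (matched sets only).
#'
#' @param exposed,controls the data.frames given to [match_exposed()],
#'   augmented with covariate columns.
#' @param mr a `match_result`.
#' @param covariates covariate column names to balance-check.
#' @return data.frame `covariate`, `smd_before`, `smd_after`.
#' @export
match_balance <- function(exposed, controls, mr, covariates) {
  smd <- function(a, b) {
    a <- as.numeric(a); b <- as.numeric(b)
    sp <- sqrt((stats::var(a) + stats::var(b)) / 2)
    if (!is.finite(sp) || sp == 0) return(0)
    (mean(a, na.rm = TRUE) - mean(b, na.rm = TRUE)) / sp
  }
  em <- exposed[match(mr$matches$exposed_id, exposed$respondent_id), ,
                drop = FALSE]
  cm <- controls[match(mr$matches$control_id, controls$respondent_id), ,
                 drop = FALSE]
  rows <- lapply(covariates, function(cv) {
    conv <- function(d) {
      v <- d[[cv]]
      if (cv == "marital_status") as.numeric(v == "married_cohabiting")
      else as.numeric(v)
    }
    data.frame(covariate = cv,
               smd_before = smd(conv(exposed), conv(controls)),
               smd_after = smd(conv(em), conv(cm)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cluster-level effect on the propensity-matched subset
#'
#' Restricts the follow-up records to the matched exposed respondents and
#' their matched controls (baseline records are kept for the baseline
#' prevalence covariate) and reruns the adjusted observed/expected pipeline
#' on the subset.
#'
#' @param ds a [crt_dataset()].
#' @param spec an [outcome_spec()].
#' @param mr a `match_result` from [match_exposed()].
#' @inheritParams adjusted_effect
#' @return a `crt_effect` with `scale = "matched"`.
#' @export
matched_effect <- function(ds, spec, mr, proxy_spec = NULL, sex = NULL,
                           conf_level = 0.95) {
  if (nrow(mr$matches) == 0) stop("empty match result: nothing to analyze")
  keep_ids <- c(mr$matches$exposed_id, mr$matches$control_id)
  keep <- ds$round == "baseline" |
    (ds$round == "followup" & ds$respondent_id %in% keep_ids)
  sub <- crt_dataset(as.data.frame(ds)[keep, , drop = FALSE],
                     sites = sites(ds), filter = FALSE)
  eff <- adjusted_effect(sub, spec, proxy_spec = proxy_spec, sex = sex,
                         conf_level = conf_level)
  eff$scale <- "matched"
  eff
}
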