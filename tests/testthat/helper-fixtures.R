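# Shared fixtures and independent oracles for the test suite.

# One fully-specified respondent row with overridable fields; items and
# exposure default to missing.
new_rec <- function(...) {
  rec <- list(
    respondent_id = "r1", household_id = NA, site_id = "sA", ea_id = "sA_ea1",
    pair_id = "p1", arm = "intervention", round = "followup", sex = "female",
    age = 30L, marital_status = "married_cohabiting", polygamous = FALSE,
    ever_regular_partner = TRUE, partnered_past_year = TRUE,
    regular_partner_past_year = TRUE,
    relationship_duration = 5, residence_duration = 3,
    stayed_elsewhere_past_year = FALSE, works_outside_community = FALSE,
    time_out_in_community = 1L, gated_compound = FALSE, ea_pct_gated = 0.3,
    ea_n_households = 400L)
  for (code in crtpair::item_codes() |> unlist() |> unname()) {
    rec[[code]] <- NA_character_
  }
  for (col in paste0("exp_", c("materials", "activities", "multimedia"))) {
    rec[[col]] <- NA_character_
  }
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  as.data.frame(rec, stringsAsFactors = FALSE)
}

# Stack respondent rows, auto-numbering respondent and household ids.
make_records <- function(rows) {
  out <- do.call(rbind, rows)
  out$respondent_id <- sprintf("r%04d", seq_len(nrow(out)))
  out$household_id <- sprintf("h%04d", seq_len(nrow(out)))
  out
}

# Hand-built site summaries for the ANOVA estimators (bypasses records).
toy_summaries <- function(p, n, pair_id, arm, outcome_id = "toy") {
  n1 <- round(p * n)
  cc <- n1 == 0
  pc <- ifelse(cc, 0.5 / n, n1 / n)
  out <- data.frame(site_id = sprintf("s%02d", seq_along(p)),
                    pair_id = pair_id, arm = arm, outcome_id = outcome_id,
                    n1 = n1, n = n, p = pc, continuity_applied = cc,
                    log_prev = log(pc),
                    weight = n * pc / (1 - pc),
                    stringsAsFactors = FALSE)
  class(out) <- c("site_summary", "data.frame")
  out
}

# Independent WLS oracle: solve the weighted normal equations of
# y ~ 1 + arm + pair dummies directly and return rr, se, df, sigma2.
wls_oracle <- function(y, arm, pair_id, w, conf_level = 0.95) {
  pairs <- sort(unique(pair_id))
  X <- cbind(1, as.numeric(arm == "intervention"))
  for (p in pairs[-1]) X <- cbind(X, as.numeric(pair_id == p))
  W <- diag(w)
  XtWX <- t(X) %*% W %*% X
  beta <- solve(XtWX, t(X) %*% W %*% y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(w * res^2) / df
  vc <- sigma2 * solve(XtWX)
  se <- sqrt(vc[2, 2])
  tq <- qt(1 - (1 - conf_level) / 2, df)
  list(rr = exp(beta[2]), ci_low = exp(beta[2] - tq * se),
       ci_high = exp(beta[2] + tq * se), df = df, sigma2 = sigma2)
}

# Exhaustive assignment oracle: minimum total |a-b| over all injective
# mappings of the smaller side into the larger; returns the optimum cost.
brute_assignment_cost <- function(a, b) {
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  n <- length(a); m <- length(b)
  best <- Inf
  subsets <- utils::combn(m, n, simplify = FALSE)
  perms <- all_perms(n)
  for (s in subsets) {
    for (pm in perms) {
      cost <- sum(abs(a - b[s[pm]]))
      if (cost < best) best <- cost
    }
  }
  best
}

all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (k in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = k)
    }
  }
  out
}

# small simulation config used where full defaults would be slow
fast_cfg <- function(...) {
  sim_config(n_followup = 60, n_baseline = 40,
             outcomes = default_sim_outcomes()["physical_ipv"], ...)
}
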