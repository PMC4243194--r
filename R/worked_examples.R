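# Deterministic construction of a dataset realizing a published site-level
# cell (numerator / denominator) for one outcome, used by the worked-example
# checks: the cell's records go into one intervention site and a small
# fixed complement into its control partner, so the per-site summarizer can
# recompute the printed prevalence from item-level data.

#' Build a dataset realizing a given numerator/denominator cell
#'
#' Constructs item-level records such that the intervention site of a
#' single matched pair contains exactly `n` respondents in the outcome's
#' denominator of whom `n1` have the outcome (items assigned round-robin
#' across the outcome's code set), plus `n_ineligible` respondents outside
#' the denominator. The control site holds a fixed small complement so the
#' pair validates. Deterministic: no RNG involved.
#'
#' @param outcome_id one of the six built-in outcome ids.
#' @param n1 numerator (events).
#' @param n denominator (respondents with a non-missing outcome).
#' @param sex respondent sex for the attitude outcomes (`"female"` or
#'   `"male"`); ignored for outcomes with a sex-specific denominator.
#' @param n_ineligible extra out-of-denominator respondents added to the
#'   intervention site (unpartnered women or polygamous men, by outcome).
#' @return a [crt_dataset()].
#' @export
outcome_cell_dataset <- function(outcome_id, n1, n, sex = "female",
                                 n_ineligible = 0) {
  stopifnot(n1 >= 0, n1 <= n)
  build <- function(site, arm, n1, n, n_inel) {
    total <- n + n_inel
    rec <- data.frame(
      respondent_id = sprintf("%s_%05d", site, seq_len(total)),
      site_id = site, ea_id = paste0(site, "_ea1"), pair_id = "p1",
      arm = arm, round = "followup", age = 30L,
      marital_status = "married_cohabiting",
      ever_regular_partner = TRUE, partnered_past_year = TRUE,
      regular_partner_past_year = TRUE, polygamous = FALSE,
      stringsAsFactors = FALSE)
    event <- c(rep(TRUE, n1), rep(FALSE, n - n1), rep(NA, n_inel))
    ic <- item_codes()
    set_items <- function(codes) {
      for (j in seq_along(codes)) rec[[codes[j]]] <<- ifelse(is.na(event),
                                                             NA, "no")
      if (n1 > 0) {
        pick <- ((seq_len(n1) - 1) %% length(codes)) + 1
        for (j in seq_along(codes)) {
          rows <- which(pick == j)
          rec[[codes[j]]][rows] <<- "yes"
        }
      }
    }
    switch(outcome_id,
      accept_violence = { rec$sex <- sex; set_items(ic$accept_violence) },
      accept_refuse_sex = { rec$sex <- sex; set_items(ic$refuse_sex) },
      physical_ipv = {
        rec$sex <- "female"
        rec$partnered_past_year <- !is.na(event)
        set_items(ic$physical)
      },
      sexual_ipv = {
        rec$sex <- "female"
        rec$partnered_past_year <- !is.na(event)
        set_items(ic$sexual)
      },
      community_response = {
        rec$sex <- "female"
        # the denominator is women whose constructed IPV outcome is true
        rec$pv_slap <- ifelse(is.na(event), "no", "yes")
        for (code in setdiff(ic$physical, "pv_slap")) rec[[code]] <- "no"
        for (code in ic$sexual) rec[[code]] <- "no"
        rec$cr_helped <- ifelse(is.na(event), NA,
                                ifelse(event, "yes", "no"))
        resp <- ic$response
        for (code in resp) rec[[code]] <- ifelse(is.na(event), NA, "no")
        if (n1 > 0) {
          pick <- ((seq_len(n1) - 1) %% length(resp)) + 1
          for (j in seq_along(resp)) {
            rec[[resp[j]]][which(pick == j)] <- "yes"
          }
        }
      },
      concurrency = {
        rec$sex <- "male"
        rec$polygamous <- is.na(event)  # extras fall out of the denominator
        set_items(ic$concurrency)
      },
      stop("unknown outcome_id: ", outcome_id))
    rec
  }
  # control complement: 20 in-denominator respondents, 5 events
  records <- rbind(build("cellsite", "intervention", n1, n, n_ineligible),
                   build("ctlsite", "control", 5, 20, 0))
  crt_dataset(records)
}

#' Recompute a published prevalence cell through the pipeline
#'
#' Runs [outcome_cell_dataset()] output through [evaluate_outcome()] /
#' [summarize_sites()] and returns the intervention-site prevalence (as a
#' percentage), for comparison against a printed `n1/n (x%)` table cell.
#'
#' @inheritParams outcome_cell_dataset
#' @return list with `n1`, `n`, `prevalence` (fraction) and `percent`.
#' @export
worked_example_cell <- function(outcome_id, n1, n, sex = "female",
                                n_ineligible = 0) {
  ds <- outcome_cell_dataset(outcome_id, n1, n, sex, n_ineligible)
  spec <- default_outcome_specs()[[outcome_id]]
  s <- summarize_sites(ds, spec, round = "followup",
                       sex = if (outcome_id %in%
                                 c("accept_violence", "accept_refuse_sex"))
                         sex else NULL)
  row <- s[s$arm == "intervention", ]
  list(n1 = row$n1, n = row$n, prevalence = row$p, percent = 100 * row$p)
}
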