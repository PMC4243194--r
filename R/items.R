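#' Questionnaire item code registry
#'
#' Canonical item codes for the survey instrument. Composite outcomes are
#' built from these code sets:
#' \describe{
#'   \item{physical violence (7 acts)}{slapped/thrown, pushed/shoved,
#'     hit with fist, kicked/dragged/beaten, choked/burnt, weapon threat,
#'     stick (panga) threat}
#'   \item{sexual violence (2 acts)}{physically forced intercourse,
#'     intercourse through intimidation/fear}
#'   \item{acceptability of partner violence (12 scenarios)}{e.g. she
#'     disobeys, answers back, neglects children, refuses sex}
#'   \item{acceptability of sex refusal (1 item)}{a married woman may refuse
#'     sex when she does not feel like it}
#'   \item{community response (1 gate + 6 response types)}{someone tried to
#'     help, plus the type of help given}
#'   \item{concurrency (1 item)}{another sexual partner in the last 12
#'     months while partnered}
#' }
#'
#' @return named list of character vectors of item codes.
#' @export
item_codes <- function() {
  list(
    physical = c("pv_slap", "pv_push", "pv_fist", "pv_kick", "pv_choke",
                 "pv_weapon", "pv_panga"),
    sexual = c("sv_forced", "sv_afraid"),
    accept_violence = c("av_disobey", "av_answer_back", "av_disrespect",
                        "av_suspect_unfaithful", "av_unfaithful", "av_gossip",
                        "av_neglect_children", "av_housework", "av_refuse_sex",
                        "av_accuse_infidelity", "av_tell_secrets", "av_angry"),
    refuse_sex = "rs_refuse",
    response_gate = "cr_helped",
    response = c("cr_gathered", "cr_knocked", "cr_separated", "cr_informed",
                 "cr_asked", "cr_told"),
    concurrency = "cc_other_partner"
  )
}

all_item_codes <- function() unname(unlist(item_codes()))

exposure_routes <- function() c("materials", "activities", "multimedia")

exposure_levels <- function() c("never", "once", "few_times", "many_times")

exposure_columns <- function() paste0("exp_", exposure_routes())

covariate_columns <- function() {
  c("relationship_duration", "residence_duration",
    "stayed_elsewhere_past_year", "works_outside_community",
    "time_out_in_community", "gated_compound", "ea_pct_gated",
    "ea_n_households")
}
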