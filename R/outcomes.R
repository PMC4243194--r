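# Composite binary outcomes built from questionnaire items, and the
# intervention-exposure classification.
#
# Each outcome is a spec: an eligibility predicate over respondents (the
# denominator), a set of item codes, a combination rule and the direction of
# change the intervention is expected to produce. Six built-in specs cover
# the trial's primary indicators.

#' Define a composite outcome
#'
#' @param outcome_id short identifier.
#' @param eligible function taking the records data.frame and returning a
#'   logical vector: who belongs in the denominator.
#' @param item_codes character vector of item codes combined by `rule`.
#' @param rule `"any_yes"` (at least one item answered yes) or
#'   `"helped_and_any_response"` (the `cr_helped` gate answered yes AND at
#'   least one of the response-type items yes).
#' @param direction `"increase"` or `"decrease"`: hypothesized direction of
#'   the intervention effect.
#' @param sex optional `"female"`/`"male"` restriction applied on top of
#'   `eligible` (used to report sex-stratified attitude outcomes).
#' @return an `outcome_spec`.
#' @export
outcome_spec <- function(outcome_id, eligible, item_codes,
                         rule = c("any_yes", "helped_and_any_response"),
                         direction = c("decrease", "increase"), sex = NULL) {
  rule <- match.arg(rule)
  direction <- match.arg(direction)
  stopifnot(is.function(eligible), length(item_codes) >= 1)
  unknown <- setdiff(item_codes, all_item_codes())
  if (length(unknown) > 0) stop("unknown item code: ", unknown[1])
  structure(list(outcome_id = outcome_id, eligible = eligible,
                 item_codes = item_codes, rule = rule,
                 direction = direction, sex = sex),
            class = "outcome_spec")
}

#' @export
print.outcome_spec <- function(x, ...) {
  cat("<outcome_spec> ", x$outcome_id, " (", x$rule, ", expected ",
      x$direction, if (!is.null(x$sex)) paste0(", ", x$sex), ")\n", sep = "")
  cat("  items: ", paste(x$item_codes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Partnered (regular or casual) in the past year; missing counts as not.
partnered <- function(records) {
  !is.na(records$partnered_past_year) & records$partnered_past_year
}

# Regular partner in the past year; falls back to partnered & ever-regular
# when the dedicated column was not collected.
regular_partnered <- function(records) {
  v <- records$regular_partner_past_year
  fallback <- partnered(records) &
    (!is.na(records$ever_regular_partner) & records$ever_regular_partner)
  ifelse(is.na(v), fallback, v)
}

#' The six built-in primary outcome specifications
#'
#' \describe{
#'   \item{accept_violence}{any of 12 scenarios in which hitting one's wife
#'     is said to be justified; all respondents; expected decrease.}
#'   \item{accept_refuse_sex}{agrees a married woman may refuse sex; all
#'     respondents; expected increase.}
#'   \item{physical_ipv}{any of 7 physical acts by a partner in the past
#'     year; women partnered (regular or casual) in the past year; decrease.}
#'   \item{sexual_ipv}{either of 2 sexual acts; same denominator; decrease.}
#'   \item{community_response}{someone in the community tried to help AND
#'     used at least one appropriate response; women whose constructed
#'     physical or sexual IPV outcome is true; increase.}
#'   \item{concurrency}{another sexual partner in the past 12 months;
#'     non-polygamous men with a regular partner in the past year;
#'     decrease.}
#' }
#'
#' @return named list of [outcome_spec()] objects.
#' @export
default_outcome_specs <- function() {
  ic <- item_codes()
  list(
    accept_violence = outcome_spec(
      "accept_violence",
      eligible = function(r) rep(TRUE, nrow(r)),
      item_codes = ic$accept_violence, rule = "any_yes",
      direction = "decrease"),
    accept_refuse_sex = outcome_spec(
      "accept_refuse_sex",
      eligible = function(r) rep(TRUE, nrow(r)),
      item_codes = ic$refuse_sex, rule = "any_yes",
      direction = "increase"),
    physical_ipv = outcome_spec(
      "physical_ipv",
      eligible = function(r) r$sex == "female" & partnered(r),
      item_codes = ic$physical, rule = "any_yes",
      direction = "decrease"),
    sexual_ipv = outcome_spec(
      "sexual_ipv",
      eligible = function(r) r$sex == "female" & partnered(r),
      item_codes = ic$sexual, rule = "any_yes",
      direction = "decrease"),
    community_response = outcome_spec(
      "community_response",
      eligible = function(r) {
        ipv <- any_yes_value(r, c(ic$physical, ic$sexual))
        r$sex == "female" & partnered(r) & !is.na(ipv) & ipv
      },
      item_codes = c(ic$response_gate, ic$response),
      rule = "helped_and_any_response", direction = "increase"),
    concurrency = outcome_spec(
      "concurrency",
      eligible = function(r) {
        poly <- !is.na(r$polygamous) & r$polygamous
        r$sex == "male" & !poly & regular_partnered(r)
      },
      item_codes = ic$concurrency, rule = "any_yes",
      direction = "decrease")
  )
}

# any-yes with conservative missing handling: TRUE if any item yes, FALSE
# only if all items answered no, NA if no yes and >= 1 item missing.
any_yes_value <- function(records, codes) {
  m <- as.matrix(records[, codes, drop = FALSE]) == "yes"
  # m is TRUE / FALSE / NA per item
  any_yes <- rowSums(m, na.rm = TRUE) > 0
  all_no <- rowSums(!m, na.rm = TRUE) == length(codes)
  ifelse(any_yes, TRUE, ifelse(all_no, FALSE, NA))
}

#' Evaluate a composite outcome for every respondent
#'
#' Applies the spec's denominator predicate and combination rule. A value is
#' non-missing only for respondents in the denominator with at least one
#' relevant item answered; an `any_yes` outcome is true on any yes, false
#' only when every item was answered no, and missing otherwise.
#'
#' @param records a `crt_dataset` or records data.frame.
#' @param spec an [outcome_spec()].
#' @return data.frame with `respondent_id`, `outcome_id`, `in_denominator`,
#'   `value` (logical, `NA` allowed).
#' @export
evaluate_outcome <- function(records, spec) {
  if (!inherits(spec, "outcome_spec")) stop("unknown outcome spec")
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  denom <- spec$eligible(records)
  denom[is.na(denom)] <- FALSE
  if (!is.null(spec$sex)) denom <- denom & records$sex == spec$sex
  value <- switch(
    spec$rule,
    any_yes = any_yes_value(records, spec$item_codes),
    helped_and_any_response = {
      gate_code <- item_codes()$response_gate
      resp_codes <- setdiff(spec$item_codes, gate_code)
      gate <- records[[gate_code]]
      resp <- any_yes_value(records, resp_codes)
      # conjunction with three-valued logic: a definite no on either side
      # settles the outcome even if the other side is missing
      ifelse(!is.na(gate) & gate == "no", FALSE,
             ifelse(is.na(gate), ifelse(!is.na(resp) & !resp, FALSE, NA),
                    resp))
    })
  value[!denom] <- NA
  data.frame(respondent_id = records$respondent_id,
             outcome_id = rep(spec$outcome_id, nrow(records)),
             in_denominator = denom, value = value,
             stringsAsFactors = FALSE)
}

#' Classify intervention exposure from route-level contact counts
#'
#' Three ordered routes of contact (materials, activities, multimedia) are
#' each recorded as never / once / a few times / many times. A respondent is
#' classified `any` on contact with at least one route, and `threshold` when
#' all three routes were contacted at least once, or at least one route once
#' and a *different* route at least a few times. Missing counts are treated
#' as never (the number so treated is returned in the `n_missing_as_never`
#' attribute).
#'
#' @param records a `crt_dataset` or records data.frame with the
#'   `exp_materials`, `exp_activities`, `exp_multimedia` columns.
#' @return factor with levels `unexposed`, `any`, `threshold`.
#' @export
classify_exposure <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  m <- as.matrix(records[, exposure_columns(), drop = FALSE])
  n_missing <- sum(is.na(m))
  ord <- matrix(match(m, exposure_levels()), nrow = nrow(m))  # 1..4
  ord[is.na(ord)] <- 1L
  ge_once <- ord >= 2L
  ge_few <- ord >= 3L
  n_once <- rowSums(ge_once)
  any_exp <- n_once >= 1L
  # a route at >= few_times plus a *different* route at >= once
  other_once <- n_once - rowSums(ge_few & ge_once) # routes at exactly once
  few_and_other <- rowSums(ge_few) >= 1L &
    (other_once >= 1L | rowSums(ge_few) >= 2L)
  threshold <- n_once == 3L | few_and_other
  out <- factor(ifelse(threshold, "threshold",
                       ifelse(any_exp, "any", "unexposed")),
                levels = c("unexposed", "any", "threshold"))
  attr(out, "n_missing_as_never") <- n_missing
  out
}
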