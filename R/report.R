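# Orchestration: outcome configuration files, end-to-end analysis with
# publication-style CSV outputs, and a small command-line dispatcher.
# Artifacts are a pure function of inputs + seed (no timestamps), so a
# rerun with the same arguments reproduces them byte for byte.

eligibility_predicates <- function() {
  list(
    all = function(r) rep(TRUE, nrow(r)),
    women = function(r) r$sex == "female",
    men = function(r) r$sex == "male",
    women_partnered = function(r) r$sex == "female" & partnered(r),
    women_with_ipv = default_outcome_specs()$community_response$eligible,
    men_nonpoly_regular = default_outcome_specs()$concurrency$eligible
  )
}

#' Read an outcome-specification config
#'
#' JSON with a top-level `outcomes` array; each entry has `outcome_id`,
#' `items` (item codes), `rule`, `direction`, and `eligible`, one of the
#' named denominator predicates (`all`, `women`, `men`, `women_partnered`,
#' `women_with_ipv`, `men_nonpoly_regular`). This is the extension point
#' for secondary outcomes; the packaged default config reproduces
#' [default_outcome_specs()].
#'
#' @param path JSON file path.
#' @return named list of [outcome_spec()] objects.
#' @export
read_outcome_config <- function(path) {
  cfgs <- jsonlite::read_json(path, simplifyVector = TRUE)$outcomes
  preds <- eligibility_predicates()
  out <- list()
  for (i in seq_len(nrow(cfgs))) {
    row <- cfgs[i, ]
    if (!(row$eligible %in% names(preds))) {
      stop("unknown eligibility predicate: ", row$eligible)
    }
    out[[row$outcome_id]] <- outcome_spec(
      row$outcome_id, preds[[row$eligible]],
      item_codes = unlist(row$items), rule = row$rule,
      direction = row$direction)
  }
  out
}

fmt_cell <- function(n1, n) {
  sprintf("%d/%d (%d%%)", n1, n, as.integer(round(100 * n1 / n)))
}

fmt_rr <- function(eff) {
  sprintf("%.2f (%.2f to %.2f)", eff$rr, eff$ci_low, eff$ci_high)
}

arm_cells <- function(summ) {
  by_arm <- function(a) {
    s <- summ[summ$arm == a, , drop = FALSE]
    c(n1 = sum(s$n1), n = sum(s$n))
  }
  list(intervention = by_arm("intervention"), control = by_arm("control"))
}

#' Run the full cluster-level analysis and write report tables
#'
#' For every outcome spec: baseline and follow-up event counts by arm,
#' crude and adjusted cluster-level risk ratios with 95% CIs, the unpaired
#' t-test sensitivity estimate, and control-arm between-cluster CVs. Writes
#' `effects.csv` (one row per outcome, raw fractions plus formatted cells),
#' `descriptives.csv` and `analysis_log.txt` under `report_dir`.
#'
#' @param ds a [crt_dataset()] (both rounds).
#' @param specs named list of [outcome_spec()]s.
#' @param report_dir output directory, created if needed; `NULL` to skip
#'   writing.
#' @param seed recorded in the log (the analysis itself is deterministic).
#' @return data.frame of effect results, invisibly when writing.
#' @export
analyze_trial <- function(ds, specs = default_outcome_specs(),
                          report_dir = NULL, seed = NA) {
  log_lines <- c(sprintf("crtpair %s analysis",
                         as.character(utils::packageVersion("crtpair"))),
                 sprintf("records: %d; sites: %d; seed: %s", nrow(ds),
                         nrow(sites(ds)), as.character(seed)))
  rep <- validation_report(ds)
  if (!is.null(rep)) {
    log_lines <- c(log_lines, sprintf(
      "validation: %d input rows, %d retained (excluded: %s)", rep$n_input,
      rep$n_retained,
      paste(names(rep$exclusions), rep$exclusions, sep = "=", collapse = ", ")))
  }
  rows <- list()
  for (o in names(specs)) {
    spec <- specs[[o]]
    fu <- tryCatch(summarize_sites(ds, spec, round = "followup"),
                   error = function(e) {
                     log_lines <<- c(log_lines, sprintf(
                       "follow-up summaries failed for '%s': %s", o,
                       conditionMessage(e)))
                     NULL
                   })
    if (is.null(fu)) {
      rows[[o]] <- data.frame(
        outcome_id = o, direction = spec$direction,
        baseline_intervention = NA_character_, baseline_control = NA_character_,
        followup_intervention = NA_character_, followup_control = NA_character_,
        fu_intervention_prev = NA_real_, fu_control_prev = NA_real_,
        crude_rr = NA_real_, crude_ci_low = NA_real_, crude_ci_high = NA_real_,
        crude_fmt = NA_character_, adjusted_rr = NA_real_,
        adjusted_ci_low = NA_real_, adjusted_ci_high = NA_real_,
        adjusted_fmt = NA_character_, ttest_rr = NA_real_,
        ttest_ci_low = NA_real_, ttest_ci_high = NA_real_,
        k_control_fu = NA_real_, stringsAsFactors = FALSE)
      next
    }
    if (any(fu$continuity_applied)) {
      log_lines <- c(log_lines, sprintf(
        "continuity correction (0.5 added to zero numerator) for '%s' in site(s): %s",
        o, paste(fu$site_id[fu$continuity_applied], collapse = ", ")))
    }
    bl <- tryCatch(summarize_sites(ds, spec, round = "baseline"),
                   error = function(e) NULL)
    crude <- crude_effect(fu)
    adj <- tryCatch(adjusted_effect(ds, spec), error = function(e) {
      log_lines <<- c(log_lines, sprintf("adjusted model failed for '%s': %s",
                                         o, conditionMessage(e)))
      NULL
    })
    if (!is.null(adj)) {
      oe <- attr(adj, "oe")
      if (any(oe$continuity_applied)) {
        log_lines <- c(log_lines, sprintf(
          "continuity correction (0.5 added to zero observed count) for '%s' in site(s): %s",
          o, paste(oe$site_id[oe$continuity_applied], collapse = ", ")))
      }
    }
    tt <- unpaired_ttest_effect(fu)
    cv <- estimate_cv(fu[fu$arm == "control", , drop = FALSE],
                      round = "followup", arm_set = "control_only")
    fu_cells <- arm_cells(fu)
    bl_cells <- if (!is.null(bl)) arm_cells(bl)
    cell_or_na <- function(cells, a) {
      if (is.null(cells)) NA_character_ else
        fmt_cell(cells[[a]][["n1"]], cells[[a]][["n"]])
    }
    rows[[o]] <- data.frame(
      outcome_id = o, direction = spec$direction,
      baseline_intervention = cell_or_na(bl_cells, "intervention"),
      baseline_control = cell_or_na(bl_cells, "control"),
      followup_intervention = cell_or_na(fu_cells, "intervention"),
      followup_control = cell_or_na(fu_cells, "control"),
      fu_intervention_prev = fu_cells$intervention[["n1"]] /
        fu_cells$intervention[["n"]],
      fu_control_prev = fu_cells$control[["n1"]] / fu_cells$control[["n"]],
      crude_rr = crude$rr, crude_ci_low = crude$ci_low,
      crude_ci_high = crude$ci_high, crude_fmt = fmt_rr(crude),
      adjusted_rr = if (is.null(adj)) NA_real_ else adj$rr,
      adjusted_ci_low = if (is.null(adj)) NA_real_ else adj$ci_low,
      adjusted_ci_high = if (is.null(adj)) NA_real_ else adj$ci_high,
      adjusted_fmt = if (is.null(adj)) NA_character_ else fmt_rr(adj),
      ttest_rr = tt$rr, ttest_ci_low = tt$ci_low, ttest_ci_high = tt$ci_high,
      k_control_fu = cv$k,
      stringsAsFactors = FALSE)
  }
  effects <- do.call(rbind, rows)
  rownames(effects) <- NULL
  if (!is.null(report_dir)) {
    dir.create(report_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(effects, file.path(report_dir, "effects.csv"),
                     row.names = FALSE)
    utils::write.csv(describe_respondents(ds),
                     file.path(report_dir, "descriptives.csv"),
                     row.names = FALSE)
    writeLines(log_lines, file.path(report_dir, "analysis_log.txt"))
    return(invisible(effects))
  }
  effects
}

#' Respondent characteristics by round, arm and sex
#'
#' @param ds a [crt_dataset()].
#' @return data.frame: n, mean age, percent married/cohabiting, percent
#'   partnered in the past year, per round x arm x sex.
#' @export
describe_respondents <- function(ds) {
  d <- as.data.frame(ds)
  grp <- interaction(d$round, d$arm, d$sex, drop = TRUE)
  rows <- lapply(split(d, grp), function(g) {
    data.frame(round = g$round[1], arm = g$arm[1], sex = g$sex[1],
               n = nrow(g), mean_age = round(mean(g$age), 1),
               pct_married = round(100 * mean(g$marital_status ==
                                                "married_cohabiting")),
               pct_partnered_py = round(100 * mean(g$partnered_past_year,
                                                   na.rm = TRUE)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$round, out$arm, out$sex), ]
  rownames(out) <- NULL
  out
}

#' Run the exposure-matched secondary analysis
#'
#' Classifies exposure, fits the propensity model on intervention-arm
#' respondents, matches threshold-exposed respondents to controls, and
#' computes matched cluster-level effects for each outcome spec.
#'
#' @param ds a [crt_dataset()].
#' @param specs outcome specs to analyze.
#' @param within_pair restrict matches to the same pair.
#' @param covariates propensity covariates.
#' @param report_dir optional output directory for `matches.csv` and
#'   `balance.csv`.
#' @return list with `match` (the `match_result`), `balance`, `effects`
#'   (data.frame of matched RRs).
#' @export
matched_analysis <- function(ds, specs = default_outcome_specs(),
                             within_pair = FALSE,
                             covariates = default_propensity_covariates(),
                             report_dir = NULL) {
  fu <- ds[ds$round == "followup", , drop = FALSE]
  pm <- fit_propensity(ds, covariates)
  cls <- classify_exposure(fu)
  score <- pm$score(fu)
  ok <- !is.na(score)
  exposed <- data.frame(respondent_id = fu$respondent_id,
                        score = score, pair_id = fu$pair_id,
                        stringsAsFactors = FALSE)[
                          ok & fu$arm == "intervention" & cls == "threshold", ]
  controls <- data.frame(respondent_id = fu$respondent_id,
                         score = score, pair_id = fu$pair_id,
                         stringsAsFactors = FALSE)[ok & fu$arm == "control", ]
  mr <- match_exposed(exposed, controls, within_pair = within_pair)
  bal_cov <- setdiff(covariates, "pair_id")
  fu_cov <- cbind(fu, score = score)
  bal <- match_balance(fu_cov[ok & fu$arm == "intervention" &
                                cls == "threshold", ],
                       fu_cov[ok & fu$arm == "control", ], mr,
                       c(bal_cov, "score"))
  rows <- lapply(names(specs), function(o) {
    eff <- tryCatch(matched_effect(ds, specs[[o]], mr),
                    error = function(e) NULL)
    data.frame(outcome_id = o,
               matched_rr = if (is.null(eff)) NA_real_ else eff$rr,
               matched_ci_low = if (is.null(eff)) NA_real_ else eff$ci_low,
               matched_ci_high = if (is.null(eff)) NA_real_ else eff$ci_high,
               stringsAsFactors = FALSE)
  })
  effects <- do.call(rbind, rows)
  if (!is.null(report_dir)) {
    dir.create(report_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(mr$matches, file.path(report_dir, "matches.csv"),
                     row.names = FALSE)
    utils::write.csv(bal, file.path(report_dir, "balance.csv"),
                     row.names = FALSE)
    utils::write.csv(effects, file.path(report_dir, "matched_effects.csv"),
                     row.names = FALSE)
  }
  list(match = mr, balance = bal, effects = effects)
}

default_precision_grid <- function() {
  g <- expand.grid(c = 4, n = c(100, 150), p0 = c(0.15, 0.25, 0.45, 0.60, 0.85),
                   rr = c(0.5, 0.7, 1.3), k = c(0, 0.2, 0.45))
  g[g$rr * g$p0 < 1, , drop = FALSE]  # feasible scenarios only
}

parse_cli_args <- function(args) {
  out <- list(flags = character(), opts = list())
  i <- 1
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i < length(args) && !startsWith(args[[i + 1]], "--")) {
        out$opts[[key]] <- args[[i + 1]]
        i <- i + 2
      } else {
        out$flags <- c(out$flags, key)
        i <- i + 1
      }
    } else i <- i + 1
  }
  out
}

#' Command-line entry point
#'
#' Subcommands:
#' \describe{
#'   \item{analyze}{`--data <csv> [--baseline <csv>] [--outcomes <json>]
#'     --report <dir> [--seed <int>]`: full primary analysis.}
#'   \item{simulate}{`--seed <int> --out <csv> [--pairs N] [--n-followup N]
#'     [--n-baseline N]`: write a synthetic trial.}
#'   \item{match}{`--data <csv> --report <dir> [--within-pair]`: exposure
#'     matching and matched effects.}
#'   \item{design-precision}{`--out <csv>`: precision over the default
#'     scenario grid.}
#'   \item{design-randomize}{`--pairs <csv with site_a,site_b> --seed <int>
#'     --out <csv>`: pair-matched randomization.}
#' }
#' Invoke as `Rscript -e 'crtpair::cli_run()' analyze --data ...` or from R.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return integer exit status, invisibly (0 on success).
#' @export
cli_run <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0) stop("no subcommand given")
    sub <- args[[1]]
    p <- parse_cli_args(args[-1])
    opt <- p$opts
    switch(sub,
      analyze = {
        ds <- read_dataset(opt$data, schema = opt$schema)
        if (!is.null(opt$baseline)) {
          bl <- read_dataset(opt$baseline, schema = opt$schema)
          ds <- crt_dataset(rbind(as.data.frame(ds), as.data.frame(bl)),
                            filter = FALSE)
        }
        specs <- if (!is.null(opt$outcomes)) read_outcome_config(opt$outcomes)
          else default_outcome_specs()
        analyze_trial(ds, specs, report_dir = opt$report,
                      seed = opt$seed %||% NA)
      },
      simulate = {
        cfg <- sim_config(
          pairs = as.integer(opt$pairs %||% 4),
          n_followup = as.integer(opt[["n-followup"]] %||% 150),
          n_baseline = as.integer(opt[["n-baseline"]] %||% 100))
        ds <- simulate_trial(cfg, as.integer(opt$seed))
        write_dataset(ds, opt$out)
      },
      match = {
        ds <- read_dataset(opt$data, schema = opt$schema)
        matched_analysis(ds, within_pair = "within-pair" %in% p$flags,
                         report_dir = opt$report)
      },
      `design-precision` = {
        utils::write.csv(precision_grid(default_precision_grid()),
                         opt$out, row.names = FALSE)
      },
      `design-randomize` = {
        pairs <- utils::read.csv(opt$pairs, stringsAsFactors = FALSE)
        utils::write.csv(randomize_pairs(pairs, as.integer(opt$seed)),
                         opt$out, row.names = FALSE)
      },
      stop("unknown subcommand: ", sub))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
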