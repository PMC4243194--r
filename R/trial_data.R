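# Individual-level trial data: canonical columns, validation, CSV I/O.
#
# A dataset is a plain data.frame of respondents plus a small site table
# (site_id, pair_id, arm), wrapped in an S3 class so downstream operations
# can assume validated input. Eligibility rules (age 18-49, at least one
# year of residence, one respondent per household) are applied at read /
# construction time so the analysis functions never see ineligible rows.

core_columns <- function() {
  c("respondent_id", "site_id", "ea_id", "pair_id", "arm", "round", "sex",
    "age", "marital_status", "ever_regular_partner", "partnered_past_year")
}

optional_columns <- function() {
  c("household_id", "polygamous", "regular_partner_past_year",
    covariate_columns())
}

dataset_columns <- function() {
  c(core_columns(), "household_id", "polygamous",
    "regular_partner_past_year", all_item_codes(), exposure_columns(),
    covariate_columns())
}

logical_columns <- function() {
  c("polygamous", "ever_regular_partner", "partnered_past_year",
    "regular_partner_past_year", "stayed_elsewhere_past_year",
    "works_outside_community", "gated_compound")
}

integer_columns <- function() c("age", "time_out_in_community", "ea_n_households")

numeric_columns <- function() {
  c("relationship_duration", "residence_duration", "ea_pct_gated")
}

categorical_levels <- function() {
  list(arm = c("intervention", "control"),
       round = c("baseline", "followup"),
       sex = c("female", "male"),
       marital_status = c("married_cohabiting", "other"))
}

#' Construct a validated trial dataset
#'
#' Wraps a respondent data.frame (one row per interview) and a site table in
#' a `crt_dataset`. Missing optional columns are added as `NA`; eligibility
#' filters are applied and recorded in a validation report (accessible via
#' [validation_report()]).
#'
#' Eligibility (applied when `filter = TRUE`): age within 18-49; residence
#' duration of at least one year when recorded; at most one respondent per
#' non-missing household identifier within a survey round. Partner-violence
#' items of respondents not partnered in the past year are coerced to
#' missing, matching the instrument's skip pattern.
#'
#' @param records data.frame of respondents; see [dataset_columns()].
#' @param sites optional data.frame with `site_id`, `pair_id`, `arm`;
#'   derived from `records` when `NULL`.
#' @param filter apply eligibility filters (default `TRUE`).
#' @return a `crt_dataset`: the records with class attributes, a `sites`
#'   attribute and a `report` attribute.
#' @export
crt_dataset <- function(records, sites = NULL, filter = TRUE) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  n_input <- nrow(records)
  for (col in setdiff(dataset_columns(), names(records))) {
    records[[col]] <- rep(NA, n_input)
  }
  records <- records[, dataset_columns(), drop = FALSE]
  records <- coerce_types(records)
  check_levels(records)

  exclusions <- c(age = 0L, residence = 0L, household = 0L)
  notes <- character()
  if (filter && n_input > 0) {
    bad_age <- is.na(records$age) | records$age < 18 | records$age > 49
    exclusions["age"] <- sum(bad_age)
    records <- records[!bad_age, , drop = FALSE]
    bad_res <- !is.na(records$residence_duration) & records$residence_duration < 1
    exclusions["residence"] <- sum(bad_res)
    records <- records[!bad_res, , drop = FALSE]
    key <- ifelse(is.na(records$household_id), NA,
                  paste(records$round, records$site_id, records$household_id))
    dup <- !is.na(key) & duplicated(key)
    exclusions["household"] <- sum(dup)
    records <- records[!dup, , drop = FALSE]
    rownames(records) <- NULL
  }

  # skip pattern: partner-violence items only asked of the partnered
  pv_cols <- c(item_codes()$physical, item_codes()$sexual)
  unpartnered <- !is.na(records$partnered_past_year) & !records$partnered_past_year
  n_coerced <- sum(!is.na(as.matrix(records[unpartnered, pv_cols, drop = FALSE])))
  if (n_coerced > 0) {
    records[unpartnered, pv_cols] <- NA_character_
    notes <- c(notes, sprintf(
      "%d partner-violence responses of unpartnered respondents set to missing",
      n_coerced))
  }

  if (is.null(sites)) {
    sites <- unique(records[, c("site_id", "pair_id", "arm")])
    rownames(sites) <- NULL
  }
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  check_sites(sites, records)

  structure(records,
            class = c("crt_dataset", "data.frame"),
            sites = sites,
            report = list(n_input = n_input, n_retained = nrow(records),
                          exclusions = exclusions, notes = notes))
}

coerce_types <- function(records) {
  chr_cols <- c("respondent_id", "household_id", "site_id", "ea_id",
                "pair_id", "arm", "round", "sex", "marital_status",
                all_item_codes(), exposure_columns())
  for (col in chr_cols) {
    v <- as.character(records[[col]])
    v[!is.na(v) & v == ""] <- NA_character_
    records[[col]] <- v
  }
  for (col in logical_columns()) records[[col]] <- parse_logical(records[[col]], col)
  for (col in integer_columns()) records[[col]] <- parse_number(records[[col]], col, TRUE)
  for (col in numeric_columns()) records[[col]] <- parse_number(records[[col]], col, FALSE)
  records
}

parse_logical <- function(v, col) {
  if (is.logical(v)) return(v)
  v <- tolower(as.character(v))
  v[!is.na(v) & v == ""] <- NA_character_
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes")] <- TRUE
  out[v %in% c("false", "f", "0", "no")] <- FALSE
  bad <- which(!is.na(v) & is.na(out))
  if (length(bad) > 0) {
    stop("unknown logical value '", v[bad[1]], "' in column '", col,
         "' at row ", bad[1])
  }
  out
}

parse_number <- function(v, col, integer) {
  if (is.numeric(v)) return(if (integer) as.integer(round(v)) else as.numeric(v))
  v <- as.character(v)
  v[!is.na(v) & v == ""] <- NA_character_
  suppressWarnings(out <- as.numeric(v))
  bad <- which(!is.na(v) & is.na(out))
  if (length(bad) > 0) {
    stop("cannot parse value '", v[bad[1]], "' in column '", col,
         "' at row ", bad[1])
  }
  if (integer) as.integer(round(out)) else out
}

check_levels <- function(records) {
  levs <- categorical_levels()
  for (col in names(levs)) {
    v <- records[[col]]
    bad <- which(!is.na(v) & !(v %in% levs[[col]]))
    if (length(bad) > 0) {
      stop("unknown categorical level '", v[bad[1]], "' in column '", col,
           "' at row ", bad[1])
    }
  }
  for (col in all_item_codes()) {
    v <- records[[col]]
    bad <- which(!is.na(v) & !(v %in% c("yes", "no")))
    if (length(bad) > 0) {
      stop("unknown item response '", v[bad[1]], "' in column '", col,
           "' at row ", bad[1])
    }
  }
  for (col in exposure_columns()) {
    v <- records[[col]]
    bad <- which(!is.na(v) & !(v %in% exposure_levels()))
    if (length(bad) > 0) {
      stop("unknown exposure level '", v[bad[1]], "' in column '", col,
           "' at row ", bad[1])
    }
  }
  invisible(TRUE)
}

check_sites <- function(sites, records) {
  if (nrow(sites) == 0) return(invisible(TRUE))
  if (anyDuplicated(sites$site_id) > 0) {
    stop("site table has conflicting rows for site '",
         sites$site_id[duplicated(sites$site_id)][1], "'")
  }
  missing_sites <- setdiff(unique(records$site_id), sites$site_id)
  if (length(missing_sites) > 0) {
    stop("records reference unknown site '", missing_sites[1], "'")
  }
  for (p in unique(sites$pair_id)) {
    arms <- sites$arm[sites$pair_id == p]
    if (length(arms) != 2 || !setequal(arms, c("intervention", "control"))) {
      stop("pair '", p, "' must contain exactly one intervention and one ",
           "control site")
    }
  }
  invisible(TRUE)
}

#' @export
print.crt_dataset <- function(x, ...) {
  sites <- attr(x, "sites")
  rep <- attr(x, "report")
  cat("<crt_dataset> ", nrow(x), " respondents, ", nrow(sites), " sites, ",
      length(unique(sites$pair_id)), " pairs\n", sep = "")
  if (!is.null(rep)) {
    cat("  input rows: ", rep$n_input, "; excluded: ",
        paste(names(rep$exclusions), rep$exclusions, sep = "=",
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Validation report of a dataset
#'
#' @param ds a `crt_dataset`.
#' @return list with `n_input`, `n_retained`, `exclusions` (named integer
#'   vector) and `notes`.
#' @export
validation_report <- function(ds) {
  stopifnot(inherits(ds, "crt_dataset"))
  attr(ds, "report")
}

#' Site metadata table of a dataset
#' @param ds a `crt_dataset`.
#' @return data.frame with `site_id`, `pair_id`, `arm`.
#' @export
sites <- function(ds) attr(ds, "sites")

#' Read an individual-level trial dataset from CSV
#'
#' Reads an RFC-4180 CSV (UTF-8, header row), optionally renaming file
#' columns to the canonical names through a schema, validates types and
#' categorical levels, and applies the eligibility filters. Missing values
#' are encoded as empty strings in the file and kept distinct from "no"
#' internally: composite-outcome denominators depend on telling not-asked
#' apart from answered-no.
#'
#' @param path CSV file path.
#' @param schema optional schema: either a named character vector mapping
#'   canonical column name -> file column name, or the path of a JSON file
#'   with a top-level `columns` object holding that mapping.
#' @return a [crt_dataset()].
#' @export
read_dataset <- function(path, schema = NULL) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    map <- if (is.character(schema) && length(schema) == 1 && file.exists(schema)) {
      unlist(jsonlite::read_json(schema)$columns)
    } else unlist(schema)
    for (canonical in names(map)) {
      filecol <- map[[canonical]]
      if (!(filecol %in% names(raw))) {
        stop("missing mandatory column: ", filecol)
      }
      names(raw)[names(raw) == filecol] <- canonical
    }
  }
  mandatory <- c(core_columns(), all_item_codes())
  absent <- setdiff(mandatory, names(raw))
  if (length(absent) > 0) stop("missing mandatory column: ", absent[1])
  crt_dataset(raw)
}

#' Write a trial dataset to CSV
#'
#' Inverse of [read_dataset()]: missing values become empty strings,
#' logicals become `true`/`false`. `read_dataset(write_dataset(ds))`
#' preserves every field value.
#'
#' @param ds a `crt_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "crt_dataset"))
  out <- as.data.frame(ds, stringsAsFactors = FALSE)
  for (col in logical_columns()) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         ifelse(out[[col]], "true", "false"))
  }
  for (col in names(out)) {
    v <- out[[col]]
    if (!is.character(v)) v <- as.character(v)
    v[is.na(v)] <- ""
    out[[col]] <- v
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
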