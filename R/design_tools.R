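# Design-stage utilities: pair-matched randomization and precision
# estimation for a cluster randomized design with between-cluster
# variation.

#' Randomize sites to arms within matched pairs
#'
#' Reproduces the draw-from-a-bag allocation: within each pair one site is
#' assigned to intervention uniformly at random, the other to control.
#'
#' @param pairs a list of length-2 character vectors, or a data.frame with
#'   columns `site_a`, `site_b` (optionally `pair_id`).
#' @param seed integer seed; the allocation is a pure function of
#'   `pairs` and `seed`.
#' @return data.frame `site_id`, `pair_id`, `arm`.
#' @export
randomize_pairs <- function(pairs, seed) {
  if (is.data.frame(pairs)) {
    pid <- if ("pair_id" %in% names(pairs)) as.character(pairs$pair_id) else
      as.character(seq_len(nrow(pairs)))
    pairs <- Map(c, pairs$site_a, pairs$site_b)
    names(pairs) <- pid
  }
  if (is.null(names(pairs))) names(pairs) <- as.character(seq_along(pairs))
  all_sites <- unlist(pairs, use.names = FALSE)
  if (anyDuplicated(all_sites) > 0) {
    stop("duplicate site in pairs list: ",
         all_sites[duplicated(all_sites)][1])
  }
  stopifnot(all(lengths(pairs) == 2))
  with_seed(seed, {
    rows <- lapply(names(pairs), function(p) {
      first_is_intervention <- stats::runif(1) < 0.5
      arms <- if (first_is_intervention) c("intervention", "control") else
        c("control", "intervention")
      data.frame(site_id = pairs[[p]], pair_id = p, arm = arms,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Design-stage precision of a cluster-level risk ratio
#'
#' Expected 95% (or `conf_level`) confidence interval for the risk ratio
#' from a cluster randomized design with `c` clusters per arm, `n`
#' respondents per cluster, control prevalence `p0`, true risk ratio `rr`
#' (so intervention prevalence `p1 = rr * p0`) and between-cluster
#' coefficient of variation `k`. The variance of the log risk ratio is the
#' standard unmatched-CRT approximation:
#' var = (1/c) * ((1-p1)/(p1 n) + k^2) + (1/c) * ((1-p0)/(p0 n) + k^2),
#' and the interval is `rr * exp(+/- z * sqrt(var))` with a normal
#' quantile, the design-stage convention.
#'
#' @param c clusters per arm (>= 2).
#' @param n respondents per cluster.
#' @param p0 control-arm prevalence, in (0, 1).
#' @param rr true risk ratio (> 0); `rr * p0` must be in (0, 1).
#' @param k between-cluster coefficient of variation (>= 0).
#' @param conf_level confidence level.
#' @return list with `rr`, `ci_low`, `ci_high`, `var_log_rr`, and the
#'   per-arm variance components `component_intervention`,
#'   `component_control`.
#' @export
precision_estimate <- function(c, n, p0, rr, k, conf_level = 0.95) {
  p1 <- rr * p0
  if (p0 <= 0 || p0 >= 1 || p1 <= 0 || p1 >= 1) {
    stop("prevalences must lie in (0, 1): p0 = ", p0, ", p1 = rr * p0 = ", p1)
  }
  stopifnot(c >= 2, n >= 1, k >= 0)
  comp1 <- ((1 - p1) / (p1 * n) + k^2) / c
  comp0 <- ((1 - p0) / (p0 * n) + k^2) / c
  v <- comp1 + comp0
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(rr = rr, ci_low = rr * exp(-z * sqrt(v)), ci_high = rr * exp(z * sqrt(v)),
       var_log_rr = v, component_intervention = comp1,
       component_control = comp0)
}

#' Precision over a grid of design scenarios
#'
#' @param grid data.frame with columns `c`, `n`, `p0`, `rr`, `k`.
#' @param conf_level confidence level.
#' @return the grid with `ci_low`, `ci_high`, `ci_width_ratio`
#'   (`ci_high / ci_low`) and `var_log_rr` appended.
#' @export
precision_grid <- function(grid, conf_level = 0.95) {
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pe <- precision_estimate(grid$c[i], grid$n[i], grid$p0[i], grid$rr[i],
                             grid$k[i], conf_level)
    cbind(grid[i, , drop = FALSE],
          data.frame(ci_low = pe$ci_low, ci_high = pe$ci_high,
                     ci_width_ratio = pe$ci_high / pe$ci_low,
                     var_log_rr = pe$var_log_rr))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
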