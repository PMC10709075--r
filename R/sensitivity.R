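#' One-way deterministic sweep over a parameter's literature range
#'
#' Re-evaluates the baseline-vs-complete-regionalization differential at
#' `n_points` evenly spaced values of one parameter across its literature
#' range, all other parameters at baseline. Sweeps carry fractional expected
#' counts through (`rounding = "off"` by default) so the curves are smooth
#' rather than patient-count staircases; pass `rounding = "half-up"` to see
#' the whole-patient version.
#'
#' @param param_name Flat parameter field name (see [flatten_parameters()]).
#' @param range Optional two elements `c(low, high)` or a single-row subset
#'   of [parameter_ranges()]; defaults to the parameter's literature range.
#' @param n_points Number of evenly spaced test values (>= 2; endpoints
#'   included; a degenerate range repeats its single value).
#' @param params Baseline `model_parameters`.
#' @param rounding Count rounding convention for the model runs.
#' @return A data frame with one row per tested value: `parameter`, `value`,
#'   `delta_deaths`, `delta_complications`, `delta_cost`.
#' @examples
#' one_way_sweep("lvc_mortality_30d", n_points = 5)
#' @export
one_way_sweep <- function(param_name, range = NULL, n_points = 11,
                          params = default_parameters(),
                          rounding = c("off", "half-up")) {
  rounding <- match.arg(rounding)
  stopifnot(n_points >= 2)
  if (!param_name %in% .param_fields) {
    stop("unknown parameter: ", param_name, call. = FALSE)
  }
  if (is.null(range)) {
    tab <- parameter_ranges()
    row <- tab[tab$name == param_name, ]
    range <- c(row$low, row$high)
  } else if (is.data.frame(range)) {
    range <- c(range$low, range$high)
  }
  stopifnot(length(range) == 2, range[1] <= range[2])
  values <- seq(range[1], range[2], length.out = n_points)

  rows <- lapply(values, function(v) {
    p <- set_parameters(params, stats::setNames(list(v), param_name))
    d <- regionalization_differential(p, rounding = rounding)
    data.frame(parameter = param_name, value = v,
               delta_deaths = d$delta_deaths,
               delta_complications = d$delta_complications,
               delta_cost = d$delta_cost,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Smallest regionalization fraction achieving a target saving
#'
#' Finds, by bisection, the smallest future-state high-volume fraction in
#' `[current, 1]` whose differential on the chosen metric reaches `target`.
#' Uses fractional expected counts (rounding off), under which the
#' differential is continuous and monotone non-decreasing in the fraction
#' whenever high-volume rates are no worse than low-volume rates.
#'
#' @param params `model_parameters`.
#' @param metric `"deaths"`, `"complications"`, or `"cost"`.
#' @param target Required differential (current minus future) on that metric.
#' @param tol Bisection tolerance on the fraction.
#' @return The smallest fraction meeting the target, or `NA_real_` if even
#'   complete regionalization does not reach it.
#' @examples
#' threshold_fraction(default_parameters(), "deaths", 10)
#' @export
threshold_fraction <- function(params, metric = c("deaths", "complications",
                                                  "cost"),
                               target, tol = 1e-6) {
  metric <- match.arg(metric)
  field <- switch(metric, deaths = "delta_deaths",
                  complications = "delta_complications", cost = "delta_cost")
  current <- params$p_hvc
  f <- function(x) {
    regionalization_differential(params, future_hvc_fraction = x,
                                 rounding = "off")[[field]]
  }
  if (f(current) >= target) return(current)
  if (f(1) < target) return(NA_real_)
  lo <- current
  hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) >= target) hi <- mid else lo <- mid
  }
  hi
}

#' Probabilistic sensitivity analysis over the literature ranges
#'
#' Draws `n_draws` parameter sets (by default uniform over each literature
#' range, independently across parameters), evaluates the
#' current-vs-complete-regionalization differential for each draw with
#' fractional expected counts, and summarizes the distribution of the three
#' deltas. Identical seeds give bit-identical summaries.
#'
#' @param ranges A [parameter_ranges()] table (possibly modified).
#' @param n_draws Number of Monte-Carlo draws (>= 1).
#' @param seed Integer root seed.
#' @param dist Sampling family: `"uniform"` over each range, or
#'   `"beta-gamma"` (beta for proportions, gamma for costs, matched to the
#'   baseline value and range; see [sampling_spec()]).
#' @return An object of class `psa_summary`: `n_draws`, `seed`, a `draws`
#'   data frame (sampled parameters plus per-draw deltas), and a `summary`
#'   data frame with mean, 2.5th and 97.5th percentiles of each delta, plus
#'   `prob_cost_saving`, the fraction of draws with positive cost savings.
#' @examples
#' run_psa(n_draws = 100, seed = 1)
#' @export
run_psa <- function(ranges = parameter_ranges(), n_draws = 1000, seed = 1,
                    dist = c("uniform", "beta-gamma")) {
  dist <- match.arg(dist)
  stopifnot(n_draws >= 1)
  spec <- sampling_spec(ranges = ranges, dist = dist, seed = seed,
                        n = n_draws)
  draws <- sample_parameters(spec)

  deltas <- t(vapply(draws, function(p) {
    d <- regionalization_differential(p, rounding = "off")
    c(d$delta_deaths, d$delta_complications, d$delta_cost)
  }, numeric(3)))
  colnames(deltas) <- c("delta_deaths", "delta_complications", "delta_cost")

  flat <- do.call(rbind, lapply(draws, function(p) {
    as.data.frame(t(flatten_parameters(p)))
  }))
  draws_df <- cbind(flat, as.data.frame(deltas))

  qs <- apply(deltas, 2, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  summary_df <- data.frame(
    metric = colnames(deltas),
    mean = colMeans(deltas),
    q2.5 = qs[1, ],
    q97.5 = qs[2, ],
    row.names = NULL,
    stringsAsFactors = FALSE
  )

  structure(
    list(n_draws = n_draws, seed = seed, dist = dist,
         draws = draws_df,
         summary = summary_df,
         prob_cost_saving = mean(deltas[, "delta_cost"] > 0)),
    class = "psa_summary"
  )
}

#' @export
print.psa_summary <- function(x, ...) {
  cat(sprintf(
    "Probabilistic sensitivity analysis: %d draws (%s sampling, seed %d)\n",
    x$n_draws, x$dist, x$seed))
  print(x$summary, row.names = FALSE, digits = 4)
  cat(sprintf("  P(cost saving > 0) = %.3f\n", x$prob_cost_saving))
  invisible(x)
}

#' @export
as.data.frame.psa_summary <- function(x, ...) {
  x$summary
}
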