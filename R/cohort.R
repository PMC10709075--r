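#' Round half away from zero
#'
#' Rounds expected patient counts to whole patients with ties going away from
#' zero (`0.5 -> 1`), unlike base [round()]'s round-half-even. This is the
#' convention that reproduces every cell of the published output table from
#' the published rates.
#'
#' @param x Numeric vector (non-negative in model use).
#' @return `x` rounded to whole numbers, halves away from zero.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.4, 4.66))  # 1 2 2 5
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

.check_rounding <- function(rounding) {
  match.arg(rounding[[1]], c("half-up", "off"))
}

.maybe_round <- function(x, rounding) {
  if (rounding == "half-up") round_half_up(x) else x
}

#' Derive the annual surgical cohort from incidence
#'
#' The cohort funnel: incident cases, of which a fraction present with
#' localized or regional (resectable) disease, of which a fraction actually
#' undergo resection. Under the default rounding each stage is rounded to
#' whole patients before the next stage is applied.
#'
#' @param annual_incidence New cases per year.
#' @param p_resectable Fraction of incident cases that are resectable.
#' @param p_resection Fraction of resectable patients who undergo surgery.
#' @param rounding `"half-up"` (whole patients, default) or `"off"`
#'   (fractional expected counts carried through).
#' @return An object of class `cohort_counts`: list with `n_incident`,
#'   `n_resectable`, `n_resected`.
#' @examples
#' derive_cohort(5958, 0.41, 0.40)  # 5958 -> 2443 -> 977
#' @export
derive_cohort <- function(annual_incidence, p_resectable, p_resection,
                          rounding = c("half-up", "off")) {
  rounding <- .check_rounding(rounding)
  n_resectable <- .maybe_round(annual_incidence * p_resectable, rounding)
  n_resected <- .maybe_round(n_resectable * p_resection, rounding)
  structure(
    list(n_incident = annual_incidence,
         n_resectable = n_resectable,
         n_resected = n_resected),
    class = "cohort_counts"
  )
}

#' Allocate resections across high- and low-volume centers
#'
#' The high-volume count is rounded (or left fractional) and the low-volume
#' count is obtained by subtraction, so the two always sum exactly to the
#' cohort: independent rounding of both classes could create or destroy a
#' patient.
#'
#' @param n_resected Number of resections to allocate.
#' @param p_hvc Fraction performed at high-volume centers.
#' @inheritParams derive_cohort
#' @return Named numeric vector `c(n_hvc = , n_lvc = )`.
#' @examples
#' allocate_centers(977, 0.466)  # 455 HVC, 522 LVC
#' @export
allocate_centers <- function(n_resected, p_hvc,
                             rounding = c("half-up", "off")) {
  rounding <- .check_rounding(rounding)
  stopifnot(p_hvc >= 0, p_hvc <= 1, n_resected >= 0)
  n_hvc <- .maybe_round(n_resected * p_hvc, rounding)
  c(n_hvc = n_hvc, n_lvc = n_resected - n_hvc)
}

#' 30-day outcomes and complication costs for one center class
#'
#' Deaths and complications are independent marginal expected counts
#' (`n * rate`, rounded per the policy); no joint distribution or overlap is
#' modelled. The complication cost is the exact product of the complication
#' count and the unit cost, with no further rounding — under the default
#' policy it is therefore an exact integer number of dollars.
#'
#' @param center_class `"HVC"` or `"LVC"`.
#' @param n_surgeries Number of resections at this center class.
#' @param rates A [center_rates()] object.
#' @param unit_cost Cost (USD) of managing one complication here.
#' @inheritParams derive_cohort
#' @return An object of class `center_outcome`.
#' @examples
#' center_outcomes("LVC", 522, center_rates(0.052, 0.398), 16815)
#' @export
center_outcomes <- function(center_class, n_surgeries, rates, unit_cost,
                            rounding = c("half-up", "off")) {
  rounding <- .check_rounding(rounding)
  center_class <- match.arg(center_class, c("HVC", "LVC"))
  stopifnot(n_surgeries >= 0)
  n_deaths <- .maybe_round(n_surgeries * rates$mortality_30d, rounding)
  n_complications <- .maybe_round(n_surgeries * rates$complication_30d,
                                  rounding)
  structure(
    list(center_class = center_class,
         n_surgeries = n_surgeries,
         n_deaths = n_deaths,
         n_complications = n_complications,
         complication_cost = n_complications * unit_cost),
    class = "center_outcome"
  )
}

#' Evaluate one policy state of the model
#'
#' Composes the cohort funnel, the center allocation at `hvc_fraction`, and
#' the per-center 30-day outcomes, then totals them. `hvc_fraction = 1`
#' is complete regionalization (the future state); the baseline current state
#' uses the observed allocation stored in `params$p_hvc`.
#'
#' @param params A `model_parameters` object.
#' @param hvc_fraction Fraction of resections performed at high-volume
#'   centers in this state. Defaults to `params$p_hvc`.
#' @param label Free-text label carried into reports.
#' @inheritParams derive_cohort
#' @return An object of class `state_result`: the cohort, a data frame
#'   `outcomes` with one row per center class (columns `center_class`,
#'   `n_surgeries`, `n_deaths`, `n_complications`, `complication_cost`), and
#'   totals `total_surgeries`, `total_deaths`, `total_complications`,
#'   `total_cost`.
#' @examples
#' run_state(default_parameters(), hvc_fraction = 1, label = "future")
#' @export
run_state <- function(params, hvc_fraction = params$p_hvc, label = "state",
                      rounding = c("half-up", "off")) {
  rounding <- .check_rounding(rounding)
  validate_parameters(params)
  stopifnot(hvc_fraction >= 0, hvc_fraction <= 1)

  cohort <- derive_cohort(params$annual_incidence, params$p_resectable,
                          params$p_resection, rounding)
  alloc <- allocate_centers(cohort$n_resected, hvc_fraction, rounding)

  lvc <- center_outcomes("LVC", alloc[["n_lvc"]], params$lvc_rates,
                         params$cost_per_complication_lvc, rounding)
  hvc <- center_outcomes("HVC", alloc[["n_hvc"]], params$hvc_rates,
                         params$cost_per_complication_hvc, rounding)

  outcomes <- data.frame(
    center_class = c(lvc$center_class, hvc$center_class),
    n_surgeries = c(lvc$n_surgeries, hvc$n_surgeries),
    n_deaths = c(lvc$n_deaths, hvc$n_deaths),
    n_complications = c(lvc$n_complications, hvc$n_complications),
    complication_cost = c(lvc$complication_cost, hvc$complication_cost),
    stringsAsFactors = FALSE
  )

  structure(
    list(label = label,
         cohort = cohort,
         outcomes = outcomes,
         total_surgeries = sum(outcomes$n_surgeries),
         total_deaths = sum(outcomes$n_deaths),
         total_complications = sum(outcomes$n_complications),
         total_cost = sum(outcomes$complication_cost),
         hvc_fraction = hvc_fraction,
         rounding = rounding),
    class = "state_result"
  )
}

#' Current-minus-future differential between two policy states
#'
#' The model's headline output: how many deaths, complications, and dollars
#' the future (more regionalized) state saves relative to the current state.
#' Positive values are savings. The two states must describe the same
#' surgical cohort.
#'
#' @param current,future `state_result` objects with equal total surgeries.
#' @return An object of class `differential`: `delta_deaths`,
#'   `delta_complications`, `delta_cost` (current totals minus future
#'   totals).
#' @examples
#' p <- default_parameters()
#' compare_states(run_state(p, label = "current"),
#'                run_state(p, 1, label = "future"))
#' @export
compare_states <- function(current, future) {
  stopifnot(inherits(current, "state_result"), inherits(future, "state_result"))
  if (abs(current$total_surgeries - future$total_surgeries) > 1e-9) {
    stop(sprintf(
      "states describe different cohorts: %s vs %s total surgeries",
      format(current$total_surgeries), format(future$total_surgeries)),
      call. = FALSE)
  }
  structure(
    list(delta_deaths = current$total_deaths - future$total_deaths,
         delta_complications =
           current$total_complications - future$total_complications,
         delta_cost = current$total_cost - future$total_cost),
    class = "differential"
  )
}

#' Run current vs. future state and take the differential
#'
#' Convenience wrapper: evaluates the model at two allocation fractions on
#' the same parameter set and returns [compare_states()] of the pair.
#'
#' @param params A `model_parameters` object.
#' @param current_hvc_fraction,future_hvc_fraction Allocation fractions for
#'   the two states; defaults are the observed allocation and complete
#'   regionalization.
#' @inheritParams derive_cohort
#' @return A `differential` object.
#' @export
regionalization_differential <- function(params,
                                         current_hvc_fraction = params$p_hvc,
                                         future_hvc_fraction = 1,
                                         rounding = c("half-up", "off")) {
  rounding <- .check_rounding(rounding)
  compare_states(
    run_state(params, current_hvc_fraction, "current", rounding),
    run_state(params, future_hvc_fraction, "future", rounding)
  )
}

#' @export
print.cohort_counts <- function(x, ...) {
  cat(sprintf("Cohort funnel: %s incident -> %s resectable -> %s resected\n",
              format(x$n_incident), format(x$n_resectable),
              format(x$n_resected)))
  invisible(x)
}

#' @export
print.center_outcome <- function(x, ...) {
  cat(sprintf("%s: %s surgeries, %s deaths, %s complications, cost %s\n",
              x$center_class, format(x$n_surgeries), format(x$n_deaths),
              format(x$n_complications),
              formatC(x$complication_cost, format = "f", digits = 0,
                      big.mark = ",")))
  invisible(x)
}

#' @export
print.state_result <- function(x, ...) {
  cat(sprintf("State '%s' (HVC fraction %.3f, rounding %s)\n",
              x$label, x$hvc_fraction, x$rounding))
  print(x$outcomes, row.names = FALSE)
  cat(sprintf("  totals: %s surgeries, %s deaths, %s complications, $%s\n",
              format(x$total_surgeries), format(x$total_deaths),
              format(x$total_complications),
              formatC(x$total_cost, format = "f", digits = 0,
                      big.mark = ",")))
  invisible(x)
}

#' @export
print.differential <- function(x, ...) {
  cat(sprintf(
    "Differential (current - future): %s deaths, %s complications, $%s\n",
    format(x$delta_deaths), format(x$delta_complications),
    formatC(x$delta_cost, format = "f", digits = 0, big.mark = ",")))
  invisible(x)
}

#' @export
summary.state_result <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
as.data.frame.differential <- function(x, ...) {
  data.frame(delta_deaths = x$delta_deaths,
             delta_complications = x$delta_complications,
             delta_cost = x$delta_cost)
}
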