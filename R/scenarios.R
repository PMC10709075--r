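#' Define a policy/sensitivity scenario
#'
#' A scenario is a baseline parameter set, a set of field overrides (flat
#' field names, see [flatten_parameters()]), and the allocation fractions
#' defining its current and future states. Overrides are applied to a copy;
#' the base parameters are never mutated.
#'
#' @param name Scenario label.
#' @param base `model_parameters` to start from.
#' @param overrides Named list of replacements (flat field names). Unknown
#'   names are an error at run time.
#' @param current_hvc_fraction,future_hvc_fraction Allocation fractions for
#'   the two compared states.
#' @return An object of class `scenario_spec`.
#' @seealso [run_scenario()], [baseline_scenario()]
#' @export
scenario_spec <- function(name, base = default_parameters(),
                          overrides = list(),
                          current_hvc_fraction = base$p_hvc,
                          future_hvc_fraction = 1) {
  stopifnot(inherits(base, "model_parameters"),
            current_hvc_fraction >= 0, current_hvc_fraction <= 1,
            future_hvc_fraction >= 0, future_hvc_fraction <= 1)
  if (length(overrides) > 0 && is.null(names(overrides))) {
    stop("overrides must be a named list", call. = FALSE)
  }
  structure(
    list(name = name, base = base, overrides = overrides,
         current_hvc_fraction = current_hvc_fraction,
         future_hvc_fraction = future_hvc_fraction),
    class = "scenario_spec"
  )
}

#' Baseline scenario: observed allocation vs. complete regionalization
#'
#' Current state at the observed 46.6% high-volume share; future state with
#' every resection at a high-volume center. At the published baseline inputs
#' this yields the headline differential of 17 deaths, 29 complications, and
#' $487,635 per year.
#'
#' @param base `model_parameters` to use (defaults to the published
#'   baseline).
#' @return A `scenario_spec`.
#' @export
baseline_scenario <- function(base = default_parameters()) {
  scenario_spec("baseline", base = base)
}

#' Partial regionalization scenario
#'
#' Moves only part of the caseload to high-volume centers: the future state
#' performs `fraction` of resections at HVCs instead of all of them.
#'
#' @param fraction Future-state high-volume share, in `[0, 1]` (the published
#'   sensitivity analysis uses 0.75).
#' @inheritParams baseline_scenario
#' @return A `scenario_spec`.
#' @export
partial_regionalization <- function(fraction, base = default_parameters()) {
  stopifnot(fraction >= 0, fraction <= 1)
  scenario_spec(sprintf("partial_regionalization_%g", fraction),
                base = base, future_hvc_fraction = fraction)
}

#' Differential complication-cost scenario
#'
#' Managing a complication is assumed cheaper at high-volume centers:
#' $11,098 per complication at an HVC versus $22,364 at an LVC (the published
#' sensitivity values), all else at baseline, future state fully
#' regionalized.
#'
#' @inheritParams baseline_scenario
#' @return A `scenario_spec`.
#' @export
differential_cost_scenario <- function(base = default_parameters()) {
  scenario_spec("differential_complication_cost", base = base,
                overrides = list(cost_per_complication_hvc = 11098,
                                 cost_per_complication_lvc = 22364))
}

#' Widened complication-gap scenario
#'
#' Widens the complication-rate gap between center classes to 31.5% (HVC)
#' versus 43% (LVC). The new rates redefine the model globally, i.e. they
#' apply in both the current and the future state; future state fully
#' regionalized.
#'
#' @inheritParams baseline_scenario
#' @return A `scenario_spec`.
#' @export
widened_gap_scenario <- function(base = default_parameters()) {
  scenario_spec("widened_complication_gap", base = base,
                overrides = list(hvc_complication_30d = 0.315,
                                 lvc_complication_30d = 0.43))
}

#' Run one scenario under both rounding conventions
#'
#' Applies the scenario's overrides, evaluates the current and future states,
#' and reports the differential both with whole-patient (half-up) rounding
#' and with rounding off (fractional expected counts). The two conventions
#' are reported side by side because integer rounding can move small
#' differentials by a patient or two.
#'
#' @param spec A [scenario_spec()].
#' @return An object of class `scenario_result`: `spec`, rounded `current`,
#'   `future` and `differential`, and their `_unrounded` counterparts.
#' @export
run_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  params <- set_parameters(spec$base, spec$overrides)
  cur <- run_state(params, spec$current_hvc_fraction, "current", "half-up")
  fut <- run_state(params, spec$future_hvc_fraction, "future", "half-up")
  cur_u <- run_state(params, spec$current_hvc_fraction, "current", "off")
  fut_u <- run_state(params, spec$future_hvc_fraction, "future", "off")
  structure(
    list(spec = spec,
         params = params,
         current = cur, future = fut,
         differential = compare_states(cur, fut),
         current_unrounded = cur_u, future_unrounded = fut_u,
         differential_unrounded = compare_states(cur_u, fut_u)),
    class = "scenario_result"
  )
}

#' Run a suite of scenarios
#'
#' Deterministic: the result order matches the spec order, and repeated runs
#' are identical.
#'
#' @param specs List of [scenario_spec()] objects. Defaults to the four named
#'   scenarios: baseline, partial regionalization at 75%, differential
#'   complication costs, widened complication gap.
#' @return An object of class `scenario_suite` (list of `scenario_result`).
#' @export
run_suite <- function(specs = default_scenarios()) {
  results <- lapply(specs, run_scenario)
  class(results) <- "scenario_suite"
  results
}

#' The four named scenarios, baseline first
#'
#' @inheritParams baseline_scenario
#' @return List of `scenario_spec` objects.
#' @export
default_scenarios <- function(base = default_parameters()) {
  list(
    baseline_scenario(base),
    partial_regionalization(0.75, base),
    differential_cost_scenario(base),
    widened_gap_scenario(base)
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario '%s': current HVC %.3f -> future HVC %.3f\n",
              x$name, x$current_hvc_fraction, x$future_hvc_fraction))
  if (length(x$overrides) > 0) {
    cat("  overrides:",
        paste(sprintf("%s = %g", names(x$overrides), unlist(x$overrides)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.scenario_result <- function(x, ...) {
  print(x$spec)
  d <- x$differential
  du <- x$differential_unrounded
  cat(sprintf("  rounded:   %s deaths, %s complications, $%s saved\n",
              format(d$delta_deaths), format(d$delta_complications),
              formatC(d$delta_cost, format = "f", digits = 0,
                      big.mark = ",")))
  cat(sprintf("  unrounded: %.2f deaths, %.2f complications, $%s saved\n",
              du$delta_deaths, du$delta_complications,
              formatC(du$delta_cost, format = "f", digits = 0,
                      big.mark = ",")))
  invisible(x)
}

#' Tabulate a scenario suite
#'
#' One row per scenario with rounded and unrounded differentials, in the
#' column layout used by the CSV outputs.
#'
#' @param x A `scenario_suite`.
#' @param ... Unused.
#' @return A data frame with columns `scenario`, `delta_deaths`,
#'   `delta_complications`, `delta_cost_usd`, and their `_unrounded`
#'   counterparts.
#' @export
as.data.frame.scenario_suite <- function(x, ...) {
  if (length(x) == 0) {
    return(data.frame(scenario = character(0),
                      delta_deaths = numeric(0),
                      delta_complications = numeric(0),
                      delta_cost_usd = numeric(0),
                      delta_deaths_unrounded = numeric(0),
                      delta_complications_unrounded = numeric(0),
                      delta_cost_usd_unrounded = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(x, function(r) {
    data.frame(
      scenario = r$spec$name,
      delta_deaths = r$differential$delta_deaths,
      delta_complications = r$differential$delta_complications,
      delta_cost_usd = r$differential$delta_cost,
      delta_deaths_unrounded = r$differential_unrounded$delta_deaths,
      delta_complications_unrounded =
        r$differential_unrounded$delta_complications,
      delta_cost_usd_unrounded = r$differential_unrounded$delta_cost,
      stringsAsFactors = FALSE
    )
  }))
}

#' @export
print.scenario_suite <- function(x, ...) {
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
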