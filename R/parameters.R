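#' Per-center 30-day outcome rates
#'
#' A pair of 30-day event probabilities for one center class (high- or
#' low-volume). These are the per-operation probabilities of postoperative
#' death and of a postoperative complication within 30 days of the index
#' resection.
#'
#' @param mortality_30d Probability of 30-day postoperative death, in `[0, 1]`.
#' @param complication_30d Probability of a 30-day postoperative complication,
#'   in `[0, 1]`.
#'
#' @return An object of class `center_rates`.
#' @examples
#' center_rates(mortality_30d = 0.018, complication_30d = 0.343)
#' @export
center_rates <- function(mortality_30d, complication_30d) {
  structure(
    list(mortality_30d = mortality_30d, complication_30d = complication_30d),
    class = "center_rates"
  )
}

#' Full parameter set of the regionalization decision model
#'
#' Bundles the cohort funnel proportions, the allocation of operations across
#' center classes, the per-center 30-day outcome rates, and the unit cost of
#' managing one postoperative complication. The low-volume share is never
#' stored: it is always `1 - p_hvc`, so the two allocation probabilities sum
#' to one by construction.
#'
#' Proportions are fractions in `[0, 1]`, never percentages. Costs are whole
#' US dollars. Unit costs are kept separately for high- and low-volume centers
#' (equal at baseline) so that cost-differential scenarios need no structural
#' change.
#'
#' @param annual_incidence New pancreatic cancer cases per year (persons).
#' @param p_resectable Fraction of incident cases with localized or regional
#'   disease, i.e. eligible for curative-intent resection.
#' @param p_resection Fraction of resectable patients who actually undergo
#'   surgery.
#' @param p_hvc Fraction of resections performed at high-volume centers
#'   (at least 20 pancreatic resections annually).
#' @param hvc_rates,lvc_rates [center_rates()] for high- and low-volume
#'   centers.
#' @param cost_per_complication_hvc,cost_per_complication_lvc Cost (USD) of
#'   managing one postoperative complication at each center class.
#'
#' @return A validated object of class `model_parameters`.
#' @seealso [default_parameters()], [validate_parameters()]
#' @export
model_parameters <- function(annual_incidence,
                             p_resectable,
                             p_resection,
                             p_hvc,
                             hvc_rates,
                             lvc_rates,
                             cost_per_complication_hvc,
                             cost_per_complication_lvc) {
  params <- structure(
    list(
      annual_incidence = annual_incidence,
      p_resectable = p_resectable,
      p_resection = p_resection,
      p_hvc = p_hvc,
      hvc_rates = hvc_rates,
      lvc_rates = lvc_rates,
      cost_per_complication_hvc = cost_per_complication_hvc,
      cost_per_complication_lvc = cost_per_complication_lvc
    ),
    class = "model_parameters"
  )
  validate_parameters(params)
}

#' Baseline parameter set from the published literature
#'
#' The model's baseline: projected 2021 incidence of pancreatic cancer in
#' California (5958 cases), 41% presenting with resectable (localized or
#' regional) disease, 40% of resectable patients undergoing surgery, 46.6% of
#' resections at high-volume centers, 30-day mortality 1.8% (HVC) and 5.2%
#' (LVC), 30-day complication rates 34.3% (HVC) and 39.8% (LVC), and $16,815
#' per postoperative complication at either center class.
#'
#' @return A `model_parameters` object.
#' @examples
#' p <- default_parameters()
#' p$annual_incidence  # 5958
#' p$hvc_rates$mortality_30d  # 0.018
#' @export
default_parameters <- function() {
  model_parameters(
    annual_incidence = 5958,
    p_resectable = 0.41,
    p_resection = 0.40,
    p_hvc = 0.466,
    hvc_rates = center_rates(mortality_30d = 0.018, complication_30d = 0.343),
    lvc_rates = center_rates(mortality_30d = 0.052, complication_30d = 0.398),
    cost_per_complication_hvc = 16815,
    cost_per_complication_lvc = 16815
  )
}

# Canonical flat field names, in a fixed order. This order also fixes the
# per-parameter RNG substream assignment, so it must not be reordered.
.param_fields <- c(
  "annual_incidence", "p_resectable", "p_resection", "p_hvc",
  "hvc_mortality_30d", "hvc_complication_30d",
  "lvc_mortality_30d", "lvc_complication_30d",
  "cost_per_complication_hvc", "cost_per_complication_lvc"
)

.proportion_fields <- c(
  "p_resectable", "p_resection", "p_hvc",
  "hvc_mortality_30d", "hvc_complication_30d",
  "lvc_mortality_30d", "lvc_complication_30d"
)

#' Flatten a parameter set to a named numeric vector
#'
#' The flat representation uses one scalar per field with the same keys as the
#' config-file format (e.g. `hvc_mortality_30d` instead of the nested
#' `hvc_rates$mortality_30d`).
#'
#' @param params A `model_parameters` object.
#' @return Named numeric vector of length 10.
#' @export
flatten_parameters <- function(params) {
  stopifnot(inherits(params, "model_parameters"))
  c(
    annual_incidence = params$annual_incidence,
    p_resectable = params$p_resectable,
    p_resection = params$p_resection,
    p_hvc = params$p_hvc,
    hvc_mortality_30d = params$hvc_rates$mortality_30d,
    hvc_complication_30d = params$hvc_rates$complication_30d,
    lvc_mortality_30d = params$lvc_rates$mortality_30d,
    lvc_complication_30d = params$lvc_rates$complication_30d,
    cost_per_complication_hvc = params$cost_per_complication_hvc,
    cost_per_complication_lvc = params$cost_per_complication_lvc
  )
}

#' Build a parameter set from a named numeric vector
#'
#' Inverse of [flatten_parameters()]. All ten canonical fields must be
#' present; unknown names are an error.
#'
#' @param values Named numeric vector with exactly the canonical field names.
#' @return A validated `model_parameters` object.
#' @export
unflatten_parameters <- function(values) {
  unknown <- setdiff(names(values), .param_fields)
  if (length(unknown) > 0) {
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(.param_fields, names(values))
  if (length(missing) > 0) {
    stop("missing parameter field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  v <- as.list(values[.param_fields])
  model_parameters(
    annual_incidence = v$annual_incidence,
    p_resectable = v$p_resectable,
    p_resection = v$p_resection,
    p_hvc = v$p_hvc,
    hvc_rates = center_rates(v$hvc_mortality_30d, v$hvc_complication_30d),
    lvc_rates = center_rates(v$lvc_mortality_30d, v$lvc_complication_30d),
    cost_per_complication_hvc = v$cost_per_complication_hvc,
    cost_per_complication_lvc = v$cost_per_complication_lvc
  )
}

#' Replace named fields of a parameter set
#'
#' @param params A `model_parameters` object.
#' @param overrides Named list or vector of replacements using the canonical
#'   flat field names (see [flatten_parameters()]). Unknown names are an
#'   error.
#' @return A validated `model_parameters` object with the overrides applied.
#' @export
set_parameters <- function(params, overrides) {
  if (length(overrides) == 0) return(params)
  flat <- flatten_parameters(params)
  unknown <- setdiff(names(overrides), names(flat))
  if (length(unknown) > 0) {
    stop("override names do not match any parameter field: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  flat[names(overrides)] <- unlist(overrides)
  unflatten_parameters(flat)
}

#' Validate a parameter set
#'
#' Checks every invariant of the parameter set: all proportions (funnel,
#' allocation, and event rates) in `[0, 1]`, non-negative incidence, and
#' non-negative unit costs. The error message names every violated field at
#' once.
#'
#' @param params A `model_parameters` object.
#' @return `params`, unchanged, if valid.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "model_parameters"))
  flat <- flatten_parameters(params)
  bad <- character(0)
  for (f in .proportion_fields) {
    v <- flat[[f]]
    if (!is.finite(v) || v < 0 || v > 1) {
      bad <- c(bad, sprintf("%s = %s (must be a proportion in [0, 1])", f, v))
    }
  }
  for (f in c("annual_incidence",
              "cost_per_complication_hvc", "cost_per_complication_lvc")) {
    v <- flat[[f]]
    if (!is.finite(v) || v < 0) {
      bad <- c(bad, sprintf("%s = %s (must be non-negative)", f, v))
    }
  }
  if (length(bad) > 0) {
    stop("invalid model parameters:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  }
  params
}

#' Literature ranges for each model parameter
#'
#' One row per parameter, giving the low and high bounds reported across the
#' published sources. Parameters with a single published value get
#' `low == high`. These ranges drive the one-way sweeps ([one_way_sweep()])
#' and the probabilistic sensitivity analysis ([run_psa()]).
#'
#' The resection-rate range is the tabulated 21--41% across SEER/NCDB-era
#' population studies. Complication-rate bounds span the registry and
#' national-inpatient estimates (33.7--34.3% HVC, 39.8--41.3% LVC); the
#' complication unit-cost bounds span $9,101--$17,947 across the four cost
#' sources.
#'
#' @return A data frame of class `parameter_ranges` with columns `name`,
#'   `low`, `high`, `baseline`, `source_note`.
#' @examples
#' parameter_ranges()
#' @export
parameter_ranges <- function() {
  base <- flatten_parameters(default_parameters())
  r <- data.frame(
    name = .param_fields,
    low = c(5958, 0.41, 0.21, 0.466,
            0.017, 0.337, 0.045, 0.398,
            9101, 9101),
    high = c(5958, 0.41, 0.41, 0.466,
             0.021, 0.343, 0.061, 0.413,
             17947, 17947),
    baseline = unname(base),
    source_note = c(
      "SEER projection for California, 2021",
      "SEER, localized or regional disease at presentation",
      "SEER/NCDB population studies of resection among eligible patients",
      "California Cancer Registry allocation across center classes",
      "NCDB 30-day mortality, high-volume centers",
      "CCR/NIS 30-day complication rate, high-volume centers",
      "NCDB 30-day mortality, low-volume centers",
      "CCR/NIS 30-day complication rate, low-volume centers",
      "Vizient/NIS/institutional cost-per-complication estimates",
      "Vizient/NIS/institutional cost-per-complication estimates"
    ),
    stringsAsFactors = FALSE
  )
  class(r) <- c("parameter_ranges", "data.frame")
  r
}

#' @export
print.center_rates <- function(x, ...) {
  cat(sprintf("30-day rates: mortality %.1f%%, complications %.1f%%\n",
              100 * x$mortality_30d, 100 * x$complication_30d))
  invisible(x)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Regionalization model parameters\n")
  cat(sprintf("  annual incidence:        %g\n", x$annual_incidence))
  cat(sprintf("  resectable fraction:     %.3f\n", x$p_resectable))
  cat(sprintf("  resection fraction:      %.3f\n", x$p_resection))
  cat(sprintf("  HVC share of surgeries:  %.3f (LVC %.3f)\n",
              x$p_hvc, 1 - x$p_hvc))
  cat(sprintf("  HVC rates:  mortality %.1f%%, complications %.1f%%\n",
              100 * x$hvc_rates$mortality_30d,
              100 * x$hvc_rates$complication_30d))
  cat(sprintf("  LVC rates:  mortality %.1f%%, complications %.1f%%\n",
              100 * x$lvc_rates$mortality_30d,
              100 * x$lvc_rates$complication_30d))
  cat(sprintf("  cost per complication:   $%s (HVC), $%s (LVC)\n",
              formatC(x$cost_per_complication_hvc, format = "d", big.mark = ","),
              formatC(x$cost_per_complication_lvc, format = "d", big.mark = ",")))
  invisible(x)
}
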