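#' Specification for sampling synthetic parameter sets
#'
#' Describes how to draw plausible model parameter sets from the literature
#' heterogeneity: per parameter, a distribution kind and its range. Kinds:
#'
#' * `"uniform"` — uniform over `[low, high]`; the least-assumptive reading
#'   of a literature range, and the default.
#' * `"beta"` — beta on the proportion scale, mean fixed at the baseline
#'   value and concentration chosen so the central 95% interval is as wide as
#'   the literature range (standard practice when only a point estimate and a
#'   range are published). Only valid for proportion-valued parameters.
#' * `"gamma"` — gamma matched the same way (mean at baseline, central-95%
#'   width equal to the range); used for costs.
#' * `"point"` — degenerate: always the baseline value.
#'
#' Beta and gamma draws are clipped to `[low, high]` so every sampled set
#' respects its literature bounds. A degenerate range (`low == high`)
#' collapses any kind to a point mass.
#'
#' Each parameter draws from its own RNG substream derived deterministically
#' from the root `seed`, so adding or re-ordering draws of one parameter
#' never perturbs another's.
#'
#' @param ranges A [parameter_ranges()]-shaped data frame (`name`, `low`,
#'   `high`, `baseline`).
#' @param dist Single kind recycled to all parameters, the shorthand
#'   `"beta-gamma"` (beta for proportions, gamma for incidence/costs), or a
#'   character vector named by parameter.
#' @param seed Integer root seed.
#' @param n Number of parameter sets to draw (>= 1).
#' @return An object of class `sampling_spec`.
#' @seealso [sample_parameters()], [write_fixture()]
#' @export
sampling_spec <- function(ranges = parameter_ranges(),
                          dist = "uniform", seed = 1, n = 1) {
  stopifnot(n >= 1, is.data.frame(ranges),
            all(c("name", "low", "high", "baseline") %in% names(ranges)),
            all(ranges$low <= ranges$high))
  unknown <- setdiff(ranges$name, .param_fields)
  if (length(unknown) > 0) {
    stop("ranges name unknown parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  kinds <- .resolve_dist(dist, ranges$name)
  structure(
    list(ranges = ranges, dist = kinds,
         seed = as.integer(seed), n = as.integer(n)),
    class = "sampling_spec"
  )
}

.resolve_dist <- function(dist, param_names) {
  valid <- c("uniform", "beta", "gamma", "point")
  if (length(dist) == 1 && is.null(names(dist))) {
    if (dist == "beta-gamma") {
      kinds <- ifelse(param_names %in% .proportion_fields, "beta", "gamma")
    } else {
      kinds <- rep(match.arg(dist, valid), length(param_names))
    }
    names(kinds) <- param_names
    return(kinds)
  }
  if (is.null(names(dist)) || !all(names(dist) %in% param_names)) {
    stop("per-parameter dist must be named by parameter", call. = FALSE)
  }
  kinds <- stats::setNames(rep("uniform", length(param_names)), param_names)
  for (nm in names(dist)) kinds[[nm]] <- match.arg(dist[[nm]], valid)
  kinds
}

# Deterministic per-parameter substream seed, kept inside 32-bit range.
.substream_seed <- function(seed, k) {
  (abs(as.integer(seed)) * 69 + k * 10007) %% 2147483647L
}

# Concentration of a beta with mean m whose central 95% interval has width w.
# Restricted to the unimodal regime (both shape parameters >= 1), where the
# interval width decreases monotonically in the concentration; if even the
# flattest unimodal beta is narrower than the literature range, that
# flattest member is used.
.beta_concentration <- function(m, w) {
  width <- function(kappa) {
    stats::qbeta(0.975, m * kappa, (1 - m) * kappa) -
      stats::qbeta(0.025, m * kappa, (1 - m) * kappa)
  }
  lo <- 1.0001 * max(1 / m, 1 / (1 - m))
  if (width(lo) <= w) return(lo)
  stats::uniroot(function(k) width(k) - w, lower = lo, upper = 1e10,
                 tol = 1e-10)$root
}

# Shape of a gamma with mean m whose central 95% interval has width w.
.gamma_shape <- function(m, w) {
  width <- function(shape) {
    stats::qgamma(0.975, shape, rate = shape / m) -
      stats::qgamma(0.025, shape, rate = shape / m)
  }
  if (width(1) <= w) return(1)
  stats::uniroot(function(s) width(s) - w, lower = 1, upper = 1e10,
                 tol = 1e-8)$root
}

.draw_parameter <- function(kind, n, low, high, baseline) {
  if (kind == "point" || low == high) {
    if (kind == "point") return(rep(baseline, n))
    return(rep(low, n))
  }
  x <- switch(kind,
    uniform = stats::runif(n, low, high),
    beta = {
      if (baseline <= 0 || baseline >= 1) {
        stop("beta sampling requires a proportion-valued baseline",
             call. = FALSE)
      }
      kappa <- .beta_concentration(baseline, high - low)
      stats::rbeta(n, baseline * kappa, (1 - baseline) * kappa)
    },
    gamma = {
      shape <- .gamma_shape(baseline, high - low)
      stats::rgamma(n, shape, rate = shape / baseline)
    }
  )
  pmin(pmax(x, low), high)
}

#' Draw synthetic parameter sets
#'
#' Generates `spec$n` complete parameter sets. Parameters absent from
#' `spec$ranges` stay at their baseline value. Every returned set passes
#' [validate_parameters()]; identical seeds give identical output.
#'
#' @param spec A [sampling_spec()].
#' @return List of `model_parameters`, length `spec$n`.
#' @examples
#' sets <- sample_parameters(sampling_spec(n = 3, seed = 42))
#' length(sets)
#' @export
sample_parameters <- function(spec) {
  stopifnot(inherits(spec, "sampling_spec"))
  base_flat <- flatten_parameters(default_parameters())
  draws <- matrix(rep(base_flat, each = spec$n), nrow = spec$n,
                  dimnames = list(NULL, names(base_flat)))
  for (i in seq_len(nrow(spec$ranges))) {
    nm <- spec$ranges$name[i]
    k <- match(nm, .param_fields)
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(.substream_seed(spec$seed, k))
    draws[, nm] <- .draw_parameter(spec$dist[[nm]], spec$n,
                                   spec$ranges$low[i], spec$ranges$high[i],
                                   spec$ranges$baseline[i])
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }
  lapply(seq_len(spec$n), function(j) unflatten_parameters(draws[j, ]))
}

#' Write sampled parameter sets to a fixture file
#'
#' Emits the sampled sets as a plain CSV (one row per set, one column per
#' flat field, full double precision) plus a sidecar config
#' (`<path>.spec`) recording the distribution kinds, ranges, seed, and n —
#' everything needed to regenerate the CSV bit-exactly with
#' [regenerate_fixture()].
#'
#' @param spec A [sampling_spec()].
#' @param path Output CSV path.
#' @return Invisibly, the list of sampled `model_parameters`.
#' @export
write_fixture <- function(spec, path) {
  sets <- sample_parameters(spec)
  mat <- do.call(rbind, lapply(sets, flatten_parameters))
  lines <- c(
    paste(.param_fields, collapse = ","),
    apply(mat, 1, function(row) {
      paste(sprintf("%.17g", row), collapse = ",")
    })
  )
  writeLines(lines, path)

  sidecar <- c(
    sprintf("seed: %d", spec$seed),
    sprintf("n: %d", spec$n),
    unlist(lapply(seq_len(nrow(spec$ranges)), function(i) {
      nm <- spec$ranges$name[i]
      sprintf("%s: %s %.17g %.17g %.17g", nm, spec$dist[[nm]],
              spec$ranges$low[i], spec$ranges$high[i],
              spec$ranges$baseline[i])
    }))
  )
  writeLines(sidecar, paste0(path, ".spec"))
  invisible(sets)
}

#' Read a parameter-set fixture back in
#'
#' @param path CSV written by [write_fixture()].
#' @return List of validated `model_parameters`.
#' @export
read_fixture <- function(path) {
  if (!file.exists(path)) stop("no such fixture: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(j) {
    unflatten_parameters(stats::setNames(as.numeric(df[j, ]), names(df)))
  })
}

#' Regenerate a fixture from its sidecar config
#'
#' Re-reads `<path>.spec`, rebuilds the [sampling_spec()], and rewrites the
#' CSV. The rewritten file is byte-identical to the original.
#'
#' @param path Fixture CSV path whose `<path>.spec` sidecar exists.
#' @return Invisibly, the regenerated list of parameter sets.
#' @export
regenerate_fixture <- function(path) {
  sidecar <- paste0(path, ".spec")
  if (!file.exists(sidecar)) stop("no sidecar config: ", sidecar,
                                  call. = FALSE)
  lines <- readLines(sidecar)
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+): (.*)$", lines))
  keys <- vapply(kv, `[`, "", 2)
  vals <- vapply(kv, `[`, "", 3)
  seed <- as.integer(vals[keys == "seed"])
  n <- as.integer(vals[keys == "n"])
  prows <- which(!(keys %in% c("seed", "n")))
  parts <- strsplit(vals[prows], " ", fixed = TRUE)
  ranges <- data.frame(
    name = keys[prows],
    low = vapply(parts, function(p) as.numeric(p[2]), 0),
    high = vapply(parts, function(p) as.numeric(p[3]), 0),
    baseline = vapply(parts, function(p) as.numeric(p[4]), 0),
    stringsAsFactors = FALSE
  )
  dist <- stats::setNames(vapply(parts, `[`, "", 1), keys[prows])
  spec <- sampling_spec(ranges = ranges, dist = dist, seed = seed, n = n)
  write_fixture(spec, path)
}
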