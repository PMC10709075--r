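#' Read model parameters from a flat config file
#'
#' The config dialect is deliberately strict: one `key: value` pair per line
#' (blank lines and `#` comments allowed), keys exactly the flat field names
#' of [flatten_parameters()], values plain decimal numbers. Percent strings
#' (`46.6%`) are rejected — proportions must be fractions. Unknown keys and
#' missing keys are errors, never silently ignored, and parse errors report
#' the offending line number.
#'
#' @param path Config file path. The packaged default,
#'   `system.file("extdata", "default_parameters.conf", package = "pancreg")`,
#'   reproduces [default_parameters()] exactly.
#' @return A validated `model_parameters` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  values <- numeric(0)
  num_re <- "^[-+]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][-+]?[0-9]+)?$"
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[i])
    if (grepl("^\\s*$", line)) next
    m <- regexec("^\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*?)\\s*$", line)
    parts <- regmatches(line, m)[[1]]
    if (length(parts) != 3) {
      stop(sprintf("config parse error at line %d: %s", i, lines[i]),
           call. = FALSE)
    }
    key <- parts[2]
    raw <- parts[3]
    if (!key %in% .param_fields) {
      stop(sprintf("unknown config key at line %d: %s", i, key),
           call. = FALSE)
    }
    if (key %in% names(values)) {
      stop(sprintf("duplicate config key at line %d: %s", i, key),
           call. = FALSE)
    }
    if (!grepl(num_re, raw)) {
      stop(sprintf(
        "config value for '%s' at line %d is not a plain number: '%s'%s",
        key, i, raw,
        if (grepl("%", raw, fixed = TRUE))
          " (percent strings are rejected; use a fraction in [0, 1])"
        else ""), call. = FALSE)
    }
    values[key] <- as.numeric(raw)
  }
  missing <- setdiff(.param_fields, names(values))
  if (length(missing) > 0) {
    stop("config is missing key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  unflatten_parameters(values)
}

#' Write model parameters to a flat config file
#'
#' Inverse of [read_config()]: emits one `key: value` line per flat field,
#' in canonical order, at full precision. `read_config(write_config(p))` is
#' the identity on parameters.
#'
#' @param params `model_parameters`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(params, path) {
  flat <- flatten_parameters(params)
  writeLines(sprintf("%s: %s", names(flat),
                     vapply(flat, .format_number, "")), path)
  invisible(path)
}

# Shortest decimal representation that round-trips exactly through
# as.numeric; avoids scientific notation for config readability.
.format_number <- function(x) {
  for (digits in 1:17) {
    s <- formatC(x, digits = digits, format = "g", flag = "#")
    s <- sub("\\.$", "", s)
    if (!grepl("e", s) && as.numeric(s) == x) return(s)
  }
  sprintf("%.17g", x)
}

#' Write the two-state outcome report
#'
#' Emits the published table's layout as CSV: per-center rows and a TOTAL
#' row for each state, then a differential footer row (current totals minus
#' future totals). Columns are exactly
#' `state,center_class,surgeries,deaths,complications,complication_costs_usd`.
#' Machine output keeps costs as plain numbers; `pretty = TRUE` formats
#' dollars with separators for human reading.
#'
#' @param current,future `state_result` objects over the same cohort.
#' @param path Output CSV path.
#' @param pretty Format costs as `$1,234,567` instead of plain numbers.
#' @return Invisibly, the report as a data frame.
#' @export
write_report <- function(current, future, path, pretty = FALSE) {
  diff <- compare_states(current, future)

  state_rows <- function(s) {
    rbind(
      data.frame(state = s$label,
                 center_class = s$outcomes$center_class,
                 surgeries = s$outcomes$n_surgeries,
                 deaths = s$outcomes$n_deaths,
                 complications = s$outcomes$n_complications,
                 complication_costs_usd = s$outcomes$complication_cost,
                 stringsAsFactors = FALSE),
      data.frame(state = s$label, center_class = "TOTAL",
                 surgeries = s$total_surgeries,
                 deaths = s$total_deaths,
                 complications = s$total_complications,
                 complication_costs_usd = s$total_cost,
                 stringsAsFactors = FALSE)
    )
  }

  tab <- rbind(
    state_rows(current),
    state_rows(future),
    data.frame(state = "differential", center_class = "TOTAL",
               surgeries = current$total_surgeries - future$total_surgeries,
               deaths = diff$delta_deaths,
               complications = diff$delta_complications,
               complication_costs_usd = diff$delta_cost,
               stringsAsFactors = FALSE)
  )

  out <- tab
  out$surgeries <- vapply(tab$surgeries, .format_number, "")
  out$deaths <- vapply(tab$deaths, .format_number, "")
  out$complications <- vapply(tab$complications, .format_number, "")
  if (pretty) {
    out$complication_costs_usd <- paste0(
      "$", formatC(tab$complication_costs_usd, format = "f", digits = 0,
                   big.mark = ","))
  } else {
    out$complication_costs_usd <-
      vapply(tab$complication_costs_usd, .format_number, "")
  }
  lines <- c(paste(names(out), collapse = ","),
             apply(out, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(tab)
}

#' Validate an emitted report file
#'
#' Re-parses a [write_report()] CSV and checks its arithmetic: each state's
#' TOTAL row equals the column sums of its center rows, and the differential
#' row equals current totals minus future totals.
#'
#' @param path Report CSV path (machine format, not `pretty`).
#' @return `TRUE` invisibly if the report is internally consistent; error
#'   otherwise.
#' @export
validate_report <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  expected_cols <- c("state", "center_class", "surgeries", "deaths",
                     "complications", "complication_costs_usd")
  if (!identical(names(df), expected_cols)) {
    stop("report columns are not the canonical layout", call. = FALSE)
  }
  num_cols <- expected_cols[3:6]
  states <- setdiff(unique(df$state), "differential")
  if (length(states) != 2) {
    stop("report must contain exactly two states plus a differential row",
         call. = FALSE)
  }
  totals <- list()
  for (s in states) {
    centers <- df[df$state == s & df$center_class != "TOTAL", ]
    total <- df[df$state == s & df$center_class == "TOTAL", ]
    if (nrow(total) != 1) stop("state '", s, "' needs one TOTAL row",
                               call. = FALSE)
    for (col in num_cols) {
      if (abs(sum(centers[[col]]) - total[[col]]) > 1e-6) {
        stop(sprintf("TOTAL row of state '%s' does not sum in column %s",
                     s, col), call. = FALSE)
      }
    }
    totals[[s]] <- total
  }
  d <- df[df$state == "differential", ]
  if (nrow(d) != 1) stop("report needs one differential row", call. = FALSE)
  for (col in num_cols) {
    if (abs((totals[[1]][[col]] - totals[[2]][[col]]) - d[[col]]) > 1e-6) {
      stop("differential row inconsistent in column ", col, call. = FALSE)
    }
  }
  invisible(TRUE)
}
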