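#' @title Tidy input tables
#' @description
#' The pipeline consumes five tidy CSV tables (comma-separated, UTF-8, "."
#' decimal, mandatory header row). All concentrations are molar
#' (\eqn{\mu}mol/L) unless a file is read with `unit = "ug/mL"`, in which
#' case values are converted on ingestion; retrodialysis concentrations are
#' always \eqn{\mu}g/mL (the unit the retroperfusate is prepared in). Times
#' are hours; plasma/dialysate times are relative to the start of their
#' dosing interval.
#'
#' \describe{
#'   \item{plasma}{`subject_id, analyte, interval_index, time, concentration[, below_lloq]`}
#'   \item{dialysate}{`subject_id, analyte, catheter_id, interval_index, t_start, t_end, concentration[, below_lloq]`}
#'   \item{retrodialysis}{`subject_id, catheter_id, occasion[, replicate], retroperfusate_conc, retrodialysate_conc`}
#'   \item{doses}{`subject_id, interval_index, start_time, amount, route, duration`}
#'   \item{subjects}{`subject_id, phenotype, body_weight`}
#' }
#' @name input-tables
NULL

PHENOTYPES <- c("RM", "NM", "RM_PM", "IM")
ROUTES <- c("iv_infusion", "oral")

.required_cols <- list(
  plasma = c("subject_id", "analyte", "interval_index", "time", "concentration"),
  dialysate = c("subject_id", "analyte", "catheter_id", "interval_index",
                "t_start", "t_end", "concentration"),
  retrodialysis = c("subject_id", "catheter_id", "occasion",
                    "retroperfusate_conc", "retrodialysate_conc"),
  doses = c("subject_id", "interval_index", "start_time", "amount",
            "route", "duration"),
  subjects = c("subject_id", "phenotype", "body_weight")
)

.schema_stop <- function(schema, row, msg) {
  stop(sprintf("[%s] row %s: %s", schema, paste(row, collapse = ","), msg),
       call. = FALSE)
}

#' Read and validate one of the five input tables
#'
#' Reads a CSV, checks the declared schema (column presence, value ranges,
#' interval ordering), flags below-LLOQ concentrations, and returns a
#' validated data frame. Validation failures name the offending row so the
#' source file can be fixed.
#'
#' @param path Path to a CSV file.
#' @param schema One of `"plasma"`, `"dialysate"`, `"retrodialysis"`,
#'   `"doses"`, `"subjects"`.
#' @param analytes Analyte set, as from [default_analytes()]; used for unit
#'   conversion and LLOQ flagging of sample tables.
#' @param unit Concentration unit of the file for plasma/dialysate tables:
#'   `"umol/L"` (canonical, default) or `"ug/mL"` (converted on read).
#' @return A validated data frame with a `row` provenance column (original
#'   file row) for sample tables.
#' @export
read_samples <- function(path, schema = c("plasma", "dialysate",
                                          "retrodialysis", "doses", "subjects"),
                         analytes = default_analytes(),
                         unit = c("umol/L", "ug/mL")) {
  schema <- match.arg(schema)
  unit <- match.arg(unit)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_table(df, schema, analytes = analytes, unit = unit)
}

#' Validate an in-memory input table
#'
#' Same checks as [read_samples()] for a data frame already in memory.
#'
#' @inheritParams read_samples
#' @param df Data frame with the columns of the declared schema.
#' @return The validated (possibly unit-converted and LLOQ-flagged) table.
#' @export
validate_table <- function(df, schema, analytes = default_analytes(),
                           unit = "umol/L") {
  need <- .required_cols[[schema]]
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop(sprintf("[%s] missing column(s): %s", schema,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df$row <- seq_len(nrow(df))

  if (schema == "subjects") {
    bad <- which(!(df$phenotype %in% PHENOTYPES))
    if (length(bad)) .schema_stop(schema, bad[1],
      sprintf("phenotype '%s' not in {%s}", df$phenotype[bad[1]],
              paste(PHENOTYPES, collapse = ", ")))
    bad <- which(!is.finite(df$body_weight) | df$body_weight <= 0)
    if (length(bad)) .schema_stop(schema, bad[1], "body_weight must be > 0")
    return(df)
  }

  if (schema == "doses") {
    bad <- which(!is.finite(df$amount) | df$amount <= 0)
    if (length(bad)) .schema_stop(schema, bad[1], "amount must be > 0")
    bad <- which(!(df$route %in% ROUTES))
    if (length(bad)) .schema_stop(schema, bad[1],
      sprintf("route '%s' not in {%s}", df$route[bad[1]],
              paste(ROUTES, collapse = ", ")))
    bad <- which(df$duration < 0 |
                 (df$route == "iv_infusion") != (df$duration > 0))
    if (length(bad)) .schema_stop(schema, bad[1],
      "duration must be > 0 for iv_infusion and 0 for oral")
    for (s in unique(df$subject_id)) {
      d <- df[df$subject_id == s, ]
      d <- d[order(d$start_time), ]
      if (is.unsorted(d$interval_index, strictly = TRUE)) {
        .schema_stop(schema, d$row[1],
          sprintf("interval_index not strictly increasing with start_time for subject %s", s))
      }
    }
    return(df)
  }

  if (schema == "retrodialysis") {
    bad <- which(!is.finite(df$retroperfusate_conc) | df$retroperfusate_conc <= 0 |
                 !is.finite(df$retrodialysate_conc) | df$retrodialysate_conc <= 0)
    if (length(bad)) .schema_stop(schema, bad[1],
      "retroperfusate and retrodialysate concentrations must be > 0")
    over <- which(df$retrodialysate_conc > df$retroperfusate_conc)
    if (length(over)) {
      warning(sprintf("[retrodialysis] %d record(s) with retrodialysate > retroperfusate (rows %s): implied delivery < 0%%, records will be excluded from calibration",
                      length(over), paste(over, collapse = ",")),
              call. = FALSE)
    }
    if (!"replicate" %in% names(df)) df$replicate <- 1L
    return(df)
  }

  ## plasma / dialysate sample tables
  bad <- which(!is.finite(df$concentration) | df$concentration < 0)
  if (length(bad)) .schema_stop(schema, bad[1], "concentration must be >= 0")
  if (unit == "ug/mL") {
    for (a in unique(df$analyte)) {
      if (!a %in% names(analytes)) {
        .schema_stop(schema, which(df$analyte == a)[1],
                     sprintf("unknown analyte '%s'", a))
      }
      i <- df$analyte == a
      df$concentration[i] <- ugml_to_umolL(df$concentration[i], analytes[[a]])
    }
  }
  bad <- which(!(df$analyte %in% names(analytes)))
  if (length(bad)) .schema_stop(schema, bad[1],
    sprintf("unknown analyte '%s'", df$analyte[bad[1]]))

  if (schema == "plasma") {
    bad <- which(df$time < 0)
    if (length(bad)) .schema_stop(schema, bad[1], "time must be >= 0")
  } else {
    bad <- which(!(df$t_end > df$t_start) | df$t_start < 0)
    if (length(bad)) .schema_stop(schema, bad[1],
                                  "need t_end > t_start >= 0")
    key <- interaction(df$subject_id, df$analyte, df$catheter_id,
                       df$interval_index, drop = TRUE)
    for (k in levels(key)) {
      d <- df[key == k, ]
      d <- d[order(d$t_start), ]
      if (nrow(d) > 1 && any(d$t_start[-1] < d$t_end[-nrow(d)] - 1e-9)) {
        i <- which(d$t_start[-1] < d$t_end[-nrow(d)] - 1e-9)[1]
        .schema_stop(schema, d$row[i + 1], "overlapping collection intervals")
      }
    }
  }

  ## LLOQ flagging: a stated below_lloq column is honoured, otherwise
  ## concentrations are compared against the analyte's matrix LLOQ.
  mat <- if (schema == "plasma") "plasma" else "dialysate"
  lloq <- vapply(df$analyte, function(a) lloq_umolL(analytes[[a]], mat), 0)
  computed <- df$concentration < lloq
  if ("below_lloq" %in% names(df)) {
    df$below_lloq <- as.logical(df$below_lloq) | computed
  } else {
    df$below_lloq <- computed
  }
  df
}

#' Write an input table to CSV
#'
#' Writes the canonical CSV dialect (comma, ".", header, no row names, no
#' quoting of numerics). Reading the file back with [read_samples()]
#' reproduces all records.
#'
#' @param df A validated table.
#' @param path Output path.
#' @export
write_table_csv <- function(df, path) {
  df <- df[, setdiff(names(df), "row"), drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Concentration-time profile
#'
#' One subject x analyte x matrix x dosing-interval series ready for
#' noncompartmental analysis: strictly increasing times (hours, relative to
#' interval start), positive concentrations (\eqn{\mu}mol/L), BLQ records
#' already removed. A leading zero concentration is permitted only as the
#' pre-first-dose anchor at t = 0.
#'
#' @param subject_id,analyte,matrix,interval_index Series identity; `matrix`
#'   is `"plasma"` or `"isf"`.
#' @param time,concentration Numeric vectors of equal length.
#' @return An object of class `conc_profile`.
#' @export
conc_profile <- function(subject_id, analyte, matrix, interval_index,
                         time, concentration) {
  stopifnot(length(time) == length(concentration))
  if (length(time) == 0L) {
    stop("empty profile", call. = FALSE)
  }
  o <- order(time)
  time <- time[o]; concentration <- concentration[o]
  if (any(diff(time) <= 0)) {
    stop("profile times must be strictly increasing", call. = FALSE)
  }
  if (any(concentration < 0) || any(concentration[-1] == 0)) {
    stop("profile concentrations must be positive (zero allowed only at the leading anchor)",
         call. = FALSE)
  }
  structure(
    list(subject_id = subject_id, analyte = analyte, matrix = matrix,
         interval_index = interval_index, time = time,
         concentration = concentration),
    class = "conc_profile"
  )
}

#' @export
print.conc_profile <- function(x, ...) {
  cat(sprintf("<conc_profile> %s %s %s interval %s: %d points, t in [%g, %g] h\n",
              x$subject_id, x$analyte, x$matrix, x$interval_index,
              length(x$time), min(x$time), max(x$time)))
  invisible(x)
}

#' @export
as.data.frame.conc_profile <- function(x, ...) {
  data.frame(subject_id = x$subject_id, analyte = x$analyte,
             matrix = x$matrix, interval_index = x$interval_index,
             time = x$time, concentration = x$concentration)
}

#' Remove below-LLOQ records and build a profile
#'
#' Drops BLQ records from one subject x analyte x matrix x interval slice of
#' a sample table and returns a [conc_profile()]. The pre-dose baseline of
#' the first dosing interval (a BLQ observation at t = 0 before any drug has
#' been given) is represented as an explicit zero-concentration anchor at
#' t = 0 rather than dropped; no half-LLOQ imputation is performed.
#'
#' @param records Rows of a validated plasma-style table (columns `time`,
#'   `concentration`, `below_lloq`) for a single series.
#' @param subject_id,analyte,matrix,interval_index Series identity.
#' @return A `conc_profile`, or `NULL` (with a warning) when every record is
#'   BLQ and no profile can be formed.
#' @export
drop_blq <- function(records, subject_id, analyte, matrix, interval_index) {
  keep <- !records$below_lloq
  anchor0 <- interval_index == 1 && any(records$below_lloq & records$time == 0)
  records <- records[keep, , drop = FALSE]
  time <- records$time
  conc <- records$concentration
  if (anchor0) {
    time <- c(0, time)
    conc <- c(0, conc)
  }
  if (length(time) == 0L) {
    warning(sprintf("all records below LLOQ for %s %s %s interval %s; empty profile",
                    subject_id, analyte, matrix, interval_index), call. = FALSE)
    return(NULL)
  }
  conc_profile(subject_id, analyte, matrix, interval_index, time, conc)
}
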