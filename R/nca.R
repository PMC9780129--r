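#' Assign mid-time points to dialysate collection intervals
#'
#' Each microdialysate sample integrates the ISF concentration over a
#' collection interval; for all time-based evaluations the sample is placed
#' at the interval's arithmetic midpoint \eqn{(t_{start}+t_{end})/2}.
#'
#' @param t_start,t_end Numeric vectors of interval bounds (hours, relative
#'   to the dosing-interval start); must be valid, sorted, non-overlapping.
#' @return Numeric vector of midpoint times.
#' @examples
#' assign_midpoints(c(0, 0.5), c(0.5, 1))  # 0.25 0.75
#' @export
assign_midpoints <- function(t_start, t_end) {
  stopifnot(length(t_start) == length(t_end))
  if (any(t_end <= t_start)) stop("need t_end > t_start", call. = FALSE)
  (t_start + t_end) / 2
}

#' AUC by the linear-up/log-down trapezoidal rule
#'
#' Computes the area under the concentration-time curve from the first
#' point (or an optional prepended anchor) to the last positive
#' concentration. Rising or flat segments, and any segment touching a zero
#' concentration, contribute the arithmetic trapezoid
#' \eqn{(C_1+C_2)/2\,\Delta t}; strictly declining positive segments
#' contribute the logarithmic-mean trapezoid
#' \eqn{(C_1-C_2)/\ln(C_1/C_2)\,\Delta t}, which is exact for
#' mono-exponential decline.
#'
#' @param time,conc Numeric vectors; strictly increasing times, non-negative
#'   concentrations (zero only as a leading anchor or trailing BLQ-censored
#'   boundary).
#' @param anchor Optional `c(time, concentration)` prepended before the first
#'   point (e.g. a zero pre-dose anchor or a steady-state carry-back value).
#' @return A list with `auc_last` (\eqn{\mu}mol h/L) and `t_last` (h, time
#'   of the last positive concentration), or `NULL` when fewer than two
#'   usable points remain.
#' @examples
#' auc_linuplogdown(c(0, 1), c(0, 10))$auc_last  # 5
#' auc_linuplogdown(c(0, 1), c(10, 5))$auc_last  # 5 / log(2)
#' @export
auc_linuplogdown <- function(time, conc, anchor = NULL) {
  stopifnot(length(time) == length(conc))
  if (!is.null(anchor)) {
    stopifnot(length(anchor) == 2)
    if (length(time) && anchor[1] >= time[1]) {
      stop("anchor time must precede the first observation", call. = FALSE)
    }
    time <- c(anchor[1], time)
    conc <- c(anchor[2], conc)
  }
  if (any(diff(time) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(conc < 0)) stop("negative concentration", call. = FALSE)
  ## integrate up to the last positive concentration only
  pos <- which(conc > 0)
  if (length(pos) == 0L) return(NULL)
  i_last <- pos[length(pos)]
  time <- time[seq_len(i_last)]
  conc <- conc[seq_len(i_last)]
  if (length(time) < 2L) return(NULL)

  c1 <- conc[-length(conc)]; c2 <- conc[-1]
  dt <- diff(time)
  lin <- (c1 + c2) / 2 * dt
  logdown <- c2 < c1 & c2 > 0 & c1 > 0
  seg <- lin
  seg[logdown] <- (c1[logdown] - c2[logdown]) /
    log(c1[logdown] / c2[logdown]) * dt[logdown]
  list(auc_last = sum(seg), t_last = time[length(time)])
}

#' Maximum concentration and its time
#'
#' @param time,conc Profile vectors; ties in the maximum are broken to the
#'   earliest time (standard NCA convention).
#' @return List with `c_max` and `t_max`.
#' @export
cmax_tmax <- function(time, conc) {
  if (length(conc) == 0L) stop("empty profile", call. = FALSE)
  i <- which.max(conc)  # which.max returns the first (earliest) maximum
  list(c_max = conc[i], t_max = time[i])
}

#' Trough concentration at the end of a 12 h dosing interval
#'
#' Returns the concentration of the profile point closest to 12 h within a
#' tolerance. Plasma profiles carry an exact 12 h sample; ISF profiles end
#' at the 11.5 h midpoint of the final collection interval, hence the
#' default tolerance of 0.6 h.
#'
#' @param time,conc Profile vectors.
#' @param at Nominal trough time (h), default 12.
#' @param tolerance Admissible distance from `at` (h).
#' @return `c_min` (\eqn{\mu}mol/L), or `NULL` when no point lies within
#'   tolerance (missing-trough signal).
#' @export
cmin_12h <- function(time, conc, at = 12, tolerance = 0.6) {
  d <- abs(time - at)
  if (!length(d) || min(d) > tolerance) return(NULL)
  conc[which.min(d)]
}

#' Classify a voriconazole plasma trough against the therapeutic window
#'
#' The therapeutic-drug-monitoring target for total voriconazole plasma
#' trough concentrations is 1-2 ug/mL (2.86-5.73 umol/L), not to exceed
#' 4.5-6 ug/mL (12.9-17.2 umol/L). Classification uses the permissive
#' reading of the soft bands: `below` under 2.86, `above` only beyond
#' 17.2, `within` otherwise, with troughs in (12.9, 17.2] additionally
#' flagged `borderline_high`.
#'
#' @param c_min Trough concentration, \eqn{\mu}mol/L (total VRC in plasma).
#' @return List with `class` (one of `"below"`, `"within"`, `"above"`),
#'   `borderline_high` flag, and the four band edges.
#' @examples
#' classify_window(2.22)$class   # "below"
#' classify_window(12.0)$class   # "within"
#' @export
classify_window <- function(c_min) {
  if (!is.finite(c_min) || c_min < 0) stop("invalid trough concentration", call. = FALSE)
  edges <- c(lower = 2.86, lower_upper = 5.73, upper_soft = 12.9, upper = 17.2)
  cls <- if (c_min < edges[["lower"]]) "below"
         else if (c_min > edges[["upper"]]) "above"
         else "within"
  list(class = cls,
       borderline_high = c_min > edges[["upper_soft"]] && c_min <= edges[["upper"]],
       edges = edges)
}

#' Noncompartmental metrics for one concentration-time profile
#'
#' Computes AUC to the last positive concentration (linear-up/log-down),
#' Cmax/tmax, the 12 h trough, and — for voriconazole plasma profiles —
#' the therapeutic-window class of the trough.
#'
#' ISF profiles have no observation at t = 0; the AUC anchor there is
#' policy-driven: `"zero"` prepends a zero anchor (single-dose interval),
#' `"carry_back"` prepends the first observed value at t = 0 (steady-state
#' intervals), `"none"` integrates from the first midpoint.
#'
#' @param profile A [conc_profile()].
#' @param isf_anchor Anchor policy for ISF profiles of multiple-dose
#'   intervals; the first dosing interval always uses a zero anchor (no drug
#'   is present before the first dose).
#' @param cmin_tolerance Tolerance (h) passed to [cmin_12h()].
#' @param warn Emit a warning when the AUC is undefined (fewer than two
#'   usable points, as in sparsely sampled intervals).
#' @return One-row data frame of class `pk_metrics` with fields
#'   `subject_id, analyte, matrix, interval_index, auc_last, t_last, c_max,
#'   t_max, c_min, n_points, window_class, borderline_high, anchor_policy`.
#' @export
nca_profile <- function(profile,
                        isf_anchor = c("carry_back", "zero", "none"),
                        cmin_tolerance = 0.6, warn = TRUE) {
  isf_anchor <- match.arg(isf_anchor)
  stopifnot(inherits(profile, "conc_profile"))
  time <- profile$time; conc <- profile$concentration
  anchor <- NULL
  policy <- "observed"
  if (profile$matrix == "isf" && time[1] > 0) {
    if (profile$interval_index == 1) {
      anchor <- c(0, 0); policy <- "zero"
    } else if (isf_anchor == "zero") {
      anchor <- c(0, 0); policy <- "zero"
    } else if (isf_anchor == "carry_back") {
      anchor <- c(0, conc[1]); policy <- "carry_back"
    } else {
      policy <- "none"
    }
  }
  auc <- auc_linuplogdown(time, conc, anchor = anchor)
  if (is.null(auc)) {
    if (warn) {
      warning(sprintf("undefined AUC (fewer than 2 usable points) for %s %s %s interval %s",
                      profile$subject_id, profile$analyte, profile$matrix,
                      profile$interval_index), call. = FALSE)
    }
    auc <- list(auc_last = NA_real_, t_last = NA_real_)
  }
  mx <- cmax_tmax(time, conc)
  cmin <- cmin_12h(time, conc, tolerance = cmin_tolerance)
  wc <- "not_applicable"; border <- NA
  if (profile$analyte == "VRC" && profile$matrix == "plasma" && !is.null(cmin)) {
    w <- classify_window(cmin)
    wc <- w$class; border <- w$borderline_high
  }
  out <- data.frame(subject_id = profile$subject_id, analyte = profile$analyte,
                    matrix = profile$matrix,
                    interval_index = profile$interval_index,
                    auc_last = auc$auc_last, t_last = auc$t_last,
                    c_max = mx$c_max, t_max = mx$t_max,
                    c_min = if (is.null(cmin)) NA_real_ else cmin,
                    n_points = length(time), window_class = wc,
                    borderline_high = border, anchor_policy = policy,
                    stringsAsFactors = FALSE)
  class(out) <- c("pk_metrics", class(out))
  out
}

#' Noncompartmental analysis of a set of profiles
#'
#' @param profiles List of [conc_profile()] objects.
#' @inheritParams nca_profile
#' @return `pk_metrics` data frame, one row per profile.
#' @export
nca_table <- function(profiles, isf_anchor = "carry_back",
                      cmin_tolerance = 0.6, warn = FALSE) {
  out <- do.call(rbind, lapply(profiles, nca_profile,
                               isf_anchor = isf_anchor,
                               cmin_tolerance = cmin_tolerance, warn = warn))
  rownames(out) <- NULL
  out
}
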