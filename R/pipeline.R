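#' Build concentration-time profiles from validated tables
#'
#' Plasma profiles are formed per subject x analyte x interval after BLQ
#' removal ([drop_blq()]); dialysate samples are calibrated to ISF
#' concentrations ([apply_calibration()]), placed at interval midpoints
#' ([assign_midpoints()]) and formed into ISF profiles.
#'
#' @param tables List with validated `plasma`, `dialysate`, `retrodialysis`
#'   tables (as returned by [simulate_trial()] or read with
#'   [read_samples()]).
#' @param average_within_occasion Passed to [aggregate_calibration()].
#' @return List with `profiles` (list of [conc_profile()]), `calibration`
#'   (per-catheter table) and `log` (exclusion counts).
#' @export
build_profiles <- function(tables, average_within_occasion = TRUE) {
  retro <- tables$retrodialysis
  calib <- do.call(rbind, lapply(split(retro, retro$subject_id),
                                 aggregate_calibration,
                                 average_within_occasion = average_within_occasion))
  rownames(calib) <- NULL
  dial <- apply_calibration(tables$dialysate, calib)

  profiles <- list()
  log <- list(n_blq_plasma = sum(tables$plasma$below_lloq),
              n_blq_dialysate = sum(tables$dialysate$below_lloq),
              empty_profiles = character(0))
  add_profile <- function(p) {
    if (!is.null(p)) profiles[[length(profiles) + 1L]] <<- p
  }

  pl <- tables$plasma
  for (g in split(pl, list(pl$subject_id, pl$analyte, pl$interval_index),
                  drop = TRUE)) {
    p <- withCallingHandlers(
      drop_blq(g, g$subject_id[1], g$analyte[1], "plasma", g$interval_index[1]),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(p)) {
      log$empty_profiles <- c(log$empty_profiles,
                              paste(g$subject_id[1], g$analyte[1], "plasma",
                                    g$interval_index[1]))
    }
    add_profile(p)
  }

  for (g in split(dial, list(dial$subject_id, dial$analyte, dial$interval_index),
                  drop = TRUE)) {
    keep <- !g$below_lloq
    if (!any(keep)) {
      log$empty_profiles <- c(log$empty_profiles,
                              paste(g$subject_id[1], g$analyte[1], "isf",
                                    g$interval_index[1]))
      next
    }
    g <- g[keep, , drop = FALSE]
    g <- g[order(g$t_start), , drop = FALSE]
    add_profile(conc_profile(g$subject_id[1], g$analyte[1], "isf",
                             g$interval_index[1],
                             assign_midpoints(g$t_start, g$t_end),
                             g$conc_isf))
  }
  list(profiles = profiles, calibration = calib, log = log)
}

.find_metric <- function(metrics, sid, analyte, matrix, interval) {
  i <- metrics$subject_id == sid & metrics$analyte == analyte &
    metrics$matrix == matrix & metrics$interval_index == interval
  if (!any(i)) NA_real_ else metrics$auc_last[which(i)[1]]
}

#' Run the full analysis pipeline
#'
#' Orchestrates calibration, profile building, noncompartmental analysis and
#' the ratio analyses over a set of input tables (measured or simulated).
#' Stage failures abort with the stage name.
#'
#' @param tables List of the five validated input tables, or a `sim_trial`.
#'   Alternatively `scenario` may be given.
#' @param scenario Optional `sim_scenario`; when supplied (and `tables` is
#'   `NULL`) the trial is simulated first.
#' @param isf_anchor ISF AUC anchor policy for multiple-dose intervals
#'   (`"carry_back"`, `"zero"`, `"none"`), see [nca_profile()].
#' @param cmin_tolerance Trough-matching tolerance in hours.
#' @param fu_vrc Fraction unbound used for unbound-corrected penetration of
#'   the parent.
#' @param average_within_occasion Retrodialysis replicate policy, see
#'   [aggregate_calibration()].
#' @return Object of class `vrc_run`: list with `calibration`, `metrics`
#'   (PK metrics table), `penetration` (ISF:plasma AUC ratio table),
#'   `metabolic` (NO:VRC AUC ratio table), `ratio_points`,
#'   `ratio_summaries`, `trend` (ratio-vs-concentration statistic per
#'   subject x matrix), `fold_ranges`, `window` (trough classification),
#'   `log`, and `config`.
#' @export
run_pipeline <- function(tables = NULL, scenario = NULL,
                         isf_anchor = c("carry_back", "zero", "none"),
                         cmin_tolerance = 0.6, fu_vrc = 0.50,
                         average_within_occasion = TRUE) {
  isf_anchor <- match.arg(isf_anchor)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  if (is.null(tables)) {
    if (is.null(scenario)) stop("either tables or scenario must be supplied",
                                call. = FALSE)
    tables <- stage("simulate", simulate_trial(scenario))
  }
  for (nm in c("plasma", "dialysate", "retrodialysis")) {
    if (is.null(tables[[nm]])) {
      stage(if (nm == "retrodialysis" || nm == "dialysate") "calibration" else "profiles",
            stop(sprintf("missing input table '%s'", nm)))
    }
  }

  built <- stage("calibration", build_profiles(tables, average_within_occasion))
  metrics <- stage("nca", nca_table(built$profiles, isf_anchor = isf_anchor,
                                    cmin_tolerance = cmin_tolerance))

  subjects <- tables$subjects
  pheno <- function(sid) {
    subjects$phenotype[match(sid, subjects$subject_id)]
  }
  sids <- unique(metrics$subject_id)
  rich <- sort(unique(metrics$interval_index[metrics$matrix == "isf" &
                                             metrics$n_points >= 8]))

  penetration <- stage("ratios", {
    rows <- list()
    for (sid in sids) for (a in c("VRC", "NO")) for (k in rich) {
      auc_p <- .find_metric(metrics, sid, a, "plasma", k)
      auc_i <- .find_metric(metrics, sid, a, "isf", k)
      if (is.na(auc_p) || is.na(auc_i)) next
      pr <- penetration_ratio(auc_i, auc_p,
                              fu = if (a == "VRC") fu_vrc else NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, phenotype = pheno(sid), analyte = a,
        interval_index = k, auc_isf = auc_i, auc_plasma = auc_p,
        ratio = pr$raw, unbound_corrected = pr$unbound_corrected,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })

  metabolic <- stage("ratios", {
    rows <- list()
    for (sid in sids) for (mx in c("plasma", "isf")) for (k in rich) {
      auc_v <- .find_metric(metrics, sid, "VRC", mx, k)
      auc_n <- .find_metric(metrics, sid, "NO", mx, k)
      if (is.na(auc_v) || is.na(auc_n)) next
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, phenotype = pheno(sid), matrix = mx,
        interval_index = k, auc_no = auc_n, auc_vrc = auc_v,
        ratio = auc_metabolic_ratio(auc_n, auc_v), stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })

  ratio_points <- stage("ratios", {
    key <- vapply(built$profiles, function(p)
      paste(p$subject_id, p$matrix, p$interval_index, sep = "\r"), "")
    analyte <- vapply(built$profiles, `[[`, "", "analyte")
    pts <- list(); skipped <- 0L
    for (k in unique(key)) {
      iv <- which(key == k & analyte == "VRC")
      io <- which(key == k & analyte == "NO")
      if (length(iv) == 1L && length(io) == 1L) {
        rp <- suppressWarnings(concentration_ratios(built$profiles[[iv]],
                                                    built$profiles[[io]]))
        skipped <- skipped + attr(rp, "n_skipped")
        pts[[length(pts) + 1L]] <- rp
      }
    }
    out <- do.call(rbind, pts)
    attr(out, "n_skipped") <- skipped
    out
  })
  built$log$n_ratio_points_skipped <- attr(ratio_points, "n_skipped")

  summaries <- stage("ratios", ratio_summaries(ratio_points))

  trend <- stage("ratios", {
    rows <- list()
    for (g in split(ratio_points,
                    list(ratio_points$subject_id, ratio_points$matrix),
                    drop = TRUE)) {
      if (nrow(g) < 3L || diff(range(g$vrc_conc)) == 0) next
      tr <- ratio_vs_concentration(g)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = g$subject_id[1], phenotype = pheno(g$subject_id[1]),
        matrix = g$matrix[1], n = tr$n, trend = tr$trend,
        saturation_consistent = tr$saturation_consistent,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })

  fold_ranges <- stage("ratios", {
    rows <- list()
    for (a in c("VRC", "NO")) for (mx in c("plasma", "isf")) for (k in rich) {
      i <- metrics$analyte == a & metrics$matrix == mx &
        metrics$interval_index == k & is.finite(metrics$auc_last)
      if (sum(i) < 2) next
      fr <- fold_range(metrics$auc_last[i], metrics$subject_id[i])
      rows[[length(rows) + 1L]] <- data.frame(
        analyte = a, matrix = mx, interval_index = k, fold = fr$fold,
        max_subject = fr$argmax_id, min_subject = fr$argmin_id,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })

  window <- stage("reporting", {
    i <- metrics$analyte == "VRC" & metrics$matrix == "plasma" &
      is.finite(metrics$c_min)
    data.frame(subject_id = metrics$subject_id[i],
               phenotype = pheno(metrics$subject_id[i]),
               interval_index = metrics$interval_index[i],
               c_min = metrics$c_min[i],
               window_class = metrics$window_class[i],
               borderline_high = metrics$borderline_high[i],
               stringsAsFactors = FALSE)
  })

  structure(
    list(calibration = built$calibration, metrics = metrics,
         penetration = penetration, metabolic = metabolic,
         ratio_points = ratio_points, ratio_summaries = summaries,
         trend = trend, fold_ranges = fold_ranges, window = window,
         log = built$log,
         config = list(isf_anchor = isf_anchor,
                       cmin_tolerance = cmin_tolerance, fu_vrc = fu_vrc,
                       average_within_occasion = average_within_occasion)),
    class = "vrc_run"
  )
}

#' @export
print.vrc_run <- function(x, ...) {
  cat("Voriconazole microdialysis PK analysis\n")
  cat(sprintf("  catheters calibrated : %d (rD %.1f-%.1f%%)\n",
              nrow(x$calibration), min(x$calibration$rd_percent),
              max(x$calibration$rd_percent)))
  cat(sprintf("  PK metric rows       : %d (anchor policy: %s)\n",
              nrow(x$metrics), x$config$isf_anchor))
  cat(sprintf("  BLQ excluded         : %d plasma, %d dialysate\n",
              x$log$n_blq_plasma, x$log$n_blq_dialysate))
  cat(sprintf("  ratio points         : %d (%d skipped)\n",
              nrow(x$ratio_points), x$log$n_ratio_points_skipped))
  invisible(x)
}

#' @export
summary.vrc_run <- function(object, ...) {
  cat("== ISF:plasma AUC penetration (rich intervals) ==\n")
  print(.wide_ratio(object$penetration, "analyte"), row.names = FALSE)
  cat("\n== NO:VRC metabolic AUC ratio ==\n")
  print(.wide_ratio(object$metabolic, "matrix"), row.names = FALSE)
  cat("\n== VRC plasma trough window classification ==\n")
  print(object$window, row.names = FALSE)
  invisible(object)
}

## phenotype x interval wide rendering of a long ratio table
.wide_ratio <- function(long, facet) {
  out <- list()
  for (f in unique(long[[facet]])) {
    d <- long[long[[facet]] == f, ]
    w <- stats::reshape(d[, c("phenotype", "interval_index", "ratio")],
                        idvar = "phenotype", timevar = "interval_index",
                        direction = "wide")
    names(w) <- sub("^ratio\\.", "interval_", names(w))
    w <- cbind(stats::setNames(data.frame(f), facet), w)
    out[[length(out) + 1L]] <- w
  }
  do.call(rbind, out)
}

#' Write the report bundle of a pipeline run
#'
#' Writes the calibration report, PK metrics table, penetration and
#' metabolic ratio tables, ratio-point long table, trend statistics, trough
#' window classification and a run log as CSV/text files. Outputs are
#' deterministic: the same run object yields byte-identical files.
#'
#' @param run A `vrc_run`.
#' @param dir Output directory (created if missing).
#' @return Character vector of file paths, invisibly.
#' @export
write_report_bundle <- function(run, dir) {
  stopifnot(inherits(run, "vrc_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  calib <- run$calibration
  calib$per_occasion_rd <- vapply(calib$per_occasion_rd, paste,
                                  "", collapse = ";")
  files <- c(
    calibration = "calibration.csv", metrics = "pk_metrics.csv",
    penetration = "penetration_ratios.csv", metabolic = "metabolic_ratios.csv",
    ratio_points = "ratio_points.csv", ratio_summaries = "ratio_summaries.csv",
    trend = "ratio_trend.csv", fold_ranges = "fold_ranges.csv",
    window = "window_classification.csv"
  )
  paths <- character(0)
  for (nm in names(files)) {
    obj <- if (nm == "calibration") calib else run[[nm]]
    p <- file.path(dir, files[[nm]])
    utils::write.csv(obj, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  logp <- file.path(dir, "run_log.txt")
  lines <- c(
    sprintf("isf_anchor: %s", run$config$isf_anchor),
    sprintf("cmin_tolerance_h: %g", run$config$cmin_tolerance),
    sprintf("fu_vrc: %g", run$config$fu_vrc),
    sprintf("average_within_occasion: %s", run$config$average_within_occasion),
    sprintf("blq_excluded_plasma: %d", run$log$n_blq_plasma),
    sprintf("blq_excluded_dialysate: %d", run$log$n_blq_dialysate),
    sprintf("ratio_points_skipped: %d", run$log$n_ratio_points_skipped),
    if (length(run$log$empty_profiles))
      paste("empty_profile:", run$log$empty_profiles) else character(0)
  )
  writeLines(lines, logp)
  invisible(c(paths, logp))
}
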