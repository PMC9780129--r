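#' Sample-level metabolic ratio points
#'
#' Matches a metabolite profile to the parent profile of the same subject,
#' matrix and dosing interval and computes the molar concentration ratio
#' NO/VRC at every matched time. Plasma samples match on identical nominal
#' times; ISF samples, placed at interval midpoints, match on identical
#' midpoints. Times at which the parent is BLQ or unmatched are skipped and
#' counted.
#'
#' @param vrc_profile,no_profile [conc_profile()] objects sharing subject,
#'   matrix and interval.
#' @param time_tol Numeric tolerance for time matching (h).
#' @return Data frame of class `ratio_points` (`subject_id, matrix,
#'   interval_index, time, vrc_conc, no_conc, ratio`) with attribute
#'   `n_skipped` (unmatched metabolite times). Zero matches yield an empty
#'   frame with a warning.
#' @export
concentration_ratios <- function(vrc_profile, no_profile, time_tol = 1e-6) {
  stopifnot(inherits(vrc_profile, "conc_profile"),
            inherits(no_profile, "conc_profile"),
            vrc_profile$matrix == no_profile$matrix,
            vrc_profile$interval_index == no_profile$interval_index,
            vrc_profile$subject_id == no_profile$subject_id)
  idx <- vapply(no_profile$time, function(t) {
    j <- which(abs(vrc_profile$time - t) <= time_tol)
    if (length(j) == 1L && vrc_profile$concentration[j] > 0) j else NA_integer_
  }, 0L)
  matched <- !is.na(idx)
  out <- data.frame(
    subject_id = rep(vrc_profile$subject_id, sum(matched)),
    matrix = rep(vrc_profile$matrix, sum(matched)),
    interval_index = rep(vrc_profile$interval_index, sum(matched)),
    time = no_profile$time[matched],
    vrc_conc = vrc_profile$concentration[idx[matched]],
    no_conc = no_profile$concentration[matched],
    stringsAsFactors = FALSE
  )
  out$ratio <- out$no_conc / out$vrc_conc
  attr(out, "n_skipped") <- sum(!matched)
  if (nrow(out) == 0L) {
    warning("no matched times between parent and metabolite profiles", call. = FALSE)
  }
  class(out) <- c("ratio_points", class(out))
  out
}

#' AUC-level metabolic ratio (metabolite/parent)
#'
#' @param auc_no,auc_vrc Molar AUCs of metabolite and parent for the same
#'   subject, matrix and dosing interval (\eqn{\mu}mol h/L).
#' @return Dimensionless AUC ratio, or `NA` with a warning when the parent
#'   AUC is zero or undefined.
#' @examples
#' auc_metabolic_ratio(50.4, 45.3)  # 1.1126 (prints as 1.11 at 3 s.f.)
#' @export
auc_metabolic_ratio <- function(auc_no, auc_vrc) {
  if (any(!is.finite(auc_vrc)) || any(auc_vrc == 0, na.rm = TRUE)) {
    warning("undefined metabolic AUC ratio: parent AUC is zero or undefined",
            call. = FALSE)
    return(rep(NA_real_, max(length(auc_no), length(auc_vrc))))
  }
  auc_no / auc_vrc
}

#' Tissue penetration ratio (ISF/plasma), optionally unbound-corrected
#'
#' The extent of target-site exposure is the ratio of the AUC in
#' interstitial space fluid to the AUC in plasma (total concentrations).
#' Because only unbound drug equilibrates into ISF, dividing the raw ratio
#' by the plasma fraction unbound gives the unbound-corrected penetration
#' (voriconazole: fu = 0.50).
#'
#' @param auc_isf,auc_plasma AUCs for the same subject, analyte, interval.
#' @param fu Optional fraction unbound; when supplied, the corrected ratio
#'   is returned alongside the raw one.
#' @return List with `raw` and `unbound_corrected` (`NA` when `fu` absent).
#' @examples
#' penetration_ratio(11.2, 25.5, fu = 0.50)$raw  # 0.4392...
#' @export
penetration_ratio <- function(auc_isf, auc_plasma, fu = NULL) {
  if (any(!is.finite(auc_plasma)) || any(auc_plasma == 0, na.rm = TRUE)) {
    warning("undefined penetration ratio: plasma AUC is zero or undefined",
            call. = FALSE)
    return(list(raw = NA_real_, unbound_corrected = NA_real_))
  }
  raw <- auc_isf / auc_plasma
  corrected <- if (is.null(fu) || is.na(fu)) NA_real_ else raw / fu
  list(raw = raw, unbound_corrected = corrected)
}

#' Fold range of a per-subject metric
#'
#' max/min of a set of positive values, together with the identities of the
#' extreme subjects — the paper-style "x-fold difference" summary of
#' interindividual variability.
#'
#' @param values Positive numeric vector (one value per subject).
#' @param ids Identifiers parallel to `values`.
#' @return List with `fold` (>= 1), `argmax_id`, `argmin_id`.
#' @examples
#' fold_range(c(25.5, 45.3), c("RM", "IM"))$fold  # 1.776...
#' @export
fold_range <- function(values, ids = seq_along(values)) {
  if (length(values) < 2L) stop("fold_range needs at least 2 values", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("fold_range requires positive values", call. = FALSE)
  }
  i_max <- which.max(values); i_min <- which.min(values)
  list(fold = values[i_max] / values[i_min],
       argmax_id = ids[i_max], argmin_id = ids[i_min])
}

#' Group summaries of metabolic ratio points
#'
#' Median, minimum, maximum and interquartile spread of the concentration
#' ratio per subject x matrix x dosing interval, computed over all ratio
#' points of the group.
#'
#' @param points `ratio_points` rows (possibly concatenated across groups).
#' @return Data frame with one row per subject x matrix x interval:
#'   `n, median, min, max, iqr`.
#' @export
ratio_summaries <- function(points) {
  if (nrow(points) == 0L) stop("no ratio points to summarize", call. = FALSE)
  groups <- split(points, list(points$subject_id, points$matrix,
                               points$interval_index), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    data.frame(subject_id = g$subject_id[1], matrix = g$matrix[1],
               interval_index = g$interval_index[1], n = nrow(g),
               median = stats::median(g$ratio), min = min(g$ratio),
               max = max(g$ratio),
               iqr = unname(diff(stats::quantile(g$ratio, c(0.25, 0.75)))),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$subject_id, out$matrix, out$interval_index), ]
}

#' Metabolic ratio versus parent concentration, with trend statistic
#'
#' Orders the ratio points by parent (VRC) concentration and computes a
#' Kendall-type rank-concordance statistic by explicit pair counting:
#' over all point pairs, concordant pairs (ratio and concentration move the
#' same way) contribute +1, discordant pairs -1, ties 0; the sum is divided
#' by the number of pairs. A clearly negative statistic — ratios falling as
#' the parent concentration rises — is the signature of saturable (or
#' auto-inhibited) metabolite formation; under first-order (linear)
#' metabolism the ratio is concentration-independent and the statistic is
#' near zero.
#'
#' @param points `ratio_points` rows (typically all samples of one subject
#'   within one matrix, pooled across dosing intervals).
#' @return List with `pairs` (data frame sorted by `vrc_conc`), `trend`
#'   (statistic in [-1, 1]), `n`, and `saturation_consistent`
#'   (`trend < 0`). Constant parent concentration gives an error (trend
#'   undefined).
#' @export
ratio_vs_concentration <- function(points) {
  n <- nrow(points)
  if (n < 3L) stop("need at least 3 ratio points for a trend", call. = FALSE)
  x <- points$vrc_conc; y <- points$ratio
  if (diff(range(x)) == 0) stop("undefined trend: constant parent concentration",
                                call. = FALSE)
  s <- 0L
  for (i in seq_len(n - 1L)) {
    dx <- x[(i + 1L):n] - x[i]
    dy <- y[(i + 1L):n] - y[i]
    s <- s + sum(sign(dx) * sign(dy))
  }
  trend <- s / (n * (n - 1) / 2)
  o <- order(points$vrc_conc)
  list(pairs = points[o, c("vrc_conc", "ratio")], trend = trend, n = n,
       saturation_consistent = trend < 0)
}
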