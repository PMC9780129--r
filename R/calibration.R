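#' Relative delivery from a retrodialysis record
#'
#' During retrodialysis the catheter is perfused with a known drug
#' concentration (retroperfusate) and the loss across the membrane is
#' measured in the collected retrodialysate. Relative delivery is
#' \deqn{rD\,[\%] = 100 - 100 \cdot C_{retrodialysate} / C_{retroperfusate}}
#' and is assumed equal to the relative recovery (RR) that dilutes tissue
#' concentrations in microdialysate.
#'
#' @param retroperfusate_conc,retrodialysate_conc Concentrations in
#'   \eqn{\mu}g/mL; the retroperfusate concentration must be positive.
#' @return Relative delivery in percent. Values outside (0, 100] (i.e.
#'   retrodialysate at or above the retroperfusate level) are returned as
#'   computed; [aggregate_calibration()] excludes them with a warning.
#' @examples
#' relative_delivery(200, 50)  # 75
#' @export
relative_delivery <- function(retroperfusate_conc, retrodialysate_conc) {
  if (any(!is.finite(retroperfusate_conc)) || any(retroperfusate_conc <= 0)) {
    stop("invalid retrodialysis record: retroperfusate concentration must be > 0",
         call. = FALSE)
  }
  if (any(retrodialysate_conc < 0)) {
    stop("invalid retrodialysis record: retrodialysate concentration must be >= 0",
         call. = FALSE)
  }
  100 - 100 * retrodialysate_conc / retroperfusate_conc
}

#' Per-catheter calibration from retrodialysis records
#'
#' Aggregates a subject's retrodialysis records into one calibration per
#' catheter. Replicate records within an occasion are averaged first, then
#' the catheter's relative delivery is the unweighted arithmetic mean over
#' its occasions. A catheter used throughout the trial is therefore
#' calibrated with the mean of both occasions; after a mid-trial catheter
#' replacement each catheter keeps only the occasions performed on it.
#'
#' Records implying rD outside (0, 100] are excluded with a warning;
#' calibrations outside a plausibility band (default 20-100%) are flagged
#' `suspect` but retained.
#'
#' @param records Validated retrodialysis table rows for one subject
#'   (columns `subject_id, catheter_id, occasion, replicate,
#'   retroperfusate_conc, retrodialysate_conc`).
#' @param average_within_occasion Average replicate retrodialysate samples
#'   within an occasion before applying the delivery equation (default), or
#'   treat every replicate as its own determination.
#' @param plausibility_band Length-2 numeric, percent; calibrations outside
#'   it are flagged.
#' @return A data frame of class `calibration_result` with one row per
#'   catheter: `subject_id, catheter_id, rd_percent, n_occasions,
#'   per_occasion_rd` (list column), `suspect`.
#' @export
aggregate_calibration <- function(records, average_within_occasion = TRUE,
                                  plausibility_band = c(20, 100)) {
  stopifnot(nrow(records) >= 1)
  if (length(unique(records$subject_id)) != 1L) {
    stop("aggregate_calibration expects records of a single subject", call. = FALSE)
  }
  subj <- records$subject_id[1]
  rd_all <- relative_delivery(records$retroperfusate_conc,
                              records$retrodialysate_conc)
  valid <- rd_all > 0 & rd_all <= 100
  if (any(!valid)) {
    warning(sprintf("calibration failure: %d retrodialysis record(s) with rD outside (0, 100%%] excluded (subject %s)",
                    sum(!valid), subj), call. = FALSE)
  }
  records <- records[valid, , drop = FALSE]
  rd_all <- rd_all[valid]
  if (nrow(records) == 0L) {
    stop(sprintf("missing calibration: no valid retrodialysis record for subject %s",
                 subj), call. = FALSE)
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(records)), records$catheter_id),
    function(i) {
      rec <- records[i, , drop = FALSE]
      rd <- rd_all[i]
      if (average_within_occasion) {
        per_occ <- vapply(split(rd, rec$occasion), mean, 0)
      } else {
        per_occ <- rd
      }
      data.frame(subject_id = rec$subject_id[1],
                 catheter_id = rec$catheter_id[1],
                 rd_percent = mean(per_occ),
                 n_occasions = length(unique(rec$occasion)),
                 per_occasion_rd = I(list(unname(per_occ))),
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out$suspect <- out$rd_percent < plausibility_band[1] |
                 out$rd_percent > plausibility_band[2]
  class(out) <- c("calibration_result", class(out))
  out
}

#' Map microdialysate concentrations to ISF concentrations
#'
#' Inverts the recovery dilution: \eqn{C_{ISF} = C_{\mu D} / rD \cdot 100\%}.
#' The same (voriconazole-derived) calibration is applied to both analytes:
#' the metabolite's recovery is surrogated by the parent's.
#'
#' @param conc_dialysate Microdialysate concentration(s), \eqn{\mu}mol/L.
#' @param rd_percent Relative delivery in percent, in (0, 100].
#' @return ISF concentration(s), \eqn{\mu}mol/L.
#' @examples
#' dialysate_to_isf(1.0, 80)    # 1.25
#' dialysate_to_isf(0.75, 75.2) # 0.9973...
#' @export
dialysate_to_isf <- function(conc_dialysate, rd_percent) {
  if (any(!is.finite(rd_percent)) || any(rd_percent <= 0) || any(rd_percent > 100)) {
    stop("unusable calibration: rd_percent must lie in (0, 100]", call. = FALSE)
  }
  conc_dialysate / rd_percent * 100
}

#' Apply per-catheter calibration to a dialysate table
#'
#' Looks up each sample's catheter in the calibration table of its subject
#' and converts the measured dialysate concentration to an ISF
#' concentration. BLQ samples are carried through flagged, not converted.
#'
#' @param dialysate Validated dialysate table.
#' @param calibration `calibration_result` rows covering every
#'   subject x catheter present in `dialysate`.
#' @return The dialysate table with columns `rd_percent` and `conc_isf`
#'   added.
#' @export
apply_calibration <- function(dialysate, calibration) {
  key_d <- paste(dialysate$subject_id, dialysate$catheter_id, sep = "\r")
  key_c <- paste(calibration$subject_id, calibration$catheter_id, sep = "\r")
  idx <- match(key_d, key_c)
  if (anyNA(idx)) {
    miss <- unique(paste0(dialysate$subject_id, "/", dialysate$catheter_id)[is.na(idx)])
    stop(sprintf("missing calibration for catheter(s): %s (affects %d dialysate sample(s))",
                 paste(miss, collapse = ", "), sum(is.na(idx))), call. = FALSE)
  }
  dialysate$rd_percent <- calibration$rd_percent[idx]
  dialysate$conc_isf <- ifelse(dialysate$below_lloq, NA_real_,
                               dialysate_to_isf(dialysate$concentration,
                                                dialysate$rd_percent))
  dialysate
}
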