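#' Published exposure values of the reference clinical study
#'
#' Exposure metrics printed in the reference clinical microdialysis study
#' of voriconazole in four healthy volunteers (one per CYP2C19
#' genotype-predicted phenotype): per-interval molar AUC extremes in plasma
#' and ISF, the ISF:plasma AUC ratio table and the metabolite:parent AUC
#' ratio table for the three intensively sampled dosing intervals (1, 5, 7).
#' The raw concentration data of that study are not public; these printed
#' summary values serve as inputs for the arithmetic cross-checks in
#' [paper_crosscheck()].
#'
#' @return A list of data frames: `auc` (phenotype, analyte, matrix,
#'   interval_index, auc in \eqn{\mu}mol h/L; the per-interval extreme
#'   values with their subjects), `penetration` (AUC_ISF/AUC_plasma) and
#'   `metabolic` (AUC_NO/AUC_VRC) tables.
#' @export
reference_study_values <- function() {
  auc <- rbind(
    data.frame(phenotype = c("RM", "IM"), analyte = "VRC", matrix = "plasma",
               interval_index = 1, auc = c(25.5, 45.3)),
    data.frame(phenotype = c("RM", "IM"), analyte = "VRC", matrix = "plasma",
               interval_index = 5, auc = c(31.9, 124)),
    data.frame(phenotype = c("RM", "IM"), analyte = "VRC", matrix = "plasma",
               interval_index = 7, auc = c(27.2, 130)),
    data.frame(phenotype = c("RM", "IM"), analyte = "NO", matrix = "plasma",
               interval_index = 1, auc = c(84.3, 50.4)),
    data.frame(phenotype = c("RM", "RM_PM"), analyte = "VRC", matrix = "isf",
               interval_index = 1, auc = c(11.2, 22.2)),
    data.frame(phenotype = c("RM", "IM"), analyte = "NO", matrix = "isf",
               interval_index = 1, auc = c(20.7, 2.84))
  )
  penetration <- expand.grid(phenotype = c("RM", "NM", "RM_PM", "IM"),
                             interval_index = c(1, 5, 7),
                             analyte = c("VRC", "NO"),
                             stringsAsFactors = FALSE)
  penetration$ratio <- c(
    0.440, 0.425, 0.506, 0.355,   # VRC interval 1
    0.682, 0.620, 0.464, 0.698,   # VRC interval 5
    0.624, 0.601, 0.524, 0.564,   # VRC interval 7
    0.245, 0.242, 0.243, 0.0564,  # NO interval 1
    0.262, 0.443, 0.270, 0.0683,  # NO interval 5
    0.329, 0.494, 0.397, 0.0769   # NO interval 7
  )
  metabolic <- expand.grid(phenotype = c("RM", "NM", "RM_PM", "IM"),
                           interval_index = c(1, 5, 7),
                           matrix = c("plasma", "isf"),
                           stringsAsFactors = FALSE)
  metabolic$ratio <- c(
    3.30, 2.71, 1.26, 1.11,       # plasma interval 1
    4.57, 2.34, 1.04, 0.780,      # plasma interval 5
    4.71, 2.78, 1.13, 0.764,      # plasma interval 7
    1.84, 1.54, 0.608, 0.177,     # isf interval 1
    1.75, 1.67, 0.604, 0.0763,    # isf interval 5
    2.49, 2.28, 0.852, 0.104      # isf interval 7
  )
  list(auc = auc, penetration = penetration, metabolic = metabolic)
}

.ulp <- function(printed, digits) {
  10^(floor(log10(abs(printed))) - (digits - 1))
}

#' Arithmetic cross-checks against the published study values
#'
#' Recomputes, through the package's ratio functions, twelve quantities the
#' reference study prints — per-interval fold differences in exposure,
#' metabolic AUC ratios, tissue penetration ratios, and the maximum
#' plasma:ISF exposure folds — from the study's printed AUC and ratio
#' tables, and compares each with the printed value at its printed
#' precision (agreement within one unit in the last printed digit, since
#' the study rounded from unrounded inputs).
#'
#' @return Data frame of class `paper_crosscheck`: `id, computed, printed,
#'   digits, agree`, one row per cross-check.
#' @export
paper_crosscheck <- function() {
  ref <- reference_study_values()
  g_auc <- function(ph, an, mx, iv) {
    ref$auc$auc[ref$auc$phenotype == ph & ref$auc$analyte == an &
                ref$auc$matrix == mx & ref$auc$interval_index == iv]
  }
  g_met <- function(ph, mx, iv) {
    ref$metabolic$ratio[ref$metabolic$phenotype == ph &
                        ref$metabolic$matrix == mx &
                        ref$metabolic$interval_index == iv]
  }
  fold <- function(a, b) fold_range(c(a, b))$fold

  checks <- list(
    ## interindividual fold differences in exposure
    list(id = "fold_vrc_plasma_auc_interval1",
         computed = fold(g_auc("RM", "VRC", "plasma", 1),
                         g_auc("IM", "VRC", "plasma", 1)), printed = 1.8, digits = 2),
    list(id = "fold_vrc_plasma_auc_interval5",
         computed = fold(g_auc("RM", "VRC", "plasma", 5),
                         g_auc("IM", "VRC", "plasma", 5)), printed = 3.9, digits = 2),
    list(id = "fold_vrc_plasma_auc_interval7",
         computed = fold(g_auc("RM", "VRC", "plasma", 7),
                         g_auc("IM", "VRC", "plasma", 7)), printed = 4.8, digits = 2),
    list(id = "fold_no_isf_auc_interval1",
         computed = fold(g_auc("RM", "NO", "isf", 1),
                         g_auc("IM", "NO", "isf", 1)), printed = 7.3, digits = 2),
    ## metabolite:parent AUC ratios recomputed from printed AUCs
    list(id = "metabolic_auc_ratio_plasma_im_interval1",
         computed = auc_metabolic_ratio(g_auc("IM", "NO", "plasma", 1),
                                        g_auc("IM", "VRC", "plasma", 1)),
         printed = 1.11, digits = 3),
    list(id = "metabolic_auc_ratio_plasma_rm_interval1",
         computed = auc_metabolic_ratio(g_auc("RM", "NO", "plasma", 1),
                                        g_auc("RM", "VRC", "plasma", 1)),
         printed = 3.30, digits = 3),
    ## tissue penetration recomputed from printed AUCs
    list(id = "penetration_vrc_rm_interval1",
         computed = penetration_ratio(g_auc("RM", "VRC", "isf", 1),
                                      g_auc("RM", "VRC", "plasma", 1))$raw,
         printed = 0.440, digits = 3),
    ## maximum plasma:ISF exposure folds (inverse minimum penetration)
    list(id = "max_plasma_to_isf_fold_vrc",
         computed = 1 / min(ref$penetration$ratio[ref$penetration$analyte == "VRC"]),
         printed = 2.82, digits = 3),
    list(id = "max_plasma_to_isf_fold_no",
         computed = 1 / min(ref$penetration$ratio[ref$penetration$analyte == "NO"]),
         printed = 17.7, digits = 3),
    ## interindividual folds of the metabolic AUC ratio
    list(id = "fold_metabolic_ratio_plasma_interval1",
         computed = fold(g_met("RM", "plasma", 1), g_met("IM", "plasma", 1)),
         printed = 3.0, digits = 2),
    list(id = "fold_metabolic_ratio_isf_interval5",
         computed = fold(g_met("RM", "isf", 5), g_met("IM", "isf", 5)),
         printed = 23, digits = 2),
    list(id = "fold_metabolic_ratio_isf_interval7",
         computed = fold(g_met("RM", "isf", 7), g_met("IM", "isf", 7)),
         printed = 24, digits = 2)
  )
  out <- do.call(rbind, lapply(checks, function(ck) {
    data.frame(id = ck$id, computed = ck$computed, printed = ck$printed,
               digits = ck$digits,
               agree = abs(ck$computed - ck$printed) <=
                 .ulp(ck$printed, ck$digits) + 1e-12,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("paper_crosscheck", class(out))
  out
}

#' @export
print.paper_crosscheck <- function(x, ...) {
  cat(sprintf("Cross-checks against published study values: %d/%d agree at printed precision\n\n",
              sum(x$agree), nrow(x)))
  df <- x
  df$computed <- signif(df$computed, 4)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
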