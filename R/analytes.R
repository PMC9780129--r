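#' Analyte specification
#'
#' Describes one analyte: its molar mass (used for the canonical
#' \eqn{\mu}g/mL \eqn{\leftrightarrow} \eqn{\mu}mol/L conversion), the lower
#' limits of quantification of the bioanalytical assay in plasma and in
#' microdialysate, and the plasma fraction unbound.
#'
#' All concentrations inside the package are molar (\eqn{\mu}mol/L); mass
#' units appear only at I/O boundaries and in assay constants.
#'
#' @param name Analyte identifier, e.g. `"VRC"` or `"NO"`.
#' @param molar_mass Molar mass in g/mol; must be positive.
#' @param lloq_plasma Lower limit of quantification in plasma, \eqn{\mu}g/mL.
#' @param lloq_dialysate Lower limit of quantification in microdialysate,
#'   \eqn{\mu}g/mL.
#' @param fraction_unbound Plasma fraction unbound, in (0, 1]. `NA` when not
#'   established for the analyte.
#' @return An object of class `analyte_spec`.
#' @examples
#' vrc <- analyte_spec("VRC", 349.31, 0.005, 0.004, 0.50)
#' ugml_to_umolL(1, vrc)  # 2.863 umol/L
#' @export
analyte_spec <- function(name, molar_mass, lloq_plasma, lloq_dialysate,
                         fraction_unbound = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(molar_mass) || length(molar_mass) != 1L ||
      !is.finite(molar_mass) || molar_mass <= 0) {
    stop("invalid analyte: molar_mass must be a positive number", call. = FALSE)
  }
  if (lloq_plasma <= 0 || lloq_dialysate <= 0) {
    stop("invalid analyte: LLOQ values must be positive", call. = FALSE)
  }
  if (!is.na(fraction_unbound) &&
      (fraction_unbound <= 0 || fraction_unbound > 1)) {
    stop("invalid analyte: fraction_unbound must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(name = name, molar_mass = molar_mass,
         lloq_plasma = lloq_plasma, lloq_dialysate = lloq_dialysate,
         fraction_unbound = fraction_unbound),
    class = "analyte_spec"
  )
}

#' @export
print.analyte_spec <- function(x, ...) {
  cat(sprintf("<analyte_spec> %s: M = %.2f g/mol, LLOQ %.3g (plasma) / %.3g (dialysate) ug/mL, fu = %s\n",
              x$name, x$molar_mass, x$lloq_plasma, x$lloq_dialysate,
              ifelse(is.na(x$fraction_unbound), "NA",
                     format(x$fraction_unbound))))
  invisible(x)
}

#' Default analyte set: voriconazole and voriconazole N-oxide
#'
#' Voriconazole (VRC, 349.31 g/mol, fu = 0.50) and its N-oxide metabolite
#' (NO, 365.31 g/mol; plasma protein binding not established). Assay LLOQs
#' are 0.005 ug/mL in plasma and 0.004 ug/mL in microdialysate for both
#' analytes. Molar masses can be overridden for sensitivity analyses.
#'
#' @param molar_mass_vrc,molar_mass_no Optional molar-mass overrides (g/mol).
#' @return Named list with elements `VRC` and `NO`, each an [analyte_spec()].
#' @export
default_analytes <- function(molar_mass_vrc = 349.31, molar_mass_no = 365.31) {
  list(
    VRC = analyte_spec("VRC", molar_mass_vrc, 0.005, 0.004, 0.50),
    NO  = analyte_spec("NO",  molar_mass_no,  0.005, 0.004, NA_real_)
  )
}

#' Concentration unit conversion
#'
#' Converts between mass (\eqn{\mu}g/mL) and molar (\eqn{\mu}mol/L)
#' concentration units: \eqn{\mu mol/L = 1000 \cdot (\mu g/mL) / M} with
#' molar mass \eqn{M} in g/mol. The two functions are exact inverses.
#'
#' @param x Numeric vector of concentrations; must be non-negative.
#' @param analyte An [analyte_spec()].
#' @return Numeric vector of the converted concentrations.
#' @examples
#' vrc <- default_analytes()$VRC
#' ugml_to_umolL(c(1, 2, 4.5, 6), vrc)  # 2.86, 5.73, 12.9, 17.2
#' @export
ugml_to_umolL <- function(x, analyte) {
  stopifnot(inherits(analyte, "analyte_spec"))
  if (any(x < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  1000 * x / analyte$molar_mass
}

#' @rdname ugml_to_umolL
#' @export
umolL_to_ugml <- function(x, analyte) {
  stopifnot(inherits(analyte, "analyte_spec"))
  if (any(x < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  x * analyte$molar_mass / 1000
}

#' Assay LLOQ in molar units
#'
#' @param analyte An [analyte_spec()].
#' @param matrix `"plasma"` or `"isf"`/`"dialysate"` (dialysate LLOQ applies
#'   to microdialysate samples).
#' @return LLOQ in \eqn{\mu}mol/L.
#' @export
lloq_umolL <- function(analyte, matrix = c("plasma", "dialysate", "isf")) {
  matrix <- match.arg(matrix)
  lloq <- if (matrix == "plasma") analyte$lloq_plasma else analyte$lloq_dialysate
  ugml_to_umolL(lloq, analyte)
}
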