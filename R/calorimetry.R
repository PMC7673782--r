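# Indirect-calorimetry derivations.
#
# Closed-form quantities computed from O2 consumption (Vo2) and CO2
# production (Vco2), both normalized per kg^0.75 of metabolic body mass
# upstream of this package; units are carried as labels only and no
# conversion is attempted.  Negative oxidation values (possible under the
# printed formulas, e.g. during intense lipogenesis) are preserved and
# flagged, never clipped.

#' Respiratory exchange ratio
#'
#' RER = Vco2 / Vo2; near 1 for pure carbohydrate oxidation, near 0.7 for
#' pure lipid oxidation.
#'
#' @param vco2 CO2 production.
#' @param vo2 O2 consumption (> 0), same units as \code{vco2}.
#' @return \code{vco2 / vo2}, vectorized.
#' @export
rer <- function(vco2, vo2) {
  if (any(vo2 <= 0)) stop("vo2 must be > 0")
  vco2 / vo2
}

#' Energy expenditure
#'
#' \code{1.44 * vo2 * (3.815 + 1.232 * rer)}, in kcal/day/kg^0.75 when Vo2
#' is per kg^0.75.
#'
#' @param vo2 O2 consumption.
#' @param rer Respiratory exchange ratio; values outside \[0.6, 1.3\]
#'   trigger a warning (physiologically implausible).
#' @return Energy expenditure, vectorized.
#' @export
energy_expenditure <- function(vo2, rer) {
  if (any(is.finite(rer) & (rer < 0.6 | rer > 1.3)))
    warning("RER outside [0.6, 1.3]: check input units")
  1.44 * vo2 * (3.815 + 1.232 * rer)
}

#' Glucose oxidation
#'
#' \code{((4.545 * vco2) - (3.205 * vo2)) / 1000}, in g/min/kg^0.75.
#' May be negative; see [calorimetry_derive()] for the flag.
#'
#' @param vo2 O2 consumption.
#' @param vco2 CO2 production.
#' @return Glucose oxidation rate, vectorized.
#' @export
glucose_oxidation <- function(vo2, vco2) {
  (4.545 * vco2 - 3.205 * vo2) / 1000
}

#' Lipid oxidation
#'
#' \code{(1.672 * (vo2 - vco2)) / 1000}, in g/min/kg^0.75; exactly 0 when
#' RER = 1.
#'
#' @param vo2 O2 consumption.
#' @param vco2 CO2 production.
#' @return Lipid oxidation rate, vectorized.
#' @export
lipid_oxidation <- function(vo2, vco2) {
  1.672 * (vo2 - vco2) / 1000
}

#' Derive all calorimetry quantities for a measurement table
#'
#' @param df Data.frame with columns \code{vo2} and \code{vco2} (one row
#'   per measurement interval; any other columns are carried through).
#' @return The table with columns \code{rer}, \code{energy_expenditure},
#'   \code{glucose_oxidation}, \code{glucose_ox_negative} (flag) and
#'   \code{lipid_oxidation} appended.
#' @export
calorimetry_derive <- function(df) {
  stopifnot(all(c("vo2", "vco2") %in% names(df)))
  df$rer <- rer(df$vco2, df$vo2)
  df$energy_expenditure <- energy_expenditure(df$vo2, df$rer)
  df$glucose_oxidation <- glucose_oxidation(df$vo2, df$vco2)
  df$glucose_ox_negative <- df$glucose_oxidation < 0
  df$lipid_oxidation <- lipid_oxidation(df$vo2, df$vco2)
  df
}

#' Read / write calorimetry TSV time series
#'
#' @param path TSV file with at least \code{vo2} and \code{vco2} columns.
#' @return Data.frame.
#' @export
read_calorimetry <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @param df Table (typically from [calorimetry_derive()]).
#' @param path Output TSV path.
#' @rdname read_calorimetry
#' @return For \code{write_calorimetry}, \code{path} invisibly.
#' @export
write_calorimetry <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
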