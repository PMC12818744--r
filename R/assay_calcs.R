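# Closed-form calculations for the two wet-lab readouts used to validate
# designed peptides: plate-reader turbidity and fluorophore partitioning.

#' Relative turbidity from absorbance at 600 nm
#'
#' tau_relative% = 100 - 100 * 10^(-A600): 0% at zero absorbance,
#' strictly increasing, asymptote 100%.
#'
#' @param a600 Non-negative absorbance value(s).
#' @return Relative turbidity in percent.
#' @export
relative_turbidity <- function(a600) {
  if (any(a600 < 0)) stop("a600 must be non-negative", call. = FALSE)
  100 - 100 * 10^(-a600)
}

#' Encapsulation efficiency from total and supernatant concentrations
#'
#' EE% = 100 (CT - Csup) / CT, i.e. the fraction of the guest fluorophore
#' partitioned out of the supernatant into the condensate phase, reported
#' in percent.  Scale-invariant in the concentration unit.  Supernatant
#' readings above the total (evaporation / measurement noise) are clamped
#' to 0% with a warning.
#'
#' @param c_total Total fluorophore concentration (> 0), any unit.
#' @param c_sup Supernatant concentration (>= 0), same unit.
#' @return Encapsulation efficiency in percent.
#' @export
encapsulation_efficiency <- function(c_total, c_sup) {
  if (any(c_total <= 0)) stop("c_total must be positive", call. = FALSE)
  if (any(c_sup < 0)) stop("c_sup must be non-negative", call. = FALSE)
  ee <- 100 * (c_total - c_sup) / c_total
  over <- ee < 0
  if (any(over)) {
    warning(sum(over), " supernatant reading(s) exceed the total; ",
            "EE clamped to 0%")
    ee[over] <- 0
  }
  ee
}

#' Apply the assay formulas to a readings table
#'
#' Accepts a data frame of `(sample, a600)` or `(sample, c_total, c_sup)`
#' readings, optionally with a `blank` column subtracted from `a600`
#' before the turbidity formula, and appends the computed column.
#'
#' @param readings Data frame of raw readings.
#' @return The table with `relative_turbidity` and/or `ee_percent` added.
#' @export
assay_table <- function(readings) {
  if (!is.null(readings$a600)) {
    a <- readings$a600
    if (!is.null(readings$blank)) a <- pmax(a - readings$blank, 0)
    readings$relative_turbidity <- relative_turbidity(a)
  }
  if (!is.null(readings$c_total) && !is.null(readings$c_sup))
    readings$ee_percent <- encapsulation_efficiency(readings$c_total,
                                                    readings$c_sup)
  readings
}
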