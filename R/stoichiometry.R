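#' Oligomer count from an assembly mass
#'
#' Number of monomer copies in an assembly peak: the mass quotient rounded
#' to the nearest integer (half away from zero). The raw quotient and
#' rounding residual are attached for inspection.
#'
#' @param mass_assembly Assembly mass in kDa (> 0).
#' @param mass_monomer Monomer mass in kDa (> 0).
#' @return Integer copy number with attributes `quotient` and `residual`.
#' @export
#' @examples
#' oligomer_count(1046.4, 26.1) # 40
oligomer_count <- function(mass_assembly, mass_monomer) {
  if (any(!is.finite(mass_assembly)) || any(mass_assembly <= 0) ||
      any(!is.finite(mass_monomer)) || any(mass_monomer <= 0)) {
    stopf("masses must be positive and finite")
  }
  q <- mass_assembly / mass_monomer
  n <- as.integer(round_half_away(q))
  structure(n, quotient = q, residual = q - n)
}

#' Interpret an AUC c(s) mass distribution
#'
#' Assigns an oligomer count to every peak of a sedimentation-derived mass
#' distribution and computes the assembled fraction: the proportion of
#' total reported signal residing in peaks of two or more copies.
#'
#' @param peaks data.frame with `mass_kda` and `fraction` columns (see
#'   [read_auc_peaks]).
#' @param mass_monomer Monomer mass in kDa.
#' @return List of class `stoichiometry_report`: `peaks` (input plus
#'   `n_mer` and `quotient`), `assembled_fraction`, `mass_monomer`.
#' @export
#' @examples
#' interpret_distribution(
#'   data.frame(mass_kda = c(26.1, 1046.4), fraction = c(0.08, 0.92)), 26.1)
interpret_distribution <- function(peaks, mass_monomer) {
  if (nrow(peaks) == 0L) stopf("empty peak list")
  peaks <- validate_auc_peaks(peaks)
  n <- oligomer_count(peaks$mass_kda, mass_monomer)
  peaks$n_mer <- as.integer(n)
  peaks$quotient <- attr(n, "quotient")
  total <- sum(peaks$fraction)
  if (total <= 0) stopf("total reported fraction is zero")
  structure(
    list(peaks = peaks,
         assembled_fraction = sum(peaks$fraction[peaks$n_mer >= 2L]) / total,
         mass_monomer = mass_monomer),
    class = "stoichiometry_report"
  )
}

#' @export
print.stoichiometry_report <- function(x, ...) {
  cat(sprintf("stoichiometry_report: monomer %.1f kDa, %d peak(s), %.1f%% assembled\n",
              x$mass_monomer, nrow(x$peaks), 100 * x$assembled_fraction))
  print(x$peaks)
  invisible(x)
}
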