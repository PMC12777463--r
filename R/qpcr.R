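#' Relative expression by the delta-Cq method
#'
#' `2^-(Cq_target - Cq_reference)`, the standard relative quantification
#' assuming perfect doubling per PCR cycle. Vectorised over replicates.
#'
#' @param cq_target,cq_reference Quantification cycles (positive, finite).
#' @return Relative expression values (dimensionless, strictly positive).
#' @export
#' @examples
#' delta_cq(25, 22) # 2^-3 = 0.125
delta_cq <- function(cq_target, cq_reference) {
  if (length(cq_target) != length(cq_reference)) {
    stop_validation("cq_target and cq_reference must have equal length",
                    "rareniche_validation_error")
  }
  bad <- !is.finite(cq_target) | !is.finite(cq_reference) |
    cq_target <= 0 | cq_reference <= 0
  if (any(bad)) {
    stop_validation("Cq values must be finite and positive",
                    "rareniche_validation_error")
  }
  2^-(cq_target - cq_reference)
}

#' Normalized 3C interaction frequency
#'
#' Chromosome-conformation-capture signal normalized in two multiplicative
#' steps: within-library, by the same primer pair's signal on a BAC
#' artificial ligation library (controls PCR efficiency); between samples,
#' by a reference-locus ratio (calibrator over sample). Because both steps
#' are pure ratios the composition order is irrelevant.
#'
#' @param interaction_signal qPCR signal of the 3C ligation product.
#' @param bac_signal Same primer pair on the BAC library.
#' @param sample_ref_signal Reference-locus signal in the sample library.
#' @param calibrator_ref_signal Reference-locus signal in the calibrator.
#' @return Normalized interaction frequency (strictly positive).
#' @export
#' @examples
#' normalize_3c(300, 100, 50, 100) # 3 * 2 = 6
normalize_3c <- function(interaction_signal, bac_signal, sample_ref_signal,
                         calibrator_ref_signal) {
  vals <- cbind(interaction_signal, bac_signal, sample_ref_signal,
                calibrator_ref_signal)
  if (any(!is.finite(vals) | vals <= 0)) {
    stop_validation("all 3C signals must be finite and strictly positive",
                    "rareniche_validation_error")
  }
  (interaction_signal / bac_signal) *
    (calibrator_ref_signal / sample_ref_signal)
}
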