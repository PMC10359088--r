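#' Per-drug centering of log-IC50 values (IC50*)
#'
#' Subtracts each drug's mean log-IC50 (over observed entries) from that
#' drug's column, so every column of the result has mean zero.  Centering
#' removes uniform potency/toxicity differences between drugs and makes the
#' per-patient minimum pick out the drug with the largest *differential*
#' effect — the quantity a companion biomarker can act on.  The operation is
#' idempotent and invariant to adding a per-drug constant to the input.
#'
#' @param Y a [sensitivity_matrix()] on the `"log_ic50"` (or already
#'   `"ic50_star"`) scale.  Values must already be logarithms.
#' @return a `sensitivity_matrix` on the `"ic50_star"` scale; missing entries
#'   stay missing.
#' @export
compute_ic50_star <- function(Y) {
  sc <- response_scale(Y)
  if (sc == "benefit")
    stop("compute_ic50_star expects log-IC50 values, not benefit scale",
         call. = FALSE)
  v <- unclass(Y)
  n_obs <- colSums(!is.na(v))
  if (any(n_obs == 0L))
    stop("cannot normalize all-missing drug column: ",
         paste(colnames(v)[n_obs == 0L], collapse = ", "), call. = FALSE)
  centered <- sweep(v, 2L, colMeans(v, na.rm = TRUE))
  # guard against accumulated rounding so the ic50_star invariant holds
  centered <- sweep(centered, 2L, colMeans(centered, na.rm = TRUE))
  sensitivity_matrix(centered, scale = "ic50_star")
}

signed_sqrt <- function(x) sign(x) * sqrt(abs(x))

#' Apply a response transform
#'
#' `"signed_sqrt"` maps y to sign(y) * sqrt(|y|): an odd, strictly increasing
#' compression that shrinks the dynamic range so single extreme responders do
#' not dominate summed split objectives.  Being order-preserving it never
#' changes which of two responses is better.
#'
#' @param Y a [sensitivity_matrix()].
#' @param transform `"identity"` or `"signed_sqrt"`.
#' @return a `sensitivity_matrix` on the same scale.
#' @export
apply_transform <- function(Y, transform = c("identity", "signed_sqrt")) {
  transform <- match.arg(transform)
  if (transform == "identity") return(Y)
  sensitivity_matrix(signed_sqrt(unclass(Y)), scale = response_scale(Y))
}

#' Flip an IC50-type matrix to the benefit scale
#'
#' Negates the values and marks the result `"benefit"` (larger is better),
#' so that maximizing benefit is exactly minimizing (log-)IC50 or IC50*.
#' All fitters work internally on the benefit scale; this keeps the split
#' objectives written as maximizations consistent with IC50-type inputs
#' where lower means more sensitive.
#'
#' @param Y a [sensitivity_matrix()].
#' @return a `sensitivity_matrix` with scale `"benefit"`.  Calling on an
#'   already-benefit matrix warns and returns it unchanged.
#' @export
to_benefit <- function(Y) {
  if (response_scale(Y) == "benefit") {
    warning("matrix is already on the benefit scale; returning unchanged",
            call. = FALSE)
    return(Y)
  }
  sensitivity_matrix(-unclass(Y), scale = "benefit")
}
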