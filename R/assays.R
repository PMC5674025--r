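# Small exactly-specified assay formulas used in downstream reporting.

#' Ellipsoid tumor volume from caliper measurements
#'
#' \code{volume (mm^3) = width^2 * length / 2}, the standard caliper
#' approximation for xenograft tumors.
#'
#' @param width,length caliper measurements in mm, >= 0.
#' @return volume in mm^3, vectorized.
#' @examples
#' tumor_volume(2, 4)   # 8
#' tumor_volume(3, 5)   # 22.5
#' @export
tumor_volume <- function(width, length) {
  if (any(width < 0) || any(length < 0))
    stop("domain error: width and length must be >= 0")
  width^2 * length / 2
}

#' A qPCR sample (target + housekeeping cycle thresholds)
#'
#' @param ct_target,ct_housekeeping cycle thresholds, finite and > 0.
#' @return object of class \code{qpcr_sample}.
#' @export
qpcr_sample <- function(ct_target, ct_housekeeping) {
  stopifnot(is.finite(ct_target), ct_target > 0,
            is.finite(ct_housekeeping), ct_housekeeping > 0)
  structure(list(ct_target = ct_target,
                 ct_housekeeping = ct_housekeeping),
            class = "qpcr_sample")
}

#' Relative expression by the double-delta-Ct method
#'
#' \eqn{\Delta Ct = Ct_{target} - Ct_{housekeeping}} per sample;
#' \eqn{\Delta\Delta Ct = \Delta Ct_{treated} - \Delta Ct_{control}};
#' fold change \eqn{= 2^{-\Delta\Delta Ct}}. The sign convention is
#' treated-minus-control, so a LOWER treated \eqn{\Delta Ct} (i.e. more
#' target expression, since Ct falls as template rises) gives a fold
#' change above 1.
#'
#' @param treated,control \code{\link{qpcr_sample}} objects.
#' @return dimensionless fold change.
#' @examples
#' ddct_fold_change(qpcr_sample(20, 15), qpcr_sample(22, 15))  # 4
#' @export
ddct_fold_change <- function(treated, control) {
  stopifnot(inherits(treated, "qpcr_sample"),
            inherits(control, "qpcr_sample"))
  d_treated <- treated$ct_target - treated$ct_housekeeping
  d_control <- control$ct_target - control$ct_housekeeping
  2^-(d_treated - d_control)
}

#' Wound-healing (scratch) closure rate
#'
#' Fraction of the original wound width recovered at follow-up:
#' \code{(width_0 - width_t) / width_0}. A follow-up width larger than the
#' original (the wound grew) is a domain error rather than being clipped,
#' so data-entry mistakes surface.
#'
#' @param width_0 original wound width, > 0.
#' @param width_t wound width at follow-up, in \code{[0, width_0]}.
#' @return closure fraction in \[0, 1\], vectorized.
#' @examples
#' wound_healing_rate(80, 20)  # 0.75
#' @export
wound_healing_rate <- function(width_0, width_t) {
  if (any(width_0 <= 0)) stop("domain error: width_0 must be > 0")
  if (any(width_t < 0)) stop("domain error: width_t must be >= 0")
  if (any(width_t > width_0))
    stop("domain error: wound wider than at time 0 (width_t > width_0)")
  (width_0 - width_t) / width_0
}
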