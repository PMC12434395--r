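#' Caliper tumor volume
#'
#' The standard two-diameter ellipsoid approximation used for subcutaneous
#' xenografts: `volume = pi * short^2 * long / 6` (mm3). If the short
#' diameter exceeds the long one the two are swapped with a warning rather
#' than erroring, since caliper logs are noisy.
#'
#' @param short_diameter,long_diameter caliper diameters in mm (>= 0).
#' @return Tumor volume in mm3 (vectorised).
#' @examples
#' tumor_volume(6, 12)   # 226.19 mm3
#' tumor_volume(10, 10)  # sphere limit, 523.6 mm3
#' @export
tumor_volume <- function(short_diameter, long_diameter) {
  if (any(short_diameter < 0) || any(long_diameter < 0)) {
    stop("diameters must be >= 0")
  }
  swap <- short_diameter > long_diameter
  if (any(swap)) {
    warning(sprintf("%d measurement(s) had short > long diameter; swapped",
                    sum(swap)))
    tmp <- short_diameter[swap]
    short_diameter[swap] <- long_diameter[swap]
    long_diameter[swap] <- tmp
  }
  pi * short_diameter^2 * long_diameter / 6
}

#' Resistant cell abundance from labeled counts
#'
#' Resistant abundance is read from RFP-positive counts when available,
#' otherwise computed as total minus GFP-positive (sensitive) counts. The
#' rule used is recorded in the result's `"rule"` attribute.
#'
#' @param total total cell count.
#' @param gfp_positive GFP-positive (sensitive) count, `0 <= gfp <= total`.
#' @param rfp_positive optional RFP-positive (resistant) count.
#' @return Resistant cell count with attribute `rule` =
#'   `"rfp"` or `"total_minus_gfp"`.
#' @export
resistant_abundance <- function(total, gfp_positive, rfp_positive = NULL) {
  if (any(gfp_positive < 0) || any(gfp_positive > total)) {
    stop("`gfp_positive` must satisfy 0 <= gfp_positive <= total")
  }
  if (!is.null(rfp_positive)) {
    structure(rfp_positive, rule = "rfp")
  } else {
    structure(total - gfp_positive, rule = "total_minus_gfp")
  }
}

#' Relative DNA quantification by the 2^(-ddCt) method
#'
#' Computes \eqn{\Delta\Delta Ct = (Ct_{target} - Ct_{ref})_{sample} -
#' (Ct_{target} - Ct_{ref})_{calibrator}} and returns
#' \eqn{2^{-\Delta\Delta Ct} \times 100} (percent of calibrator), assuming
#' 100% amplification efficiency. Target here is the GFP or RFP marker
#' amplicon; the reference is a housekeeping gene (GAPDH-style).
#'
#' @param sample,calibrator lists or one-row data.frames with numeric
#'   `ct_target` and `ct_reference` (PCR cycles, finite and positive).
#' @return Percent relative quantity (100 = equal to calibrator).
#' @examples
#' s <- list(ct_target = 21, ct_reference = 18)
#' ddct_ratio(s, s)  # 100
#' @export
ddct_ratio <- function(sample, calibrator) {
  check_ct <- function(x, who) {
    for (f in c("ct_target", "ct_reference")) {
      v <- x[[f]]
      if (is.null(v) || !is.finite(v) || v <= 0) {
        stop(sprintf("%s: `%s` must be finite and positive", who, f))
      }
    }
  }
  check_ct(sample, "sample"); check_ct(calibrator, "calibrator")
  ddct <- (sample$ct_target - sample$ct_reference) -
    (calibrator$ct_target - calibrator$ct_reference)
  2^(-ddct) * 100
}

#' Calibrate qPCR readout against known input ratios
#'
#' Ordinary least-squares standard curve of measured 2^(-ddCt) x 100
#' values against known input percentages, as used to map qPCR readouts of
#' GFP/RFP DNA onto the input-ratio scale. Returns slope, intercept and
#' Pearson R-squared; the object's `predict` method maps future measured
#' values to the input-ratio scale by inverting the line.
#'
#' @param measured numeric vector of measured percentages.
#' @param known_input numeric vector of known input percentages (same
#'   length, >= 3 points, non-constant).
#' @return An object of class `std_curve` with `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @examples
#' known <- c(0, 15, 25, 50, 75, 85, 100)
#' cal <- calibrate_standard_curve(known * 1.02 + 1, known)
#' cal$r_squared
#' @export
calibrate_standard_curve <- function(measured, known_input) {
  if (length(measured) != length(known_input)) {
    stop("`measured` and `known_input` must have equal length")
  }
  if (length(measured) < 3L) stop("need >= 3 calibration points")
  if (stats::sd(known_input) == 0) stop("`known_input` has zero variance")
  fit <- stats::lm(measured ~ known_input)
  r2 <- suppressWarnings(stats::cor(measured, known_input))^2
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n = length(measured), fit = fit),
            class = "std_curve")
}

#' @export
print.std_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve: measured = %.4g + %.4g x input (R^2 = %.4f, n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' @param object a `std_curve`.
#' @param measured new measured percentages to map to the input scale.
#' @param ... unused.
#' @rdname calibrate_standard_curve
#' @export
predict.std_curve <- function(object, measured, ...) {
  (measured - object$intercept) / object$slope
}

#' Serialize / restore a standard-curve calibration
#'
#' @param x a `std_curve`.
#' @param path JSON file path.
#' @rdname calibrate_standard_curve
#' @export
write_std_curve <- function(x, path) {
  jsonlite::write_json(x[c("slope", "intercept", "r_squared", "n")], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname calibrate_standard_curve
#' @export
read_std_curve <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "std_curve")
}
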