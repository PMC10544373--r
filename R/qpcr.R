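#' Fit a qPCR standard curve
#'
#' Ordinary least squares of y = log10(copies/ul) on x = CT cycle value.
#' A curve is considered usable for absolute quantification only when
#' R-squared exceeds 0.99; weaker fits trigger a warning.
#'
#' @param ct numeric vector of CT values (>= 3 points).
#' @param copies numeric vector of known copies/ul, positive, same length.
#' @return Object of class `standard_curve`: list with `slope`, `intercept`,
#'   `r_squared`, `usable` and the fitted points.
#' @export
fit_standard_curve <- function(ct, copies) {
  stopifnot(length(ct) == length(copies))
  if (length(ct) < 3) stop("need at least 3 calibration points")
  if (any(copies <= 0)) stop("copies must be positive")
  if (length(unique(ct)) < 2) stop("degenerate fit: all CT values identical")
  y <- log10(copies)
  fit <- lm(y ~ ct)
  r2 <- summary(fit)$r.squared
  usable <- r2 > 0.99
  if (!usable)
    warning(sprintf("standard curve R^2 = %.4f <= 0.99: not usable for quantification", r2))
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r_squared = r2, usable = usable,
                 points = data.frame(ct = ct, copies = copies)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve: log10(copies/ul) = %.4f * CT + %.4f\n",
              x$slope, x$intercept))
  cat(sprintf("  R^2 = %.4f (%s)\n", x$r_squared,
              if (x$usable) "usable, R^2 > 0.99" else "NOT usable"))
  invisible(x)
}

#' Predict copies/ul from CT values with a standard curve
#'
#' @param object a `standard_curve` (or a list with `slope` and `intercept`,
#'   e.g. published coefficients).
#' @param ct CT values.
#' @param ... unused.
#' @return copies/ul, i.e. `10^(slope * ct + intercept)`.
#' @export
predict.standard_curve <- function(object, ct, ...) {
  10^(object$slope * ct + object$intercept)
}

#' Plasmid copy number from DNA concentration
#'
#' Closed-form conversion of a double-stranded DNA concentration into
#' copies/ul: `conc * 1e-9 * 6.02e23 / (bp * 660)`, with 660 g/mol the mean
#' molar mass per base pair.
#'
#' @param conc_ng_ul concentration in ng/ul (>= 0).
#' @param amplicon_bp template length in bp (> 0).
#' @return copies/ul. Linear in concentration, inversely proportional to bp.
#' @export
copies_from_concentration <- function(conc_ng_ul, amplicon_bp) {
  if (any(amplicon_bp <= 0)) stop("amplicon_bp must be positive")
  if (any(conc_ng_ul < 0)) stop("concentration must be non-negative")
  conc_ng_ul * 1e-9 * 6.02e23 / (amplicon_bp * 660)
}
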