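#' Specificity calibration curve
#'
#' The empirical distribution of classifier scores on held-out negative
#' sites. Specificity at a decision threshold t is the fraction of true
#' negatives scoring below t, so the curve converts any threshold into an
#' estimated specificity and vice versa — this is what makes stringency
#' adjustment continuous.
#'
#' @param negative_scores Scores of held-out negatives.
#' @return Object of class `calibration_curve` with `sorted_negative_scores`
#'   and `n`. Warns when fewer than 50 scores are supplied.
#' @export
calibration_curve <- function(negative_scores) {
  s <- sort(as.numeric(negative_scores))
  if (length(s) < 1L) stop("empty calibration set")
  if (length(s) < 50L) {
    warning("calibration curve built from only ", length(s),
            " negative scores; specificity estimates will be coarse")
  }
  structure(list(sorted_negative_scores = s, n = length(s)),
            class = "calibration_curve")
}

#' Estimated specificity at a decision threshold
#'
#' Fraction of calibration negatives scoring strictly below `threshold`,
#' with linear interpolation between adjacent order statistics (knots at
#' `(s_(i), (i - 0.5) / n)`, the inverse of a type-5 quantile). Thresholds
#' at or below the minimum score give 0; above the maximum give 1.
#'
#' @param curve A [calibration_curve()].
#' @param threshold Decision threshold(s).
#' @return Estimated specificity in \[0, 1\] (vectorized over `threshold`).
#' @export
estimate_specificity <- function(curve, threshold) {
  stopifnot(inherits(curve, "calibration_curve"))
  s <- curve$sorted_negative_scores
  n <- curve$n
  if (n == 1L) return(ifelse(threshold > s, 1, 0))
  knots_y <- (seq_len(n) - 0.5) / n
  out <- approx(s, knots_y, xout = threshold, rule = 2, ties = mean)$y
  out[threshold <= s[1L]] <- 0
  out[threshold > s[n]] <- 1
  out
}

#' Decision threshold achieving a requested stringency
#'
#' The stringency quantile of the calibration negatives (type-5 linear
#' interpolation), i.e. the inverse of [estimate_specificity()] up to
#' interpolation.
#'
#' @param curve A [calibration_curve()].
#' @param stringency Requested specificity, strictly between 0 and 1.
#' @return Decision threshold (vectorized over `stringency`).
#' @export
threshold_for_stringency <- function(curve, stringency) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(stringency <= 0 | stringency >= 1)) {
    stop("stringency must be strictly between 0 and 1")
  }
  unname(quantile(curve$sorted_negative_scores, probs = stringency,
                  type = 5, names = FALSE))
}
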