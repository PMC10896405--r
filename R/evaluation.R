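#' Root-mean-squared error
#'
#' @param pred,ref numeric vectors of equal length >= 1, in target units.
#' @return scalar RMSE.
#' @export
rmse <- function(pred, ref) {
  if (!length(pred) || length(pred) != length(ref))
    .stopCond("shapecompValueError", "pred and ref must be equal-length, nonempty")
  sqrt(mean((pred - ref)^2))
}

#' RMSE as a percentage of a baseline model's RMSE
#'
#' Normalization used to compare model permutations: the fully linear
#' PCA + OLS pipeline is the 100% reference, so values below 100 mean the
#' permutation beats the linear baseline.
#'
#' @param modelRMSE,baselineRMSE scalars; baseline must be > 0.
#' @return percentage.
#' @export
normalizedRMSE <- function(modelRMSE, baselineRMSE) {
  if (!is.finite(baselineRMSE) || baselineRMSE <= 0)
    .stopCond("shapecompValueError", "baseline RMSE must be positive")
  100 * modelRMSE / baselineRMSE
}

#' Coefficient of determination (agreement form)
#'
#' \eqn{R^2 = 1 - SS_{res} / SS_{tot}} about the reference mean — the
#' agreement definition, not squared correlation, so systematic bias lowers it.
#'
#' @param pred,ref numeric vectors; ref must have nonzero variance.
#' @return scalar (1 = perfect, 0 = no better than the reference mean).
#' @export
rSquared <- function(pred, ref) {
  sst <- sum((ref - mean(ref))^2)
  if (sst <= 0)
    .stopCond("shapecompValueError", "reference values are constant")
  1 - sum((pred - ref)^2) / sst
}

#' Build a test-retest precision pair set
#'
#' @param subjectId vector of subject identifiers.
#' @param m1,m2 same-day duplicate measurements, finite, in target units.
#' @return data.frame with class \code{"precisionPairs"}.
#' @export
precisionPairs <- function(subjectId, m1, m2) {
  if (!length(m1) || length(m1) != length(m2) || length(subjectId) != length(m1))
    .stopCond("shapecompValueError", "need equal-length nonempty pair vectors")
  if (!all(is.finite(m1)) || !all(is.finite(m2)))
    .stopCond("shapecompValueError", "both measurements must be finite for every pair")
  structure(data.frame(subject_id = subjectId, m1 = m1, m2 = m2),
            class = c("precisionPairs", "data.frame"))
}

#' Test-retest precision as a root-mean-square coefficient of variation
#'
#' The duplicate-scan precision statistic: each pair contributes a
#' within-subject SD \eqn{|m_1 - m_2| / \sqrt{2}}; their root mean square is
#' divided by the grand mean of all 2n measurements and expressed in percent.
#'
#' @param pairs a \code{\link{precisionPairs}} set (>= 1 pair, positive grand mean).
#' @return percent CV.
#' @export
cvPercent <- function(pairs) {
  gm <- mean(c(pairs$m1, pairs$m2))
  if (!is.finite(gm) || gm <= 0)
    .stopCond("shapecompValueError", "grand mean must be positive for %CV")
  sdw <- abs(pairs$m1 - pairs$m2) / sqrt(2)
  100 * sqrt(mean(sdw^2)) / gm
}

#' Test-retest precision as RMSE between trials
#'
#' Plain RMSE between trial 1 and trial 2 over duplicate pairs (no sqrt(2)
#' divisor), used for percentage-valued targets where a %CV of a percentage
#' is not conventional.
#'
#' @param pairs a \code{\link{precisionPairs}} set.
#' @return RMSE in target units.
#' @export
repeatRMSE <- function(pairs) rmse(pairs$m1, pairs$m2)
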