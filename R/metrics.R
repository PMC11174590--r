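#' Leaf moisture content from fresh and dry mass
#'
#' Gravimetric (oven-drying) definition of leaf moisture content on a
#' fresh-mass basis: `100 * (fresh - dry) / fresh`. This is the percent
#' scale used throughout the package.
#'
#' @param fresh Fresh mass (g), positive.
#' @param dry Dry mass (g), `0 < dry <= fresh`.
#' @return Moisture content in percent of fresh mass.
#' @examples
#' leafMoisturePct(100, 30)  # 70
#' @export
leafMoisturePct <- function(fresh, dry) {
  if (any(fresh <= 0)) stop("fresh mass must be positive")
  if (any(dry <= 0)) stop("dry mass must be positive")
  if (any(dry > fresh)) stop("dry mass exceeds fresh mass")
  100 * (fresh - dry) / fresh
}

#' Coefficient of determination
#'
#' Default is the residual form `1 - SS_res / SS_tot`, the convention for
#' reporting validation-set accuracy (it can be negative for models worse
#' than the mean). The explained-variance form
#' `sum((pred - mean(obs))^2) / sum((obs - mean(obs))^2)` is available via
#' `form = "explained"`; the two coincide for least-squares-consistent
#' predictions on the training set.
#'
#' @param obs,pred Numeric vectors of equal length.
#' @param form `"residual"` (default) or `"explained"`.
#' @return Scalar R-squared.
#' @export
rSquared <- function(obs, pred, form = c("residual", "explained")) {
  form <- match.arg(form)
  stopifnot(length(obs) == length(pred), length(obs) >= 2)
  sstot <- sum((obs - mean(obs))^2)
  if (sstot == 0) stop("observations have zero variance; R-squared undefined")
  if (form == "residual") 1 - sum((obs - pred)^2) / sstot
  else sum((pred - mean(obs))^2) / sstot
}

#' Root mean square error
#' @param obs,pred Numeric vectors of equal length.
#' @return Scalar RMSE in the units of `obs`.
#' @export
rmse <- function(obs, pred) {
  stopifnot(length(obs) == length(pred), length(obs) >= 1)
  sqrt(mean((pred - obs)^2))
}

#' Mean relative error (percent)
#'
#' Mean of absolute relative errors times 100. Observations must be
#' strictly positive (moisture percentages always are).
#'
#' @param obs,pred Numeric vectors of equal length; `obs > 0`.
#' @return Scalar MRE in percent.
#' @export
mre <- function(obs, pred) {
  stopifnot(length(obs) == length(pred), length(obs) >= 1)
  if (any(obs <= 0)) stop("mre() requires strictly positive observations")
  mean(abs(pred - obs) / obs) * 100
}

#' Evaluate predictions with the package's three metrics
#' @param obs,pred Numeric vectors of equal length.
#' @return Named numeric vector `c(R2, RMSE, MRE)`.
#' @export
evalMetrics <- function(obs, pred) {
  c(R2 = rSquared(obs, pred), RMSE = rmse(obs, pred), MRE = mre(obs, pred))
}
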