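#' Fit a Beta distribution by method of moments
#'
#' Converts a (mean, SE) pair reported for a probability or utility into
#' Beta hyperparameters with exactly that mean and standard error, for use
#' in probabilistic sensitivity analysis.
#'
#' @param mean Mean of the quantity, strictly inside (0, 1).
#' @param se Standard error; must satisfy `se^2 < mean * (1 - mean)`
#'   (the Bernoulli variance bound).
#' @return A list with elements `alpha` and `beta`.
#' @examples
#' beta_from_moments(0.0205, 0.0041)
#' @export
beta_from_moments <- function(mean, se) {
  stopifnot(is.numeric(mean), is.numeric(se), length(mean) == 1L, length(se) == 1L)
  if (mean <= 0 || mean >= 1) {
    stop("beta_from_moments(): mean must lie strictly in (0, 1); got ", mean,
         " (degenerate mean: use family = 'fixed')")
  }
  if (se <= 0) stop("beta_from_moments(): se must be positive")
  v <- se^2
  if (v >= mean * (1 - mean)) {
    stop("beta_from_moments(): infeasible moments, se^2 = ", v,
         " >= mean*(1-mean) = ", mean * (1 - mean))
  }
  nu <- mean * (1 - mean) / v - 1
  list(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Fit a Gamma distribution by method of moments
#'
#' @param mean Mean cost (or visit rate), > 0.
#' @param se Standard error, > 0.
#' @return A list with elements `shape` and `scale` such that
#'   `shape * scale = mean` and `shape * scale^2 = se^2`.
#' @examples
#' gamma_from_moments(2758, 308)
#' @export
gamma_from_moments <- function(mean, se) {
  stopifnot(is.numeric(mean), is.numeric(se), length(mean) == 1L, length(se) == 1L)
  if (mean <= 0 || se <= 0) {
    stop("gamma_from_moments(): mean and se must be positive")
  }
  list(shape = (mean / se)^2, scale = se^2 / mean)
}

#' Fit a Lognormal distribution by method of moments on the natural scale
#'
#' Hazard ratios are reported with mean and SE on the natural (HR) scale;
#' this matches the lognormal's natural-scale mean and SD to them, so
#' `exp(mu + sigma^2/2) = mean` and the lognormal SD equals `se`.
#'
#' @param mean Natural-scale mean (the hazard ratio), > 0.
#' @param se Natural-scale standard error, > 0.
#' @return A list with elements `mu` (meanlog) and `sigma` (sdlog).
#' @examples
#' lognormal_from_moments(0.29, 0.0995)
#' @export
lognormal_from_moments <- function(mean, se) {
  stopifnot(is.numeric(mean), is.numeric(se), length(mean) == 1L, length(se) == 1L)
  if (mean <= 0 || se <= 0) {
    stop("lognormal_from_moments(): mean and se must be positive")
  }
  sigma2 <- log(1 + (se / mean)^2)
  list(mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' Inflate a cost to a target year with the consumer price index
#'
#' @param cost Cost in original-year currency.
#' @param cpi_source_year CPI index of the year the cost was observed.
#' @param cpi_target_year CPI index of the target (reporting) year.
#' @return `cost * cpi_target_year / cpi_source_year`.
#' @export
cpi_adjust <- function(cost, cpi_source_year, cpi_target_year) {
  if (any(cpi_source_year <= 0) || any(cpi_target_year <= 0)) {
    stop("cpi_adjust(): CPI indices must be positive")
  }
  cost * cpi_target_year / cpi_source_year
}
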