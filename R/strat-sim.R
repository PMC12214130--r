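#' Two-normal mixture model of sex stratification
#'
#' Specification of the analytic model used to study how standardizing
#' expression within each sex versus in the combined group changes which
#' values exceed an outlier threshold. Each sex's (already confounder
#' corrected) expression is modelled as a normal distribution; the combined
#' group is their two-component mixture, standardized by the mixture mean
#' and standard deviation.
#'
#' @param mean_diff Standardized mean difference `d` between the two sexes.
#' @param var_female,var_male Variances of the two sex distributions
#'   (positive).
#' @param mix_weight Mixture weight of the female component, in `[0, 1]`.
#' @param z_threshold Outlier threshold on the absolute Z score.
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(mean_diff = 0, var_female = 1, var_male = 1,
                         mix_weight = 0.5, z_threshold = 2.5) {
  if (var_female <= 0 || var_male <= 0) {
    stop("variances must be positive")
  }
  if (mix_weight < 0 || mix_weight > 1) stop("mix_weight must be in [0, 1]")
  if (z_threshold <= 0) stop("z_threshold must be positive")
  structure(
    list(mean_diff = mean_diff, var_female = var_female,
         var_male = var_male, mix_weight = mix_weight,
         z_threshold = z_threshold),
    class = "mixture_spec"
  )
}

## Probability that a N(mu, sd) value lies in the symmetric-outlier region
## {|x - m| > r} complement intersection helpers are inlined below; the
## gain/loss masses reduce to differences of normal CDFs at the region
## boundaries.

#' Outlier-status change fractions under a sex mean shift
#'
#' With sexes distributed N(0, 1) and N(d, 1) (equal mixing), the stratified
#' Z score of an individual is computed within their own sex, while the
#' combined Z score standardizes by the mixture mean `d/2` and standard
#' deviation `sqrt(1 + d^2/4)`. The functions returns the probability mass
#' that is an outlier under exactly one of the two standardizations:
#' `gain` is stratified-only (outliers uncovered by stratification), `loss`
#' is combined-only (outliers visible only in the pooled group). Both are
#' computed in closed form from Gaussian CDFs.
#'
#' @param spec A [mixture_spec()] with `var_female = var_male = 1`.
#' @return A list with elements `gain` and `loss` (probabilities).
#' @export
mean_shift_change_fractions <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (spec$var_female <= 0 || spec$var_male <= 0) {
    stop("variances must be positive")
  }
  if (abs(spec$var_female - 1) > 1e-12 || abs(spec$var_male - 1) > 1e-12) {
    stop("mean-shift mode requires unit variances in both sexes")
  }
  d <- abs(spec$mean_diff)
  z <- spec$z_threshold
  w <- spec$mix_weight
  s <- sqrt(w * (1 - w) * d^2 + 1)  # mixture sd; (1 + d^2/4) at w = 1/2
  m <- (1 - w) * d                  # mixture mean seen from the female side
  ## Female component X ~ N(0, 1):
  ##   stratified outlier iff |x| > z
  ##   combined outlier iff |x - m| > z s, i.e. x < m - z s or x > m + z s
  ## The male component N(d, 1) is the mirror image (reflect about d/2 when
  ## w = 1/2), so per-component masses are averaged with the mixture weights
  ## computed on each side.
  comp_change <- function(mu, m_mix) {
    lo <- m_mix - z * s
    hi <- m_mix + z * s
    ## stratified outlier region: x < mu - z or x > mu + z
    ## combined outlier region:   x < lo     or x > hi
    ## stratified-only = stratified tails intersected with [lo, hi]
    gain <- clipped_mass(mu, lo, min(mu - z, hi)) +
      clipped_mass(mu, max(mu + z, lo), hi)
    ## combined-only = combined tails intersected with [mu - z, mu + z]
    loss <- clipped_mass(mu, mu - z, min(lo, mu + z)) +
      clipped_mass(mu, max(hi, mu - z), mu + z)
    c(gain = gain, loss = loss)
  }
  f <- comp_change(0, m)
  mns <- comp_change(d, m)
  list(gain = unname(w * f["gain"] + (1 - w) * mns["gain"]),
       loss = unname(w * f["loss"] + (1 - w) * mns["loss"]))
}

## N(mu, 1) mass of the interval [a, b], zero when it is empty
clipped_mass <- function(mu, a, b) {
  if (b <= a) return(0)
  stats::pnorm(b, mean = mu) - stats::pnorm(a, mean = mu)
}

#' Mean difference beyond which no combined-only outliers exist
#'
#' As the sex mean difference grows, the pooled mixture becomes wide enough
#' that its outlier region is a subset of the stratified one; the
#' combined-only ("loss") mass vanishes when the near-side combined
#' boundary meets the stratified boundary, i.e. at the root of
#' `z * sqrt(1 + d^2/4) - d/2 = z`. In closed form `d* = 4 z / (z^2 - 1)`
#' (equal mixing); at the conventional threshold `z = 2.5` this is
#' `40/21 = 1.9048`, i.e. 1.9 to one decimal.
#'
#' @param z_threshold Outlier threshold (> 1; below 1 the combined spread
#'   can never catch up and no crossover exists).
#' @return The crossover mean difference `d*` (numeric scalar).
#' @export
crossover_mean_difference <- function(z_threshold = 2.5) {
  if (z_threshold <= 1) stop("no crossover exists for z_threshold <= 1")
  4 * z_threshold / (z_threshold^2 - 1)
}

#' Outlier-status change fractions under a sex variance shift
#'
#' Both sexes are centred at zero; one has variance `var_female`, the other
#' `var_male`. Within-sex standardization divides by the own-sex standard
#' deviation, the combined group by the mixture standard deviation
#' `sqrt(w * var_female + (1 - w) * var_male)`. The resulting gain/loss
#' masses depend only on the variance ratio, so scaling both variances by
#' any positive constant leaves them unchanged.
#'
#' @param spec A [mixture_spec()] with `mean_diff = 0`.
#' @return A list with elements `gain` and `loss`.
#' @export
variance_shift_change_fractions <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (spec$var_female <= 0 || spec$var_male <= 0) {
    stop("variances must be positive")
  }
  if (abs(spec$mean_diff) > 1e-12) {
    stop("variance-shift mode requires mean_diff = 0")
  }
  z <- spec$z_threshold
  w <- spec$mix_weight
  s <- sqrt(w * spec$var_female + (1 - w) * spec$var_male)
  comp <- function(sigma) {
    ## X ~ N(0, sigma^2): stratified outlier iff |x| > z sigma,
    ## combined outlier iff |x| > z s.
    if (s >= sigma) {
      c(gain = 2 * (stats::pnorm(z * s / sigma) - stats::pnorm(z)),
        loss = 0)
    } else {
      c(gain = 0,
        loss = 2 * (stats::pnorm(z) - stats::pnorm(z * s / sigma)))
    }
  }
  f <- comp(sqrt(spec$var_female))
  m <- comp(sqrt(spec$var_male))
  list(gain = unname(w * f["gain"] + (1 - w) * m["gain"]),
       loss = unname(w * f["loss"] + (1 - w) * m["loss"]))
}

#' Monte-Carlo check of the analytic change fractions
#'
#' Simulates `n` individuals per sex, forms stratified and combined groups,
#' standardizes each empirically (sample mean / SD), and counts
#' individuals whose outlier status differs between the two
#' standardizations. This validates the closed-form fractions, which use
#' population mixture moments, against finite-sample behaviour.
#'
#' @param spec A [mixture_spec()].
#' @param n Individuals per sex (at least 1e4).
#' @param seed Integer seed.
#' @return A list with `gain`, `loss`, their Monte-Carlo standard errors
#'   (`gain_se`, `loss_se`), and `n`.
#' @export
monte_carlo_check <- function(spec, n = 1e6, seed = 1) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (n < 1e4) stop("n must be at least 1e4")
  set.seed(seed)
  z <- spec$z_threshold
  xf <- stats::rnorm(n, 0, sqrt(spec$var_female))
  xm <- stats::rnorm(n, spec$mean_diff, sqrt(spec$var_male))
  zf <- (xf - mean(xf)) / stats::sd(xf)
  zm <- (xm - mean(xm)) / stats::sd(xm)
  pooled <- c(xf, xm)
  zc <- (pooled - mean(pooled)) / stats::sd(pooled)
  strat <- abs(c(zf, zm)) > z
  comb <- abs(zc) > z
  ntot <- 2 * n
  gain <- mean(strat & !comb)
  loss <- mean(comb & !strat)
  list(gain = gain, loss = loss,
       gain_se = sqrt(gain * (1 - gain) / ntot),
       loss_se = sqrt(loss * (1 - loss) / ntot),
       n = ntot)
}
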