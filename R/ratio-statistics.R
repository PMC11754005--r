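#' Phenotypic covariance between the component traits
#'
#' The phenotypic covariance of two traits decomposes into a genetic and an
#' environmental part,
#' \deqn{cov(p_1, p_2) = r_G h_1 h_2 \sigma_{p1}\sigma_{p2} +
#'   r_E \sqrt{(1-h_1^2)(1-h_2^2)}\, \sigma_{p1}\sigma_{p2},}
#' where \eqn{h_j = \sqrt{h_j^2}}. With unit phenotypic variances this is
#' the familiar \eqn{r_G h_1 h_2 + r_E \sqrt{(1-h_1^2)(1-h_2^2)}}; the
#' \eqn{\sigma_{p1}\sigma_{p2}} factor is the dimensionally forced
#' generalisation.
#'
#' @param params A [GeneticParams-class] object.
#' @return The phenotypic covariance (trait units squared), equal to the
#'   sum of [geneticCovariance()] and [environmentalCovariance()].
#' @examples
#' componentCovariance(geneticParams(h2_1 = 0.1, h2_2 = 0.5,
#'                                   rG = -0.5, rE = -0.5))  # -0.447
#' @export
componentCovariance <- function(params) {
    stopifnot(is(params, "GeneticParams"))
    validObject(params)
    geneticCovariance(params) + environmentalCovariance(params)
}

#' @rdname componentCovariance
#' @export
geneticCovariance <- function(params) {
    stopifnot(is(params, "GeneticParams"))
    params@rG * sqrt(params@h2_1 * params@h2_2) *
        sqrt(params@varp1 * params@varp2)
}

#' @rdname componentCovariance
#' @export
environmentalCovariance <- function(params) {
    stopifnot(is(params, "GeneticParams"))
    params@rE * sqrt((1 - params@h2_1) * (1 - params@h2_2)) *
        sqrt(params@varp1 * params@varp2)
}

#' Delta-method moments of the ratio trait
#'
#' Second-order Taylor (delta-method) approximations to the mean and
#' variance of the ratio trait \eqn{p_0 = p_1 / p_2}:
#' \deqn{E(p_0) \approx \mu_1/\mu_2 - cov(p_1,p_2)/\mu_2^2 +
#'   \mu_1 var(p_2)/\mu_2^3}
#' \deqn{var(p_0) \approx var(p_1)/\mu_2^2 + \mu_1^2 var(p_2)/\mu_2^4 -
#'   2\mu_1 cov(p_1,p_2)/\mu_2^3}
#' The approximations are accurate when both coefficients of variation are
#' small (roughly CV <= 0.10); the error grows with the denominator's CV.
#'
#' @param params A [GeneticParams-class] object; \code{mu2} must be nonzero.
#' @param cov_p Phenotypic covariance between the component traits. Defaults
#'   to [componentCovariance()] of \code{params}.
#' @return \code{deltaMean}/\code{deltaVariance}: a single number.
#'   \code{deltaMoments}: a one-row data.frame with columns \code{e_p0},
#'   \code{var_p0} and \code{cov_p}.
#' @examples
#' gp <- geneticParams()            # mu = 10, varp = 1
#' deltaMean(gp, cov_p = -0.5)      # 1.015
#' deltaVariance(gp, cov_p = 0.5)   # 0.01
#' @export
deltaMean <- function(params, cov_p = componentCovariance(params)) {
    stopifnot(is(params, "GeneticParams"))
    if (params@mu2 == 0) stop("delta-method mean undefined for mu2 = 0")
    params@mu1 / params@mu2 - cov_p / params@mu2^2 +
        params@mu1 * params@varp2 / params@mu2^3
}

#' @rdname deltaMean
#' @export
deltaVariance <- function(params, cov_p = componentCovariance(params)) {
    stopifnot(is(params, "GeneticParams"))
    if (params@mu2 == 0) stop("delta-method variance undefined for mu2 = 0")
    params@varp1 / params@mu2^2 +
        params@mu1^2 * params@varp2 / params@mu2^4 -
        2 * params@mu1 * cov_p / params@mu2^3
}

#' @rdname deltaMean
#' @export
deltaMoments <- function(params, cov_p = componentCovariance(params)) {
    data.frame(e_p0 = deltaMean(params, cov_p),
               var_p0 = deltaVariance(params, cov_p),
               cov_p = cov_p)
}

#' Delta-method approximation to the ratio trait's heritability
#'
#' Applies the same second-order ratio expansion to the (unobservable)
#' breeding value of the ratio trait as to its phenotype, giving
#' \deqn{h_0^2 \approx \frac{var(g_1)/E(g_2)^2 + E(g_1)^2 var(g_2)/E(g_2)^4
#'   - 2 E(g_1) cov(g_1,g_2)/E(g_2)^3}
#'   {var(p_1)/\mu_2^2 + \mu_1^2 var(p_2)/\mu_2^4 -
#'    2\mu_1 cov(p_1,p_2)/\mu_2^3}}
#' with \eqn{var(g_j) = h_j^2 \sigma_{pj}^2}. Breeding values are relative
#' quantities, so their assumed means \eqn{E(g_1)}, \eqn{E(g_2)} are a
#' location choice the caller makes; they default to the trait means, under
#' which the approximation reduces to \eqn{h^2} when the two traits share a
#' heritability and are uncorrelated.
#'
#' @param params A [GeneticParams-class] object.
#' @param eg1,eg2 Assumed mean breeding values of Traits 1 and 2;
#'   \code{eg2} must be nonzero.
#' @return Approximate heritability of the ratio trait (unitless).
#' @examples
#' deltaHeritability(geneticParams(h2_1 = 0.3, h2_2 = 0.3))  # 0.3
#' @export
deltaHeritability <- function(params, eg1 = params@mu1, eg2 = params@mu2) {
    stopifnot(is(params, "GeneticParams"))
    validObject(params)
    if (eg2 == 0) stop("assumed mean breeding value eg2 must be nonzero")
    varg1 <- params@h2_1 * params@varp1
    varg2 <- params@h2_2 * params@varp2
    covg <- geneticCovariance(params)
    cove <- environmentalCovariance(params)
    num <- varg1 / eg2^2 + eg1^2 * varg2 / eg2^4 - 2 * eg1 * covg / eg2^3
    den <- params@varp1 / params@mu2^2 +
        params@mu1^2 * params@varp2 / params@mu2^4 -
        2 * params@mu1 * (covg + cove) / params@mu2^3
    if (den == 0) stop("delta-method phenotypic variance is zero")
    num / den
}

#' Four-moment summary of a sample
#'
#' Population-moment (divide-by-n) estimates of the mean, variance,
#' skewness and excess kurtosis of a numeric sample. No small-sample bias
#' correction is applied: intended sample sizes are 1e4 and up, where the
#' correction is negligible. Kurtosis is excess kurtosis, so a normal
#' sample is centred on 0.
#'
#' @param values Numeric vector, length >= 4, with positive variance.
#' @return A [MomentSummary-class] object.
#' @examples
#' momentSummary(rexp(1e4))   # skewness near 2, excess kurtosis near 6
#' @export
momentSummary <- function(values) {
    values <- as.numeric(values)
    n <- length(values)
    if (n < 4L)
        stop("need at least 4 values for a four-moment summary")
    if (anyNA(values)) stop("values must not contain NA")
    m <- mean(values)
    d <- values - m
    m2 <- mean(d^2)
    if (m2 == 0)
        stop("sample variance is zero; skewness and kurtosis are undefined")
    new("MomentSummary", n = n, mean = m, variance = m2,
        skewness = mean(d^3) / m2^1.5,
        kurtosis = mean(d^4) / m2^2 - 3)
}
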