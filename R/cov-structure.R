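# Lower Cholesky of a 2x2 PSD matrix, tolerating a singular (but PSD)
# matrix, which base chol() rejects without pivoting.
.chol2x2Lower <- function(M, label) {
    a <- M[1, 1]; b <- M[2, 1]; c <- M[2, 2]
    tol <- 1e-12 * max(1, abs(a), abs(c))
    if (a < -tol || c < -tol)
        stop(sprintf("%s covariance matrix is not positive semidefinite",
                     label))
    a <- max(a, 0); c <- max(c, 0)
    l11 <- sqrt(a)
    if (l11 > 0) {
        l21 <- b / l11
    } else {
        if (abs(b) > tol)
            stop(sprintf(
                "%s covariance matrix is not positive semidefinite (zero variance with nonzero covariance)",
                label))
        l21 <- 0
    }
    rest <- c - l21^2
    if (rest < -tol)
        stop(sprintf("%s covariance matrix is not positive semidefinite",
                     label))
    l22 <- sqrt(max(rest, 0))
    matrix(c(l11, l21, 0, l22), 2, 2)
}

#' Build the covariance structure implied by genetic parameters
#'
#' Assembles the 2x2 additive-genetic matrix \code{G} (diagonal
#' \code{h2_j * varp_j}, off-diagonal \code{rG * sqrt(G11 * G22)}), the
#' environmental matrix \code{E} (diagonal \code{(1 - h2_j) * varp_j},
#' off-diagonal \code{rE * sqrt(E11 * E22)}), their sum \code{P}, and the
#' lower Cholesky factors \code{Lg}, \code{Le} used to turn independent
#' standard-normal deviates into correlated breeding values and residuals.
#'
#' @param params A [GeneticParams-class] object.
#' @return A [CovStructure-class] object.
#' @examples
#' cs <- buildCovStructure(geneticParams(h2_1 = 0.1, h2_2 = 0.1,
#'                                       rG = -0.5, rE = -0.5))
#' genCov(cs)   # [[0.1, -0.05], [-0.05, 0.1]]
#' @export
buildCovStructure <- function(params) {
    stopifnot(is(params, "GeneticParams"))
    validObject(params)
    g11 <- params@h2_1 * params@varp1
    g22 <- params@h2_2 * params@varp2
    e11 <- (1 - params@h2_1) * params@varp1
    e22 <- (1 - params@h2_2) * params@varp2
    G <- matrix(c(g11, params@rG * sqrt(g11 * g22),
                  params@rG * sqrt(g11 * g22), g22), 2, 2)
    E <- matrix(c(e11, params@rE * sqrt(e11 * e22),
                  params@rE * sqrt(e11 * e22), e22), 2, 2)
    new("CovStructure", G = G, E = E, P = G + E,
        Lg = .chol2x2Lower(G, "genetic"),
        Le = .chol2x2Lower(E, "environmental"))
}
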