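#' @import methods
NULL

#' Genetic parameterisation of two component traits
#'
#' Holds the full bivariate parameterisation of the two normally distributed
#' component traits of a ratio trait: trait means, phenotypic variances,
#' heritabilities, and the genetic and environmental correlations between
#' the traits' breeding values and residuals.
#'
#' @slot mu1,mu2 numeric(1). Means of Traits 1 (numerator) and 2
#'   (denominator), in trait units. \code{mu2} must be nonzero because the
#'   ratio trait divides by Trait 2.
#' @slot varp1,varp2 numeric(1). Phenotypic variances, strictly positive.
#' @slot h2_1,h2_2 numeric(1). Heritabilities in \[0, 1\].
#' @slot rG numeric(1). Genetic correlation between the two traits'
#'   breeding values, in \[-1, 1\].
#' @slot rE numeric(1). Environmental correlation between the two traits'
#'   residual deviations, in \[-1, 1\].
#'
#' @seealso [geneticParams()] for the user-facing constructor.
#' @exportClass GeneticParams
setClass("GeneticParams",
    representation(
        mu1 = "numeric", mu2 = "numeric",
        varp1 = "numeric", varp2 = "numeric",
        h2_1 = "numeric", h2_2 = "numeric",
        rG = "numeric", rE = "numeric"
    )
)

setValidity("GeneticParams", function(object) {
    msg <- character()
    sc <- function(x) length(x) == 1L && is.finite(x)
    for (s in c("mu1", "mu2", "varp1", "varp2", "h2_1", "h2_2", "rG", "rE"))
        if (!sc(slot(object, s)))
            msg <- c(msg, sprintf("'%s' must be a single finite number", s))
    if (length(msg)) return(msg)
    if (object@mu2 == 0)
        msg <- c(msg, "mu2 must be nonzero (ratio trait divides by Trait 2)")
    if (object@varp1 <= 0 || object@varp2 <= 0)
        msg <- c(msg, "phenotypic variances must be > 0")
    if (object@h2_1 < 0 || object@h2_1 > 1 || object@h2_2 < 0 || object@h2_2 > 1)
        msg <- c(msg, "heritabilities must lie in [0, 1]")
    if (abs(object@rG) > 1 || abs(object@rE) > 1)
        msg <- c(msg, "correlations must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
})

#' Covariance structure of the component traits
#'
#' The 2x2 additive-genetic (\code{G}), environmental (\code{E}) and
#' phenotypic (\code{P = G + E}) covariance matrices implied by a
#' [GeneticParams-class] object, together with the lower Cholesky factors
#' \code{Lg} and \code{Le} used to generate correlated breeding values and
#' residuals.
#'
#' @slot G,E,P 2x2 numeric matrices.
#' @slot Lg,Le 2x2 lower-triangular matrices with \code{Lg \%*\% t(Lg) == G}
#'   and \code{Le \%*\% t(Le) == E}.
#'
#' @seealso [buildCovStructure()]
#' @exportClass CovStructure
setClass("CovStructure",
    representation(
        G = "matrix", E = "matrix", P = "matrix",
        Lg = "matrix", Le = "matrix"
    )
)

setValidity("CovStructure", function(object) {
    msg <- character()
    for (s in c("G", "E", "P", "Lg", "Le")) {
        m <- slot(object, s)
        if (!is.numeric(m) || !identical(dim(m), c(2L, 2L)))
            msg <- c(msg, sprintf("'%s' must be a 2x2 numeric matrix", s))
    }
    if (length(msg)) return(msg)
    tol <- 1e-10
    if (max(abs(object@Lg %*% t(object@Lg) - object@G)) > tol)
        msg <- c(msg, "Lg %*% t(Lg) does not reproduce G")
    if (max(abs(object@Le %*% t(object@Le) - object@E)) > tol)
        msg <- c(msg, "Le %*% t(Le) does not reproduce E")
    if (max(abs(object@G + object@E - object@P)) > tol)
        msg <- c(msg, "P must equal G + E")
    if (object@Lg[1, 2] != 0 || object@Le[1, 2] != 0)
        msg <- c(msg, "Cholesky factors must be lower triangular")
    if (length(msg)) msg else TRUE
})

#' Population design for the two-generation simulation
#'
#' Mating design of the pedigreed simulation: each sire is mated to
#' \code{damsPerSire} dams and every dam produces \code{offspringPerDam}
#' offspring, so the offspring generation has
#' \code{nSires * damsPerSire * offspringPerDam} individuals.
#'
#' @slot nSires,damsPerSire,offspringPerDam integer(1), all >= 1.
#'
#' @seealso [populationDesign()]
#' @exportClass PopulationDesign
setClass("PopulationDesign",
    representation(
        nSires = "integer",
        damsPerSire = "integer",
        offspringPerDam = "integer"
    )
)

setValidity("PopulationDesign", function(object) {
    msg <- character()
    for (s in c("nSires", "damsPerSire", "offspringPerDam")) {
        v <- slot(object, s)
        if (length(v) != 1L || is.na(v) || v < 1L)
            msg <- c(msg, sprintf("'%s' must be a single integer >= 1", s))
    }
    if (length(msg)) msg else TRUE
})

#' Per-individual trait records
#'
#' A generation of simulated individuals: identifiers, pedigree links
#' (\code{NA} for founders), breeding values \code{g1}, \code{g2},
#' phenotypes \code{p1}, \code{p2} and the ratio phenotype
#' \code{p0 = p1 / p2}. Residual deviations are stored implicitly as
#' \code{p - mu - g}.
#'
#' @slot data data.frame with columns \code{id}, \code{generation},
#'   \code{sire_id}, \code{dam_id}, \code{g1}, \code{g2}, \code{p1},
#'   \code{p2}, \code{p0}.
#'
#' @seealso [simulateBaseGeneration()], [simulateOffspring()],
#'   [readTraitTable()], [writeTraitTable()]
#' @exportClass TraitTable
setClass("TraitTable", representation(data = "data.frame"))

.traitTableCols <- c("id", "generation", "sire_id", "dam_id",
                     "g1", "g2", "p1", "p2", "p0")

setValidity("TraitTable", function(object) {
    d <- object@data
    missing <- setdiff(.traitTableCols, names(d))
    if (length(missing))
        return(sprintf("missing columns: %s", paste(missing, collapse = ", ")))
    if (nrow(d) && any(abs(d$p0 * d$p2 - d$p1) > 1e-10 * pmax(1, abs(d$p1))))
        return("p0 * p2 must equal p1 for every row")
    TRUE
})

#' Four-moment summary of a sample
#'
#' Mean, variance, skewness and kurtosis of a sample of (typically
#' ratio-trait) values. Moments are population moments (divide-by-n);
#' kurtosis is reported as excess kurtosis, so a normal sample is centred
#' on 0.
#'
#' @slot n integer(1). Sample size.
#' @slot mean,variance,skewness,kurtosis numeric(1).
#'
#' @seealso [momentSummary()]
#' @exportClass MomentSummary
setClass("MomentSummary",
    representation(
        n = "integer", mean = "numeric", variance = "numeric",
        skewness = "numeric", kurtosis = "numeric"
    )
)

setValidity("MomentSummary", function(object) {
    if (object@variance < 0) "variance must be >= 0" else TRUE
})

#' Midparent-offspring heritability estimate
#'
#' Additive-genetic variance, phenotypic variance and their ratio, estimated
#' from midparent-offspring statistics over families. The heritability is
#' deliberately not clamped to \[0, 1\]: sampling variation can push a raw
#' estimate outside the parameter space and downstream replicate averaging
#' needs the raw value.
#'
#' @slot sigma2_g numeric(1). Estimated additive-genetic variance,
#'   \code{2 * cov(midparent, offspring)}.
#' @slot sigma2_p numeric(1). Estimated phenotypic variance,
#'   \code{2 * var(midparent)}.
#' @slot h2 numeric(1). \code{sigma2_g / sigma2_p}.
#' @slot nFamilies integer(1). Number of midparent-offspring pairs used.
#' @slot trait character(1). Which trait was analysed (\code{"p0"},
#'   \code{"p1"} or \code{"p2"}).
#'
#' @seealso [estimateHeritability()]
#' @exportClass HeritabilityEstimate
setClass("HeritabilityEstimate",
    representation(
        sigma2_g = "numeric", sigma2_p = "numeric", h2 = "numeric",
        nFamilies = "integer", trait = "character"
    )
)

setValidity("HeritabilityEstimate", function(object) {
    msg <- character()
    if (object@sigma2_p <= 0)
        msg <- c(msg, "sigma2_p must be > 0")
    if (abs(object@h2 - object@sigma2_g / object@sigma2_p) > 1e-12 *
            max(1, abs(object@h2)))
        msg <- c(msg, "h2 must equal sigma2_g / sigma2_p")
    if (length(msg)) msg else TRUE
})
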