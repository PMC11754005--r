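#' Construct a GeneticParams object
#'
#' Bundle the bivariate parameterisation of the two component traits of a
#' ratio trait. Defaults reproduce the reference conditions: both
#' traits with mean 10 and phenotypic variance 1.
#'
#' @param mu1,mu2 Trait means (trait units); \code{mu2} must be nonzero.
#' @param varp1,varp2 Phenotypic variances (> 0).
#' @param h2_1,h2_2 Heritabilities, in \[0, 1\].
#' @param rG Genetic correlation between the traits, in \[-1, 1\].
#' @param rE Environmental correlation between the traits, in \[-1, 1\].
#'
#' @return A [GeneticParams-class] object.
#' @examples
#' gp <- geneticParams(h2_1 = 0.1, h2_2 = 0.5, rG = -0.5, rE = -0.5)
#' componentCovariance(gp)
#' @export
geneticParams <- function(mu1 = 10, mu2 = 10, varp1 = 1, varp2 = 1,
                          h2_1 = 0.3, h2_2 = 0.3, rG = 0, rE = 0) {
    new("GeneticParams",
        mu1 = as.numeric(mu1), mu2 = as.numeric(mu2),
        varp1 = as.numeric(varp1), varp2 = as.numeric(varp2),
        h2_1 = as.numeric(h2_1), h2_2 = as.numeric(h2_2),
        rG = as.numeric(rG), rE = as.numeric(rE))
}

#' Construct a PopulationDesign object
#'
#' The full-scale study design mates each of 100,000 sires to 10 dams, each
#' dam producing two offspring (2,000,000 offspring). The default here is
#' that design; grid experiments use a scaled-down profile (see
#' [experimentConfig()]).
#'
#' @param nSires Number of sires in the base generation.
#' @param damsPerSire Dams mated to each sire.
#' @param offspringPerDam Offspring produced by each dam.
#'
#' @return A [PopulationDesign-class] object.
#' @examples
#' populationDesign(nSires = 2000)
#' @export
populationDesign <- function(nSires = 100000L, damsPerSire = 10L,
                             offspringPerDam = 2L) {
    new("PopulationDesign",
        nSires = as.integer(nSires),
        damsPerSire = as.integer(damsPerSire),
        offspringPerDam = as.integer(offspringPerDam))
}

#' @describeIn PopulationDesign-class total number of offspring implied by
#'   the design.
#' @param design A [PopulationDesign-class] object.
#' @export
nOffspring <- function(design) {
    stopifnot(is(design, "PopulationDesign"))
    design@nSires * design@damsPerSire * design@offspringPerDam
}

#' @describeIn PopulationDesign-class number of dams (= number of families).
#' @export
nDams <- function(design) {
    stopifnot(is(design, "PopulationDesign"))
    design@nSires * design@damsPerSire
}

setMethod("show", "GeneticParams", function(object) {
    cat("GeneticParams\n")
    cat(sprintf("  means:        mu1 = %g, mu2 = %g\n", object@mu1, object@mu2))
    cat(sprintf("  variances:    varp1 = %g, varp2 = %g\n",
                object@varp1, object@varp2))
    cat(sprintf("  heritability: h2_1 = %g, h2_2 = %g\n",
                object@h2_1, object@h2_2))
    cat(sprintf("  correlations: rG = %g, rE = %g\n", object@rG, object@rE))
})

setMethod("show", "PopulationDesign", function(object) {
    cat(sprintf(
        "PopulationDesign: %d sires x %d dams/sire x %d offspring/dam (%d offspring)\n",
        object@nSires, object@damsPerSire, object@offspringPerDam,
        nOffspring(object)))
})

setMethod("show", "CovStructure", function(object) {
    cat("CovStructure\n  G:\n")
    print(object@G)
    cat("  E:\n")
    print(object@E)
})

setMethod("show", "MomentSummary", function(object) {
    cat(sprintf(
        "MomentSummary (n = %d)\n  mean = %.6g, variance = %.6g\n  skewness = %.6g, excess kurtosis = %.6g\n",
        object@n, object@mean, object@variance,
        object@skewness, object@kurtosis))
})

setMethod("show", "HeritabilityEstimate", function(object) {
    cat(sprintf(
        "HeritabilityEstimate for %s (%d families)\n  sigma2_g = %.6g, sigma2_p = %.6g, h2 = %.4f\n",
        object@trait, object@nFamilies, object@sigma2_g, object@sigma2_p,
        object@h2))
})

setMethod("show", "TraitTable", function(object) {
    d <- object@data
    gen <- if (nrow(d)) paste(unique(d$generation), collapse = "+") else "empty"
    cat(sprintf("TraitTable: %d individuals (%s)\n", nrow(d), gen))
    if (nrow(d)) print(utils::head(d, 4))
})
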