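# Population (divide-by-n) covariance and variance; the study's n is large
# enough that Bessel's correction is noise, and the delta formulas assume
# population moments.
.covN <- function(x, y) mean(x * y) - mean(x) * mean(y)
.varN <- function(x) .covN(x, x)

#' Estimate heritability from midparent-offspring statistics
#'
#' For each family (one sire, one dam, their full sibs) the midparent value
#' is \code{m = (p_s + p_d) / 2} and the offspring value \code{o} is the
#' family mean of the sibs' records (or, with
#' \code{pairing = "per_offspring"}, each sib's own record, the family then
#' contributing several pairs). The estimates are
#' \deqn{\hat\sigma^2_g = 2\, cov(m, o), \qquad
#'       \hat\sigma^2_p = 2\, var(m), \qquad
#'       \hat h^2 = \hat\sigma^2_g / \hat\sigma^2_p,}
#' with divide-by-n sample statistics over families. Unrelated parents give
#' \code{var(m) = sigma2_p / 2} and \code{cov(m, o) = sigma2_g / 2}, so both
#' estimators are consistent; family means leave the covariance expectation
#' unchanged while reducing noise. For the ratio trait the parent values are
#' the parents' own ratios \code{p1/p2}, not a ratio of midparent
#' components. The heritability is not clamped to \[0, 1\].
#'
#' @param parents Founder [TraitTable-class] (generation G0).
#' @param offspring Offspring [TraitTable-class] whose pedigree links
#'   resolve into \code{parents}.
#' @param trait Which trait to analyse: \code{"p0"} (ratio, default),
#'   \code{"p1"} or \code{"p2"}.
#' @param pairing \code{"family_mean"} (default) or \code{"per_offspring"}.
#' @return A [HeritabilityEstimate-class] object.
#' @examples
#' des <- populationDesign(nSires = 500)
#' pop <- simulatePopulation(geneticParams(h2_1 = 0.3), des, seed = 11)
#' estimateHeritability(pop$g0, pop$g1, trait = "p1")
#' @export
estimateHeritability <- function(parents, offspring,
                                 trait = c("p0", "p1", "p2"),
                                 pairing = c("family_mean",
                                             "per_offspring")) {
    stopifnot(is(parents, "TraitTable"), is(offspring, "TraitTable"))
    trait <- match.arg(trait)
    pairing <- match.arg(pairing)
    dp <- parents@data
    do <- offspring@data
    si <- match(do$sire_id, dp$id)
    di <- match(do$dam_id, dp$id)
    if (anyNA(si) || anyNA(di))
        stop("some offspring have a sire or dam not present in 'parents'")

    v <- do[[trait]]
    m_each <- (dp[[trait]][si] + dp[[trait]][di]) / 2
    if (pairing == "family_mean") {
        # one family per (sire, dam) mating; integer-code the pair cheaply
        key <- si * (nrow(dp) + 1) + di
        first <- !duplicated(key)
        fam <- match(key, key[first])
        cnt <- tabulate(fam, nbins = sum(first))
        o <- as.numeric(rowsum(v, fam, reorder = FALSE)) / cnt
        m <- m_each[first]                           # constant within family
    } else {
        o <- v
        m <- m_each
    }
    nfam <- length(o)
    if (nfam < 2L)
        stop("need at least 2 families to estimate variance components")
    s2g <- 2 * .covN(m, o)
    s2p <- 2 * .varN(m)
    new("HeritabilityEstimate",
        sigma2_g = s2g, sigma2_p = s2p, h2 = s2g / s2p,
        nFamilies = nfam, trait = trait)
}
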