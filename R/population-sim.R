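#' @importFrom stats rnorm var cov sd
NULL

# Derive a per-replicate RNG seed from (base seed, cell index, replicate
# index). Mixed multiplicatively; every product stays below 2^53 so the
# arithmetic is exact in doubles, and the result is kept in [1, 2^31 - 2]
# for set.seed().
.deriveSeed <- function(baseSeed, cell = 0L, replicate = 0L) {
    m <- 2147483647
    s <- ((baseSeed %% m) * 48271 + cell * 1299709 + replicate * 7919) %% m
    as.integer(s + 1)
}

.newTraitTable <- function(id, generation, sire_id, dam_id, g1, g2, p1, p2) {
    new("TraitTable", data = data.frame(
        id = id, generation = generation,
        sire_id = sire_id, dam_id = dam_id,
        g1 = g1, g2 = g2, p1 = p1, p2 = p2, p0 = p1 / p2))
}

.warnNearZeroDenominator <- function(p2, mu2) {
    nbad <- sum(abs(p2) < 1e-6 * abs(mu2))
    if (nbad > 0)
        warning(sprintf(
            "%d denominator phenotype(s) within 1e-6 * |mu2| of zero; ratio records kept as-is",
            nbad))
}

#' Simulate the unrelated base generation
#'
#' Draws \code{nSires + nSires * damsPerSire} unrelated, unselected,
#' non-inbred founders. Breeding values are \code{Lg \%*\% z} and residuals
#' \code{Le \%*\% z} with independent standard-normal \code{z}, so
#' \code{(g1, g2)} is bivariate normal with covariance \code{G} and
#' phenotypes are \code{p_j = mu_j + g_j + e_j}. Sires get ids
#' \code{1..nSires}, dams the following ids.
#'
#' @param params A [GeneticParams-class] object.
#' @param design A [PopulationDesign-class] object.
#' @param seed Integer seed; the generation is reproducible given
#'   (\code{seed}, \code{design}, \code{params}). \code{NULL} uses the
#'   current RNG state.
#' @return A [TraitTable-class] of founders (generation \code{"G0"},
#'   pedigree links \code{NA}).
#' @examples
#' g0 <- simulateBaseGeneration(geneticParams(),
#'                              populationDesign(nSires = 100), seed = 1)
#' @export
simulateBaseGeneration <- function(params, design, seed = NULL) {
    stopifnot(is(params, "GeneticParams"), is(design, "PopulationDesign"))
    validObject(design)
    cs <- buildCovStructure(params)
    if (!is.null(seed)) set.seed(.deriveSeed(seed))
    n <- design@nSires + nDams(design)
    Lg <- cs@Lg; Le <- cs@Le
    z1 <- rnorm(n); z2 <- rnorm(n); z3 <- rnorm(n); z4 <- rnorm(n)
    g1 <- Lg[1, 1] * z1
    g2 <- Lg[2, 1] * z1 + Lg[2, 2] * z2
    p1 <- params@mu1 + g1 + Le[1, 1] * z3
    p2 <- params@mu2 + g2 + Le[2, 1] * z3 + Le[2, 2] * z4
    .warnNearZeroDenominator(p2, params@mu2)
    .newTraitTable(
        id = seq_len(n),
        generation = rep("G0", n),
        sire_id = rep(NA_integer_, n), dam_id = rep(NA_integer_, n),
        g1 = g1, g2 = g2, p1 = p1, p2 = p2)
}

#' Simulate one offspring generation by Mendelian sampling
#'
#' Dams are shuffled (seeded) and assigned in consecutive blocks of
#' \code{damsPerSire} to each sire; every dam produces
#' \code{offspringPerDam} offspring. Offspring breeding values are the
#' midparent mean plus a Mendelian-sampling deviation generated through the
#' genetic Cholesky factor scaled by \code{sqrt(0.5)}:
#' \deqn{g_{i1} = (g_{s1}+g_{d1})/2 + \sqrt{0.5}\, Lg_{11} z_{i1}}
#' \deqn{g_{i2} = (g_{s2}+g_{d2})/2 + \sqrt{0.5}\,(Lg_{21} z_{i1} +
#'   Lg_{22} z_{i2})}
#' The \code{sqrt(0.5)} scale gives the within-family genetic covariance
#' \code{G/2}, which keeps the offspring generation's genetic variance equal
#' to the founders' for non-inbred, unselected parents. Phenotypes are
#' \code{p_j = mu_j + g_j + (Le z)_j} with fresh residual deviates.
#'
#' @param g0 Founder [TraitTable-class] from [simulateBaseGeneration()].
#' @param params A [GeneticParams-class] object.
#' @param design A [PopulationDesign-class] object consistent with
#'   \code{g0}.
#' @param seed Integer seed for mating order, Mendelian sampling and
#'   residuals; \code{NULL} uses the current RNG state.
#' @return A [TraitTable-class] of offspring (generation \code{"G1"}) whose
#'   \code{sire_id}/\code{dam_id} resolve to rows of \code{g0}.
#' @examples
#' des <- populationDesign(nSires = 100)
#' g0 <- simulateBaseGeneration(geneticParams(), des, seed = 1)
#' g1 <- simulateOffspring(g0, geneticParams(), des, seed = 2)
#' @export
simulateOffspring <- function(g0, params, design, seed = NULL) {
    stopifnot(is(g0, "TraitTable"), is(params, "GeneticParams"),
              is(design, "PopulationDesign"))
    validObject(design)
    d0 <- g0@data
    sires <- d0[d0$id <= design@nSires & is.na(d0$sire_id), , drop = FALSE]
    dams <- d0[d0$id > design@nSires & is.na(d0$sire_id), , drop = FALSE]
    if (nrow(sires) != design@nSires || nrow(dams) != nDams(design))
        stop(sprintf(
            "founder table has %d sires and %d dams; design requires %d and %d",
            nrow(sires), nrow(dams), design@nSires, nDams(design)))
    cs <- buildCovStructure(params)
    if (!is.null(seed)) set.seed(.deriveSeed(seed))

    damOrder <- sample.int(nrow(dams))            # seeded shuffle
    damIdx <- damOrder                            # block b -> sire b %/% dps
    sireOfDam <- rep(seq_len(design@nSires), each = design@damsPerSire)

    k <- design@offspringPerDam
    off_dam <- rep(damIdx, each = k)              # row index into dams
    off_sire <- rep(sireOfDam, each = k)          # row index into sires
    n <- length(off_dam)

    Lg <- cs@Lg; Le <- cs@Le
    mid1 <- (sires$g1[off_sire] + dams$g1[off_dam]) / 2
    mid2 <- (sires$g2[off_sire] + dams$g2[off_dam]) / 2
    z1 <- rnorm(n); z2 <- rnorm(n); z3 <- rnorm(n); z4 <- rnorm(n)
    s <- sqrt(0.5)
    g1 <- mid1 + s * Lg[1, 1] * z1
    g2 <- mid2 + s * (Lg[2, 1] * z1 + Lg[2, 2] * z2)
    p1 <- params@mu1 + g1 + Le[1, 1] * z3
    p2 <- params@mu2 + g2 + Le[2, 1] * z3 + Le[2, 2] * z4
    .warnNearZeroDenominator(p2, params@mu2)
    .newTraitTable(
        id = max(d0$id) + seq_len(n),
        generation = rep("G1", n),
        sire_id = sires$id[off_sire], dam_id = dams$id[off_dam],
        g1 = g1, g2 = g2, p1 = p1, p2 = p2)
}

#' Simulate founders plus one offspring generation
#'
#' Convenience wrapper running [simulateBaseGeneration()] and
#' [simulateOffspring()] under a single seed.
#'
#' @inheritParams simulateBaseGeneration
#' @param seed Integer seed (required here, for end-to-end
#'   reproducibility).
#' @return A list with elements \code{g0} and \code{g1}, both
#'   [TraitTable-class].
#' @examples
#' pop <- simulatePopulation(geneticParams(),
#'                           populationDesign(nSires = 50), seed = 7)
#' @export
simulatePopulation <- function(params, design, seed) {
    g0 <- simulateBaseGeneration(params, design, seed = seed)
    g1 <- simulateOffspring(g0, params, design, seed = NULL)
    list(g0 = g0, g1 = g1)
}

#' Simulate ratio records from independent individuals
#'
#' Draws \code{n} independent pairs \eqn{p_1 \sim N(\mu_1, (CV_1\mu_1)^2)},
#' \eqn{p_2 \sim N(\mu_2, (CV_2\mu_2)^2)} and returns the ratios
#' \eqn{p_1/p_2}. No truncation or rejection is applied near a zero
#' denominator — truncation would bias the moments; at the study's settings
#' (\eqn{\mu_2 = 10\sigma_2} or farther) a non-positive denominator has
#' negligible probability. A warning reports any \code{|p2| < 1e-6 * mu2}.
#'
#' @param mu1,mu2 Component means (> 0).
#' @param cv1,cv2 Coefficients of variation (> 0).
#' @param n Number of records.
#' @param seed Optional integer seed.
#' @return Numeric vector of \code{n} ratio values.
#' @examples
#' r <- simulateIndependentRecords(10, 10, 0.05, 0.15, n = 1e4, seed = 1)
#' momentSummary(r)
#' @export
simulateIndependentRecords <- function(mu1, mu2, cv1, cv2, n = 2000000L,
                                       seed = NULL) {
    stopifnot(mu1 > 0, mu2 > 0, cv1 > 0, cv2 > 0, n >= 1)
    if (!is.null(seed)) set.seed(.deriveSeed(seed))
    p1 <- rnorm(n, mu1, cv1 * mu1)
    p2 <- rnorm(n, mu2, cv2 * mu2)
    .warnNearZeroDenominator(p2, mu2)
    p1 / p2
}
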