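test_that("covariance structure reproduces its generating parameters", {
    cs <- buildCovStructure(geneticParams(h2_1 = 0.1, h2_2 = 0.1,
                                          rG = -0.5, rE = -0.5))
    expect_equal(genCov(cs), matrix(c(0.1, -0.05, -0.05, 0.1), 2, 2))
    expect_equal(envCov(cs), matrix(c(0.9, -0.45, -0.45, 0.9), 2, 2))
    expect_equal(phenCov(cs), genCov(cs) + envCov(cs))

    # uncorrelated traits: diagonal Cholesky factors
    cs0 <- buildCovStructure(geneticParams(h2_1 = 0.4, h2_2 = 0.2))
    expect_equal(cholGen(cs0), diag(sqrt(c(0.4, 0.2))))
    expect_equal(cholGen(cs0)[2, 1], 0)

    # round trip L %*% t(L) over random valid parameters
    set.seed(3)
    for (i in 1:20) {
        gp <- geneticParams(varp1 = runif(1, 0.1, 5), varp2 = runif(1, 0.1, 5),
                            h2_1 = runif(1), h2_2 = runif(1),
                            rG = runif(1, -1, 1), rE = runif(1, -1, 1))
        cs <- buildCovStructure(gp)
        expect_lt(max(abs(cholGen(cs) %*% t(cholGen(cs)) - genCov(cs))), 1e-10)
        expect_lt(max(abs(cholEnv(cs) %*% t(cholEnv(cs)) - envCov(cs))), 1e-10)
    }

    # zero variance with nonzero covariance is caught and names the matrix
    expect_error(ratioherit:::.chol2x2Lower(matrix(c(0, 1, 1, 1), 2, 2),
                                            "genetic"),
                 "genetic")
    # boundary: h2 = 1 leaves a singular (all-zero) environmental matrix
    cs1 <- buildCovStructure(geneticParams(h2_1 = 1, h2_2 = 1, rG = 0.3))
    expect_equal(cholEnv(cs1), matrix(0, 2, 2))
})

test_that("base generation has the designed size, moments and covariance", {
    gp <- geneticParams(h2_1 = 0.3, h2_2 = 0.5, rG = 0.5, rE = -0.5)
    des <- populationDesign(nSires = 1000L)
    g0 <- simulateBaseGeneration(gp, des, seed = 4)
    d <- traitData(g0)
    n <- 1000L + nDams(des)
    expect_equal(nrow(d), n)
    expect_true(all(d$generation == "G0"))
    expect_true(all(is.na(d$sire_id)) && all(is.na(d$dam_id)))
    expect_equal(d$p0, d$p1 / d$p2)

    # sample variance of g1 within 4 SE of h2 * varp (SE = sqrt(2/n) * v)
    se <- sqrt(2 / n)
    expect_lt(abs(var(d$g1) - 0.3), 4 * se * 0.3)
    expect_lt(abs(var(d$g2) - 0.5), 4 * se * 0.5)
    expect_lt(abs(cov(d$g1, d$g2) - 0.5 * sqrt(0.15)), 0.02)
    expect_lt(abs(mean(d$p1) - 10), 0.02)
    expect_lt(abs(var(d$p1) - 1), 0.03)

    # zero heritability: no genetic variation at all
    d0 <- traitData(simulateBaseGeneration(
        geneticParams(h2_1 = 0, h2_2 = 0, rE = 0.5), des, seed = 5))
    expect_true(all(d0$g1 == 0) && all(d0$g2 == 0))
})

test_that("offspring generation respects the pedigree design", {
    gp <- geneticParams(h2_1 = 0.3, h2_2 = 0.3, rG = -0.5, rE = 0.5)
    des <- populationDesign(nSires = 50L)
    pop <- simulatePopulation(gp, des, seed = 6)
    d1 <- traitData(pop$g1)
    d0 <- traitData(pop$g0)
    expect_equal(nrow(d1), nOffspring(des))
    expect_true(all(d1$sire_id %in% d0$id) && all(d1$dam_id %in% d0$id))
    # every dam appears in exactly offspringPerDam rows
    expect_true(all(table(d1$dam_id) == des@offspringPerDam))
    # every sire in damsPerSire * offspringPerDam rows
    expect_true(all(table(d1$sire_id) ==
                    des@damsPerSire * des@offspringPerDam))
    # each dam is mated to exactly one sire
    expect_true(all(tapply(d1$sire_id, d1$dam_id,
                           function(s) length(unique(s))) == 1))
    expect_equal(d1$p0 * d1$p2, d1$p1)

    # design mismatch is caught
    expect_error(simulateOffspring(pop$g0, gp, populationDesign(nSires = 60L)),
                 "design requires")
})

test_that("Mendelian sampling keeps genetic variance stationary across generations", {
    des <- populationDesign(nSires = 1000L)
    for (cell in list(c(0.1, 0.5, -0.5, -0.5), c(0.3, 0.3, 0.5, 0.5),
                      c(0.5, 0.1, 0, -0.5))) {
        gp <- geneticParams(h2_1 = cell[1], h2_2 = cell[2],
                            rG = cell[3], rE = cell[4])
        pop <- simulatePopulation(gp, des, seed = 8)
        d1 <- traitData(pop$g1)
        n <- nrow(d1)
        # full sibs raise the variance of the variance estimate; allow 6
        # i.i.d.-based SEs
        expect_lt(abs(var(d1$g1) - cell[1]), 6 * sqrt(2 / n) * max(cell[1], 0.2))
        expect_lt(abs(var(d1$g2) - cell[2]), 6 * sqrt(2 / n) * max(cell[2], 0.2))
    }

    # zero genetic variance: offspring breeding values are exactly midparent 0
    pop0 <- simulatePopulation(geneticParams(h2_1 = 0, h2_2 = 0),
                               populationDesign(nSires = 20L), seed = 9)
    expect_true(all(traitData(pop0$g1)$g1 == 0))
})

test_that("offspring-midparent and full-sib breeding-value covariances equal G/2", {
    gp <- geneticParams(h2_1 = 0.3, h2_2 = 0.5, rG = 0.5)
    G <- genCov(buildCovStructure(gp))
    des <- populationDesign(nSires = 1000L)
    pop <- simulatePopulation(gp, des, seed = 10)
    d0 <- traitData(pop$g0); d1 <- traitData(pop$g1)
    si <- match(d1$sire_id, d0$id); di <- match(d1$dam_id, d0$id)
    mid <- cbind((d0$g1[si] + d0$g1[di]) / 2, (d0$g2[si] + d0$g2[di]) / 2)
    off <- cbind(d1$g1, d1$g2)
    expect_lt(max(abs(cov(off, mid) - G / 2)), 0.01)

    # full sibs: consecutive offspring of the same dam
    ord <- order(d1$dam_id, d1$id)
    a <- ord[seq(1, length(ord), 2)]; b <- ord[seq(2, length(ord), 2)]
    expect_lt(max(abs(cov(off[a, ], off[b, ]) - G / 2)), 0.01)
})

test_that("simulation is reproducible from its seed", {
    gp <- geneticParams(h2_1 = 0.3, h2_2 = 0.3, rG = -0.5, rE = 0.5)
    des <- populationDesign(nSires = 30L)
    p1 <- simulatePopulation(gp, des, seed = 123)
    p2 <- simulatePopulation(gp, des, seed = 123)
    expect_identical(traitData(p1$g0), traitData(p2$g0))
    expect_identical(traitData(p1$g1), traitData(p2$g1))
    p3 <- simulatePopulation(gp, des, seed = 124)
    expect_false(identical(traitData(p3$g1), traitData(p1$g1)))
})

test_that("independent ratio records have the expected mean and shape", {
    # vanishing CVs: all records collapse on the ratio of means
    r <- simulateIndependentRecords(10, 10, 1e-6, 1e-6, n = 1000, seed = 1)
    expect_lt(max(abs(r - 1)), 1e-4)

    # mean follows mu1/mu2 * (1 + cv2^2), insensitive to cv1
    for (mu in list(c(10, 25), c(10, 10), c(25, 10))) {
        m1 <- mean(simulateIndependentRecords(mu[1], mu[2], 0.05, 0.05,
                                              n = 2e5, seed = 2))
        m2 <- mean(simulateIndependentRecords(mu[1], mu[2], 0.15, 0.05,
                                              n = 2e5, seed = 3))
        target <- mu[1] / mu[2] * (1 + 0.05^2)
        expect_equal(m1, target, tolerance = 0.005)
        expect_equal(m2, target, tolerance = 0.005)
    }
})

test_that("trait tables round-trip through TSV with 0-coded missing parents", {
    gp <- geneticParams(h2_1 = 0.3, h2_2 = 0.3)
    des <- populationDesign(nSires = 10L)
    pop <- simulatePopulation(gp, des, seed = 11)
    f <- tempfile(fileext = ".tsv")
    writeTraitTable(pop$g1, f)
    raw <- utils::read.table(f, header = TRUE, sep = "\t")
    expect_true(all(raw$sire_id > 0))
    back <- readTraitTable(f)
    expect_equal(traitData(back)$p1, traitData(pop$g1)$p1, tolerance = 1e-12)
    expect_equal(traitData(back)$sire_id, traitData(pop$g1)$sire_id)

    writeTraitTable(pop$g0, f)
    g0back <- readTraitTable(f)
    expect_true(all(is.na(traitData(g0back)$sire_id)))

    expect_error(readTraitTable(tempfile()), "does not exist")
    # a file missing required columns is rejected
    f2 <- tempfile(fileext = ".tsv")
    utils::write.table(data.frame(id = 1, p1 = 2), f2, sep = "\t",
                       row.names = FALSE)
    expect_error(readTraitTable(f2), "missing trait-table columns")
})
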