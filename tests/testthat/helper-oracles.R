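# Independent brute-force central moments (two-pass sums), used as the
# oracle for momentSummary.
bruteMoments <- function(x) {
    n <- length(x)
    m <- sum(x) / n
    c2 <- sum((x - m)^2) / n
    c3 <- sum((x - m)^3) / n
    c4 <- sum((x - m)^4) / n
    list(n = n, mean = m, variance = c2,
         skewness = c3 / c2^1.5, kurtosis = c4 / c2^2 - 3)
}

# The reference 81-cell parameter grid (means 10, unit variances).
studyGrid <- function() {
    expand.grid(h2_1 = c(0.1, 0.3, 0.5), h2_2 = c(0.1, 0.3, 0.5),
                rG = c(-0.5, 0, 0.5), rE = c(-0.5, 0, 0.5))
}

gridCellParams <- function(cell) {
    geneticParams(h2_1 = cell$h2_1, h2_2 = cell$h2_2,
                  rG = cell$rG, rE = cell$rE)
}

# Replicate means of per-population statistics for one parameter cell.
replicateStats <- function(params, design, nrep, baseSeed,
                           trait = "p0", cellIndex = 0L) {
    t(sapply(seq_len(nrep), function(r) {
        pop <- simulatePopulation(params, design,
                                  seed = baseSeed + 1000L * cellIndex + r)
        est <- estimateHeritability(pop$g0, pop$g1, trait = trait)
        c(h2 = heritability(est),
          var_p0 = momentSummary(traitData(pop$g1)$p0)@variance)
    }))
}
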