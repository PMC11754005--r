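#' Configuration for the two grid experiments
#'
#' Bundles the parameter grids, population design, replication and base
#' seed for [runExperiment1()] (independent ratio records over mean-ratio
#' and CV grids) and [runExperiment2()] (two-generation populations over
#' heritability and correlation grids).
#'
#' The default is a desk-scale profile: 2,000 sires x 10 dams x 2 offspring
#' (40,000 offspring, 20,000 families), 20 replicates per cell and 1e5
#' independent records per replicate. Replicate means at this size
#' reproduce the full-scale expectations to about +/-0.02 in heritability,
#' in minutes instead of hours. \code{fullScale = TRUE} switches to the
#' reference design: 100,000 sires, 100 replicates, 2e6 records.
#'
#' @param meanRatios List of length-2 numeric vectors \code{c(mu1, mu2)}
#'   for experiment 1. The default grid is
#'   10/25, 10/20, 10/15, 10/10, 15/10, 20/10, 25/10.
#' @param cvGrid Coefficients of variation for experiment 1; each cell
#'   crosses \code{cvGrid} with itself.
#' @param h2Grid Heritabilities for experiment 2; crossed with itself for
#'   the two traits.
#' @param rGrid Genetic and environmental correlations for experiment 2;
#'   crossed with itself.
#' @param design A [PopulationDesign-class] for experiment 2.
#' @param nReplicates Replicates per grid cell.
#' @param nRecords Independent records per replicate (experiment 1).
#' @param baseSeed Base RNG seed; every replicate's stream is derived from
#'   (\code{baseSeed}, cell index, replicate index), so results are
#'   independent of evaluation order.
#' @param scaleFactor Multiplier applied to \code{design@nSires} for
#'   desk-scale runs of a full-scale design; the scaled population must
#'   keep at least 100 families.
#' @param fullScale If \code{TRUE}, use the full reference scale.
#' @return An \code{ExperimentConfig} object.
#' @examples
#' cfg <- experimentConfig(nReplicates = 2, nRecords = 1e4)
#' @export
experimentConfig <- function(meanRatios = list(
                                 c(10, 25), c(10, 20), c(10, 15), c(10, 10),
                                 c(15, 10), c(20, 10), c(25, 10)),
                             cvGrid = c(0.05, 0.10, 0.15),
                             h2Grid = c(0.1, 0.3, 0.5),
                             rGrid = c(-0.5, 0, 0.5),
                             design = populationDesign(nSires = 2000L),
                             nReplicates = 20L,
                             nRecords = 100000L,
                             baseSeed = 1L,
                             scaleFactor = 1,
                             fullScale = FALSE) {
    if (fullScale) {
        design <- populationDesign(nSires = 100000L)
        nReplicates <- 100L
        nRecords <- 2000000L
    }
    stopifnot(length(meanRatios) >= 1,
              all(vapply(meanRatios, length, 1L) == 2L),
              length(cvGrid) >= 1, length(h2Grid) >= 1, length(rGrid) >= 1,
              nReplicates >= 1, nRecords >= 1, scaleFactor > 0)
    scaled <- max(1L, as.integer(round(design@nSires * scaleFactor)))
    design <- populationDesign(scaled, design@damsPerSire,
                               design@offspringPerDam)
    if (nDams(design) < 100)
        stop("scaled design has fewer than 100 families; increase nSires or scaleFactor")
    new("ExperimentConfig",
        meanRatios = meanRatios, cvGrid = as.numeric(cvGrid),
        h2Grid = as.numeric(h2Grid), rGrid = as.numeric(rGrid),
        design = design, nReplicates = as.integer(nReplicates),
        nRecords = as.integer(nRecords), baseSeed = as.integer(baseSeed))
}

#' @exportClass ExperimentConfig
setClass("ExperimentConfig",
    representation(
        meanRatios = "list", cvGrid = "numeric",
        h2Grid = "numeric", rGrid = "numeric",
        design = "PopulationDesign",
        nReplicates = "integer", nRecords = "integer",
        baseSeed = "integer"
    )
)

setMethod("show", "ExperimentConfig", function(object) {
    cat(sprintf(
        "ExperimentConfig: %d mean ratios x %d CVs^2 | %d h2^2 x %d r^2 cells\n",
        length(object@meanRatios), length(object@cvGrid),
        length(object@h2Grid), length(object@rGrid)))
    cat(sprintf("  %d replicates, %d records (exp. 1), base seed %d\n",
                object@nReplicates, object@nRecords, object@baseSeed))
    show(object@design)
})

.meanSd <- function(x, prefix) {
    out <- data.frame(mean(x), if (length(x) > 1) sd(x) else 0)
    names(out) <- paste0(prefix, c("_mean", "_sd"))
    out
}

.aggregateMoments <- function(reps) {
    # reps: data.frame with columns mean, variance, skewness, kurtosis
    cbind(.meanSd(reps$mean, "mean"),
          .meanSd(reps$variance, "variance"),
          .meanSd(reps$variance * 10, "variance_x10"),
          .meanSd(reps$skewness, "skewness"),
          .meanSd(reps$kurtosis, "kurtosis"))
}

#' Run the independent-records ratio-distribution experiment
#'
#' For every (mean ratio, CV1, CV2) cell, simulates \code{nReplicates}
#' independent record sets with [simulateIndependentRecords()], summarises
#' each with [momentSummary()], and reports the mean and SD over replicates
#' of each of the four moments. The default configuration yields the
#' 7 x 9 = 63-cell grid.
#'
#' @param config An \code{ExperimentConfig} from [experimentConfig()].
#' @param verbose Log per-cell progress to stderr.
#' @return A data.frame with one row per cell: \code{mu1}, \code{mu2},
#'   \code{cv1}, \code{cv2}, \code{n_records}, \code{n_replicates}, then
#'   \code{<stat>_mean} and \code{<stat>_sd} for mean, variance,
#'   variance_x10, skewness and kurtosis.
#' @examples
#' cfg <- experimentConfig(meanRatios = list(c(10, 10)), cvGrid = 0.1,
#'                         nReplicates = 2, nRecords = 1e4)
#' runExperiment1(cfg)
#' @export
runExperiment1 <- function(config, verbose = FALSE) {
    stopifnot(is(config, "ExperimentConfig"))
    cells <- expand.grid(ratio = seq_along(config@meanRatios),
                         cv1 = config@cvGrid, cv2 = config@cvGrid)
    rows <- vector("list", nrow(cells))
    for (ci in seq_len(nrow(cells))) {
        mu <- config@meanRatios[[cells$ratio[ci]]]
        cv1 <- cells$cv1[ci]; cv2 <- cells$cv2[ci]
        if (verbose)
            message(sprintf("experiment1 cell %d/%d: mu %g/%g cv (%g, %g)",
                            ci, nrow(cells), mu[1], mu[2], cv1, cv2))
        reps <- tryCatch(
            do.call(rbind, lapply(seq_len(config@nReplicates), function(r) {
                vals <- simulateIndependentRecords(
                    mu[1], mu[2], cv1, cv2, n = config@nRecords,
                    seed = .deriveSeed(config@baseSeed, ci, r))
                as.data.frame(momentSummary(vals))
            })),
            error = function(e) stop(sprintf(
                "experiment1 cell (mu=%g/%g, cv1=%g, cv2=%g) failed: %s",
                mu[1], mu[2], cv1, cv2, conditionMessage(e))))
        rows[[ci]] <- cbind(
            data.frame(mu1 = mu[1], mu2 = mu[2], cv1 = cv1, cv2 = cv2,
                       n_records = config@nRecords,
                       n_replicates = config@nReplicates),
            .aggregateMoments(reps))
    }
    do.call(rbind, rows)
}

#' Run the two-generation heritability experiment
#'
#' For every (h2_1, h2_2, rG, rE) cell, simulates \code{nReplicates}
#' two-generation populations, summarises the ratio trait's distribution in
#' the offspring generation with [momentSummary()], estimates its
#' heritability with [estimateHeritability()], and aggregates means and SDs
#' over replicates. The default grids give the 81-cell layout (3
#' heritabilities for each trait x 3 values for each correlation).
#'
#' @param config An \code{ExperimentConfig} from [experimentConfig()].
#' @param componentTraits Also estimate heritability of the component
#'   traits p1 and p2 per replicate (adds \code{h2_p1_*}, \code{h2_p2_*}
#'   columns).
#' @param verbose Log per-cell progress to stderr.
#' @return A data.frame with one row per cell: the four grid parameters,
#'   design sizes, moment aggregates as in [runExperiment1()], and
#'   \code{sigma2_g}, \code{sigma2_p}, \code{h2} aggregates for the ratio
#'   trait.
#' @examples
#' cfg <- experimentConfig(h2Grid = 0.3, rGrid = 0,
#'                         design = populationDesign(nSires = 200),
#'                         nReplicates = 2)
#' runExperiment2(cfg)
#' @export
runExperiment2 <- function(config, componentTraits = FALSE,
                           verbose = FALSE) {
    stopifnot(is(config, "ExperimentConfig"))
    cells <- expand.grid(h2_1 = config@h2Grid, h2_2 = config@h2Grid,
                         rG = config@rGrid, rE = config@rGrid)
    rows <- vector("list", nrow(cells))
    for (ci in seq_len(nrow(cells))) {
        cell <- cells[ci, ]
        if (verbose)
            message(sprintf(
                "experiment2 cell %d/%d: h2 (%g, %g), rG %g, rE %g",
                ci, nrow(cells), cell$h2_1, cell$h2_2, cell$rG, cell$rE))
        params <- geneticParams(h2_1 = cell$h2_1, h2_2 = cell$h2_2,
                                rG = cell$rG, rE = cell$rE)
        reps <- tryCatch(
            do.call(rbind, lapply(seq_len(config@nReplicates), function(r) {
                pop <- simulatePopulation(
                    params, config@design,
                    seed = .deriveSeed(config@baseSeed, ci, r))
                mom <- as.data.frame(momentSummary(traitData(pop$g1)$p0))
                est <- estimateHeritability(pop$g0, pop$g1, trait = "p0")
                out <- cbind(mom[c("mean", "variance", "skewness",
                                   "kurtosis")],
                             data.frame(sigma2_g = geneticVariance(est),
                                        sigma2_p = phenotypicVariance(est),
                                        h2 = heritability(est)))
                if (componentTraits) {
                    out$h2_p1 <- heritability(
                        estimateHeritability(pop$g0, pop$g1, trait = "p1"))
                    out$h2_p2 <- heritability(
                        estimateHeritability(pop$g0, pop$g1, trait = "p2"))
                }
                out
            })),
            error = function(e) stop(sprintf(
                "experiment2 cell (h2_1=%g, h2_2=%g, rG=%g, rE=%g) failed: %s",
                cell$h2_1, cell$h2_2, cell$rG, cell$rE,
                conditionMessage(e))))
        agg <- cbind(
            data.frame(h2_1 = cell$h2_1, h2_2 = cell$h2_2,
                       rG = cell$rG, rE = cell$rE,
                       n_sires = config@design@nSires,
                       n_families = nDams(config@design),
                       n_replicates = config@nReplicates),
            .aggregateMoments(reps),
            .meanSd(reps$sigma2_g, "sigma2_g"),
            .meanSd(reps$sigma2_p, "sigma2_p"),
            .meanSd(reps$h2, "h2"))
        if (componentTraits)
            agg <- cbind(agg, .meanSd(reps$h2_p1, "h2_p1"),
                         .meanSd(reps$h2_p2, "h2_p2"))
        rows[[ci]] <- agg
    }
    do.call(rbind, rows)
}

#' Write a grid-experiment summary as CSV
#'
#' One row per grid cell, deterministic column order (as produced by the
#' experiment drivers), round-trip readable with [readSummary()].
#'
#' @param summary A data.frame from [runExperiment1()] or
#'   [runExperiment2()].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' cfg <- experimentConfig(meanRatios = list(c(10, 10)), cvGrid = 0.1,
#'                         nReplicates = 1, nRecords = 1e4)
#' writeSummary(runExperiment1(cfg), f)
#' @export
writeSummary <- function(summary, path) {
    stopifnot(is.data.frame(summary))
    tryCatch(
        utils::write.csv(summary, path, row.names = FALSE, quote = FALSE),
        error = function(e) stop(sprintf("cannot write summary to '%s': %s",
                                         path, conditionMessage(e))))
    invisible(path)
}

#' @rdname writeSummary
#' @export
readSummary <- function(path) {
    if (!file.exists(path))
        stop(sprintf("summary file '%s' does not exist", path))
    utils::read.csv(path, stringsAsFactors = FALSE)
}
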