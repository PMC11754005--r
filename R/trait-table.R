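#' Read and write trait tables as TSV
#'
#' Tab-separated serialisation of a [TraitTable-class] with header columns
#' \code{id, generation, sire_id, dam_id, g1, g2, p1, p2, p0}. A missing
#' parent is encoded as \code{0} in the file, following common
#' pedigree-file convention, and mapped back to \code{NA} on read.
#'
#' @param x A [TraitTable-class] object.
#' @param path File path.
#' @return \code{writeTraitTable} returns \code{path} invisibly;
#'   \code{readTraitTable} returns a [TraitTable-class].
#' @examples
#' tt <- simulateBaseGeneration(geneticParams(),
#'                              populationDesign(nSires = 10), seed = 1)
#' f <- tempfile(fileext = ".tsv")
#' writeTraitTable(tt, f)
#' identical(traitData(readTraitTable(f)), traitData(tt))
#' @export
writeTraitTable <- function(x, path) {
    stopifnot(is(x, "TraitTable"))
    d <- x@data
    d$sire_id[is.na(d$sire_id)] <- 0L
    d$dam_id[is.na(d$dam_id)] <- 0L
    tryCatch(
        utils::write.table(d, path, sep = "\t", quote = FALSE,
                           row.names = FALSE),
        error = function(e) stop(sprintf("cannot write trait table to '%s': %s",
                                         path, conditionMessage(e))))
    invisible(path)
}

#' @rdname writeTraitTable
#' @export
readTraitTable <- function(path) {
    if (!file.exists(path))
        stop(sprintf("trait table file '%s' does not exist", path))
    d <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
    missing <- setdiff(.traitTableCols, names(d))
    if (length(missing))
        stop(sprintf("'%s' is missing trait-table columns: %s", path,
                     paste(missing, collapse = ", ")))
    d$sire_id[d$sire_id == 0L] <- NA_integer_
    d$dam_id[d$dam_id == 0L] <- NA_integer_
    d$p0 <- d$p1 / d$p2   # recompute: TSV text rounding must not break p0*p2==p1
    new("TraitTable", data = d[.traitTableCols])
}
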