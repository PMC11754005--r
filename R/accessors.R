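#' @name accessors
#' @title Accessors for ratioherit S4 objects
#'
#' @description Small accessor generics so downstream code never reaches
#' into slots: covariance matrices and Cholesky factors of a
#' [CovStructure-class], the record data.frame of a [TraitTable-class],
#' and the components of [MomentSummary-class] and
#' [HeritabilityEstimate-class] objects.
#'
#' @param object An S4 object from this package.
#' @param x Object for \code{as.data.frame} coercions.
#' @param ... Unused.
#' @return The accessed component; coercions return a one-row
#'   \code{data.frame} (\code{TraitTable} returns its full record table).
NULL

#' @rdname accessors
#' @export
setGeneric("genCov", function(object) standardGeneric("genCov"))
#' @rdname accessors
#' @export
setGeneric("envCov", function(object) standardGeneric("envCov"))
#' @rdname accessors
#' @export
setGeneric("phenCov", function(object) standardGeneric("phenCov"))
#' @rdname accessors
#' @export
setGeneric("cholGen", function(object) standardGeneric("cholGen"))
#' @rdname accessors
#' @export
setGeneric("cholEnv", function(object) standardGeneric("cholEnv"))

setMethod("genCov", "CovStructure", function(object) object@G)
setMethod("envCov", "CovStructure", function(object) object@E)
setMethod("phenCov", "CovStructure", function(object) object@P)
setMethod("cholGen", "CovStructure", function(object) object@Lg)
setMethod("cholEnv", "CovStructure", function(object) object@Le)

#' @rdname accessors
#' @export
setGeneric("traitData", function(object) standardGeneric("traitData"))
setMethod("traitData", "TraitTable", function(object) object@data)

#' @rdname accessors
#' @export
setGeneric("heritability", function(object) standardGeneric("heritability"))
setMethod("heritability", "HeritabilityEstimate", function(object) object@h2)

#' @rdname accessors
#' @export
setGeneric("geneticVariance",
           function(object) standardGeneric("geneticVariance"))
setMethod("geneticVariance", "HeritabilityEstimate",
          function(object) object@sigma2_g)

#' @rdname accessors
#' @export
setGeneric("phenotypicVariance",
           function(object) standardGeneric("phenotypicVariance"))
setMethod("phenotypicVariance", "HeritabilityEstimate",
          function(object) object@sigma2_p)

#' @rdname accessors
#' @export
setGeneric("nFamilies", function(object) standardGeneric("nFamilies"))
setMethod("nFamilies", "HeritabilityEstimate",
          function(object) object@nFamilies)

#' @rdname accessors
#' @export
as.data.frame.MomentSummary <- function(x, ...) {
    data.frame(n = x@n, mean = x@mean, variance = x@variance,
               skewness = x@skewness, kurtosis = x@kurtosis)
}

#' @rdname accessors
#' @export
as.data.frame.HeritabilityEstimate <- function(x, ...) {
    data.frame(trait = x@trait, sigma2_g = x@sigma2_g,
               sigma2_p = x@sigma2_p, h2 = x@h2, n_families = x@nFamilies)
}

#' @rdname accessors
#' @export
as.data.frame.TraitTable <- function(x, ...) x@data
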