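#' @rdname GenotypeData-class
#' @param x A `GenotypeData` object.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypeData-class
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @rdname GenotypeData-class
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname CholeskyLoadings-class
#' @param x A `CholeskyLoadings` object.
#' @export
setGeneric("pathLoadings", function(x) standardGeneric("pathLoadings"))

#' @rdname GeneticCovariance-class
#' @param x A `GeneticCovariance` object.
#' @export
setGeneric("geneticCovariance", function(x) standardGeneric("geneticCovariance"))

#' @rdname GeneticCovariance-class
#' @export
setGeneric("samplingCovariance", function(x) standardGeneric("samplingCovariance"))

#' @rdname GeneticCovariance-class
#' @export
setGeneric("geneticCorrelation", function(x) standardGeneric("geneticCorrelation"))

#' @rdname LatentSumStats-class
#' @param x A `LatentSumStats` object.
#' @export
setGeneric("resilienceStats", function(x) standardGeneric("resilienceStats"))

#' @rdname LatentSumStats-class
#' @export
setGeneric("eduYearsStats", function(x) standardGeneric("eduYearsStats"))

#' @rdname LatentSumStats-class
#' @export
setGeneric("effectiveSampleSizes", function(x) standardGeneric("effectiveSampleSizes"))

#' @rdname LocusTable-class
#' @param x A `LocusTable` object.
#' @export
setGeneric("lociTable", function(x) standardGeneric("lociTable"))

#' @rdname LocusTable-class
#' @export
setGeneric("lociRanges", function(x) standardGeneric("lociRanges"))

#' @rdname LocusTable-class
#' @export
setGeneric("leadSnps", function(x) standardGeneric("leadSnps"))

#' @rdname LocusTable-class
#' @export
setGeneric("independentSnps", function(x) standardGeneric("independentSnps"))
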