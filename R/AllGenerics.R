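#' @rdname GenotypeData-class
#' @param x,object a `GenotypeData` (or `SimulatedPanel`) object.
#' @export
setGeneric("snpNames", function(x) standardGeneric("snpNames"))

#' @rdname GenotypeData-class
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname GenotypeData-class
#' @export
setGeneric("sampleStatus", function(x) standardGeneric("sampleStatus"))

#' @rdname GenotypeData-class
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname GenotypeData-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname SimulatedPanel-class
#' @param x a `SimulatedPanel` object.
#' @export
setGeneric("simPanel", function(x) standardGeneric("simPanel"))

#' @rdname SimulatedPanel-class
#' @export
setGeneric("truthLoci", function(x) standardGeneric("truthLoci"))

#' @rdname SimulatedPanel-class
#' @export
setGeneric("modelSpecs", function(x) standardGeneric("modelSpecs"))

#' @rdname AcoResult-class
#' @param x an `AcoResult` object.
#' @export
setGeneric("topSets", function(x) standardGeneric("topSets"))

#' @rdname AcoResult-class
#' @export
setGeneric("finalTau", function(x) standardGeneric("finalTau"))

#' @rdname StageOneResult-class
#' @param x a `StageOneResult` object.
#' @export
setGeneric("suspectedSets", function(x) standardGeneric("suspectedSets"))

#' @rdname StageOneResult-class
#' @export
setGeneric("topPheromoneLoci", function(x) standardGeneric("topPheromoneLoci"))

#' @rdname EvaluationReport-class
#' @param x an `EvaluationReport` object.
#' @export
setGeneric("metrics", function(x) standardGeneric("metrics"))
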