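#' @rdname StudyDesign-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname StudyDesign-accessors
#' @export
setGeneric("otuOf", function(x, samples) standardGeneric("otuOf"))

#' @rdname StudyDesign-accessors
#' @export
setGeneric("otuLabels", function(x) standardGeneric("otuLabels"))

#' @rdname StudyDesign-accessors
#' @export
setGeneric("eodFeatures", function(x) standardGeneric("eodFeatures"))

#' @rdname StudyDesign-accessors
#' @export
setGeneric("phenotypeOf", function(x, otu, feature) standardGeneric("phenotypeOf"))

#' @rdname StudyDesign-accessors
#' @export
setGeneric("samplesOfOtu", function(x, otu) standardGeneric("samplesOfOtu"))

#' @rdname StudyDesign-accessors
#' @export
setGeneric("phenotypeGroups", function(x, feature) standardGeneric("phenotypeGroups"))

#' @rdname EodExperiment-accessors
#' @export
setGeneric("studyDesign", function(x) standardGeneric("studyDesign"))

#' @rdname EodExperiment-accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname DGEResult-accessors
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))

#' @rdname DGEResult-accessors
#' @export
setGeneric("comparedOtus", function(x) standardGeneric("comparedOtus"))

#' @rdname GeneSetFamily-accessors
#' @export
setGeneric("setA", function(x) standardGeneric("setA"))

#' @rdname GeneSetFamily-accessors
#' @export
setGeneric("setAPrime", function(x, feature = NULL, phenotype = NULL)
  standardGeneric("setAPrime"))

#' @rdname GeneSetFamily-accessors
#' @export
setGeneric("setB", function(x, feature = NULL, phenotype = NULL)
  standardGeneric("setB"))

#' @rdname GeneSetFamily-accessors
#' @export
setGeneric("setC", function(x, feature = NULL, phenotype = NULL)
  standardGeneric("setC"))

#' @rdname GODag-accessors
#' @export
setGeneric("goTerms", function(x) standardGeneric("goTerms"))

#' @rdname GODag-accessors
#' @export
setGeneric("goParents", function(x) standardGeneric("goParents"))

#' @rdname GODag-accessors
#' @export
setGeneric("goAncestors", function(x, term) standardGeneric("goAncestors"))
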