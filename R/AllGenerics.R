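#' @rdname BinaryMutationMatrix-class
#' @param x a BinaryMutationMatrix
#' @export
setGeneric("mutationMatrix", function(x) standardGeneric("mutationMatrix"))

#' @rdname BinaryMutationMatrix-class
#' @export
setGeneric("patientNames", function(x) standardGeneric("patientNames"))

#' @rdname BinaryMutationMatrix-class
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' @rdname BinaryMutationMatrix-class
#' @export
setGeneric("groupSplit", function(x) standardGeneric("groupSplit"))

#' @rdname BinaryMutationMatrix-class
#' @param value replacement value
#' @export
setGeneric("groupSplit<-", function(x, value) standardGeneric("groupSplit<-"))

#' @rdname BinaryMutationMatrix-class
#' @export
setGeneric("geneFrequency", function(x) standardGeneric("geneFrequency"))

#' @rdname AssociationRuleSet-class
#' @param x an AssociationRuleSet
#' @export
setGeneric("rules", function(x) standardGeneric("rules"))

#' @rdname SOMModel-class
#' @param x a SOMModel
#' @export
setGeneric("codebook", function(x) standardGeneric("codebook"))

#' @rdname SOMModel-class
#' @export
setGeneric("unitAssignments", function(x) standardGeneric("unitAssignments"))

#' @rdname SOMModel-class
#' @export
setGeneric("mapQuality", function(x) standardGeneric("mapQuality"))

#' @rdname SubtypeAssignmentSet-class
#' @param x a SubtypeAssignmentSet
#' @export
setGeneric("subtypeLabels", function(x) standardGeneric("subtypeLabels"))

#' @rdname SubtypeAssignmentSet-class
#' @export
setGeneric("primaryLabels", function(x) standardGeneric("primaryLabels"))
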