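#' Construct a BinaryMutationMatrix
#'
#' @param mat logical or 0/1 numeric matrix, patients as rows and genes as
#'   columns (row and column names required).
#' @param group optional character/factor of length `nrow(mat)` giving a
#'   two-group split of the patients (e.g. largest study vs the rest).
#' @param colData optional extra per-patient metadata (data.frame/DataFrame).
#' @return a \linkS4class{BinaryMutationMatrix}
#' @examples
#' m <- matrix(c(1, 0, 1, 1), 2, 2,
#'     dimnames = list(c("P1", "P2"), c("TP53", "MYD88")))
#' binaryMutationMatrix(m)
#' @export
binaryMutationMatrix <- function(mat, group = NULL, colData = NULL) {
    if (is.null(rownames(mat)) || is.null(colnames(mat)))
        stop("patient (row) and gene (column) names are required")
    storage.mode(mat) <- "integer"
    cd <- S4Vectors::DataFrame(row.names = rownames(mat))
    if (!is.null(colData)) cd <- cbind(cd, S4Vectors::DataFrame(colData))
    if (!is.null(group)) cd$group <- as.character(group)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(mutations = t(mat)), colData = cd)
    new("BinaryMutationMatrix", se)
}

#' @rdname BinaryMutationMatrix-class
#' @export
setMethod("mutationMatrix", "BinaryMutationMatrix", function(x) {
    t(SummarizedExperiment::assay(x, "mutations")) == 1L
})

#' @rdname BinaryMutationMatrix-class
#' @export
setMethod("patientNames", "BinaryMutationMatrix", function(x) colnames(x))

#' @rdname BinaryMutationMatrix-class
#' @export
setMethod("geneNames", "BinaryMutationMatrix", function(x) rownames(x))

#' @rdname BinaryMutationMatrix-class
#' @export
setMethod("groupSplit", "BinaryMutationMatrix", function(x) {
    g <- SummarizedExperiment::colData(x)$group
    if (is.null(g)) NULL else stats::setNames(as.character(g), colnames(x))
})

#' @rdname BinaryMutationMatrix-class
#' @export
setReplaceMethod("groupSplit", "BinaryMutationMatrix", function(x, value) {
    if (!is.null(value)) {
        if (length(value) != ncol(x))
            stop("group split must cover every patient")
        value <- as.character(value)
    }
    SummarizedExperiment::colData(x)$group <- value
    validObject(x)
    x
})

#' @rdname BinaryMutationMatrix-class
#' @export
setMethod("geneFrequency", "BinaryMutationMatrix", function(x) {
    rowMeans(SummarizedExperiment::assay(x, "mutations"))
})

setMethod("show", "BinaryMutationMatrix", function(object) {
    cat(sprintf("BinaryMutationMatrix: %d patients x %d genes\n",
        ncol(object), nrow(object)))
    cat(sprintf("  mutated cells: %d (density %.3f)\n",
        sum(SummarizedExperiment::assay(object, "mutations")),
        mean(SummarizedExperiment::assay(object, "mutations"))))
    g <- groupSplit(object)
    if (!is.null(g))
        cat("  group split:", paste(sprintf("%s=%d", names(table(g)),
            table(g)), collapse = ", "), "\n")
})

#' @rdname AssociationRuleSet-class
#' @export
setMethod("rules", "AssociationRuleSet", function(x) x@rules)

#' @rdname AssociationRuleSet-class
#' @param object an AssociationRuleSet
setMethod("show", "AssociationRuleSet", function(object) {
    cat(sprintf("AssociationRuleSet: %d rules over %d patients\n",
        nrow(object@rules), object@nPatients))
    p <- object@params
    cat(sprintf("  minSupport=%g minConfidence=%g maxAntecedentSize=%s\n",
        p$minSupport, p$minConfidence, as.character(p$maxAntecedentSize)))
    if (nrow(object@rules)) {
        top <- utils::head(object@rules[order(-object@rules$lift), ], 5L)
        for (i in seq_len(nrow(top)))
            cat(sprintf("  {%s} => %s  supp=%.3f conf=%.3f lift=%.2f\n",
                top$antecedent[i], top$consequent[i], top$support[i],
                top$confidence[i], top$lift[i]))
    }
})

#' @rdname AssociationRuleSet-class
setMethod("length", "AssociationRuleSet", function(x) nrow(x@rules))

#' @rdname SOMModel-class
#' @export
setMethod("codebook", "SOMModel", function(x) x@codebook)

#' @rdname SOMModel-class
#' @export
setMethod("unitAssignments", "SOMModel", function(x) x@assignment)

#' @rdname SOMModel-class
#' @export
setMethod("mapQuality", "SOMModel", function(x) x@quality)

#' @rdname SOMModel-class
#' @param object a SOMModel
setMethod("show", "SOMModel", function(object) {
    cat(sprintf("SOMModel: %dx%d grid, %d features, %d mapped genes\n",
        object@gridRows, object@gridCols, ncol(object@codebook),
        length(object@assignment)))
    cat(sprintf("  mean BMU distance: %.4f\n", object@quality))
})

#' @rdname SubtypeAssignmentSet-class
#' @export
setMethod("subtypeLabels", "SubtypeAssignmentSet", function(x)
    x@assignments$labels)

#' @rdname SubtypeAssignmentSet-class
#' @export
setMethod("primaryLabels", "SubtypeAssignmentSet", function(x)
    stats::setNames(x@assignments$primary, x@assignments$patient_id))

#' @rdname SubtypeAssignmentSet-class
setMethod("length", "SubtypeAssignmentSet", function(x) nrow(x@assignments))

#' @rdname SubtypeAssignmentSet-class
#' @param object a SubtypeAssignmentSet
setMethod("show", "SubtypeAssignmentSet", function(object) {
    cat(sprintf("SubtypeAssignmentSet (%s mode): %d patients\n",
        object@mode, nrow(object@assignments)))
    print(table(object@assignments$primary))
})

#' @rdname SubtypeAssignmentSet-class
#' @param row.names,optional,... passed on / ignored (S3 compatibility)
#' @export
as.data.frame.SubtypeAssignmentSet <- function(x, row.names = NULL,
                                               optional = FALSE, ...) {
    a <- x@assignments
    data.frame(patient_id = a$patient_id,
        labels = vapply(a$labels, paste, "", collapse = "|"),
        primary = a$primary,
        rule_hits = vapply(a$rule_hits, paste, "", collapse = "|"),
        stringsAsFactors = FALSE)
}
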