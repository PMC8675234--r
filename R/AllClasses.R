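#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData colData<-
NULL

#' Patients-by-genes binary mutation matrix
#'
#' Container for an analysis-ready presence/absence mutation matrix.
#' Internally the object is a \linkS4class{SummarizedExperiment} with genes
#' as rows and patients as columns (a single \code{"mutations"} assay of 0/1
#' integers); user-facing accessors present the matrix in the
#' patients-by-genes orientation that the mining operations are defined on.
#' An optional two-group split of patients (used by the cross-study
#' concordance filter) lives in \code{colData(x)$group}.
#'
#' @slot .Data inherits all SummarizedExperiment slots.
#' @seealso [binaryMutationMatrix()], [buildBinaryMatrix()]
#' @export
setClass("BinaryMutationMatrix", contains = "SummarizedExperiment")

setValidity("BinaryMutationMatrix", function(object) {
    msg <- character()
    if (!"mutations" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'mutations' is required")
    else {
        a <- SummarizedExperiment::assay(object, "mutations")
        if (!all(a %in% c(0L, 1L)))
            msg <- c(msg, "assay 'mutations' must be binary (0/1)")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene symbols")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate patient identifiers")
    if (is.null(rownames(object)) || is.null(colnames(object)))
        msg <- c(msg, "gene and patient names are required")
    g <- SummarizedExperiment::colData(object)$group
    if (!is.null(g)) {
        if (anyNA(g) || length(unique(g)) != 2L)
            msg <- c(msg, "'group' must bipartition the patients (two levels, no NA)")
    }
    if (length(msg)) msg else TRUE
})

#' Set of mined association rules
#'
#' Rules of the form antecedent gene set -> single consequent gene, with
#' in-sample support, confidence and lift. Antecedents are stored as
#' `"/"`-joined sorted gene symbols.
#'
#' @slot rules data.frame with columns antecedent, consequent, support,
#'   confidence, lift, antecedentSize.
#' @slot nPatients number of patients (transactions) the rules were mined from.
#' @slot params mining parameters (minSupport, minConfidence, maxAntecedentSize).
#' @export
setClass("AssociationRuleSet",
    representation(rules = "data.frame", nPatients = "integer", params = "list"))

setValidity("AssociationRuleSet", function(object) {
    r <- object@rules
    need <- c("antecedent", "consequent", "support", "confidence", "lift")
    if (!all(need %in% names(r)))
        return(paste("rules must have columns:", paste(need, collapse = ", ")))
    if (nrow(r)) {
        if (any(r$support <= 0) || any(r$support > r$confidence + 1e-12) ||
            any(r$confidence > 1 + 1e-12))
            return("expected 0 < support <= confidence <= 1")
        if (any(r$lift <= 0)) return("lift must be positive")
    }
    TRUE
})

#' Self-organizing map over anchor-lift gene profiles
#'
#' A rectangular grid of codebook vectors trained online on gene-level lift
#' profiles; \code{quality} is the mean Euclidean distance of inputs to their
#' best-matching units.
#'
#' @slot codebook units x features numeric matrix (row i = unit i; units are
#'   numbered column-major, left-to-right then bottom-to-top of the grid).
#' @slot gridRows,gridCols grid dimensions.
#' @slot assignment named integer vector, gene -> best-matching unit.
#' @slot quality mean BMU distance.
#' @slot schedule training schedule actually used.
#' @slot seed RNG seed used for initialization and presentation order.
#' @export
setClass("SOMModel",
    representation(codebook = "matrix", gridRows = "integer",
        gridCols = "integer", assignment = "integer", quality = "numeric",
        schedule = "list", seed = "integer"))

setValidity("SOMModel", function(object) {
    if (nrow(object@codebook) != object@gridRows * object@gridCols)
        return("codebook rows must equal gridRows * gridCols")
    if (length(object@quality) != 1L || object@quality < 0)
        return("quality must be a single non-negative number")
    if (length(object@assignment) &&
        (min(object@assignment) < 1L ||
         max(object@assignment) > nrow(object@codebook)))
        return("assignments must index codebook units")
    TRUE
})

#' Per-patient genetic subtype assignments
#'
#' Multi-label subtype membership plus a precedence-resolved primary label
#' for each patient, with the mutated genes that triggered each label.
#'
#' @slot assignments S4Vectors DataFrame with columns patient_id (character),
#'   labels (CharacterList), primary (character), rule_hits (CharacterList).
#' @slot mode classifier mode, "basic" or "extended".
#' @export
setClass("SubtypeAssignmentSet",
    representation(assignments = "DataFrame", mode = "character"))

setValidity("SubtypeAssignmentSet", function(object) {
    a <- object@assignments
    need <- c("patient_id", "labels", "primary", "rule_hits")
    if (!all(need %in% names(a)))
        return(paste("assignments must have columns:", paste(need, collapse = ", ")))
    ok <- c("JAKSTAT", "BCL_CREBBP", "MCD", "TP53_INDEPENDENT", "SPARSE")
    if (nrow(a) && !all(a$primary %in% ok))
        return("unknown primary label")
    if (nrow(a)) {
        empty <- lengths(a$labels) == 0L
        if (any(empty != (a$primary == "SPARSE")))
            return("primary SPARSE iff the label set is empty")
    }
    TRUE
})
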