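## Harmonization of multi-study somatic mutation calls: canonical mutation
## type vocabulary, gene symbol normalization, binarization, and the two
## cross-study exclusion filters (Fisher concordance, minimum frequency).

#' Canonical mutation-type vocabulary
#'
#' The closed set of mutation-type labels used throughout the package.
#' @return character vector of the six canonical labels
#' @export
canonicalMutationTypes <- function() {
    c("TruncatingSNV", "SpliceSiteSNV", "MissenseSNV", "Indel",
      "SynonymousSNV", "MultipleTypes")
}

.norm_label <- function(x) gsub("[ -]+", "_", tolower(trimws(x)))

.default_synonyms <- function() {
    path <- system.file("extdata", "mutation_type_synonyms.tsv",
        package = "lymphomine", mustWork = TRUE)
    utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Standardize free-text mutation-type labels
#'
#' Maps study-specific labels (MAF `Variant_Classification` values,
#' free-text tags) onto the canonical vocabulary through a shipped,
#' user-editable synonym table. Matching is case-insensitive and treats
#' spaces, hyphens and underscores alike.
#'
#' @param raw_label character vector of labels to map
#' @param synonyms optional replacement synonym table (data.frame with
#'   columns `raw_label`, `canonical`); defaults to the shipped table
#' @return character vector of canonical labels
#' @examples
#' standardizeMutationType(c("Missense_Mutation", "Nonsense_Mutation"))
#' @export
standardizeMutationType <- function(raw_label, synonyms = NULL) {
    if (any(!nzchar(trimws(raw_label))))
        stop("empty mutation-type label")
    if (is.null(synonyms)) synonyms <- .default_synonyms()
    stopifnot(all(c("raw_label", "canonical") %in% names(synonyms)))
    map <- stats::setNames(synonyms$canonical, .norm_label(synonyms$raw_label))
    ## canonical labels always map to themselves
    map[.norm_label(canonicalMutationTypes())] <- canonicalMutationTypes()
    out <- map[.norm_label(raw_label)]
    if (anyNA(out)) {
        bad <- unique(raw_label[is.na(out)])
        stop("unmapped mutation-type label(s): ", paste(bad, collapse = ", "),
             ". Extend the synonym table to map them.")
    }
    unname(out)
}

#' Normalize gene symbols
#'
#' Uppercases symbols and resolves known aliases to their GRCh37-era HGNC
#' symbols through a shipped alias table (no network lookup).
#'
#' @param symbols character vector of gene symbols
#' @param aliases optional replacement alias table (columns `alias`, `symbol`)
#' @return character vector of normalized symbols
#' @export
normalizeGeneSymbol <- function(symbols, aliases = NULL) {
    if (any(!nzchar(trimws(symbols)))) stop("empty gene symbol")
    if (is.null(aliases)) {
        path <- system.file("extdata", "gene_alias_table.tsv",
            package = "lymphomine", mustWork = TRUE)
        aliases <- utils::read.delim(path, stringsAsFactors = FALSE)
    }
    up <- toupper(trimws(symbols))
    map <- stats::setNames(aliases$symbol, toupper(aliases$alias))
    hit <- up %in% names(map)
    up[hit] <- unname(map[up[hit]])
    up
}

#' Read somatic mutation calls
#'
#' Reads either the package's simple call format (columns `patient_id`,
#' `gene_symbol`, `mutation_type`, `cohort`) or a MAF-like file
#' (`Tumor_Sample_Barcode`, `Hugo_Symbol`, `Variant_Classification`,
#' optionally a cohort column). Mutation types are standardized and gene
#' symbols normalized on the way in.
#'
#' @param path file path (tab-delimited)
#' @param format `"simple"` or `"maf"`
#' @param cohort cohort tag to use when the MAF has no cohort column
#' @return data.frame of calls (patient_id, gene_symbol, mutation_type, cohort)
#' @export
readMutationCalls <- function(path, format = c("simple", "maf"),
                              cohort = "cohort1") {
    format <- match.arg(format)
    d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    if (format == "maf") {
        need <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Variant_Classification")
        if (!all(need %in% names(d)))
            stop("MAF input lacks columns: ",
                 paste(setdiff(need, names(d)), collapse = ", "))
        d <- data.frame(patient_id = d$Tumor_Sample_Barcode,
            gene_symbol = d$Hugo_Symbol,
            mutation_type = d$Variant_Classification,
            cohort = if ("cohort" %in% names(d)) d$cohort else cohort,
            stringsAsFactors = FALSE)
    }
    need <- c("patient_id", "gene_symbol", "mutation_type", "cohort")
    if (!all(need %in% names(d)))
        stop("call table lacks columns: ",
             paste(setdiff(need, names(d)), collapse = ", "))
    d$gene_symbol <- normalizeGeneSymbol(d$gene_symbol)
    d$mutation_type <- standardizeMutationType(d$mutation_type)
    d[need]
}

#' Build the binary mutation matrix from a call list
#'
#' Binarizes calls into a patients-by-genes presence/absence matrix. A
#' patient carrying more than one distinct mutation type in the same gene is
#' recorded in the collapsed call log with type `MultipleTypes`. The call
#' log (one row per patient-gene pair) is kept in
#' `S4Vectors::metadata(x)$callLog`; the per-patient cohort tag in
#' `colData(x)$cohort`.
#'
#' @param calls data.frame with columns patient_id, gene_symbol,
#'   mutation_type, cohort (as from [readMutationCalls()] or
#'   [simulateCohort()])
#' @param excludeSynonymous if TRUE, purely synonymous patient-gene pairs do
#'   not set the presence bit (default FALSE: the canonical vocabulary keeps
#'   synonymous calls)
#' @return a \linkS4class{BinaryMutationMatrix}
#' @export
buildBinaryMatrix <- function(calls, excludeSynonymous = FALSE) {
    need <- c("patient_id", "gene_symbol", "mutation_type")
    if (!is.data.frame(calls) || nrow(calls) == 0L)
        stop("empty call list")
    if (!all(need %in% names(calls)))
        stop("call table lacks columns: ",
             paste(setdiff(need, names(calls)), collapse = ", "))
    bad <- setdiff(unique(calls$mutation_type), canonicalMutationTypes())
    if (length(bad))
        stop("non-canonical mutation types (run standardizeMutationType): ",
             paste(bad, collapse = ", "))
    key <- paste(calls$patient_id, calls$gene_symbol, sep = "\r")
    types <- lapply(split(calls$mutation_type, key), unique)
    logType <- vapply(types, function(tt)
        if (length(tt) > 1L) "MultipleTypes" else tt, "")
    parts <- do.call(rbind, strsplit(names(logType), "\r", fixed = TRUE))
    callLog <- data.frame(patient_id = parts[, 1L], gene_symbol = parts[, 2L],
        mutation_type = unname(logType), stringsAsFactors = FALSE)
    if (excludeSynonymous)
        callLog <- callLog[callLog$mutation_type != "SynonymousSNV", ,
                           drop = FALSE]
    patients <- unique(calls$patient_id)
    genes <- sort(unique(calls$gene_symbol))
    m <- matrix(0L, length(patients), length(genes),
        dimnames = list(patients, genes))
    m[cbind(match(callLog$patient_id, patients),
            match(callLog$gene_symbol, genes))] <- 1L
    cohort <- NULL
    if ("cohort" %in% names(calls)) {
        tab <- unique(calls[c("patient_id", "cohort")])
        if (!anyDuplicated(tab$patient_id))
            cohort <- tab$cohort[match(patients, tab$patient_id)]
    }
    x <- binaryMutationMatrix(m,
        colData = if (is.null(cohort)) NULL else
            data.frame(cohort = cohort, row.names = patients))
    S4Vectors::metadata(x)$callLog <- callLog
    x
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by hypergeometric probability-mass summation: the
#' sum of probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table. This is the same
#' two-sidedness definition as `stats::fisher.test` (and differs from
#' doubling the one-sided tail on asymmetric tables).
#'
#' @param table 2x2 matrix of non-negative integer counts
#'   (rows: mutated/wild-type; columns: group A/group B)
#' @return two-sided p-value in (0, 1]
#' @examples
#' fisherExact2x2(matrix(c(5, 5, 5, 5), 2))  # 1
#' @export
fisherExact2x2 <- function(table) {
    table <- as.matrix(table)
    if (!all(dim(table) == c(2L, 2L))) stop("expected a 2x2 table")
    if (any(table < 0)) stop("negative counts")
    if (any(table != round(table))) stop("counts must be integers")
    m <- table[1, 1] + table[1, 2]   # row 1 margin
    n <- table[2, 1] + table[2, 2]   # row 2 margin
    k <- table[1, 1] + table[2, 1]   # column 1 margin
    if (m + n == 0L || (k == 0L && table[1, 2] + table[2, 2] == 0L))
        stop("at least one margin must be positive")
    support <- max(0L, k - n):min(k, m)
    probs <- stats::dhyper(support, m, n, k)
    pobs <- stats::dhyper(table[1, 1], m, n, k)
    p <- sum(probs[probs <= pobs * (1 + 1e-7)])
    min(p, 1)
}

.require_split <- function(x) {
    g <- groupSplit(x)
    if (is.null(g))
        stop("matrix has no group_split; set groupSplit(x) first")
    g
}

#' Cross-study concordance filter
#'
#' Retains genes whose mutation frequency does not differ significantly
#' between the two patient groups (per-gene two-sided Fisher's exact test);
#' genes with p below `alpha` are flagged for exclusion as likely
#' study-specific artifacts.
#'
#' @param x a \linkS4class{BinaryMutationMatrix} with a group split
#' @param alpha significance level for exclusion (default 0.001)
#' @return list with `retained` (gene names) and `report` (data.frame gene,
#'   p, excluded)
#' @export
concordanceFilter <- function(x, alpha = 0.001) {
    stopifnot(alpha >= 0, alpha <= 1)
    g <- .require_split(x)
    lev <- unique(g)
    m <- mutationMatrix(x)
    inA <- g == lev[1L]
    nA <- sum(inA); nB <- sum(!inA)
    p <- vapply(geneNames(x), function(gene) {
        a <- sum(m[inA, gene]); c_ <- sum(m[!inA, gene])
        fisherExact2x2(matrix(c(a, nA - a, c_, nB - c_), 2L))
    }, 0)
    report <- data.frame(gene = geneNames(x), p = unname(p),
        excluded = unname(p < alpha), stringsAsFactors = FALSE)
    list(retained = report$gene[!report$excluded], report = report)
}

#' Minimum-frequency filter
#'
#' Retains genes mutated in at least `minFreq` of patients in BOTH the whole
#' cohort and the designated larger group.
#'
#' @param x a \linkS4class{BinaryMutationMatrix}
#' @param minFreq minimum mutation frequency (default 0.03)
#' @param largerGroup patient IDs of the larger group; defaults to the
#'   bigger side of the group split when one is present, else all patients
#' @return list with `retained` (gene names) and `report` (data.frame gene,
#'   freq_all, freq_larger, excluded)
#' @export
frequencyFilter <- function(x, minFreq = 0.03, largerGroup = NULL) {
    stopifnot(minFreq >= 0, minFreq <= 1)
    if (is.null(largerGroup)) {
        g <- groupSplit(x)
        largerGroup <- if (is.null(g)) patientNames(x) else
            names(g)[g == names(which.max(table(g)))]
    }
    if (!all(largerGroup %in% patientNames(x)))
        stop("largerGroup contains unknown patients")
    m <- mutationMatrix(x)
    fAll <- colMeans(m)
    fLarge <- colMeans(m[largerGroup, , drop = FALSE])
    keep <- fAll >= minFreq & fLarge >= minFreq
    report <- data.frame(gene = geneNames(x), freq_all = unname(fAll),
        freq_larger = unname(fLarge), excluded = unname(!keep),
        stringsAsFactors = FALSE)
    list(retained = report$gene[keep], report = report)
}

#' Harmonize a multi-study call set into an analysis-ready matrix
#'
#' Convenience wrapper: builds the binary matrix, splits patients into the
#' largest single study versus the rest, applies the concordance and
#' frequency filters, and returns the filtered matrix together with the
#' per-gene filter report.
#'
#' @inheritParams buildBinaryMatrix
#' @inheritParams concordanceFilter
#' @inheritParams frequencyFilter
#' @return list: `matrix` (filtered \linkS4class{BinaryMutationMatrix}),
#'   `report` (merged per-gene filter report), `groups` (the split used)
#' @export
harmonizeCohort <- function(calls, alpha = 0.001, minFreq = 0.03,
                            excludeSynonymous = FALSE) {
    x <- buildBinaryMatrix(calls, excludeSynonymous = excludeSynonymous)
    cohort <- SummarizedExperiment::colData(x)$cohort
    if (is.null(cohort))
        stop("calls need a 'cohort' column to derive the two-group split")
    largest <- names(which.max(table(cohort)))
    groupSplit(x) <- ifelse(cohort == largest, "largest_study", "rest")
    conc <- concordanceFilter(x, alpha = alpha)
    freq <- frequencyFilter(x, minFreq = minFreq)
    keep <- intersect(conc$retained, freq$retained)
    report <- merge(conc$report, freq$report, by = "gene",
        suffixes = c("_concordance", "_frequency"))
    report$retained <- report$gene %in% keep
    xf <- x[keep, ]
    list(matrix = xf, report = report, groups = groupSplit(x))
}

#' Write a binary mutation matrix as TSV (patients as rows)
#' @param x a BinaryMutationMatrix
#' @param path output path
#' @export
writeBinaryMatrixTsv <- function(x, path) {
    m <- mutationMatrix(x) * 1L
    d <- data.frame(patient_id = rownames(m), m, check.names = FALSE,
        stringsAsFactors = FALSE)
    g <- groupSplit(x)
    if (!is.null(g)) d$group <- unname(g)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a binary mutation matrix written by [writeBinaryMatrixTsv()]
#' @param path input path
#' @return a BinaryMutationMatrix
#' @export
readBinaryMatrixTsv <- function(path) {
    d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    group <- if ("group" %in% names(d)) d$group else NULL
    genes <- setdiff(names(d), c("patient_id", "group"))
    m <- as.matrix(d[genes])
    rownames(m) <- d$patient_id
    binaryMutationMatrix(m, group = group)
}
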