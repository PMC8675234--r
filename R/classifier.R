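## Rule-based five-subtype genetic classifier: multi-label membership from
## the mutation profile plus a precedence-resolved primary label.

.PRECEDENCE <- c("JAKSTAT", "BCL_CREBBP", "MCD")

#' Subtype-defining gene sets
#'
#' The grouping rules: JAK-STAT-related (SOCS1 or STAT6; the extended
#' phenotype adds ITPKB, GNA13 and CIITA), BCL2-CREBBP (BCL2 or CREBBP),
#' MCD (MYD88 or CD79B), TP53 (TP53).
#'
#' @param mode "basic" or "extended" (extended widens only the JAK-STAT rule)
#' @return named list of gene sets
#' @export
subtypeGeneSets <- function(mode = c("basic", "extended")) {
    mode <- match.arg(mode)
    jak <- c("SOCS1", "STAT6")
    if (mode == "extended") jak <- c(jak, "ITPKB", "GNA13", "CIITA")
    list(JAKSTAT = jak,
         BCL_CREBBP = c("BCL2", "CREBBP"),
         MCD = c("MYD88", "CD79B"),
         TP53 = "TP53")
}

.assign_one <- function(profile, sets, combine) {
    hits <- lapply(sets, function(gg) intersect(gg, profile))
    held <- if (combine == "any") names(sets)[lengths(hits) > 0L]
        else names(sets)[vapply(seq_along(sets), function(i)
            all(sets[[i]] %in% profile), TRUE)]
    named <- intersect(.PRECEDENCE, held)
    primary <- if (length(named)) named[1L]
        else if ("TP53" %in% held) "TP53_INDEPENDENT"
        else "SPARSE"
    ruleHits <- unlist(lapply(held, function(lab)
        paste(lab, hits[[lab]], sep = ":")), use.names = FALSE)
    list(labels = held, primary = primary,
        rule_hits = if (is.null(ruleHits)) character() else ruleHits)
}

#' Assign genetic subtypes from mutation profiles
#'
#' Applies the grouping rules to every patient: the multi-label set of
#' subtype memberships plus a single primary label resolved by the
#' precedence JAKSTAT > BCL_CREBBP > MCD > TP53-independent; patients held
#' by no rule are SPARSE (undefined). A TP53-mutant patient is
#' TP53-independent only when no named group claims them.
#'
#' @param x a \linkS4class{BinaryMutationMatrix}, or a character vector of
#'   mutated genes for a single patient
#' @param mode classifier mode, see [subtypeGeneSets()]
#' @param combine `"any"` (a single defining gene suffices; the default,
#'   matching the or-phrased rules) or `"all"` (every defining gene required)
#' @return a \linkS4class{SubtypeAssignmentSet}
#' @examples
#' assignSubtypes(c("SOCS1", "STAT6", "B2M"))
#' @export
assignSubtypes <- function(x, mode = c("basic", "extended"),
                           combine = c("any", "all")) {
    mode <- match.arg(mode)
    combine <- match.arg(combine)
    sets <- subtypeGeneSets(mode)
    profiles <- if (is(x, "BinaryMutationMatrix")) {
        m <- mutationMatrix(x)
        stats::setNames(lapply(rownames(m), function(p)
            colnames(m)[m[p, ]]), rownames(m))
    } else if (is.character(x)) {
        list(patient1 = x)
    } else stop("x must be a BinaryMutationMatrix or a gene character vector")
    res <- lapply(profiles, .assign_one, sets = sets, combine = combine)
    df <- S4Vectors::DataFrame(
        patient_id = names(profiles),
        labels = S4Vectors::SimpleList(lapply(res, `[[`, "labels")),
        primary = vapply(res, `[[`, "", "primary"),
        rule_hits = S4Vectors::SimpleList(lapply(res, `[[`, "rule_hits")))
    new("SubtypeAssignmentSet", assignments = df, mode = mode)
}

#' Cohort composition by genetic subtype
#'
#' Group sizes and proportions for the (overlapping) multi-label groups and
#' the (partitioning) primary labels, the group overlap matrix, and — when
#' clinical records are supplied — the GCB / non-GCB cell-of-origin split per
#' group.
#'
#' @param assignments a \linkS4class{SubtypeAssignmentSet}
#' @param clinical optional clinical data.frame with patient_id and
#'   coo_subtype columns; patient IDs must match the assignments
#' @return list: `groups` (data.frame group, n, proportion, and COO columns
#'   when available), `primary` (data.frame of the primary-label partition),
#'   `overlap` (matrix of shared patients between multi-label groups)
#' @export
cohortComposition <- function(assignments, clinical = NULL) {
    a <- assignments@assignments
    n <- nrow(a)
    groups <- c("JAKSTAT", "BCL_CREBBP", "MCD", "TP53", "SPARSE")
    member <- vapply(groups, function(g) {
        if (g == "SPARSE") lengths(a$labels) == 0L
        else vapply(seq_len(n), function(i) g %in% a$labels[[i]], TRUE)
    }, logical(n))
    if (!is.matrix(member)) member <- matrix(member, nrow = 1L,
        dimnames = list(NULL, groups))
    gdf <- data.frame(group = groups, n = colSums(member),
        proportion = colSums(member) / n, stringsAsFactors = FALSE,
        row.names = NULL)
    if (!is.null(clinical)) {
        orphans <- setdiff(a$patient_id, clinical$patient_id)
        if (length(orphans))
            stop("patients missing from clinical records: ",
                 paste(orphans, collapse = ", "))
        coo <- clinical$coo_subtype[match(a$patient_id, clinical$patient_id)]
        gdf$n_gcb <- colSums(member & coo == "GCB")
        gdf$n_nongcb <- colSums(member & coo == "nonGCB")
    }
    primaryTab <- table(factor(a$primary, levels = c("JAKSTAT", "BCL_CREBBP",
        "MCD", "TP53_INDEPENDENT", "SPARSE")))
    pdf <- data.frame(primary = names(primaryTab),
        n = as.integer(primaryTab),
        proportion = as.integer(primaryTab) / n,
        stringsAsFactors = FALSE, row.names = NULL)
    overlap <- crossprod(member)
    list(groups = gdf, primary = pdf, overlap = overlap)
}
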