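## Subtype-level clinical statistics: per-group therapy response tables,
## categorical tests (chi-square / Fisher), and group-vs-rest survival.

.GROUPS <- c("JAKSTAT", "BCL_CREBBP", "MCD", "TP53", "SPARSE")

.group_membership <- function(assignments) {
    a <- assignments@assignments
    member <- vapply(.GROUPS, function(g) {
        if (g == "SPARSE") lengths(a$labels) == 0L
        else vapply(seq_len(nrow(a)), function(i) g %in% a$labels[[i]], TRUE)
    }, logical(nrow(a)))
    if (!is.matrix(member))
        member <- matrix(member, nrow = 1L, dimnames = list(NULL, .GROUPS))
    rownames(member) <- a$patient_id
    member
}

.check_ids <- function(assignments, records) {
    orphans <- setdiff(assignments@assignments$patient_id, records$patient_id)
    if (length(orphans))
        stop("patients missing from clinical records: ",
             paste(orphans, collapse = ", "))
}

#' Per-subtype therapy response table
#'
#' Complete-response rate per (overlapping) subtype group for one therapy
#' line; patients not treated on that line are excluded from the
#' denominator. Each group is compared against all other patients pooled
#' (2x2 responders/non-responders x group/rest, chi-square with Fisher
#' fallback when an expected count is below 5). Printed-style percentages
#' are rounded half-away-from-zero to one decimal; the tests use the exact
#' fractions.
#'
#' @param assignments a \linkS4class{SubtypeAssignmentSet}
#' @param records clinical data.frame (patient_id, induction_cr, salvage_cr,
#'   cart_cr with values yes/no/not_treated)
#' @param therapyLine one of "induction", "salvage", "cart"
#' @return data.frame (group, treated, responders, rate, rate_pct, p_vs_rest;
#'   rate is NA and the test skipped for groups with no treated patient)
#' @export
responseRateTable <- function(assignments, records,
        therapyLine = c("induction", "salvage", "cart")) {
    therapyLine <- match.arg(therapyLine)
    .check_ids(assignments, records)
    col <- paste0(therapyLine, "_cr")
    if (!col %in% names(records)) stop("records lack column ", col)
    member <- .group_membership(assignments)
    resp <- records[[col]][match(rownames(member), records$patient_id)]
    treatedAll <- resp != "not_treated"
    crAll <- resp == "yes"
    out <- lapply(.GROUPS, function(g) {
        inG <- member[, g]
        treated <- sum(inG & treatedAll)
        responders <- sum(inG & crAll)
        restTreated <- sum(!inG & treatedAll)
        restResponders <- sum(!inG & crAll)
        p <- NA_real_
        if (treated > 0L && restTreated > 0L) {
            tab <- matrix(c(responders, treated - responders,
                restResponders, restTreated - restResponders), 2L)
            p <- categoricalTest(tab, method = "auto")$p
        }
        data.frame(group = g, treated = treated, responders = responders,
            rate = if (treated > 0L) responders / treated else NA_real_,
            rate_pct = if (treated > 0L)
                .round_half_away(100 * responders / treated, 1L) else NA_real_,
            p_vs_rest = p, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Categorical test on an r x c count table
#'
#' Pearson chi-square without continuity correction by default; `"auto"`
#' falls back to the exact Fisher test for 2x2 tables with any expected
#' count below 5.
#'
#' @param table matrix of non-negative counts
#' @param method "chi2", "fisher_2x2" or "auto"
#' @return list: `statistic` (NA on the Fisher path), `p`, `method` (the
#'   test actually applied)
#' @export
categoricalTest <- function(table, method = c("chi2", "fisher_2x2", "auto")) {
    method <- match.arg(method)
    table <- as.matrix(table)
    if (any(table < 0)) stop("negative counts")
    if (any(rowSums(table) == 0) || any(colSums(table) == 0))
        stop("degenerate table: zero margin")
    expected <- outer(rowSums(table), colSums(table)) / sum(table)
    if (method == "auto")
        method <- if (all(dim(table) == 2L) && any(expected < 5))
            "fisher_2x2" else "chi2"
    if (method == "fisher_2x2") {
        if (!all(dim(table) == 2L)) stop("fisher_2x2 needs a 2x2 table")
        list(statistic = NA_real_, p = fisherExact2x2(table),
            method = "fisher_2x2")
    } else {
        stat <- sum((table - expected)^2 / expected)
        df <- (nrow(table) - 1L) * (ncol(table) - 1L)
        list(statistic = stat,
            p = stats::pchisq(stat, df, lower.tail = FALSE),
            method = "chi2")
    }
}

#' Subtype-versus-rest survival report
#'
#' One log-rank test per subtype group (members vs all other patients) plus
#' Kaplan-Meier step-function coordinates per group.
#'
#' @param assignments a \linkS4class{SubtypeAssignmentSet}
#' @param records clinical data.frame with patient_id, os_months, os_event
#' @return list: `tests` (data.frame group, n, events, statistic, p),
#'   `km` (data.frame of KM coordinates, groups "<group>" and "rest")
#' @export
subtypeSurvivalReport <- function(assignments, records) {
    .check_ids(assignments, records)
    member <- .group_membership(assignments)
    idx <- match(rownames(member), records$patient_id)
    time <- records$os_months[idx]
    event <- records$os_event[idx]
    keep <- !is.na(time) & !is.na(event)
    if (sum(event[keep]) < 1) stop("no events")
    tests <- list(); km <- list()
    for (g in .GROUPS) {
        inG <- member[, g] & keep
        rest <- !member[, g] & keep
        if (!sum(inG)) next
        if (!sum(rest))
            stop("group ", g, " covers the whole cohort; no complement")
        lr <- logrankTest(time[inG], event[inG], time[rest], event[rest])
        tests[[g]] <- data.frame(group = g, n = sum(inG),
            events = sum(event[inG]), statistic = lr$statistic, p = lr$p,
            stringsAsFactors = FALSE)
        co <- kmCoordinates(c(time[inG], time[rest]),
            c(event[inG], event[rest]),
            rep(c(g, "rest"), c(sum(inG), sum(rest))))
        co$comparison <- g
        km[[g]] <- co
    }
    list(tests = do.call(rbind, c(tests, list(make.row.names = FALSE))),
        km = do.call(rbind, c(km, list(make.row.names = FALSE))))
}

#' Read a clinical table
#'
#' @param path TSV with columns patient_id, coo_subtype, age_group,
#'   induction_cr, salvage_cr, cart_cr, os_months, os_event
#' @return validated data.frame
#' @export
readClinicalTsv <- function(path) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("patient_id", "coo_subtype", "induction_cr", "salvage_cr",
        "cart_cr", "os_months", "os_event")
    if (!all(need %in% names(d)))
        stop("clinical table lacks columns: ",
             paste(setdiff(need, names(d)), collapse = ", "))
    for (col in c("induction_cr", "salvage_cr", "cart_cr")) {
        bad <- setdiff(unique(d[[col]]), c("yes", "no", "not_treated"))
        if (length(bad))
            stop("invalid values in ", col, ": ", paste(bad, collapse = ", "))
    }
    if (any(!is.na(d$os_months) & d$os_months <= 0))
        stop("os_months must be positive")
    d
}
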