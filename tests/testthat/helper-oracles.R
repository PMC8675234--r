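## Independent oracles used across the suite. These re-derive expected
## values by brute force / direct formula and never call the code paths
## they check.

## exhaustive frequent-itemset enumeration over all 2^G - 1 itemsets
bruteItemsets <- function(m, minSupport) {
    n <- nrow(m)
    genes <- sort(colnames(m))
    rows <- list()
    for (k in seq_along(genes)) {
        for (comb in utils::combn(genes, k, simplify = FALSE)) {
            cnt <- sum(rowSums(m[, comb, drop = FALSE]) == k)
            if (cnt / n >= minSupport)
                rows[[length(rows) + 1L]] <- data.frame(
                    itemset = paste(comb, collapse = "/"), size = k,
                    count = cnt, stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) return(NULL)
    out <- out[order(out$size, out$itemset), ]
    rownames(out) <- NULL
    out$support <- out$count / n
    out
}

## exhaustive rule enumeration from brute-force itemsets
bruteRules <- function(m, minSupport, minConfidence) {
    n <- nrow(m)
    cnt <- function(gg) sum(rowSums(m[, gg, drop = FALSE]) == length(gg))
    its <- bruteItemsets(m, minSupport)
    rows <- list()
    if (is.null(its)) its <- data.frame(itemset = character(),
        size = integer(), count = integer())
    for (i in which(its$size >= 2L)) {
        s <- strsplit(its$itemset[i], "/", fixed = TRUE)[[1L]]
        for (j in seq_along(s)) {
            ante <- s[-j]
            conf <- its$count[i] / cnt(ante)
            if (conf + 1e-12 < minConfidence) next
            rows[[length(rows) + 1L]] <- data.frame(
                antecedent = paste(sort(ante), collapse = "/"),
                consequent = s[j], support = its$count[i] / n,
                confidence = conf,
                lift = conf / (cnt(s[j]) / n), stringsAsFactors = FALSE)
        }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(antecedent = character(), consequent = character(),
            support = numeric(), confidence = numeric(), lift = numeric())
    out[order(out$antecedent, out$consequent), ]
}

## two-sided Fisher p by direct binomial-coefficient enumeration
fisherEnumOracle <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- a + b + c + d
    supp <- max(0, c1 - r2):min(c1, r1)
    ps <- choose(r1, supp) * choose(r2, c1 - supp) / choose(N, c1)
    pobs <- choose(r1, a) * choose(r2, c1 - a) / choose(N, c1)
    min(sum(ps[ps <= pobs * (1 + 1e-7)]), 1)
}

## hand-tabulated two-group log-rank statistic (observed - expected over
## hypergeometric variance at each distinct event time)
logrankOracle <- function(timeA, eventA, timeB, eventB) {
    time <- c(timeA, timeB); event <- c(eventA, eventB)
    g <- rep(c(1L, 2L), c(length(timeA), length(timeB)))
    O <- 0; E <- 0; V <- 0
    for (t in sort(unique(time[event == 1]))) {
        atRisk <- time >= t
        n1 <- sum(atRisk & g == 1L); n <- sum(atRisk)
        d <- sum(time == t & event == 1)
        d1 <- sum(time == t & event == 1 & g == 1L)
        O <- O + d1
        E <- E + d * n1 / n
        if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    (O - E)^2 / V
}

## seeded random binary matrix (patients x genes)
randBinaryMatrix <- function(nPatients, nGenes, seed, p = 0.3) {
    set.seed(seed)
    m <- matrix(rbinom(nPatients * nGenes, 1L, p), nPatients, nGenes,
        dimnames = list(sprintf("P%03d", seq_len(nPatients)),
            sprintf("G%02d", seq_len(nGenes))))
    m
}

## clinical record skeleton for constructed cohorts
blankClinical <- function(ids) {
    data.frame(patient_id = ids, coo_subtype = "GCB", age_group = "<60",
        induction_cr = "not_treated", salvage_cr = "not_treated",
        cart_cr = "not_treated", os_months = 12, os_event = 0L,
        stringsAsFactors = FALSE)
}
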