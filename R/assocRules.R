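## Apriori frequent-itemset and association-rule mining over the binary
## mutation matrix, with support / confidence / lift, the pairwise lift
## matrix, and the top-k rule graph.

.join_set <- function(gg) paste(sort(gg), collapse = "/")
.split_set <- function(s) strsplit(s, "/", fixed = TRUE)[[1L]]

#' Mine frequent gene itemsets (apriori)
#'
#' Level-wise candidate generation with the downward-closure prune: a
#' candidate of size k is counted only if all of its (k-1)-subsets are
#' frequent. Returns exactly the itemsets with support >= `minSupport`;
#' supports are exact in-sample fractions.
#'
#' @param x a \linkS4class{BinaryMutationMatrix}
#' @param minSupport minimum support in (0, 1]
#' @param maxSize optional cap on itemset size
#' @return data.frame (itemset as "/"-joined sorted genes, size, count,
#'   support) with attribute `nPatients`
#' @export
mineFrequentItemsets <- function(x, minSupport = 0.03, maxSize = Inf) {
    stopifnot(minSupport > 0, minSupport <= 1)
    m <- mutationMatrix(x)
    if (nrow(m) == 0L || ncol(m) == 0L) stop("empty matrix")
    n <- nrow(m)
    storage.mode(m) <- "integer"
    counts <- colSums(m)
    keep <- counts / n >= minSupport
    level <- lapply(colnames(m)[keep], identity)
    levelCount <- counts[keep]
    empty <- data.frame(itemset = character(), size = integer(),
        count = integer(), stringsAsFactors = FALSE)
    if (!length(level)) {
        empty$support <- numeric()
        attr(empty, "nPatients") <- n
        attr(empty, "minSupport") <- minSupport
        return(empty)
    }
    out <- list(data.frame(itemset = unlist(level),
        size = 1L, count = as.integer(levelCount), stringsAsFactors = FALSE))
    k <- 1L
    freq <- new.env(parent = emptyenv())
    for (i in seq_along(level)) assign(level[[i]], TRUE, envir = freq)
    while (length(level) >= 2L && k < maxSize) {
        k <- k + 1L
        ## join step: sorted itemsets sharing their first k-2 items
        sets <- lapply(level, sort)
        prefix <- vapply(sets, function(s)
            paste(s[-length(s)], collapse = "/"), "")
        cand <- list()
        for (grp in split(seq_along(sets), prefix)) {
            if (length(grp) < 2L) next
            last <- vapply(sets[grp], function(s) s[length(s)], "")
            o <- order(last)
            grp <- grp[o]; last <- last[o]
            for (a in seq_len(length(grp) - 1L))
                for (b in (a + 1L):length(grp))
                    cand[[length(cand) + 1L]] <-
                        c(sets[[grp[a]]], last[b])
        }
        if (!length(cand)) break
        ## prune step: all (k-1)-subsets must be frequent
        pruned <- Filter(function(s) {
            all(vapply(seq_along(s), function(i)
                exists(.join_set(s[-i]), envir = freq), TRUE))
        }, cand)
        if (!length(pruned)) break
        cnt <- vapply(pruned, function(s)
            sum(rowSums(m[, s, drop = FALSE]) == length(s)), 0L)
        ok <- cnt / n >= minSupport
        level <- pruned[ok]
        if (!length(level)) break
        for (s in level) assign(.join_set(s), TRUE, envir = freq)
        out[[length(out) + 1L]] <- data.frame(
            itemset = vapply(level, .join_set, ""),
            size = k, count = unname(cnt[ok]), stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    res <- res[order(res$size, res$itemset), ]
    rownames(res) <- NULL
    res$support <- res$count / n
    attr(res, "nPatients") <- n
    attr(res, "minSupport") <- minSupport
    res
}

#' Generate association rules from frequent itemsets
#'
#' Enumerates all rules antecedent -> single consequent derivable from the
#' frequent itemsets, with confidence = support(rule) / support(antecedent)
#' and lift = confidence / support(consequent).
#'
#' @param itemsets output of [mineFrequentItemsets()]
#' @param minConfidence minimum confidence (default 0.1)
#' @param maxAntecedentSize maximum antecedent size (default 2)
#' @return an \linkS4class{AssociationRuleSet}
#' @export
generateRules <- function(itemsets, minConfidence = 0.1,
                          maxAntecedentSize = 2L) {
    stopifnot(minConfidence >= 0, minConfidence <= 1)
    n <- attr(itemsets, "nPatients")
    if (is.null(n)) stop("itemsets must come from mineFrequentItemsets()")
    supp <- stats::setNames(itemsets$support, itemsets$itemset)
    rows <- list()
    multi <- itemsets[itemsets$size >= 2L, , drop = FALSE]
    for (i in seq_len(nrow(multi))) {
        s <- .split_set(multi$itemset[i])
        if (length(s) - 1L > maxAntecedentSize) next
        for (j in seq_along(s)) {
            cons <- s[j]; ante <- s[-j]
            conf <- multi$support[i] / supp[[.join_set(ante)]]
            if (conf + 1e-12 < minConfidence) next
            rows[[length(rows) + 1L]] <- data.frame(
                antecedent = .join_set(ante), consequent = cons,
                support = multi$support[i], confidence = conf,
                lift = conf / supp[[cons]],
                antecedentSize = length(ante), stringsAsFactors = FALSE)
        }
    }
    rules <- if (length(rows)) do.call(rbind, rows) else
        data.frame(antecedent = character(), consequent = character(),
            support = numeric(), confidence = numeric(), lift = numeric(),
            antecedentSize = integer(), stringsAsFactors = FALSE)
    rules <- rules[order(-rules$lift, -rules$support, rules$antecedent,
        rules$consequent), ]
    rownames(rules) <- NULL
    new("AssociationRuleSet", rules = rules, nPatients = as.integer(n),
        params = list(minSupport = attr(itemsets, "minSupport"),
            minConfidence = minConfidence,
            maxAntecedentSize = maxAntecedentSize))
}

#' Pairwise lift matrix
#'
#' Symmetric matrix of in-sample lifts between genes:
#' `lift(A, B) = n * count(A and B) / (count(A) * count(B))`; the diagonal is
#' `n / count(A)`. Pairs that never co-occur get lift 0.
#'
#' @param x a \linkS4class{BinaryMutationMatrix}
#' @param genes genes to include (default: all); every gene must have
#'   nonzero frequency
#' @return symmetric numeric matrix of lifts
#' @export
pairwiseLiftMatrix <- function(x, genes = NULL) {
    m <- mutationMatrix(x)
    if (is.null(genes)) genes <- colnames(m)
    missing <- setdiff(genes, colnames(m))
    if (length(missing))
        stop("genes absent from matrix: ", paste(missing, collapse = ", "))
    m <- m[, genes, drop = FALSE] * 1L
    counts <- colSums(m)
    if (any(counts == 0L))
        stop("zero-frequency gene(s): ",
             paste(genes[counts == 0L], collapse = ", "))
    nrow(m) * crossprod(m) / outer(counts, counts)
}

#' Build the top-k rule graph
#'
#' Directed graph over the k highest-lift rules (ties broken by higher
#' support, then by the lexicographic rule string), one edge per
#' antecedent-gene/consequent pair. The node attribute `inDegreeRules`
#' counts the distinct retained rules in which the gene is the consequent
#' (the in-degree the graph rendering scales labels by).
#'
#' @param ruleSet an \linkS4class{AssociationRuleSet}
#' @param k number of rules to keep (default 300)
#' @return an `igraph` directed graph with edge attributes lift, support,
#'   rule
#' @export
topRulesGraph <- function(ruleSet, k = 300L) {
    stopifnot(k >= 0)
    r <- rules(ruleSet)
    ruleStr <- paste(r$antecedent, r$consequent, sep = "=>")
    r <- r[order(-r$lift, -r$support, ruleStr), , drop = FALSE]
    r <- utils::head(r, k)
    if (nrow(r) == 0L)
        return(igraph::make_empty_graph(directed = TRUE))
    edges <- do.call(rbind, lapply(seq_len(nrow(r)), function(i) {
        ante <- .split_set(r$antecedent[i])
        data.frame(from = ante, to = r$consequent[i], lift = r$lift[i],
            support = r$support[i],
            rule = paste(r$antecedent[i], r$consequent[i], sep = "=>"),
            stringsAsFactors = FALSE)
    }))
    g <- igraph::graph_from_data_frame(edges, directed = TRUE)
    inDeg <- table(r$consequent)
    v <- igraph::V(g)$name
    igraph::V(g)$inDegreeRules <- as.integer(ifelse(v %in% names(inDeg),
        inDeg[v], 0L))
    g
}

#' Write a rule table as TSV
#' @param ruleSet an AssociationRuleSet
#' @param path output path
#' @export
writeRulesTsv <- function(ruleSet, path) {
    utils::write.table(rules(ruleSet), path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}

#' Export a rule graph for external force-directed visualization
#'
#' GraphML export goes through igraph; GEXF is written directly (node labels
#' sized by `inDegreeRules` downstream, edge weight = lift).
#'
#' @param graph an igraph graph from [topRulesGraph()]
#' @param path output path
#' @param format "graphml" or "gexf"
#' @export
writeRuleGraph <- function(graph, path, format = c("graphml", "gexf")) {
    format <- match.arg(format)
    if (format == "graphml") {
        igraph::write_graph(graph, path, format = "graphml")
        return(invisible(path))
    }
    v <- igraph::V(graph)$name
    deg <- igraph::V(graph)$inDegreeRules
    el <- igraph::as_data_frame(graph, what = "edges")
    nodeXml <- sprintf(
        '      <node id="%s" label="%s"><attvalues><attvalue for="0" value="%d"/></attvalues></node>',
        v, v, deg)
    edgeXml <- sprintf(
        '      <edge id="%d" source="%s" target="%s" weight="%.6f"/>',
        seq_len(nrow(el)), el$from, el$to, el$lift)
    xml <- c('<?xml version="1.0" encoding="UTF-8"?>',
        '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
        '  <graph mode="static" defaultedgetype="directed">',
        '    <attributes class="node">',
        '      <attribute id="0" title="inDegreeRules" type="integer"/>',
        '    </attributes>',
        '    <nodes>', nodeXml, '    </nodes>',
        '    <edges>', edgeXml, '    </edges>',
        '  </graph>', '</gexf>')
    writeLines(xml, path)
    invisible(path)
}
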