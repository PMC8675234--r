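## Expression-level correlation screening within mutation Types and
## mean-cutoff survival analysis with multivariate proportional hazards.

.expr_matrix <- function(expr) {
    if (is(expr, "SummarizedExperiment"))
        SummarizedExperiment::assay(expr, "expression")
    else as.matrix(expr)
}

.expr_surv <- function(expr) {
    cd <- as.data.frame(SummarizedExperiment::colData(expr))
    if (!all(c("os_months", "os_event") %in% names(cd)))
        stop("expression object lacks os_months/os_event metadata")
    cd
}

#' Pairwise expression correlation
#'
#' Pearson correlation, simple linear-regression slope and the two-sided
#' p-value from the t transform of r with n-2 degrees of freedom, for each
#' requested gene pair.
#'
#' @param expr SummarizedExperiment (assay `expression`, genes x samples) or
#'   a plain genes x samples matrix
#' @param pairs data.frame with columns geneA, geneB
#' @return data.frame (geneA, geneB, n, r, slope, p)
#' @export
pairwiseExpressionCorrelation <- function(expr, pairs) {
    e <- .expr_matrix(expr)
    missing <- setdiff(unique(c(pairs$geneA, pairs$geneB)), rownames(e))
    if (length(missing))
        stop("genes absent from expression matrix: ",
             paste(missing, collapse = ", "))
    out <- lapply(seq_len(nrow(pairs)), function(i) {
        xa <- e[pairs$geneA[i], ]; xb <- e[pairs$geneB[i], ]
        if (stats::sd(xa) == 0) stop("constant gene: ", pairs$geneA[i])
        if (stats::sd(xb) == 0) stop("constant gene: ", pairs$geneB[i])
        n <- length(xa)
        r <- stats::cor(xa, xb)
        slope <- r * stats::sd(xb) / stats::sd(xa)
        p <- if (abs(r) >= 1) 0 else {
            tstat <- r * sqrt((n - 2) / (1 - r^2))
            2 * stats::pt(-abs(tstat), n - 2)
        }
        data.frame(geneA = pairs$geneA[i], geneB = pairs$geneB[i], n = n,
            r = r, slope = slope, p = p, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Screen a Type's genes on expression correlation and mutation lift
#'
#' Retains a gene when its expression is significantly correlated with the
#' Type's anchor gene (p < `alpha`) AND its pairwise mutation lift against
#' the anchor exceeds `minLift`.
#'
#' @param typeGenes candidate genes of the Type
#' @param anchor the Type's anchor gene
#' @param expr expression data (see [pairwiseExpressionCorrelation()])
#' @param liftMatrix symmetric lift matrix covering the genes (from
#'   [pairwiseLiftMatrix()])
#' @param alpha correlation significance threshold (default 0.05)
#' @param minLift minimum pairwise lift (default 1.5)
#' @return data.frame (gene, r, p, lift, retained)
#' @export
selectTypeGenes <- function(typeGenes, anchor, expr, liftMatrix,
                            alpha = 0.05, minLift = 1.5) {
    e <- .expr_matrix(expr)
    if (!anchor %in% rownames(e)) stop("anchor absent from expression: ", anchor)
    if (!anchor %in% rownames(liftMatrix))
        stop("anchor absent from lift matrix: ", anchor)
    typeGenes <- setdiff(typeGenes, anchor)
    typeGenes <- typeGenes[typeGenes %in% rownames(e) &
                           typeGenes %in% rownames(liftMatrix)]
    if (!length(typeGenes))
        return(data.frame(gene = character(), r = numeric(), p = numeric(),
            lift = numeric(), retained = logical()))
    cc <- pairwiseExpressionCorrelation(expr,
        data.frame(geneA = anchor, geneB = typeGenes,
            stringsAsFactors = FALSE))
    lift <- liftMatrix[typeGenes, anchor]
    data.frame(gene = typeGenes, r = cc$r, p = cc$p, lift = unname(lift),
        retained = cc$p < alpha & lift > minLift, stringsAsFactors = FALSE)
}

#' Dichotomize samples on a gene's mean expression
#'
#' High group: expression strictly above the mean; low group: at or below
#' (ties at the cutoff go low).
#'
#' @param expr expression data
#' @param gene gene to split on
#' @return list with `high` and `low` sample name vectors and the `cutoff`
#' @export
dichotomizeByMean <- function(expr, gene) {
    e <- .expr_matrix(expr)
    if (!gene %in% rownames(e)) stop("gene absent: ", gene)
    v <- e[gene, ]
    if (stats::sd(v) == 0) stop("constant gene: ", gene)
    cutoff <- mean(v)
    high <- colnames(e)[v > cutoff]
    low <- colnames(e)[v <= cutoff]
    if (!length(high) || !length(low))
        stop("mean cutoff produces an empty group for ", gene)
    list(high = high, low = low, cutoff = cutoff)
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of two survival samples (chi-square with one
#' degree of freedom).
#'
#' @param timeA,eventA follow-up times (months) and event indicators (1 =
#'   event) of group A
#' @param timeB,eventB same for group B
#' @return list: `statistic`, `p`, `observed` and `expected` events per group
#' @export
logrankTest <- function(timeA, eventA, timeB, eventB) {
    if (sum(eventA) + sum(eventB) < 1) stop("no events")
    if (!length(timeA) || !length(timeB)) stop("both groups must be non-empty")
    time <- c(timeA, timeB)
    event <- c(eventA, eventB)
    grp <- factor(rep(c("A", "B"), c(length(timeA), length(timeB))))
    fit <- survival::survdiff(survival::Surv(time, event) ~ grp, rho = 0)
    stat <- unname(fit$chisq)
    list(statistic = stat, p = stats::pchisq(stat, 1L, lower.tail = FALSE),
        observed = unname(fit$obs), expected = unname(fit$exp))
}

#' Multivariate Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Efron tie handling; per-covariate hazard
#' ratios with Wald 95% confidence intervals and p-values, plus the global
#' likelihood-ratio p.
#'
#' @param covariates data.frame or matrix of covariates (numeric columns;
#'   e.g. high/low expression indicators or continuous expression)
#' @param time,event survival times and event indicators
#' @return list: `fit` (data.frame covariate, coef, hr, lower95, upper95, p),
#'   `globalP` (likelihood-ratio), `n`, `events`
#' @export
coxMultivariate <- function(covariates, time, event) {
    covariates <- as.data.frame(covariates)
    if (sum(event) < 1) stop("no events")
    if (nrow(covariates) <= ncol(covariates))
        stop("need more observations than covariates")
    d <- cbind(data.frame(.time = time, .event = event), covariates)
    fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
        paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
    fit <- withCallingHandlers(
        survival::coxph(fml, data = d, ties = "efron"),
        warning = function(w) {
            if (grepl("did not converge|infinite", conditionMessage(w)))
                stop("Cox fit did not converge (possible perfect separation): ",
                     conditionMessage(w))
            invokeRestart("muffleWarning")
        })
    s <- summary(fit)
    res <- data.frame(covariate = rownames(s$coefficients),
        coef = s$coefficients[, "coef"],
        hr = s$coefficients[, "exp(coef)"],
        lower95 = s$conf.int[, "lower .95"],
        upper95 = s$conf.int[, "upper .95"],
        p = s$coefficients[, "Pr(>|z|)"],
        stringsAsFactors = FALSE, row.names = NULL)
    list(fit = res, globalP = unname(s$logtest["pvalue"]),
        n = s$n, events = unname(s$nevent))
}

#' Mean-cutoff survival screen for one gene
#'
#' Dichotomizes the cohort on the gene's mean expression and runs the
#' high-vs-low log-rank test.
#'
#' @inheritParams dichotomizeByMean
#' @return list: `logrank` (see [logrankTest()]), `nHigh`, `nLow`, `cutoff`
#' @export
expressionSurvivalScreen <- function(expr, gene) {
    cut <- dichotomizeByMean(expr, gene)
    cd <- .expr_surv(expr)
    hi <- match(cut$high, rownames(cd)); lo <- match(cut$low, rownames(cd))
    lr <- logrankTest(cd$os_months[hi], cd$os_event[hi],
        cd$os_months[lo], cd$os_event[lo])
    list(logrank = lr, nHigh = length(hi), nLow = length(lo),
        cutoff = cut$cutoff)
}

#' Kaplan-Meier step-function coordinates
#'
#' @param time,event survival data
#' @param group optional grouping factor
#' @return data.frame (group, time, surv, n_risk, n_event) suitable for
#'   plotting a step function
#' @export
kmCoordinates <- function(time, event, group = NULL) {
    if (is.null(group)) group <- rep("all", length(time))
    fit <- survival::survfit(survival::Surv(time, event) ~ g,
        data = data.frame(time = time, event = event, g = factor(group)))
    s <- summary(fit, censored = TRUE)
    strata <- if (is.null(s$strata)) rep(levels(factor(group)),
        length(s$time)) else sub("^g=", "", as.character(s$strata))
    data.frame(group = strata, time = s$time, surv = s$surv,
        n_risk = s$n.risk, n_event = s$n.event, stringsAsFactors = FALSE)
}
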