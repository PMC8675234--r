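## Synthetic cohort generator: Bernoulli-mixture mutation profiles with
## planted co-mutation blocks, subtype-dependent therapy responses and
## exponential survival, plus a deterministic fixture builder that turns
## printed marginal/pairwise contingency counts into an exact matrix.

.BLOCK_GENES <- list(
    JAKSTAT = c("SOCS1", "STAT6", "ITPKB", "CIITA", "GNA13", "B2M", "ACTB"),
    EZB     = c("KMT2D", "CREBBP", "BCL2", "EZH2", "TNFRSF14"),
    MCD     = c("MYD88", "CD79B", "PIM1", "PRDM1"),
    TP53    = "TP53")

.SUBTYPES <- c("JAKSTAT", "EZB", "MCD", "TP53", "SPARSE")

#' Planted co-mutation blocks of the default generator
#' @return named list, subtype -> defining block genes
#' @export
plantedBlocks <- function() .BLOCK_GENES

#' Default cohort simulation configuration
#'
#' Conditions of the emulated relapsed/refractory DLBCL cohort: ~96 patients,
#' ~250 gene columns, five latent subtypes with planted co-mutation blocks
#' (block genes mutated with probability 0.7 in carriers of the subtype —
#' 0.9 for TP53, whose group is defined by that single gene — against a 0.02
#' background everywhere else), high-frequency independent background genes
#' (TTN 0.37, IGLL5 0.27, DMD 0.15) and a bed of low-frequency filler genes,
#' subtype-dependent complete-response probabilities and exponential
#' overall-survival hazards.
#'
#' @param n_patients cohort size (default 96)
#' @param seed RNG seed
#' @return a validated config list for [simulateCohort()]
#' @export
defaultCohortConfig <- function(n_patients = 96L, seed = 20210677L) {
    blocks <- .BLOCK_GENES
    bp <- lapply(blocks, function(gg) {
        stats::setNames(rep(0.7, length(gg)), gg)
    })
    bp$TP53["TP53"] <- 0.9
    bp$SPARSE <- stats::setNames(numeric(0), character(0))
    filler <- sprintf("BG%03d", seq_len(230L))
    bg <- c(stats::setNames(rep(0.02, length(unlist(blocks))), unlist(blocks)),
        TTN = 0.37, IGLL5 = 0.27, DMD = 0.15,
        stats::setNames(rep(seq(0.03, 0.12, length.out = 10L), length.out =
            length(filler)), filler))
    cohortSimulationConfig(
        n_patients = n_patients,
        subtype_weights = c(JAKSTAT = 0.12, EZB = 0.23, MCD = 0.25,
            TP53 = 0.14, SPARSE = 0.26),
        block_gene_probs = bp,
        background_gene_probs = bg,
        response_probs = list(
            JAKSTAT = c(induction = 0.00, salvage = 0.15, cart = 0.38),
            EZB     = c(induction = 0.40, salvage = 0.15, cart = 0.40),
            MCD     = c(induction = 0.35, salvage = 0.15, cart = 0.40),
            TP53    = c(induction = 0.30, salvage = 0.10, cart = 0.214),
            SPARSE  = c(induction = 0.40, salvage = 0.20, cart = 0.55)),
        survival_hazards = c(JAKSTAT = 0.04, EZB = 0.04, MCD = 0.06,
            TP53 = 0.08, SPARSE = 0.03),
        coo_nongcb_probs = c(JAKSTAT = 0.33, EZB = 0.33, MCD = 0.81,
            TP53 = 0.61, SPARSE = 0.87),
        treated_probs = c(induction = 1, salvage = 0.6, cart = 0.6),
        cohort_weights = c(studyE = 0.5, studyG = 0.2, studyF = 0.15,
            studyQ = 0.15),
        censor_rate = 0.02,
        seed = seed)
}

#' Validate and assemble a cohort simulation configuration
#'
#' @param n_patients positive patient count
#' @param subtype_weights probability vector over the five latent subtypes,
#'   summing to 1
#' @param block_gene_probs list, subtype -> named vector of per-gene Bernoulli
#'   probabilities applied to carriers of that subtype (overrides background)
#' @param background_gene_probs named vector of per-gene Bernoulli
#'   probabilities applied to every patient
#' @param response_probs list, subtype -> named vector of complete-response
#'   probabilities for therapy lines induction/salvage/cart
#' @param survival_hazards named positive exponential hazards (1/month)
#' @param coo_nongcb_probs per-subtype probability of non-GCB cell of origin
#' @param treated_probs per-line probability that a patient received the line
#' @param cohort_weights sampling weights of the study tags
#' @param censor_rate hazard of independent exponential censoring
#' @param seed integer RNG seed
#' @return validated config (class `cohort_sim_config`)
#' @export
cohortSimulationConfig <- function(n_patients, subtype_weights,
        block_gene_probs, background_gene_probs, response_probs,
        survival_hazards, coo_nongcb_probs, treated_probs, cohort_weights,
        censor_rate, seed) {
    if (length(n_patients) != 1L || is.na(n_patients) || n_patients < 1)
        stop("n_patients must be a positive count")
    if (!setequal(names(subtype_weights), .SUBTYPES))
        stop("subtype_weights must cover exactly: ",
             paste(.SUBTYPES, collapse = ", "))
    if (abs(sum(subtype_weights) - 1) > 1e-12)
        stop("subtype_weights must sum to 1")
    if (!.is_prob(subtype_weights)) stop("subtype weights must be in [0,1]")
    stopifnot(all(names(block_gene_probs) %in% .SUBTYPES))
    for (s in names(block_gene_probs))
        if (length(block_gene_probs[[s]]) && !.is_prob(block_gene_probs[[s]]))
            stop("block gene probabilities must be in [0,1]")
    if (!.is_prob(background_gene_probs))
        stop("background gene probabilities must be in [0,1]")
    for (s in names(response_probs))
        if (!.is_prob(response_probs[[s]]))
            stop("response probabilities must be in [0,1]")
    if (any(survival_hazards <= 0) || censor_rate < 0)
        stop("hazards must be positive")
    cfg <- list(n_patients = as.integer(n_patients),
        subtype_weights = subtype_weights[.SUBTYPES],
        block_gene_probs = block_gene_probs,
        background_gene_probs = background_gene_probs,
        response_probs = response_probs,
        survival_hazards = survival_hazards,
        coo_nongcb_probs = coo_nongcb_probs,
        treated_probs = treated_probs,
        cohort_weights = cohort_weights,
        censor_rate = censor_rate,
        seed = as.integer(seed))
    class(cfg) <- "cohort_sim_config"
    cfg
}

#' Simulate a relapsed/refractory DLBCL-like cohort
#'
#' Each patient draws one latent subtype from the weight vector; gene
#' presence is Bernoulli with the subtype's block probability where defined,
#' the background probability otherwise. Each present gene receives a
#' mutation-type label drawn uniformly from the elementary canonical labels.
#' Therapy responses and exponential survival are drawn per subtype. The
#' latent subtype is returned in the clinical table for recovery tests.
#' Identical seed implies identical output.
#'
#' @param config a config from [cohortSimulationConfig()] /
#'   [defaultCohortConfig()]
#' @return list: `calls` (data.frame patient_id, gene_symbol, mutation_type,
#'   cohort), `clinical` (data.frame patient_id, latent_subtype, coo_subtype,
#'   age_group, induction_cr, salvage_cr, cart_cr, os_months, os_event)
#' @export
simulateCohort <- function(config) {
    if (!inherits(config, "cohort_sim_config"))
        stop("config must come from cohortSimulationConfig()")
    .with_seed(config$seed, {
        n <- config$n_patients
        ids <- sprintf("PT%04d", seq_len(n))
        subtype <- sample(.SUBTYPES, n, replace = TRUE,
            prob = config$subtype_weights)
        genes <- union(names(config$background_gene_probs),
            unlist(lapply(config$block_gene_probs, names)))
        genes <- sort(genes)
        ## per-patient presence probabilities: background, block override
        probs <- matrix(config$background_gene_probs[genes], n,
            length(genes), byrow = TRUE, dimnames = list(ids, genes))
        probs[is.na(probs)] <- 0
        for (s in names(config$block_gene_probs)) {
            bp <- config$block_gene_probs[[s]]
            if (!length(bp)) next
            rows <- subtype == s
            if (any(rows))
                probs[rows, names(bp)] <-
                    matrix(bp, sum(rows), length(bp), byrow = TRUE)
        }
        present <- matrix(stats::runif(length(probs)) < probs, n,
            length(genes), dimnames = list(ids, genes))
        idx <- which(present, arr.ind = TRUE)
        types <- setdiff(canonicalMutationTypes(), "MultipleTypes")
        cohort <- sample(names(config$cohort_weights), n, replace = TRUE,
            prob = config$cohort_weights)
        calls <- data.frame(
            patient_id = ids[idx[, 1L]],
            gene_symbol = genes[idx[, 2L]],
            mutation_type = sample(types, nrow(idx), replace = TRUE),
            cohort = cohort[idx[, 1L]],
            stringsAsFactors = FALSE)
        calls <- calls[order(calls$patient_id, calls$gene_symbol), ]
        rownames(calls) <- NULL
        ## clinical outcomes
        resp <- function(line) {
            treated <- stats::runif(n) < config$treated_probs[[line]]
            p <- vapply(subtype, function(s)
                config$response_probs[[s]][[line]], 0)
            out <- ifelse(stats::runif(n) < p, "yes", "no")
            out[!treated] <- "not_treated"
            out
        }
        induction <- resp("induction")
        salvage <- resp("salvage")
        cart <- resp("cart")
        haz <- config$survival_hazards[subtype]
        tEvent <- stats::rexp(n, haz)
        tCens <- if (config$censor_rate > 0)
            pmin(stats::rexp(n, config$censor_rate), 60) else rep(60, n)
        os <- pmin(tEvent, tCens)
        clinical <- data.frame(
            patient_id = ids,
            latent_subtype = subtype,
            coo_subtype = ifelse(stats::runif(n) <
                config$coo_nongcb_probs[subtype], "nonGCB", "GCB"),
            age_group = sample(c("<60", ">=60"), n, replace = TRUE),
            induction_cr = induction, salvage_cr = salvage, cart_cr = cart,
            os_months = round(pmax(os, 0.01), 3),
            os_event = as.integer(tEvent <= tCens),
            stringsAsFactors = FALSE)
        list(calls = calls, clinical = clinical)
    })
}

#' Build a binary matrix that reproduces printed contingency counts exactly
#'
#' Greedy constructor: each requested gene pair is first assigned its
#' co-mutated patients, then remaining per-gene marginals are filled with
#' patients that do not disturb any requested pair count. Only marginal and
#' pairwise constraints are supported; an infeasible specification raises an
#' error.
#'
#' @param n_patients number of patients
#' @param marginal_counts named integer vector, gene -> mutated patient count
#' @param pair_counts optional data.frame (geneA, geneB, count) of co-mutated
#'   patient counts
#' @return a \linkS4class{BinaryMutationMatrix} whose column sums equal
#'   `marginal_counts` and whose pair overlaps equal `pair_counts`
#' @examples
#' x <- buildFixture(92, c(SOCS1 = 19, STAT6 = 10),
#'     data.frame(geneA = "SOCS1", geneB = "STAT6", count = 8))
#' sum(mutationMatrix(x)[, "SOCS1"] & mutationMatrix(x)[, "STAT6"])  # 8
#' @export
buildFixture <- function(n_patients, marginal_counts, pair_counts = NULL) {
    n <- as.integer(n_patients)
    if (n < 1L) stop("n_patients must be positive")
    if (is.null(names(marginal_counts)) || anyDuplicated(names(marginal_counts)))
        stop("marginal_counts must be uniquely named by gene")
    if (any(marginal_counts < 0) || any(marginal_counts > n))
        stop("marginal counts must lie in [0, n_patients]")
    genes <- names(marginal_counts)
    if (is.null(pair_counts))
        pair_counts <- data.frame(geneA = character(), geneB = character(),
            count = integer(), stringsAsFactors = FALSE)
    if (nrow(pair_counts)) {
        if (!all(c(pair_counts$geneA, pair_counts$geneB) %in% genes))
            stop("pair genes must appear in marginal_counts")
        feas <- pair_counts$count <= pmin(marginal_counts[pair_counts$geneA],
            marginal_counts[pair_counts$geneB])
        if (!all(feas))
            stop("infeasible fixture: pair count exceeds a marginal for ",
                paste(pair_counts$geneA[!feas], pair_counts$geneB[!feas],
                    sep = "-", collapse = ", "))
    }
    m <- matrix(0L, n, length(genes),
        dimnames = list(sprintf("PT%04d", seq_len(n)), genes))
    ## all requested pair overlaps stay at or below target, and no marginal
    ## is exceeded, after a tentative assignment
    constraintsOK <- function() {
        if (any(colSums(m) > marginal_counts[genes])) return(FALSE)
        for (i in seq_len(nrow(pair_counts))) {
            if (sum(m[, pair_counts$geneA[i]] & m[, pair_counts$geneB[i]]) >
                pair_counts$count[i]) return(FALSE)
        }
        TRUE
    }
    trySet <- function(p, gg) {
        gg <- gg[m[p, gg] == 0L]
        if (!length(gg)) return(FALSE)
        m[p, gg] <<- 1L
        if (constraintsOK()) return(TRUE)
        m[p, gg] <<- 0L
        FALSE
    }
    ## phase 1: satisfy pair overlaps greedily (largest overlap first)
    ord <- order(-pair_counts$count, pair_counts$geneA, pair_counts$geneB)
    for (i in ord) {
        a <- pair_counts$geneA[i]; b <- pair_counts$geneB[i]
        need <- pair_counts$count[i] - sum(m[, a] & m[, b])
        p <- 1L
        while (need > 0L && p <= n) {
            if (!(m[p, a] == 1L && m[p, b] == 1L) && trySet(p, c(a, b)))
                need <- need - 1L
            p <- p + 1L
        }
        if (need > 0L)
            stop("infeasible fixture: cannot realize pair ", a, "-", b)
    }
    ## phase 2: fill remaining marginals without disturbing pair targets
    for (g in genes) {
        need <- marginal_counts[[g]] - sum(m[, g])
        if (need < 0L)
            stop("infeasible fixture: pair assignments exceed marginal of ", g)
        p <- 1L
        while (need > 0L && p <= n) {
            if (m[p, g] == 0L && trySet(p, g)) need <- need - 1L
            p <- p + 1L
        }
        if (need > 0L)
            stop("infeasible fixture: cannot realize marginal of ", g)
    }
    ## verification (construction is greedy; never return an inexact matrix)
    if (!all(colSums(m) == marginal_counts[genes]))
        stop("infeasible fixture: marginals not reproduced")
    for (i in seq_len(nrow(pair_counts))) {
        a <- pair_counts$geneA[i]; b <- pair_counts$geneB[i]
        if (sum(m[, a] & m[, b]) != pair_counts$count[i])
            stop("infeasible fixture: pair ", a, "-", b, " not reproduced")
    }
    binaryMutationMatrix(m)
}

#' Simulate an expression matrix with linked survival
#'
#' Stand-in for a whole-genome expression array cohort with follow-up:
#' requested gene pairs are drawn from a standard bivariate normal with the
#' requested correlation, all other genes are independent standard normal,
#' and survival times follow a proportional-hazards link on designated genes.
#'
#' @param n_samples number of samples
#' @param gene_pairs data.frame (geneA, geneB, correlation), |correlation| < 1;
#'   a gene may appear in at most one pair
#' @param extra_genes additional independent genes to include
#' @param survival_link list with `coefs` (named log-hazard-ratio per unit
#'   expression for a subset of genes) and `baseline_hazard` (1/month);
#'   default 0.05 baseline with no covariate effect
#' @param censor_rate exponential censoring hazard (default 0.02, capped at
#'   120 months)
#' @param seed integer RNG seed
#' @return SummarizedExperiment, assay `expression` (genes x samples),
#'   colData os_months/os_event/arm
#' @export
simulateExpression <- function(n_samples, gene_pairs = NULL,
        extra_genes = character(), survival_link = list(coefs = numeric(),
        baseline_hazard = 0.05), censor_rate = 0.02, seed = 1L) {
    if (is.null(gene_pairs))
        gene_pairs <- data.frame(geneA = character(), geneB = character(),
            correlation = numeric(), stringsAsFactors = FALSE)
    if (nrow(gene_pairs) && any(abs(gene_pairs$correlation) >= 1))
        stop("|correlation| must be < 1")
    pg <- c(gene_pairs$geneA, gene_pairs$geneB)
    if (anyDuplicated(pg))
        stop("a gene may appear in at most one pair")
    genes <- unique(c(pg, extra_genes, names(survival_link$coefs)))
    if (!length(genes)) stop("no genes requested")
    .with_seed(seed, {
        n <- as.integer(n_samples)
        expr <- matrix(stats::rnorm(length(genes) * n), length(genes), n,
            dimnames = list(genes, sprintf("S%04d", seq_len(n))))
        for (i in seq_len(nrow(gene_pairs))) {
            rho <- gene_pairs$correlation[i]
            z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
            expr[gene_pairs$geneA[i], ] <- z1
            expr[gene_pairs$geneB[i], ] <- rho * z1 + sqrt(1 - rho^2) * z2
        }
        lp <- rep(0, n)
        if (length(survival_link$coefs))
            lp <- drop(crossprod(
                expr[names(survival_link$coefs), , drop = FALSE],
                survival_link$coefs))
        haz <- survival_link$baseline_hazard * exp(lp)
        tEvent <- stats::rexp(n, haz)
        tCens <- if (censor_rate > 0)
            pmin(stats::rexp(n, censor_rate), 120) else rep(120, n)
        cd <- S4Vectors::DataFrame(
            os_months = pmax(pmin(tEvent, tCens), 0.01),
            os_event = as.integer(tEvent <= tCens),
            arm = sample(c("R-CHOP", "CHOP"), n, replace = TRUE),
            row.names = colnames(expr))
        SummarizedExperiment::SummarizedExperiment(
            assays = list(expression = expr), colData = cd)
    })
}

#' Write simulated cohort tables
#' @param sim output of [simulateCohort()]
#' @param dir output directory (created if needed)
#' @return paths of the written files
#' @export
writeCohortTsv <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    callsPath <- file.path(dir, "mutation_calls.tsv")
    clinPath <- file.path(dir, "clinical.tsv")
    utils::write.table(sim$calls, callsPath, sep = "\t", quote = FALSE,
        row.names = FALSE)
    utils::write.table(sim$clinical, clinPath, sep = "\t", quote = FALSE,
        row.names = FALSE)
    c(calls = callsPath, clinical = clinPath)
}
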