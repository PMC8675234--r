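## Patient-level k-means and gene-level SOM clustering on anchor-gene lift
## profiles, with merging of SOM units into the four mutation Types.

#' K-means clustering of patients on their binary mutation rows
#'
#' Lloyd's algorithm on the 0/1 rows with squared-Euclidean distance, best
#' of `nRestarts` seeded restarts by within-cluster sum of squares. Cluster
#' numbers are canonicalized (decreasing size, ties by the lexicographically
#' first member) so labels are reproducible.
#'
#' @param x a \linkS4class{BinaryMutationMatrix}
#' @param k number of clusters (default 4)
#' @param seed RNG seed
#' @param nRestarts random restarts (default 25)
#' @return list: `labels` (named integer vector), `sizes`, `wcss` (total
#'   within-cluster sum of squares), `centers`, `geneFrequency` (data.frame
#'   cluster, gene, count, proportion)
#' @export
kmeansPatients <- function(x, k = 4L, seed = 1L, nRestarts = 25L) {
    m <- mutationMatrix(x) * 1
    if (nrow(m) == 0L) stop("empty matrix")
    if (k > nrow(m)) stop("k exceeds the number of patients")
    fit <- .with_seed(seed,
        stats::kmeans(m, centers = k, nstart = nRestarts,
            algorithm = "Lloyd", iter.max = 200L))
    ## canonical cluster order: size desc, then first patient name
    sizes <- fit$size
    firstMember <- vapply(seq_len(k), function(cl)
        min(rownames(m)[fit$cluster == cl]), "")
    ord <- order(-sizes, firstMember)
    relabel <- integer(k); relabel[ord] <- seq_len(k)
    labels <- stats::setNames(relabel[fit$cluster], rownames(m))
    centers <- fit$centers[ord, , drop = FALSE]
    rownames(centers) <- seq_len(k)
    gf <- do.call(rbind, lapply(seq_len(k), function(cl) {
        rows <- m[labels == cl, , drop = FALSE]
        data.frame(cluster = cl, gene = colnames(m),
            count = colSums(rows), n = nrow(rows),
            proportion = colMeans(rows),
            stringsAsFactors = FALSE, row.names = NULL)
    }))
    list(labels = labels, sizes = unname(table(labels)),
        wcss = fit$tot.withinss, centers = centers, geneFrequency = gf)
}

#' Anchor-gene lift profiles
#'
#' One feature vector per non-anchor gene: its pairwise lift against each of
#' the anchor genes (default SOCS1, KMT2D, TP53, MYD88 — the high-frequency
#' representatives of the four mutation Types).
#'
#' @param x a \linkS4class{BinaryMutationMatrix}
#' @param anchors anchor genes; all must be present with nonzero frequency
#' @return numeric matrix, non-anchor genes x anchors
#' @export
anchorLiftFeatures <- function(x,
        anchors = c("SOCS1", "KMT2D", "TP53", "MYD88")) {
    m <- mutationMatrix(x) * 1L
    missing <- setdiff(anchors, colnames(m))
    if (length(missing))
        stop("anchor(s) absent from matrix: ", paste(missing, collapse = ", "))
    counts <- colSums(m)
    if (any(counts[anchors] == 0L))
        stop("zero-frequency anchor(s): ",
             paste(anchors[counts[anchors] == 0L], collapse = ", "))
    others <- setdiff(colnames(m)[counts > 0L], anchors)
    lift <- nrow(m) * crossprod(m[, others, drop = FALSE],
        m[, anchors, drop = FALSE]) / outer(counts[others], counts[anchors])
    lift
}

.grid_coords <- function(gridRows, gridCols) {
    ## units numbered left-to-right, then bottom-to-top
    u <- seq_len(gridRows * gridCols)
    cbind(x = (u - 1L) %% gridCols, y = (u - 1L) %/% gridCols)
}

#' Train a self-organizing map on gene lift profiles
#'
#' Online training on a rectangular grid: at each step the best-matching
#' unit (minimum Euclidean distance, ties to the lowest unit index) and all
#' units within the current neighborhood radius are pulled towards the input
#' with Gaussian distance weighting. Training runs in the usual two phases:
#' an ordering phase (first 20% of steps) in which the radius shrinks
#' linearly from `initialRadius` towards zero and the learning rate from
#' `initialLearningRate` to a tenth of it, then a fine-tuning phase in which
#' only the best-matching unit is updated under a linearly vanishing
#' learning rate. Codebook vectors are initialized from sampled inputs.
#'
#' @param features numeric matrix (genes x features), e.g. from
#'   [anchorLiftFeatures()]
#' @param gridRows,gridCols grid dimensions (default 4 x 4 = 16 units)
#' @param epochs training epochs (each epoch presents every input once in a
#'   seeded random order; default 200)
#' @param initialLearningRate starting learning rate (default 0.5)
#' @param initialRadius starting neighborhood radius (default half the larger
#'   grid dimension)
#' @param scale z-score the feature columns before training (default FALSE:
#'   raw lifts)
#' @param seed RNG seed for initialization and presentation order
#' @return a \linkS4class{SOMModel}
#' @export
trainSOM <- function(features, gridRows = 4L, gridCols = 4L, epochs = 200L,
        initialLearningRate = 0.5, initialRadius = NULL, scale = FALSE,
        seed = 1L) {
    features <- as.matrix(features)
    if (nrow(features) < 1L || ncol(features) < 1L)
        stop("need at least one feature vector with positive dimension")
    stopifnot(gridRows >= 1L, gridCols >= 1L, epochs >= 1L,
        initialLearningRate >= 0)
    if (scale) {
        sds <- apply(features, 2L, stats::sd)
        sds[sds == 0] <- 1
        features <- sweep(sweep(features, 2L, colMeans(features)), 2L, sds, "/")
    }
    nUnits <- gridRows * gridCols
    coords <- .grid_coords(gridRows, gridCols)
    gridDist <- as.matrix(stats::dist(coords))
    if (is.null(initialRadius)) initialRadius <- max(gridRows, gridCols) / 2
    nIn <- nrow(features)
    model <- .with_seed(seed, {
        codebook <- features[sample.int(nIn, nUnits, replace = TRUE), ,
            drop = FALSE]
        rownames(codebook) <- seq_len(nUnits)
        tTotal <- epochs * nIn
        tOrder <- max(1, round(0.2 * tTotal))  # ordering phase length
        t <- 0L
        for (e in seq_len(epochs)) {
            for (i in sample.int(nIn)) {
                if (t < tOrder) {
                    frac <- t / tOrder
                    lr <- initialLearningRate * (1 - 0.9 * frac)
                    sigma <- max(initialRadius * (1 - frac), 1e-3)
                } else {
                    frac <- (t - tOrder) / max(tTotal - tOrder, 1)
                    lr <- 0.1 * initialLearningRate * (1 - frac)
                    sigma <- 1e-3  # fine-tuning: BMU-only updates
                }
                xvec <- features[i, ]
                d2 <- rowSums(sweep(codebook, 2L, xvec)^2)
                bmu <- which.min(d2)  # ties to lowest index
                inRad <- which(gridDist[bmu, ] <= sigma)
                w <- lr * exp(-gridDist[bmu, inRad]^2 / (2 * sigma^2))
                codebook[inRad, ] <- codebook[inRad, , drop = FALSE] +
                    w * sweep(-codebook[inRad, , drop = FALSE], 2L, xvec, "+")
                t <- t + 1L
            }
        }
        codebook
    })
    ## final BMU assignment and quality
    assignment <- integer(nIn)
    dists <- numeric(nIn)
    for (i in seq_len(nIn)) {
        d2 <- rowSums(sweep(model, 2L, features[i, ])^2)
        assignment[i] <- which.min(d2)
        dists[i] <- sqrt(d2[assignment[i]])
    }
    names(assignment) <- rownames(features)
    new("SOMModel", codebook = model, gridRows = as.integer(gridRows),
        gridCols = as.integer(gridCols), assignment = assignment,
        quality = mean(dists),
        schedule = list(epochs = as.integer(epochs),
            initialLearningRate = initialLearningRate,
            initialRadius = initialRadius, scale = scale),
        seed = as.integer(seed))
}

## mean distance of inputs to their BMUs for an arbitrary codebook
.bmu_quality <- function(codebook, features) {
    mean(vapply(seq_len(nrow(features)), function(i)
        sqrt(min(rowSums(sweep(codebook, 2L, features[i, ])^2))), 0))
}

#' Merge SOM units into named mutation Types
#'
#' @param model a \linkS4class{SOMModel} (or a named gene -> unit integer
#'   vector)
#' @param spec named list, Type -> integer vector of unit indices; unit sets
#'   must be disjoint
#' @return list: `types` (Type -> gene character vector), `unassigned`
#'   (genes in unlisted units)
#' @export
mergeUnitsToTypes <- function(model, spec) {
    assignment <- if (is(model, "SOMModel")) unitAssignments(model) else model
    units <- unlist(spec, use.names = FALSE)
    if (anyDuplicated(units))
        stop("overlapping unit sets: unit(s) ",
             paste(unique(units[duplicated(units)]), collapse = ", "),
             " claimed by more than one Type")
    if (is(model, "SOMModel") &&
        length(units) && (min(units) < 1L ||
        max(units) > model@gridRows * model@gridCols))
        stop("unit index outside the grid")
    types <- lapply(spec, function(uu)
        sort(names(assignment)[assignment %in% uu]))
    list(types = types,
        unassigned = sort(names(assignment)[!assignment %in% units]))
}
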