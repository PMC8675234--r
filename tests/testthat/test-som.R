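test_that("k-means separates duplicated row groups perfectly", {
    rowA <- c(1L, 1L, 0L, 0L, 0L)
    rowB <- c(0L, 0L, 1L, 1L, 1L)
    m <- rbind(matrix(rowA, 10, 5, byrow = TRUE),
               matrix(rowB, 8, 5, byrow = TRUE))
    dimnames(m) <- list(sprintf("P%02d", 1:18), sprintf("G%d", 1:5))
    x <- binaryMutationMatrix(m)
    km <- kmeansPatients(x, k = 2, seed = 1)
    expect_equal(km$wcss, 0)
    expect_equal(unname(km$labels[1:10]), rep(1L, 10))  # larger cluster first
    expect_equal(unname(km$labels[11:18]), rep(2L, 8))
    ## k = 1: centroid is the column means
    km1 <- kmeansPatients(x, k = 1, seed = 1)
    expect_equal(unname(km1$centers[1, ]), unname(colMeans(m)))
    expect_error(kmeansPatients(x, k = 50), "exceeds")
})

test_that("k-means is deterministic under a fixed seed and reports per-cluster frequencies", {
    ## planted: 25 patients share a signature, 19 of them carry KMT2D
    m <- matrix(0L, 55, 8, dimnames = list(sprintf("P%02d", 1:55),
        c("SIG1", "SIG2", "SIG3", "KMT2D", "ALT1", "ALT2", "ALT3", "TTN")))
    m[1:25, c("SIG1", "SIG2", "SIG3")] <- 1L
    m[1:19, "KMT2D"] <- 1L
    m[26:55, c("ALT1", "ALT2", "ALT3")] <- 1L
    x <- binaryMutationMatrix(m)
    km <- kmeansPatients(x, k = 2, seed = 5)
    km2 <- kmeansPatients(x, k = 2, seed = 5)
    expect_identical(km$labels, km2$labels)
    ## best-of-restarts never loses to a random partition of the rows
    set.seed(99)
    for (i in 1:5) {
        part <- sample(1:2, nrow(m), replace = TRUE)
        wcssRand <- sum(vapply(1:2, function(cl) {
            rows <- m[part == cl, , drop = FALSE]
            if (!nrow(rows)) return(0)
            sum(sweep(rows, 2, colMeans(rows))^2)
        }, 0))
        expect_lte(km$wcss, wcssRand)
    }
    ## the 25-patient cluster reports KMT2D at 19/25 = 0.76
    cl <- unname(km$labels["P01"])
    gf <- km$geneFrequency
    expect_equal(gf$proportion[gf$cluster == cl & gf$gene == "KMT2D"], 0.76)
    expect_equal(gf$count[gf$cluster == cl & gf$gene == "KMT2D"], 19)
})

test_that("anchor lift profiles match closed forms and a recount", {
    ## gene exactly independent of an anchor: lift 1
    m <- matrix(0L, 20, 3, dimnames = list(sprintf("P%02d", 1:20),
        c("ANCH", "IND", "TWIN")))
    m[1:10, "ANCH"] <- 1L
    m[c(1:5, 11:15), "IND"] <- 1L
    m[1:10, "TWIN"] <- 1L            # perfectly co-occurring, f = 0.5
    x <- binaryMutationMatrix(m)
    f <- anchorLiftFeatures(x, anchors = "ANCH")
    expect_equal(f["IND", "ANCH"], 1.0)
    expect_equal(f["TWIN", "ANCH"], 2.0)  # 1 / f
    ## random matrix against direct recount
    mr <- randBinaryMatrix(40, 6, seed = 3, p = 0.5)
    xr <- binaryMutationMatrix(mr)
    fr <- anchorLiftFeatures(xr, anchors = c("G01", "G02"))
    for (g in rownames(fr)) for (a in c("G01", "G02"))
        expect_equal(fr[g, a],
            40 * sum(mr[, g] & mr[, a]) / (sum(mr[, g]) * sum(mr[, a])),
            tolerance = 1e-12)
    expect_error(anchorLiftFeatures(x, anchors = "NOPE"), "absent")
    mz <- cbind(mr, DEAD = 0L)
    expect_error(anchorLiftFeatures(binaryMutationMatrix(mz),
        anchors = "DEAD"), "zero-frequency")
})

test_that("SOM training fixed points and schedules behave", {
    set.seed(42)
    f <- matrix(rnorm(80), 40, 2, dimnames = list(paste0("g", 1:40), NULL))
    ## zero learning rate: codebook stays at its initialization
    som0 <- trainSOM(f, 2, 2, epochs = 5, initialLearningRate = 0, seed = 1)
    set.seed(1)
    init <- f[sample.int(40, 4, replace = TRUE), , drop = FALSE]
    expect_equal(unname(codebook(som0)), unname(init))
    ## single input on a 1x1 grid converges to that vector
    s1 <- trainSOM(matrix(c(3, 4), 1, 2,
        dimnames = list("g1", NULL)), 1, 1, epochs = 50, seed = 1)
    expect_equal(unname(codebook(s1)[1, ]), c(3, 4), tolerance = 1e-6)
    expect_equal(mapQuality(s1), 0, tolerance = 1e-6)
    ## determinism
    sA <- trainSOM(f, 2, 2, epochs = 20, seed = 7)
    sB <- trainSOM(f, 2, 2, epochs = 20, seed = 7)
    expect_identical(codebook(sA), codebook(sB))
    expect_identical(unitAssignments(sA), unitAssignments(sB))
})

test_that("a 2x1 SOM recovers two well-separated cluster means", {
    set.seed(42)
    c1 <- matrix(rnorm(40, 0, 0.05), 20, 2)
    c2 <- matrix(rnorm(40, 5, 0.05), 20, 2)
    f <- rbind(c1, c2); rownames(f) <- paste0("g", 1:40)
    som <- trainSOM(f, gridRows = 1, gridCols = 2, epochs = 200, seed = 3)
    cb <- codebook(som)
    m1 <- colMeans(c1); m2 <- colMeans(c2)
    err <- min(max(abs(cb[1, ] - m1), abs(cb[2, ] - m2)),
               max(abs(cb[1, ] - m2), abs(cb[2, ] - m1)))
    expect_lt(err, 0.1)
})

test_that("training improves map quality on planted clusters", {
    ok <- 0L
    for (seed in 1:20) {
        set.seed(seed + 500)
        f <- rbind(matrix(rnorm(30, 0, 0.3), 15, 2),
                   matrix(rnorm(30, 4, 0.3), 15, 2))
        rownames(f) <- paste0("g", 1:30)
        som <- trainSOM(f, 2, 2, epochs = 50, seed = seed)
        set.seed(seed)
        init <- f[sample.int(30, 4, replace = TRUE), , drop = FALSE]
        qInit <- lymphomine:::.bmu_quality(init, f)
        if (mapQuality(som) <= qInit + 1e-9) ok <- ok + 1L
    }
    expect_gte(ok, 18L)
})

test_that("unit merging unions genes and rejects overlapping specs", {
    assignment <- c(SOCS1 = 3L, STAT6 = 3L, B2M = 8L, KMT2D = 16L,
        TP53 = 12L)
    res <- mergeUnitsToTypes(assignment,
        list(Type1 = c(3L, 4L, 8L), Type4 = 12L))
    expect_setequal(res$types$Type1, c("SOCS1", "STAT6", "B2M"))
    expect_equal(res$types$Type4, "TP53")
    expect_equal(res$unassigned, "KMT2D")
    empty <- mergeUnitsToTypes(assignment, list())
    expect_setequal(empty$unassigned, names(assignment))
    expect_error(mergeUnitsToTypes(assignment,
        list(Type1 = c(3L, 8L), Type2 = c(8L))), "overlapping")
})

test_that("planted blocks land on distinct SOM units", {
    sim <- simulateCohort(defaultCohortConfig(96, seed = 33))
    x <- buildBinaryMatrix(sim$calls)
    f <- anchorLiftFeatures(x)
    blocks <- plantedBlocks()[c("JAKSTAT", "EZB", "MCD")]
    genes <- intersect(unlist(blocks), rownames(f))
    som <- trainSOM(f[genes, ], seed = 33)
    a <- unitAssignments(som)
    maj <- vapply(blocks, function(gg) {
        gg <- intersect(gg, names(a))
        as.integer(names(sort(table(a[gg]), decreasing = TRUE))[1L])
    }, 0L)
    expect_equal(length(unique(maj)), length(maj))
})
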