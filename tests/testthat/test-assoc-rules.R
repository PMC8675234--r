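test_that("trivial itemset boundaries behave", {
    m <- randBinaryMatrix(20, 5, seed = 1, p = 0.4)
    m[, "G01"] <- 1L
    x <- binaryMutationMatrix(m)
    its <- mineFrequentItemsets(x, 0.5)
    expect_true("G01" %in% its$itemset)
    expect_equal(its$support[its$itemset == "G01"], 1.0)
    ## min_support above the max single-gene frequency: nothing survives
    its2 <- mineFrequentItemsets(binaryMutationMatrix(
        randBinaryMatrix(20, 5, seed = 2, p = 0.2)), 0.99)
    expect_equal(nrow(its2), 0L)
    expect_error(mineFrequentItemsets(x, 0), "minSupport > 0")
})

test_that("apriori equals brute-force enumeration on random matrices", {
    for (seed in 1:5) {
        m <- randBinaryMatrix(30, 10, seed = seed, p = 0.35)
        x <- binaryMutationMatrix(m)
        got <- mineFrequentItemsets(x, 0.2)
        want <- bruteItemsets(m, 0.2)
        expect_equal(got$itemset, want$itemset)
        expect_equal(got$count, want$count)
        ## downward closure on the mined output
        for (s in got$itemset[got$size > 1L]) {
            gg <- strsplit(s, "/", fixed = TRUE)[[1L]]
            for (i in seq_along(gg))
                expect_true(paste(sort(gg[-i]), collapse = "/") %in%
                    got$itemset)
        }
        ## rules too
        rGot <- rules(generateRules(got, minConfidence = 0.3,
            maxAntecedentSize = 10L))
        rGot <- rGot[order(rGot$antecedent, rGot$consequent), ]
        rWant <- bruteRules(m, 0.2, 0.3)
        expect_equal(rGot$antecedent, rWant$antecedent)
        expect_equal(rGot$consequent, rWant$consequent)
        expect_equal(rGot$confidence, rWant$confidence, tolerance = 1e-12)
        expect_equal(rGot$lift, rWant$lift, tolerance = 1e-12)
    }
})

test_that("rule statistics reproduce printed contingency arithmetic", {
    ## 19 SOCS1 carriers of 92, 8 of whom also carry STAT6
    x <- buildFixture(92, c(SOCS1 = 19, STAT6 = 10),
        data.frame(geneA = "SOCS1", geneB = "STAT6", count = 8))
    rs <- rules(generateRules(mineFrequentItemsets(x, 0.01), 0.01))
    r <- rs[rs$antecedent == "SOCS1" & rs$consequent == "STAT6", ]
    expect_equal(r$confidence, 8 / 19, tolerance = 1e-12)
    expect_equal(r$lift, (8 / 19) / (10 / 92), tolerance = 1e-12)
})

test_that("independent genes have lift exactly 1", {
    ## support(A & B) = support(A) * support(B) by construction:
    ## A in rows 1..10, B in rows 1..5 and 11..15 of 20 -> overlap 5/20 = (10/20)*(10/20)*20
    m <- matrix(0L, 20, 2, dimnames = list(sprintf("P%02d", 1:20), c("A", "B")))
    m[1:10, "A"] <- 1L
    m[c(1:5, 11:15), "B"] <- 1L
    x <- binaryMutationMatrix(m)
    rs <- rules(generateRules(mineFrequentItemsets(x, 0.1), 0.1))
    expect_equal(rs$lift[rs$antecedent == "A" & rs$consequent == "B"], 1.0)
    L <- pairwiseLiftMatrix(x)
    expect_equal(L["A", "B"], 1.0)
})

test_that("pairwise lift matrix matches closed forms and a recount oracle", {
    m <- matrix(0L, 10, 2, dimnames = list(sprintf("P%02d", 1:10), c("A", "B")))
    m[1:5, ] <- 1L  # always co-occurring, each frequency 0.5
    L <- pairwiseLiftMatrix(binaryMutationMatrix(m))
    expect_equal(L["A", "B"], 2.0)
    expect_equal(L["A", "A"], 2.0)   # diagonal n / count
    ## diagonal closed form at 23 of 92
    x92 <- buildFixture(92, c(G = 23))
    expect_equal(pairwiseLiftMatrix(x92)["G", "G"], 4.0)
    ## random matrix vs direct recount
    mr <- randBinaryMatrix(40, 8, seed = 7, p = 0.4)
    Lr <- pairwiseLiftMatrix(binaryMutationMatrix(mr))
    for (i in 1:8) for (j in 1:8) {
        expect_equal(Lr[i, j],
            40 * sum(mr[, i] & mr[, j]) / (sum(mr[, i]) * sum(mr[, j])),
            tolerance = 1e-12)
    }
    expect_true(isSymmetric(unname(Lr)))
    ## zero-frequency gene is named in the error
    mz <- cbind(mr, ZERO = 0L)
    expect_error(pairwiseLiftMatrix(binaryMutationMatrix(mz)), "ZERO")
})

test_that("top-k rule graph selects by lift with deterministic ties", {
    m <- randBinaryMatrix(40, 8, seed = 9, p = 0.35)
    rs <- generateRules(mineFrequentItemsets(binaryMutationMatrix(m), 0.1),
        0.1)
    g0 <- topRulesGraph(rs, k = 0)
    expect_equal(igraph::ecount(g0), 0)
    r <- rules(rs)
    k <- min(5L, nrow(r))
    g <- topRulesGraph(rs, k = k)
    ## single-gene antecedents here: one edge per rule
    kept <- r[order(-r$lift, -r$support,
        paste(r$antecedent, r$consequent, sep = "=>")), ][seq_len(k), ]
    expect_equal(sort(unique(igraph::E(g)$rule)),
        sort(paste(kept$antecedent, kept$consequent, sep = "=>")))
    ## in-degree attribute counts retained rules per consequent
    deg <- table(kept$consequent)
    for (gene in names(deg))
        expect_equal(
            igraph::V(g)$inDegreeRules[igraph::V(g)$name == gene],
            as.integer(deg[[gene]]))
    ## exports are well-formed text
    gml <- tempfile(fileext = ".graphml"); gexf <- tempfile(fileext = ".gexf")
    writeRuleGraph(g, gml, "graphml")
    writeRuleGraph(g, gexf, "gexf")
    expect_true(any(grepl("graphml", readLines(gml))))
    expect_true(any(grepl("<gexf", readLines(gexf))))
    expect_no_error(xml2::read_xml(gexf))
})

test_that("single-antecedent lift is symmetric in the rule table", {
    m <- randBinaryMatrix(50, 6, seed = 10, p = 0.4)
    rs <- rules(generateRules(
        mineFrequentItemsets(binaryMutationMatrix(m), 0.1),
        minConfidence = 0, maxAntecedentSize = 1L))
    for (i in seq_len(nrow(rs))) {
        rev <- rs[rs$antecedent == rs$consequent[i] &
                  rs$consequent == rs$antecedent[i], ]
        expect_equal(rev$lift, rs$lift[i], tolerance = 1e-12)
    }
})

test_that("planted blocks show higher within- than between-block lift", {
    sim <- simulateCohort(defaultCohortConfig(96, seed = 21))
    x <- buildBinaryMatrix(sim$calls)
    blocks <- plantedBlocks()[c("JAKSTAT", "EZB", "MCD")]
    genes <- intersect(unlist(blocks), geneNames(x))
    L <- pairwiseLiftMatrix(x, genes)
    lab <- rep(names(blocks), lengths(blocks))[match(genes, unlist(blocks))]
    same <- outer(lab, lab, "==")
    ut <- upper.tri(L)
    expect_gt(mean(L[ut & same]), mean(L[ut & !same]))
})
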