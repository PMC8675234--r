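test_that("mutation-type standardization maps synonyms and rejects strays", {
    expect_equal(standardizeMutationType("Missense_Mutation"), "MissenseSNV")
    expect_equal(standardizeMutationType("Nonsense_Mutation"), "TruncatingSNV")
    expect_equal(standardizeMutationType("Frame_Shift_Del"), "Indel")
    expect_equal(standardizeMutationType("splice site"), "SpliceSiteSNV")
    expect_equal(standardizeMutationType("Silent"), "SynonymousSNV")
    expect_equal(standardizeMutationType("Truncating SNV"), "TruncatingSNV")
    expect_error(standardizeMutationType("weird_label"), "weird_label")
    expect_error(standardizeMutationType(""), "empty")
})

test_that("gene symbols are uppercased and de-aliased", {
    expect_equal(normalizeGeneSymbol(c("mll2", "Socs1", "TP53")),
        c("KMT2D", "SOCS1", "TP53"))
})

test_that("binarization collapses repeat calls and logs MultipleTypes", {
    one <- data.frame(patient_id = "P1", gene_symbol = "TP53",
        mutation_type = "MissenseSNV", cohort = "s1")
    x <- buildBinaryMatrix(one)
    expect_equal(dim(mutationMatrix(x)), c(1L, 1L))
    expect_true(mutationMatrix(x)[1, 1])

    two <- rbind(one, data.frame(patient_id = "P1", gene_symbol = "TP53",
        mutation_type = "Indel", cohort = "s1"))
    x2 <- buildBinaryMatrix(two)
    expect_equal(sum(mutationMatrix(x2)), 1L)
    log2 <- S4Vectors::metadata(x2)$callLog
    expect_equal(log2$mutation_type, "MultipleTypes")

    ## idempotent under call duplication
    x3 <- buildBinaryMatrix(rbind(two, two))
    expect_identical(mutationMatrix(x3), mutationMatrix(x2))
    expect_error(buildBinaryMatrix(one[0, ]), "empty")
})

test_that("a 92-patient / 256-gene call set yields a 92 x 256 matrix", {
    patients <- sprintf("P%02d", 1:92)
    genes <- sprintf("G%03d", 1:256)
    calls <- data.frame(
        patient_id = rep(patients, length.out = 300),
        gene_symbol = c(genes, sample(genes, 44, replace = TRUE)),
        mutation_type = "MissenseSNV", cohort = "s1")
    x <- buildBinaryMatrix(calls)
    expect_equal(dim(mutationMatrix(x)), c(92L, 256L))
})

test_that("fisherExact2x2 matches trivial closed forms and the oracle", {
    expect_equal(fisherExact2x2(matrix(c(5, 5, 5, 5), 2)), 1.0)
    expect_equal(fisherExact2x2(matrix(c(0, 0, 10, 10), 2)), 1.0)
    expect_equal(fisherExact2x2(matrix(c(8, 1, 2, 9), 2)),
        fisherEnumOracle(8, 2, 1, 9), tolerance = 1e-12)
    expect_error(fisherExact2x2(matrix(c(-1, 1, 1, 1), 2)), "negative")
})

test_that("fisherExact2x2 equals the enumeration oracle exhaustively (margins <= 8)", {
    for (a in 0:8) for (b in 0:(8 - a)) for (c in 0:8) for (d in 0:(8 - c)) {
        if (a + b + c + d == 0) next
        expect_equal(fisherExact2x2(matrix(c(a, c, b, d), 2)),
            fisherEnumOracle(a, b, c, d), tolerance = 1e-12)
    }
})

test_that("concordance filter excludes discordant genes only", {
    m <- matrix(0L, 92, 3, dimnames = list(sprintf("P%02d", 1:92),
        c("EVEN", "SKEW", "RARE")))
    grp <- rep(c("A", "B"), c(47, 45))
    m[c(1:10, 48:57), "EVEN"] <- 1L          # 10/47 vs 10/45
    m[1:20, "SKEW"] <- 1L                    # 20/47 vs 0/45
    m[c(1, 48), "RARE"] <- 1L
    x <- binaryMutationMatrix(m, group = grp)
    res <- concordanceFilter(x, alpha = 0.001)
    expect_true("EVEN" %in% res$retained)
    expect_true("RARE" %in% res$retained)
    expect_false("SKEW" %in% res$retained)
    expect_equal(res$report$p[res$report$gene == "SKEW"],
        fisherEnumOracle(20, 27, 0, 45), tolerance = 1e-12)
    ## alpha = 0 retains everything
    expect_setequal(concordanceFilter(x, alpha = 0)$retained,
        c("EVEN", "SKEW", "RARE"))
    expect_error(concordanceFilter(binaryMutationMatrix(m)), "group_split")
})

test_that("frequency filter requires the threshold in cohort AND larger group", {
    m <- matrix(0L, 92, 3, dimnames = list(sprintf("P%02d", 1:92),
        c("TTN", "LOW", "ONESIDED")))
    grp <- rep(c("A", "B"), c(47, 45))
    m[c(1:16, 48:65), "TTN"] <- 1L       # 34/92 whole, 16/47 larger
    m[1:2, "LOW"] <- 1L                  # 2/92 = 0.022
    m[48:57, "ONESIDED"] <- 1L           # 10/92 whole but 0/47 in larger
    x <- binaryMutationMatrix(m, group = grp)
    larger <- sprintf("P%02d", 1:47)
    res <- frequencyFilter(x, 0.03, larger)
    expect_true("TTN" %in% res$retained)
    expect_false("LOW" %in% res$retained)
    expect_false("ONESIDED" %in% res$retained)
    expect_setequal(frequencyFilter(x, 0, larger)$retained,
        colnames(m))
    expect_error(frequencyFilter(x, 0.03, c("NOPE")), "unknown")
})

test_that("the two filters are order-independent per-gene predicates", {
    set.seed(12)
    m <- randBinaryMatrix(60, 15, seed = 12, p = 0.15)
    x <- binaryMutationMatrix(m, group = rep(c("A", "B"), 30))
    conc <- concordanceFilter(x, alpha = 0.05)$retained
    freq <- frequencyFilter(x, 0.1)$retained
    ## both orders reduce to the same intersection
    expect_setequal(intersect(conc, freq), intersect(freq, conc))
    x1 <- x[intersect(conc, freq), ]
    expect_equal(sort(rownames(x1)), sort(intersect(conc, freq)))
})

test_that("harmonizeCohort splits on the largest study and filters", {
    sim <- simulateCohort(defaultCohortConfig(96, seed = 3))
    h <- harmonizeCohort(sim$calls)
    expect_s4_class(h$matrix, "BinaryMutationMatrix")
    expect_true(all(geneFrequency(h$matrix) >= 0.03))
    expect_equal(sort(unique(unname(h$groups))),
        c("largest_study", "rest"))
    ## round-trip through TSV
    path <- tempfile(fileext = ".tsv")
    writeBinaryMatrixTsv(h$matrix, path)
    back <- readBinaryMatrixTsv(path)
    expect_identical(mutationMatrix(back), mutationMatrix(h$matrix))
    expect_identical(groupSplit(back), groupSplit(h$matrix))
})

test_that("MAF-format reader maps columns through standardization", {
    path <- tempfile(fileext = ".maf")
    writeLines(c("Hugo_Symbol\tTumor_Sample_Barcode\tVariant_Classification",
        "mll2\tS1\tMissense_Mutation",
        "TP53\tS2\tNonsense_Mutation"), path)
    calls <- readMutationCalls(path, format = "maf", cohort = "studyX")
    expect_equal(calls$gene_symbol, c("KMT2D", "TP53"))
    expect_equal(calls$mutation_type, c("MissenseSNV", "TruncatingSNV"))
    expect_equal(unique(calls$cohort), "studyX")
})
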