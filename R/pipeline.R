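## Configuration-driven orchestration of the full analysis chain with a
## reproducibility manifest.

#' Default pipeline configuration
#'
#' A flat list of every stage parameter. `input` is either
#' `list(simulate = TRUE)` (default: run on a synthetic cohort) or
#' `list(calls = <tsv>, clinical = <tsv>)` pointing at call/clinical tables.
#'
#' @param outputDir where stage artifacts are written
#' @param seed master seed (also used for the simulated cohort)
#' @return config list
#' @export
defaultPipelineConfig <- function(outputDir = tempfile("lymphomine_run_"),
                                  seed = 20210677L) {
    list(
        input = list(simulate = TRUE),
        n_patients = 96L,
        alpha = 0.001,
        min_freq = 0.03,
        exclude_synonymous = FALSE,
        min_support = 0.03,
        min_confidence = 0.1,
        max_antecedent_size = 2L,
        top_k_rules = 300L,
        kmeans_k = 4L,
        kmeans_restarts = 25L,
        som_grid = c(4L, 4L),
        som_epochs = 200L,
        som_learning_rate = 0.5,
        anchors = c("SOCS1", "KMT2D", "TP53", "MYD88"),
        classifier_mode = "basic",
        seed = as.integer(seed),
        output_dir = outputDir)
}

#' Validate a pipeline configuration
#' @param config a config list (see [defaultPipelineConfig()])
#' @return the config, invisibly, or an error before any stage runs
#' @export
validatePipelineConfig <- function(config) {
    chk <- function(ok, what) if (!ok) stop("invalid config: ", what)
    chk(is.list(config$input), "input must be a list")
    chk(config$alpha >= 0 && config$alpha <= 1, "alpha must be in [0,1]")
    chk(config$min_freq >= 0 && config$min_freq <= 1,
        "min_freq must be in [0,1]")
    chk(config$min_support > 0 && config$min_support <= 1,
        "min_support must be in (0,1]")
    chk(config$min_confidence >= 0 && config$min_confidence <= 1,
        "min_confidence must be in [0,1]")
    chk(config$top_k_rules >= 0, "top_k_rules must be non-negative")
    chk(config$kmeans_k >= 1, "kmeans_k must be positive")
    chk(all(config$som_grid >= 1), "som_grid must be positive")
    chk(config$classifier_mode %in% c("basic", "extended"),
        "classifier_mode must be basic or extended")
    chk(is.numeric(config$seed), "seed required")
    invisible(config)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys as in [defaultPipelineConfig()] (missing keys
#'   take their defaults)
#' @return validated config list
#' @export
readPipelineConfig <- function(path) {
    user <- yaml::read_yaml(path)
    config <- defaultPipelineConfig()
    config[names(user)] <- user
    validatePipelineConfig(config)
    config
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Stages: simulate/ingest -> harmonize (binarize, two-group split,
#' concordance + frequency filters) -> mine (itemsets, rules, lift matrix,
#' top-k rule graph) -> cluster (patient k-means, anchor-lift SOM) ->
#' classify (five-subtype assignment, composition) -> stats (response
#' tables, subtype survival). Every intermediate artifact is written under
#' `config$output_dir` and a manifest (parameters, seeds, file digests) is
#' emitted; identical config implies byte-identical outputs.
#'
#' @param config pipeline configuration (see [defaultPipelineConfig()])
#' @return invisible list of in-memory stage results plus `manifest`
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
    validatePipelineConfig(config)
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(...) file.path(config$output_dir, ...)

    sim <- NULL
    if (isTRUE(config$input$simulate)) {
        sim <- .stage("simulate", {
            cfg <- defaultCohortConfig(n_patients = config$n_patients,
                seed = config$seed)
            s <- simulateCohort(cfg)
            writeCohortTsv(s, config$output_dir)
            s
        })
        calls <- sim$calls
        clinical <- sim$clinical
    } else {
        calls <- .stage("ingest", readMutationCalls(config$input$calls))
        clinical <- .stage("ingest", readClinicalTsv(config$input$clinical))
    }

    harm <- .stage("harmonize", {
        h <- harmonizeCohort(calls, alpha = config$alpha,
            minFreq = config$min_freq,
            excludeSynonymous = config$exclude_synonymous)
        writeBinaryMatrixTsv(h$matrix, out("binary_matrix.tsv"))
        utils::write.table(h$report, out("filter_report.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
        h
    })
    x <- harm$matrix

    mined <- .stage("mine", {
        itemsets <- mineFrequentItemsets(x, minSupport = config$min_support)
        ruleSet <- generateRules(itemsets,
            minConfidence = config$min_confidence,
            maxAntecedentSize = config$max_antecedent_size)
        writeRulesTsv(ruleSet, out("rules.tsv"))
        graph <- topRulesGraph(ruleSet, k = config$top_k_rules)
        if (igraph::vcount(graph) > 0) {
            writeRuleGraph(graph, out("rule_graph.graphml"), "graphml")
            writeRuleGraph(graph, out("rule_graph.gexf"), "gexf")
        }
        lift <- pairwiseLiftMatrix(x)
        utils::write.table(
            data.frame(gene = rownames(lift), lift, check.names = FALSE),
            out("lift_matrix.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
        list(itemsets = itemsets, rules = ruleSet, graph = graph,
            lift = lift)
    })

    clusters <- .stage("cluster", {
        km <- kmeansPatients(x, k = config$kmeans_k, seed = config$seed,
            nRestarts = config$kmeans_restarts)
        utils::write.table(
            data.frame(patient_id = names(km$labels), cluster = km$labels),
            out("kmeans_labels.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
        utils::write.table(km$geneFrequency, out("kmeans_gene_frequency.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
        anchors <- intersect(config$anchors, geneNames(x))
        som <- NULL
        if (length(anchors) >= 2L) {
            feats <- anchorLiftFeatures(x, anchors)
            som <- trainSOM(feats, gridRows = config$som_grid[1L],
                gridCols = config$som_grid[2L], epochs = config$som_epochs,
                initialLearningRate = config$som_learning_rate,
                seed = config$seed)
            utils::write.table(data.frame(gene = names(unitAssignments(som)),
                unit = unitAssignments(som)), out("som_assignment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
            utils::write.table(data.frame(unit = seq_len(nrow(codebook(som))),
                codebook(som), check.names = FALSE), out("som_codebook.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
            jsonlite::write_json(list(grid = config$som_grid,
                quality = mapQuality(som),
                units = lapply(seq_len(nrow(codebook(som))), function(u)
                    names(unitAssignments(som))[unitAssignments(som) == u])),
                out("som_summary.json"), auto_unbox = TRUE, digits = NA)
        }
        list(kmeans = km, som = som, anchors = anchors)
    })

    classified <- .stage("classify", {
        ## classification reads the unfiltered profile: the grouping rules
        ## name specific genes, which must not be lost to frequency filtering
        full <- buildBinaryMatrix(calls,
            excludeSynonymous = config$exclude_synonymous)
        asg <- assignSubtypes(full, mode = config$classifier_mode)
        utils::write.table(as.data.frame(asg), out("subtype_assignments.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
        comp <- cohortComposition(asg, clinical)
        utils::write.table(comp$groups, out("subtype_composition.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(list(groups = comp$groups,
            primary = comp$primary,
            overlap = as.data.frame(comp$overlap)),
            out("subtype_composition.json"), auto_unbox = TRUE, digits = NA)
        list(assignments = asg, composition = comp)
    })

    statsOut <- .stage("stats", {
        resp <- lapply(c("induction", "salvage", "cart"), function(line)
            responseRateTable(classified$assignments, clinical, line))
        names(resp) <- c("induction", "salvage", "cart")
        for (line in names(resp))
            utils::write.table(resp[[line]],
                out(sprintf("response_%s.tsv", line)), sep = "\t",
                quote = FALSE, row.names = FALSE)
        surv <- subtypeSurvivalReport(classified$assignments, clinical)
        utils::write.table(surv$tests, out("survival_tests.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
        utils::write.table(surv$km, out("km_coordinates.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
        list(response = resp, survival = surv)
    })

    files <- sort(setdiff(list.files(config$output_dir), "manifest.json"))
    manifest <- list(
        package = "lymphomine",
        package_version = as.character(utils::packageVersion("lymphomine")),
        r_version = paste(R.version$major, R.version$minor, sep = "."),
        seed = config$seed,
        parameters = config[setdiff(names(config), c("input", "output_dir"))],
        files = as.list(stats::setNames(
            unname(tools::md5sum(file.path(config$output_dir, files))),
            files)))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
        digits = NA, pretty = TRUE)
    invisible(list(simulation = sim, harmonized = harm, mined = mined,
        clusters = clusters, classified = classified, stats = statsOut,
        manifest = manifest))
}
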