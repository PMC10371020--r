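## End-to-end orchestration: simulate -> size factors -> enrichment ->
## tracks -> feature statistics -> MA rates -> mutation model -> manifest.

PIPELINE_KEYS <- c("sim", "enrichment", "feature_stats", "ma_model", "mask")

#' Validate a pipeline configuration
#'
#' @param config named list with sections \code{sim} (arguments to
#'   \code{\link{simConfig}}), \code{enrichment} (\code{engine},
#'   \code{draws}, \code{seed}), \code{feature_stats} (\code{n_boot}),
#'   \code{ma_model} (\code{rope}, \code{draws}, \code{seed},
#'   \code{terms} -- the covariate terms of the mutation model, which
#'   small demo genomes should restrict) and optional
#'   \code{mask} (BED3 path).
#' @return the config with defaults filled in; errors list offending keys.
#' @export
validatePipelineConfig <- function(config) {
    bad <- setdiff(names(config), PIPELINE_KEYS)
    if (length(bad))
        stop("unknown config key(s): ", paste(bad, collapse = ", "))
    defaults <- list(sim = list(),
        enrichment = list(engine = "vi", draws = 500, seed = 1),
        feature_stats = list(n_boot = 2000),
        ma_model = list(rope = 0.05, draws = 2000, seed = 1,
            terms = c("rdh", "expr", "head_on", "rdh_x_head_on",
                "expr_x_head_on")))
    config <- modifyList(defaults, config)
    if (!is.null(config$mask) && !file.exists(config$mask))
        stop("missing input file: ", config$mask)
    do.call(simConfig, config$sim)  # validates the sim section
    config
}

#' Run the full analysis pipeline on a simulated dataset
#'
#' Stages run in dependency order; any failure halts with the stage name.
#' Re-running with an identical config reproduces identical output digests
#' for the deterministic stages (everything except wall-clock timings in
#' the manifest).
#'
#' @param config see \code{\link{validatePipelineConfig}}; may be a path
#'   to a JSON file.
#' @param outDir output directory.
#' @param quiet suppress progress messages.
#' @return the run manifest (also written to \code{manifest.json}).
#' @export
runPipeline <- function(config, outDir, quiet = FALSE) {
    if (is.character(config)) {
        if (!file.exists(config)) stop("missing input file: ", config)
        config <- read_json(config, simplifyVector = TRUE)
    }
    config <- validatePipelineConfig(config)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    say <- function(...) if (!quiet) message("[rdhscape] ", ...)
    t0 <- Sys.time()
    stage <- "simulate"
    manifest <- list(package_version = as.character(utils::packageVersion("rdhscape")),
        stages = list())
    result <- tryCatch({
        cfg <- do.call(simConfig, config$sim)
        say(stage, ": ", cfg@genome_length, " bp genome")
        sim <- simulateDataset(cfg)
        simDir <- file.path(outDir, "sim")
        writeSimulation(cfg, sim, simDir)
        mask <- if (!is.null(config$mask))
            rtracklayer::import(config$mask, format = "bed") else NULL

        stage <- "fit-enrichment"
        say(stage)
        sf <- sizeFactorsFromSpike(sim$counts)
        counts <- applySizeFactors(sim$counts, sf)
        fits <- fitEnrichment(counts, engine = config$enrichment$engine,
            nDraws = config$enrichment$draws,
            seed = config$enrichment$seed, mask = mask)
        enrDir <- file.path(outDir, "enrichment")
        dir.create(enrDir, showWarnings = FALSE)
        for (g in names(fits)) {
            write.table(enrichmentSummary(fits[[g]]),
                file.path(enrDir, paste0(g, "_summary.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
        }

        stage <- "tracks"
        say(stage)
        trkDir <- file.path(outDir, "tracks")
        dir.create(trkDir, showWarnings = FALSE)
        for (g in names(fits)) for (s in c("+", "-")) {
            z <- enrichmentTrack(fits[[g]], s, "z")
            sm <- rollingMedian(z, 10000)
            writeTrack(sm, file.path(trkDir,
                paste0(g, "_", ifelse(s == "+", "plus", "minus"),
                    "_z_10kb.bedGraph")))
        }
        for (g in cfg@genotypes) {
            slz <- replicationSlopeZ(sim$coverage[[g]], sim$truth@rep)
            writeTrack(slz, file.path(trkDir, paste0(g, "_slope_z.bedGraph")))
        }

        stage <- "feature-stats"
        say(stage)
        tab <- featureScoreTable(fits, sim$truth@features,
            sim$truth@expression)
        write.table(tab, file.path(outDir, "feature_scores.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
        battery <- defaultBattery(cfg@genotypes)
        cmp <- runComparisons(tab, battery,
            nBoot = config$feature_stats$n_boot, seed = 1)
        write.table(cmp, file.path(outDir, "comparisons.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

        stage <- "ma-rates"
        say(stage)
        flt <- filterSVNearAlterations(sim$ma$dataset)
        ds <- flt$dataset
        rates <- do.call(rbind, lapply(unique(ds@lines$genotype), function(g) {
            gen <- sum(ds@lines$generations[ds@lines$genotype == g])
            nsv <- sum(ds@svs$line_id %in% ds@lines$id[ds@lines$genotype == g])
            r <- rateWithCI(nsv, gen)
            data.frame(genotype = g, sv_count = nsv, generations = gen,
                rate = r$rate, ci_low = r$ci_low, ci_high = r$ci_high)
        }))
        write.table(rates, file.path(outDir, "sv_rates.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

        stage <- "ma-model"
        say(stage)
        scores <- do.call(rbind, lapply(cfg@genotypes, function(g) {
            cds <- sim$ma$covariates
            cds$genotype <- g
            cds$rdh_z <- unname(
                tab[[paste0("rdh_", g)]][match(cds$id, tab$id)])
            cds$rdh_z[is.na(cds$rdh_z)] <- 0
            cds
        }))
        counts2 <- mutationCounts(ds, scores)
        fitsM <- fitMutationRegression(counts2, rope = config$ma_model$rope,
            terms = unlist(config$ma_model$terms),
            nDraws = config$ma_model$draws, seed = config$ma_model$seed)
        write.table(mutationEffectTable(fitsM),
            file.path(outDir, "mutation_effects.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

        stage <- "report"
        say(stage)
        list(fits = fits, table = tab, comparisons = cmp, rates = rates,
            mutation = fitsM)
    }, error = function(e)
        stop("pipeline failed at stage '", stage, "': ",
            conditionMessage(e), call. = FALSE))
    ## manifest: digests of every regular output file
    files <- sort(list.files(outDir, recursive = TRUE, full.names = TRUE))
    files <- files[basename(files) != "manifest.json"]
    digests <- md5sum(files)
    names(digests) <- sub(paste0("^", outDir, "/?"), "", names(digests))
    cfgFile <- tempfile(fileext = ".json")
    write_json(config, cfgFile, auto_unbox = TRUE, digits = NA)
    manifest$config_hash <- unname(md5sum(cfgFile))
    manifest$seeds <- list(sim = config$sim$seed %||% 1L,
        enrichment = config$enrichment$seed, ma_model = config$ma_model$seed)
    manifest$digests <- as.list(digests)
    manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    write_json(manifest, file.path(outDir, "manifest.json"),
        auto_unbox = TRUE, digits = NA)
    invisible(c(result, list(manifest = manifest)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default comparison battery for a set of genotypes
#'
#' Head-on versus codirectional contrasts per genotype (full CDS,
#' first-100-bp, and top-20%-expression variants) plus cross-genotype
#' contrasts paired by feature.
#'
#' @param genotypes genotype labels; the first is the reference.
#' @return battery data.frame for \code{\link{runComparisons}}.
#' @export
defaultBattery <- function(genotypes) {
    ori <- do.call(rbind, lapply(genotypes, function(g) data.frame(
        mode = "orientation", type = "CDS",
        measure = c("full", "first100", "full"),
        top20 = c(FALSE, FALSE, TRUE), genotype = g, genotype_b = NA)))
    gen <- if (length(genotypes) > 1)
        do.call(rbind, lapply(genotypes[-1], function(g) data.frame(
            mode = "genotype", type = "CDS", measure = "full",
            top20 = FALSE, genotype = g, genotype_b = genotypes[1])))
    rbind(ori, gen)
}
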