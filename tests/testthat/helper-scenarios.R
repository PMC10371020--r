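## Shared simulation scenarios, cached per test run.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
    library(S4Vectors)
})

.scn <- new.env(parent = emptyenv())

cached <- function(key, expr) {
    if (is.null(.scn[[key]])) .scn[[key]] <- force(expr)
    .scn[[key]]
}

## small fast genome for unit tests
smallCfg <- function(...) {
    args <- modifyList(list(genome_length = 5e4, ter_pos = 25000,
        n_features = c(CDS = 40L, ncRNA = 4L, rRNA = 1L, tRNA = 5L),
        n_lines = 8L, spike_length = 5e3), list(...))
    do.call(simConfig, args)
}

## zeroed-out enrichment effects (flat truth)
nullEffects <- function(spike_log2 = 1) {
    list(feature_log2 = c(CDS = 0, UTR5 = 0, UTR3 = 0, ncRNA = 0,
            rRNA = 0, tRNA = 0),
        expression_slope = c(WT = 0, dRnhB = 0, dRnhC = 0),
        orientation_effect = 0, interaction_effect = 0, gene_sd = 0,
        spike_log2 = spike_log2)
}

## mutation coefficient set with everything zero except overrides
mutCoeffs <- function(intercept = log(5e-10), ...) {
    base <- c(intercept = intercept, geno_dRnhB = 0, geno_dRnhC = 0,
        rdh = 0, expr = 0, head_on = 0, rdh_x_head_on = 0,
        expr_x_head_on = 0)
    ov <- list(...)
    for (nm in names(ov)) base[[nm]] <- ov[[nm]]
    list(transition = base, transversion = base, indel = base)
}

## the 1000-CDS MA-line scenario used by the regression tests: annotation
## and covariates are cached and reused; only the Poisson event draws
## change with the seed. `uniformSlope` uses an annotation where every
## genotype shares the reference expression slope, putting the planted
## RDH-expression correlation at ~0.5 in all genotypes.
maScenario <- function(coeffs, seed = 1L, uniformSlope = FALSE) {
    key <- if (uniformSlope) "ma_annotation_u" else "ma_annotation"
    ann <- cached(key, {
        args <- list(genome_length = 1.2e6, ter_pos = 6e5,
            n_features = c(CDS = 1000L, ncRNA = 20L, rRNA = 3L, tRNA = 40L),
            seed = 11L)
        if (uniformSlope) {
            eff <- simConfig()@enrichment_effects
            eff$expression_slope[] <- 0.3
            args$enrichment_effects <- eff
        }
        cfg0 <- do.call(simConfig, args)
        truth <- simulateAnnotation(cfg0)
        scoresOf <- function(cfg) do.call(rbind, lapply(cfg@genotypes,
            function(g) {
                d <- cached(paste0(key, "_covar"),
                    simulateMALines(cfg, truth)$covariates)
                d$genotype <- g
                d$rdh_z <- cached(paste0(key, "_rdhz_", g),
                    trueRdhZ(cfg, truth, g))
                d
            }))
        list(cfg0 = cfg0, truth = truth, scoresOf = scoresOf)
    })
    cfg <- ann$cfg0
    cfg@mutation_coeffs <- coeffs
    cfg@seed <- as.integer(seed)
    ma <- simulateMALines(cfg, ann$truth)
    scores <- ann$scoresOf(cfg)
    counts <- mutationCounts(ma$dataset, scores)
    list(cfg = cfg, truth = ann$truth, ma = ma, scores = scores,
        counts = counts)
}
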