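test_that("simulation is deterministic given the seed", {
    cfg <- smallCfg(seed = 3)
    t1 <- simulateAnnotation(cfg)
    t2 <- simulateAnnotation(cfg)
    expect_identical(as.data.frame(t1@features), as.data.frame(t2@features))
    expect_identical(t1@beta, t2@beta)
    c1 <- simulateCounts(cfg, t1)
    c2 <- simulateCounts(cfg, t2)
    expect_identical(assay(c1, "counts"), assay(c2, "counts"))
    m1 <- simulateMALines(cfg, t1)
    m2 <- simulateMALines(cfg, t1)
    expect_identical(m1$dataset@events, m2$dataset@events)
    ## a different seed changes the data
    t3 <- simulateAnnotation(smallCfg(seed = 4))
    expect_false(identical(start(t1@features), start(t3@features)))
})

test_that("written outputs are hash-stable and round-trip", {
    cfg <- smallCfg(seed = 6)
    d1 <- tempfile(); d2 <- tempfile()
    sim <- simulateDataset(cfg)
    writeSimulation(cfg, sim, d1)
    writeSimulation(cfg, simulateDataset(cfg), d2)
    f1 <- list.files(d1, recursive = TRUE)
    expect_identical(f1, list.files(d2, recursive = TRUE))
    expect_identical(unname(tools::md5sum(file.path(d1, f1))),
        unname(tools::md5sum(file.path(d2, f1))))
    ## annotation, tracks and truth read back equal the in-memory objects
    back <- readAnnotation(file.path(d1, "features.gff3"))
    ord <- match(mcols(sim$truth@features)$id, mcols(back)$id)
    expect_equal(start(back)[ord], start(sim$truth@features))
    expect_equal(mcols(back)$type[ord], mcols(sim$truth@features)$type)
    lib <- colnames(sim$counts)[1]
    tr <- readTrack(file.path(d1, paste0(lib, ".bedGraph")),
        bins = granges(rowRanges(sim$counts)))
    cnt <- assay(sim$counts, "counts")[, 1]
    expect_equal(mcols(tr)$score[cnt > 0], cnt[cnt > 0])
    bt <- read.table(file.path(d1, "truth_beta.tsv"), header = TRUE)
    wt <- bt[bt$genotype == "WT", ]
    expect_equal(wt$beta_plus, sim$truth@beta$WT[["+"]])
    cfgBack <- jsonlite::read_json(file.path(d1, "config.json"),
        simplifyVector = TRUE)
    expect_equal(cfgBack$genome_length, cfg@genome_length)
    expect_equal(cfgBack$seed, cfg@seed)
})

test_that("features are placed without overlap and CDSs carry UTRs", {
    cfg <- smallCfg(seed = 3)
    truth <- simulateAnnotation(cfg)
    f <- truth@features
    expect_true(all(width(f) >= 1))
    expect_true(max(end(f)) <= cfg@genome_length)
    hits <- findOverlaps(f, ignore.strand = TRUE, drop.self = TRUE)
    expect_length(hits, 0)
    cds <- mcols(f)$gene[mcols(f)$type == "CDS"]
    u5 <- mcols(f)$gene[mcols(f)$type == "UTR5"]
    expect_setequal(cds, u5)
    expect_equal(sum(mcols(f)$type == "CDS"), 40L)
    ## impossible requests fail loudly
    expect_error(simulateAnnotation(
        smallCfg(n_features = c(CDS = 5000L, ncRNA = 0L, rRNA = 0L,
            tRNA = 0L))), "overlap")
})

test_that("head-on fraction tracks the configured probability", {
    cfg <- simConfig(genome_length = 4e5, ter_pos = 2e5,
        n_features = c(CDS = 200L, ncRNA = 0L, rRNA = 0L, tRNA = 0L),
        head_on_prob = 0.25, seed = 12)
    truth <- simulateAnnotation(cfg)
    nHO <- sum(mcols(truth@features)$orientation[
        mcols(truth@features)$type == "CDS"] == "head_on")
    ## binomial 99.9% envelope around p = 0.25 at n = 200
    expect_gte(nHO, qbinom(5e-4, 200, 0.25))
    expect_lte(nHO, qbinom(1 - 5e-4, 200, 0.25))
})

test_that("a plus-strand gene on the forward replichore is codirectional", {
    cfg <- smallCfg(seed = 3)  # oriC = 1, ter = L/2
    truth <- simulateAnnotation(cfg)
    g <- GRanges("chr", IRanges(cfg@genome_length / 4, width = 300),
        strand = "+")
    expect_equal(mcols(classifyOrientation(g, truth@rep))$orientation,
        "codirectional")
    expect_equal(mcols(classifyOrientation(
        `strand<-`(g, value = "-"), truth@rep))$orientation, "head_on")
})

test_that("flat truth gives extracted/input ratio near one", {
    cfg <- simConfig(genome_length = 1e6, ter_pos = 5e5,
        genotypes = "WT", replicates = 1L, spike_length = 0,
        enrichment_effects = nullEffects(), seed = 8,
        n_features = c(CDS = 300L, ncRNA = 10L, rRNA = 2L, tRNA = 20L))
    truth <- simulateAnnotation(cfg)
    expect_true(all(unlist(truth@beta) == 0))
    sc <- simulateCounts(cfg, truth)
    cd <- colData(sc)
    y <- assay(sc, "counts")
    inp <- y[, cd$sample_type == "input", drop = FALSE]
    ext <- y[, cd$sample_type == "extracted" & cd$strand == "+", drop = FALSE]
    n <- nrow(y)  # 10^4 bins
    expect_equal(n, 1e4)
    ratio <- mean(ext) / mean(inp)
    ## NB moments: se of the mean ratio at depth 100, phi 1000
    se <- sqrt((1 / mean(inp)^2) * (var(as.vector(ext)) / n +
        ratio^2 * var(as.vector(inp)) / n))
    expect_lt(abs(ratio - 1), 3 * se)
})

test_that("the infinite-dispersion switch gives Poisson counts", {
    cfg <- simConfig(genome_length = 5e4, ter_pos = 25000,
        genotypes = "WT", replicates = 1L, spike_length = 1e5,
        nb_dispersion = 5, enrichment_effects = nullEffects(0),
        n_features = c(CDS = 20L, ncRNA = 2L, rRNA = 1L, tRNA = 2L),
        seed = 13)
    truth <- simulateAnnotation(cfg)
    spikeOf <- function(sc) {
        y <- assay(sc, "counts")[rowData(sc)$spike,
            colData(sc)$sample_type == "input"]
        var(y) / mean(y)
    }
    ## spike bins share a constant mean, so the Fano factor is clean
    fanoP <- spikeOf(simulateCounts(cfg, truth, poisson = TRUE))
    fanoNB <- spikeOf(simulateCounts(cfg, truth))
    expect_lt(abs(fanoP - 1), 3 * sqrt(2 / 1000))
    ## phi = 5 at depth 100 implies Fano near 1 + mu/phi = 21
    expect_gt(fanoNB, 10)
})

test_that("a planted log2 = 2 region yields a fourfold count ratio", {
    eff <- nullEffects()
    eff$feature_log2["CDS"] <- 2
    cfg <- simConfig(genome_length = 2e5, ter_pos = 1e5, genotypes = "WT",
        replicates = 2L, enrichment_effects = eff, seed = 14,
        n_features = c(CDS = 100L, ncRNA = 0L, rRNA = 0L, tRNA = 0L))
    truth <- simulateAnnotation(cfg)
    sc <- simulateCounts(cfg, truth)
    cd <- colData(sc)
    y <- assay(sc, "counts")[!rowData(sc)$spike, ]
    cdsBins <- truth@beta$WT[["+"]] == 2
    inp <- rowMeans(y[, cd$sample_type == "input", drop = FALSE])
    ext <- rowMeans(y[, cd$sample_type == "extracted" & cd$strand == "+",
        drop = FALSE])
    ratio <- mean(ext[cdsBins]) / mean(inp[cdsBins])
    expect_equal(ratio, 4, tolerance = 0.1)
    bg <- truth@beta$WT[["+"]] == 0 & truth@beta$WT[["-"]] == 0
    expect_equal(mean(ext[bg]) / mean(inp[bg]), 1, tolerance = 0.1)
})

test_that("MA totals follow the Poisson law under zero coefficients", {
    r <- 2e-9
    cfg <- smallCfg(genotypes = "WT", n_lines = 20L,
        mutation_coeffs = mutCoeffs(intercept = log(r)), seed = 15)
    truth <- simulateAnnotation(cfg)
    ma <- simulateMALines(cfg, truth)
    E <- sum(ma$covariates$length) * 20 * cfg@generations_per_line
    total <- sum(ma$dataset@events$class %in% c("transition"))
    expect_lt(abs(total - r * E), 3 * sqrt(r * E) + 1)
})

test_that("a planted genotype effect doubles the empirical rate", {
    cfg <- simConfig(genome_length = 4e5, ter_pos = 2e5,
        genotypes = c("WT", "dRnhC"), n_lines = 40L,
        n_features = c(CDS = 300L, ncRNA = 0L, rRNA = 0L, tRNA = 0L),
        mutation_coeffs = mutCoeffs(intercept = log(2e-9),
            geno_dRnhC = log(2)), seed = 16)
    truth <- simulateAnnotation(cfg)
    ma <- simulateMALines(cfg, truth)
    ev <- ma$dataset@events
    gen <- ma$dataset@lines$genotype[match(ev$line_id, ma$dataset@lines$id)]
    ratio <- sum(gen == "dRnhC") / sum(gen == "WT")
    expect_equal(ratio, 2, tolerance = 0.25)
})

test_that("zero generations produce zero mutations", {
    cfg <- smallCfg(generations_per_line = 0, seed = 17)
    truth <- simulateAnnotation(cfg)
    ma <- simulateMALines(cfg, truth)
    expect_equal(nrow(ma$dataset@events), 0L)
})

test_that("invalid configurations are rejected", {
    expect_error(simConfig(genome_length = 1e5 + 50), "divisible")
    expect_error(simConfig(oriC_pos = 0), "within the genome")
    expect_error(simConfig(oriC_pos = 5e4, ter_pos = 5e4), "differ")
    expect_error(simConfig(mean_input_depth = 0), "positive")
    expect_error(simConfig(head_on_prob = 1.5), "head_on_prob")
})
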