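mkTrack <- function(scores, binWidth = 100, masked = NULL) {
    gr <- GRanges("chr", IRanges((seq_along(scores) - 1) * binWidth + 1,
        width = binWidth))
    mcols(gr)$score <- scores
    if (!is.null(masked)) mcols(gr)$masked <- masked
    gr
}

test_that("feature aggregation takes the same-strand median of bin z", {
    plus <- mkTrack(c(0.1, 0.5, 0.9, 5, 5))
    minus <- mkTrack(rep(-1, 5))
    f <- GRanges("chr", IRanges(1, 300), strand = "+")
    expect_equal(aggregateFeatures(list("+" = plus, "-" = minus), f), 0.5)
    ## minus-strand feature reads the minus track
    fm <- GRanges("chr", IRanges(1, 300), strand = "-")
    expect_equal(aggregateFeatures(list("+" = plus, "-" = minus), fm), -1)
    ## fully masked feature is missing
    pm <- mkTrack(c(0.1, 0.5, 0.9, 5, 5), masked = c(TRUE, TRUE, TRUE, FALSE, FALSE))
    expect_true(is.na(aggregateFeatures(list("+" = pm, "-" = minus), f)))
    ## a bin counts only if its midpoint (250.5 for bin 3) lies inside
    edge <- GRanges("chr", IRanges(160, 260), strand = "+")
    expect_equal(aggregateFeatures(list("+" = plus, "-" = minus), edge), 0.9)
    ## an interval ending exactly at a midpoint's floor excludes that bin
    out <- GRanges("chr", IRanges(201, 250), strand = "+")
    expect_true(is.na(aggregateFeatures(list("+" = plus, "-" = minus), out)))
})

test_that("aggregation equals a brute-force oracle on random features", {
    set.seed(61)
    nb <- 500
    tracks <- list("+" = mkTrack(rnorm(nb)), "-" = mkTrack(rnorm(nb)))
    n <- 1000
    st <- sample(seq(1, nb * 100 - 600), n, TRUE)
    feats <- GRanges("chr", IRanges(st, width = sample(80:600, n, TRUE)),
        strand = sample(c("+", "-"), n, TRUE))
    got <- aggregateFeatures(tracks, feats)
    mids <- (seq_len(nb) - 1) * 100 + 50.5
    oracle <- vapply(seq_len(n), function(i) {
        v <- mcols(tracks[[as.character(strand(feats))[i]]])$score
        sel <- mids >= start(feats)[i] & mids <= end(feats)[i]
        if (any(sel)) median(v[sel]) else NA_real_
    }, numeric(1))
    expect_equal(got, oracle)
})

test_that("group comparison recovers a unit shift and matches enumeration", {
    set.seed(62)
    a <- rnorm(20)
    b <- a + 1
    cmp <- compareGroups(b, a, nBoot = 500)
    expect_equal(cmp$estimate, 1.0)
    expect_true(cmp$ci[1] <= 1 & 1 <= cmp$ci[2])
    ## Wilcoxon p equals full permutation enumeration for small groups
    permP <- function(x, y, alternative = "two.sided") {
        nx <- length(x); pooled <- c(x, y)
        W <- sum(rank(pooled)[seq_len(nx)]) - nx * (nx + 1) / 2
        sets <- combn(length(pooled), nx)
        Ws <- apply(sets, 2, function(idx)
            sum(rank(pooled)[idx]) - nx * (nx + 1) / 2)
        mu <- nx * length(y) / 2
        mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
    }
    for (rep in 1:3) {
        x <- round(rnorm(6), 2); y <- round(rnorm(7) + 0.5, 2)
        expect_equal(compareGroups(x, y, nBoot = 10)$p, permP(x, y),
            tolerance = 1e-12)
    }
})

test_that("identical groups give zero difference and p near one", {
    x <- c(1.2, -0.5, 0.3, 2.2, -1.7, 0.9)
    cmp <- compareGroups(x, x, nBoot = 200)
    expect_equal(cmp$estimate, 0)
    expect_gt(cmp$p, 0.9)
})

test_that("group comparison is antisymmetric", {
    set.seed(63)
    x <- rnorm(15); y <- rnorm(12) + 0.4
    a <- compareGroups(x, y, nBoot = 200, seed = 2)
    b <- compareGroups(y, x, nBoot = 200, seed = 2)
    expect_equal(a$estimate, -b$estimate)
    expect_equal(a$p, b$p)
})

test_that("paired comparison uses per-feature differences", {
    x <- c(1, 2, 3, 4, 10)
    y <- c(0, 1, 2, 3, 4)
    cmp <- compareGroups(x, y, paired = TRUE, nBoot = 200)
    expect_equal(cmp$estimate, 1)
    expect_equal(cmp$n, 5)
    ## NA pairs are dropped
    cmp2 <- compareGroups(c(x, NA), c(y, 1), paired = TRUE, nBoot = 200)
    expect_equal(cmp2$n, 5)
    expect_error(compareGroups(1:2, 2:3, paired = TRUE), ">= 3")
})

test_that("BH adjustment matches the hand-computed example", {
    expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
        rep(0.04, 4))
    ## monotone and bounded by one
    set.seed(64)
    p <- runif(30)
    adj <- p.adjust(p, method = "BH")
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("stars follow the printed FDR map", {
    expect_equal(starCategory(c(0.2, 0.05, 0.049, 0.01, 0.009, 0.001, 9e-4)),
        c("", "", "*", "*", "**", "**", "***"))
})

test_that("the comparison battery applies filters and FDR", {
    set.seed(65)
    n <- 60
    tab <- data.frame(id = sprintf("g%02d", 1:n), type = "CDS",
        orientation = sample(c("head_on", "codirectional"), n, TRUE),
        length = 300, start = 1, end = 300,
        head_on = 0, expr_z = rnorm(n))
    tab$head_on <- as.numeric(tab$orientation == "head_on")
    tab$rdh_WT <- rnorm(n) + tab$head_on
    tab$rdh100_WT <- tab$rdh_WT
    tab$rdh_dRnhB <- tab$rdh_WT + 0.5
    tab$rdh100_dRnhB <- tab$rdh_dRnhB
    battery <- defaultBattery(c("WT", "dRnhB"))
    out <- runComparisons(tab, battery, nBoot = 300)
    expect_equal(nrow(out), nrow(battery))
    expect_true(all(out$fdr >= out$p - 1e-12))
    geno <- out[out$mode == "genotype", ]
    expect_equal(geno$estimate, 0.5)
    ## top-20% filter keeps ties above the threshold
    keep <- featureFilter(tab, type = "CDS", top20 = TRUE)
    expect_equal(sum(keep), sum(tab$expr_z >= quantile(tab$expr_z, 0.8)))
    bad <- battery[1, ]
    bad$type <- "rRNA"
    expect_error(runComparisons(tab, bad, nBoot = 10), "empty group")
})

test_that("featureScoreTable aggregates fits across genotypes", {
    cfg <- smallCfg(seed = 66)
    truth <- simulateAnnotation(cfg)
    sc <- simulateCounts(cfg, truth)
    fits <- fitEnrichment(sc, seed = 5)
    tab <- featureScoreTable(fits, truth@features, truth@expression)
    expect_equal(nrow(tab), length(truth@features))
    expect_true(all(c("rdh_WT", "rdh100_WT", "rdh_dRnhC", "expr_z")
        %in% colnames(tab)))
    ## feature scores of enriched classes sit above the genome background
    expect_gt(median(tab$rdh_WT[tab$type == "rRNA"], na.rm = TRUE),
        median(tab$rdh_WT[tab$type == "CDS"], na.rm = TRUE))
    ## the first-100-bp score differs from the full score for long CDSs
    long <- tab$type == "CDS" & tab$length > 300
    expect_false(all(tab$rdh_WT[long] == tab$rdh100_WT[long]))
})

test_that("orientation regression recovers planted coefficients", {
    set.seed(67)
    n <- 500
    ho <- rbinom(n, 1, 0.3)
    ez <- rnorm(n)
    y <- 0.2 + 0.1 * ho + 0.8 * ez - 0.5 * ho * ez + rnorm(n, 0, 0.5)
    tab <- data.frame(id = seq_len(n), type = "CDS",
        orientation = ifelse(ho == 1, "head_on", "codirectional"),
        length = 300, head_on = ho, expr_z = ez, rdh_WT = y)
    fit <- fitOrientationRegression(tab, "WT", nDraws = 3000, seed = 1)
    m <- colMeans(fit$draws)
    expect_equal(unname(m["expr_z"]), 0.8, tolerance = 0.1)
    ## the planted negative interaction is detected
    expect_gt(mean(fit$draws[, "head_on:expr_z"] < 0), 0.95)
})

test_that("orientation regression handles a null response", {
    set.seed(68)
    n <- 120
    tab <- data.frame(id = seq_len(n), type = "CDS",
        orientation = "codirectional", length = 300,
        head_on = rbinom(n, 1, 0.5), expr_z = rnorm(n),
        rdh_WT = rnorm(n, 0, 0.2))
    fit <- fitOrientationRegression(tab, "WT", nDraws = 2000, seed = 2)
    for (tm in c("head_on", "expr_z", "head_on:expr_z")) {
        qs <- quantile(fit$draws[, tm], c(0.005, 0.995))
        expect_true(qs[1] < 0 & 0 < qs[2])
    }
    expect_error(fitOrientationRegression(tab[1:10, ], "WT"), ">= 20")
})

test_that("regression intervals cover planted truth across replicates", {
    set.seed(69)
    hit <- 0; total <- 0
    for (r in 1:20) {
        n <- 150
        ho <- rbinom(n, 1, 0.3)
        ez <- rnorm(n)
        beta <- c(0.2, 0.15, 0.6, -0.3)
        y <- beta[1] + beta[2] * ho + beta[3] * ez + beta[4] * ho * ez +
            rnorm(n, 0, 0.5)
        tab <- data.frame(id = seq_len(n), type = "CDS",
            orientation = "x", length = 1, head_on = ho, expr_z = ez,
            rdh_WT = y)
        fit <- fitOrientationRegression(tab, "WT", nDraws = 1200,
            nChains = 2, seed = r)
        for (j in 1:4) {
            qs <- quantile(fit$draws[, j], c(0.025, 0.975))
            hit <- hit + (qs[1] <= beta[j] & beta[j] <= qs[2])
            total <- total + 1
        }
    }
    expect_gte(hit / total, 0.85)
})
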