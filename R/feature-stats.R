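## Feature-level aggregation of enrichment z tracks and the comparison
## battery: head-on vs codirectional contrasts, cross-genotype paired
## differences with Wilcoxon tests + BH FDR, and the orientation x
## expression regression.

#' Aggregate a stranded z track to features
#'
#' A feature's score is the median of the same-strand z values over the
#' bins whose midpoint lies inside the feature. Masked or missing bins are
#' excluded; a feature with no usable bin gets NA.
#'
#' @param track named list with \code{"+"} and \code{"-"} elements, each a
#'   \code{GRanges} with a \code{score} column (and optional logical
#'   \code{masked} column).
#' @param features \code{GRanges} with strands.
#' @return numeric vector of feature scores, NA where no bin was usable.
#' @export
aggregateFeatures <- function(track, features) {
    out <- rep(NA_real_, length(features))
    for (s in c("+", "-")) {
        tr <- track[[s]]
        v <- mcols(tr)$score
        if (!is.null(mcols(tr)$masked)) v[mcols(tr)$masked] <- NA_real_
        onS <- which(as.character(strand(features)) == s)
        if (!length(onS)) next
        hits <- midpointHits(tr, features[onS])
        vals <- v[queryHits(hits)]
        keep <- !is.na(vals)
        agg <- tapply(vals[keep], subjectHits(hits)[keep], median)
        out[onS[as.integer(names(agg))]] <- agg
    }
    out
}

#' Build the per-feature score table across genotypes
#'
#' Converts each genotype's posterior-mean enrichment to robust z per
#' strand, aggregates full-length features and (for CDSs) their first
#' \code{firstN} bp, and attaches the expression z-score (robust z of
#' log2 expression, computed once).
#'
#' @param fits named list of \linkS4class{EnrichmentPosterior} (per
#'   genotype).
#' @param features annotated \code{GRanges} (with \code{id}, \code{type},
#'   \code{orientation}, \code{gene} columns).
#' @param expression data.frame with \code{id} (gene) and \code{log2_expr}
#'   or precomputed \code{z}.
#' @param firstN leading-window width for CDS starts (default 100 bp).
#' @return data.frame with one row per feature: \code{id}, \code{type},
#'   \code{orientation}, \code{length}, \code{start}, \code{end},
#'   \code{head_on}, \code{expr_z}, and per genotype \code{rdh_<g>} and
#'   \code{rdh100_<g>}.
#' @export
featureScoreTable <- function(fits, features, expression, firstN = 100) {
    if (is.null(expression$z))
        expression$z <- robustZ(expression$log2_expr)
    ez <- setNames(expression$z, expression$id)
    tab <- data.frame(id = mcols(features)$id,
        type = mcols(features)$type,
        orientation = mcols(features)$orientation,
        length = width(features),
        start = start(features), end = end(features),
        head_on = as.numeric(mcols(features)$orientation == "head_on"),
        expr_z = unname(ez[mcols(features)$gene]))
    lead <- firstNbp(features, firstN)
    for (g in names(fits)) {
        zt <- lapply(setNames(nm = c("+", "-")), function(s) {
            tr <- enrichmentTrack(fits[[g]], s, "z")
            mcols(tr)$masked <- fits[[g]]@masked
            tr
        })
        tab[[paste0("rdh_", g)]] <- aggregateFeatures(zt, features)
        tab[[paste0("rdh100_", g)]] <- aggregateFeatures(zt, lead)
    }
    tab
}

#' Compare two groups of feature scores
#'
#' Unpaired: Wilcoxon rank-sum p-value (exact for group sizes <= 25,
#' normal approximation with continuity correction otherwise), the
#' Hodges-Lehmann median difference, and a percentile bootstrap 95% CI.
#' Paired (e.g. genotypes paired by genomic feature): per-feature
#' differences, their median with a bootstrap CI, and a Wilcoxon
#' signed-rank p-value.
#'
#' @param x,y numeric score vectors (for \code{paired = TRUE}, aligned by
#'   feature; NA pairs dropped).
#' @param paired logical.
#' @param nBoot bootstrap resamples (default 10000).
#' @param level confidence level (default 0.95).
#' @param seed bootstrap seed.
#' @return list with \code{estimate}, \code{ci} (length 2), \code{p},
#'   \code{n}.
#' @export
compareGroups <- function(x, y, paired = FALSE, nBoot = 10000,
                          level = 0.95, seed = 1) {
    if (paired) {
        keep <- !is.na(x) & !is.na(y)
        d <- x[keep] - y[keep]
        if (length(d) < 3) stop("need >= 3 paired features")
        est <- median(d)
        set.seed(seed)
        bs <- vapply(seq_len(nBoot), function(i)
            median(d[sample.int(length(d), replace = TRUE)]), numeric(1))
        p <- suppressWarnings(wilcox.test(d,
            exact = length(d) <= 25)$p.value)
        n <- length(d)
    } else {
        x <- x[!is.na(x)]; y <- y[!is.na(y)]
        if (length(x) < 3 || length(y) < 3)
            stop("need >= 3 features per group")
        est <- median(outer(x, y, "-"))
        set.seed(seed)
        bs <- vapply(seq_len(nBoot), function(i)
            median(outer(x[sample.int(length(x), replace = TRUE)],
                y[sample.int(length(y), replace = TRUE)], "-")), numeric(1))
        p <- suppressWarnings(wilcox.test(x, y,
            exact = max(length(x), length(y)) <= 25,
            correct = TRUE)$p.value)
        n <- c(length(x), length(y))
    }
    alpha <- (1 - level) / 2
    list(estimate = est,
        ci = unname(quantile(bs, c(alpha, 1 - alpha))), p = p, n = n)
}

#' Significance stars from an FDR value
#'
#' One star for 0.01 <= FDR < 0.05, two for 0.001 <= FDR < 0.01, three
#' for FDR < 0.001.
#'
#' @param fdr numeric FDR values.
#' @return character vector of star strings.
#' @export
starCategory <- function(fdr) {
    as.character(cut(fdr, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
        labels = c("***", "**", "*", ""), right = FALSE))
}

#' Select features for a comparison
#'
#' Applies the filters used in the comparison battery: restriction to a
#' feature type, the top 20% most highly expressed features per genotype
#' (threshold on expression z, ties kept above the threshold), and the
#' choice of full-length versus first-100-bp scores.
#'
#' @param table a \code{\link{featureScoreTable}} result.
#' @param type feature type, or NULL for all.
#' @param top20 restrict to the top 20% by \code{expr_z}.
#' @return logical row filter.
#' @export
featureFilter <- function(table, type = NULL, top20 = FALSE) {
    keep <- rep(TRUE, nrow(table))
    if (!is.null(type)) keep <- keep & table$type == type
    if (top20) {
        thr <- quantile(table$expr_z[keep], 0.8, na.rm = TRUE)
        keep <- keep & !is.na(table$expr_z) & table$expr_z >= thr
    }
    keep
}

#' Run a battery of group comparisons with BH FDR
#'
#' Each battery row is either an orientation contrast (head-on vs
#' codirectional scores within one genotype) or a genotype contrast
#' (paired by feature). P-values across the whole battery are adjusted by
#' Benjamini-Hochberg and mapped to star categories.
#'
#' @param table a \code{\link{featureScoreTable}} result.
#' @param battery data.frame with columns \code{mode}
#'   (\code{"orientation"}/\code{"genotype"}), \code{type}, \code{measure}
#'   (\code{"full"}/\code{"first100"}), \code{top20} (logical),
#'   \code{genotype} (for orientation), \code{genotype_b} (for genotype
#'   contrasts, compared against \code{genotype}).
#' @param nBoot,seed bootstrap controls passed to
#'   \code{\link{compareGroups}}.
#' @return the battery with \code{estimate}, \code{ci_low}, \code{ci_high},
#'   \code{p}, \code{fdr}, \code{stars} columns appended.
#' @export
runComparisons <- function(table, battery, nBoot = 10000, seed = 1) {
    res <- lapply(seq_len(nrow(battery)), function(i) {
        b <- battery[i, ]
        keep <- featureFilter(table,
            type = if (is.na(b$type)) NULL else b$type,
            top20 = isTRUE(b$top20))
        if (!any(keep))
            stop("empty group after filter: type=", b$type,
                " top20=", b$top20)
        col <- function(g) paste0(
            if (identical(b$measure, "first100")) "rdh100_" else "rdh_", g)
        sub <- table[keep, ]
        if (b$mode == "orientation") {
            v <- sub[[col(b$genotype)]]
            cmp <- compareGroups(v[sub$orientation == "head_on"],
                v[sub$orientation == "codirectional"],
                paired = FALSE, nBoot = nBoot, seed = seed + i)
        } else {
            cmp <- compareGroups(sub[[col(b$genotype)]],
                sub[[col(b$genotype_b)]],
                paired = TRUE, nBoot = nBoot, seed = seed + i)
        }
        data.frame(estimate = cmp$estimate, ci_low = cmp$ci[1],
            ci_high = cmp$ci[2], p = cmp$p)
    })
    out <- cbind(battery, do.call(rbind, res))
    out$fdr <- p.adjust(out$p, method = "BH")
    out$stars <- starCategory(out$fdr)
    out
}

#' Bayesian regression of CDS enrichment on orientation and expression
#'
#' Linear model rdh_z ~ 1 + head_on + expr_z + head_on:expr_z with
#' Normal(0, 2^2) coefficient priors and a half-Normal residual scale,
#' fitted per genotype by the package's independence sampler; summaries
#' derive from the posterior draws only.
#'
#' @param table a \code{\link{featureScoreTable}} result (CDS rows used).
#' @param genotype genotype label.
#' @param nDraws,nChains,seed sampler controls.
#' @return a \code{\link{fitBayesGLM}} fit with Gaussian family; draws
#'   columns are \code{intercept}, \code{head_on}, \code{expr_z},
#'   \code{head_on:expr_z}, \code{log_sigma}.
#' @export
fitOrientationRegression <- function(table, genotype, nDraws = 4000,
                                     nChains = 4, seed = 1) {
    sub <- table[table$type == "CDS", ]
    y <- sub[[paste0("rdh_", genotype)]]
    keep <- !is.na(y) & !is.na(sub$expr_z)
    if (sum(keep) < 20) stop("need >= 20 CDSs with both scores")
    sub <- sub[keep, ]
    X <- cbind(intercept = 1, head_on = sub$head_on, expr_z = sub$expr_z,
        `head_on:expr_z` = sub$head_on * sub$expr_z)
    fitBayesGLM(X, y[keep], family = "gaussian", priorSd = 2,
        nDraws = nDraws, nChains = nChains, seed = seed)
}
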