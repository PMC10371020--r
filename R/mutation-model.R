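## MA-line statistics: SV filtering near engineered loci, exclusion of
## repair-deficient lines, exact Poisson rate estimates, the conditional
## rate-ratio test, and the Bayesian Poisson regression of per-CDS
## mutation rates with ROPE-referenced Bayes factors.

#' Remove SVs near a line's intended genetic alteration
#'
#' A structural variant is removed when its interval intersects the
#' engineered-locus interval of the same line extended by \code{window} bp
#' on both sides, endpoints inclusive (an upstream SV caller flags the
#' construction scar itself, not a spontaneous event).
#'
#' @param dataset a \linkS4class{MALineDataset} with
#'   \code{alterations}.
#' @param window flank width in bp (default 100).
#' @return list with \code{dataset} (SVs filtered) and \code{removed}
#'   (the removal report).
#' @export
#' @examples
#' # an alteration spanning 1,640,489-1,641,256 excludes SVs touching
#' # 1,640,389-1,641,356
filterSVNearAlterations <- function(dataset, window = 100) {
    sv <- dataset@svs
    al <- dataset@alterations
    if (!nrow(sv) || !nrow(al)) {
        return(list(dataset = dataset, removed = sv[0, ]))
    }
    drop <- rep(FALSE, nrow(sv))
    for (i in seq_len(nrow(sv))) {
        a <- al[al$line_id == sv$line_id[i], , drop = FALSE]
        if (!nrow(a)) next
        drop[i] <- any(sv$start[i] <= a$end + window &
            sv$end[i] >= a$start - window)
    }
    out <- dataset
    out@svs <- sv[!drop, , drop = FALSE]
    list(dataset = out, removed = sv[drop, , drop = FALSE])
}

#' Flag lines carrying SVs in guarded repair genes
#'
#' A line whose SV overlaps a guarded gene (e.g. a mismatch-repair gene,
#' whose loss would change the mutation spectrum) is flagged for
#' exclusion.
#'
#' @param dataset a \linkS4class{MALineDataset}.
#' @param guarded data.frame with \code{start}, \code{end} columns (one
#'   row per guarded gene).
#' @return named logical vector over line ids: TRUE = flagged.
#' @export
flagRepairDeficientLines <- function(dataset, guarded) {
    flags <- setNames(rep(FALSE, nrow(dataset@lines)), dataset@lines$id)
    sv <- dataset@svs
    if (!nrow(sv) || !nrow(guarded)) return(flags)
    for (i in seq_len(nrow(sv))) {
        hit <- any(sv$start[i] <= guarded$end & sv$end[i] >= guarded$start)
        if (hit) flags[sv$line_id[i]] <- TRUE
    }
    flags
}

#' Drop flagged lines from a dataset
#'
#' @param dataset a \linkS4class{MALineDataset}.
#' @param flags result of \code{\link{flagRepairDeficientLines}}.
#' @return the dataset without flagged lines (their events and SVs
#'   removed).
#' @export
dropFlaggedLines <- function(dataset, flags) {
    bad <- names(flags)[flags]
    dataset@lines <- dataset@lines[!dataset@lines$id %in% bad, , drop = FALSE]
    dataset@events <- dataset@events[!dataset@events$line_id %in% bad, , drop = FALSE]
    dataset@svs <- dataset@svs[!dataset@svs$line_id %in% bad, , drop = FALSE]
    dataset
}

#' Event rate with an exact Poisson confidence interval
#'
#' Rate = events / exposure with Garwood bounds from gamma quantiles:
#' lower = qgamma(alpha/2, events) / exposure (0 when events = 0), upper =
#' qgamma(1 - alpha/2, events + 1) / exposure.
#'
#' @param events non-negative integer event count.
#' @param exposure positive exposure (generations, or site-generations).
#' @param level confidence level (default 0.95).
#' @return list with \code{rate}, \code{ci_low}, \code{ci_high},
#'   \code{events}, \code{exposure}.
#' @export
#' @examples
#' rateWithCI(17, 265500)$rate  # 6.4e-05
rateWithCI <- function(events, exposure, level = 0.95) {
    if (exposure <= 0) stop("exposure must be positive")
    if (events < 0 || events != round(events))
        stop("events must be a non-negative integer")
    alpha <- 1 - level
    lo <- if (events == 0) 0 else qgamma(alpha / 2, events) / exposure
    hi <- qgamma(1 - alpha / 2, events + 1) / exposure
    list(rate = events / exposure, ci_low = lo, ci_high = hi,
        events = events, exposure = exposure)
}

#' Exact conditional rate-ratio test
#'
#' Conditions on the total count n = x1 + x2: under equal rates, x1 is
#' Binomial(n, t1 / (t1 + t2)). One-tailed p-values are the binomial tail
#' probabilities; the two-tailed p sums the probabilities of all outcomes
#' no more likely than the observed one.
#'
#' @param x1,x2 event counts (not both zero).
#' @param t1,t2 positive exposures.
#' @param alternative \code{"greater"} (rate1 > rate2), \code{"less"} or
#'   \code{"two.sided"}.
#' @return p-value.
#' @export
#' @examples
#' rateRatioTest(3, 100, 0, 100, "greater")  # 0.125
rateRatioTest <- function(x1, t1, x2, t2,
                          alternative = c("greater", "less", "two.sided")) {
    alternative <- match.arg(alternative)
    if (t1 <= 0 || t2 <= 0) stop("exposures must be positive")
    if (x1 + x2 == 0) stop("no events in either group")
    n <- x1 + x2
    p0 <- t1 / (t1 + t2)
    switch(alternative,
        greater = pbinom(x1 - 1, n, p0, lower.tail = FALSE),
        less = pbinom(x1, n, p0),
        two.sided = {
            d <- dbinom(0:n, n, p0)
            sum(d[d <= d[x1 + 1] * (1 + 1e-7)])
        })
}

#' Per-CDS mutation counts with exposures and covariates
#'
#' Counts events of each class falling inside each CDS, separately per
#' genotype, and attaches the exposure (CDS length x pooled generations of
#' that genotype's lines).
#'
#' @param dataset a \linkS4class{MALineDataset}.
#' @param scores long data.frame with one row per CDS x genotype:
#'   \code{id}, \code{genotype}, \code{start}, \code{end}, \code{length},
#'   \code{head_on}, \code{expr_z}, \code{rdh_z}.
#' @param classes mutation classes to tabulate; insertions and deletions
#'   are pooled as \code{"indel"}.
#' @return \code{scores} expanded to one row per CDS x genotype x class
#'   with \code{count} and \code{exposure} columns.
#' @export
mutationCounts <- function(dataset, scores,
                           classes = c("transition", "transversion", "indel")) {
    ev <- dataset@events
    ev$genotype <- dataset@lines$genotype[match(ev$line_id, dataset@lines$id)]
    ev$class[ev$class %in% c("insertion", "deletion")] <- "indel"
    gens <- tapply(dataset@lines$generations, dataset@lines$genotype, sum)
    out <- do.call(rbind, lapply(classes, function(cl) {
        s <- scores
        s$class <- cl
        s$count <- 0L
        s$exposure <- NA_real_
        for (g in unique(s$genotype)) {
            rows <- which(s$genotype == g)
            pos <- ev$position[ev$genotype == g & ev$class == cl]
            if (length(pos))
                s$count[rows] <- vapply(rows, function(r)
                    sum(pos >= s$start[r] & pos <= s$end[r]), integer(1))
            s$exposure[rows] <- s$length[rows] * gens[[g]]
        }
        s
    }))
    rownames(out) <- NULL
    out
}

#' Bayesian Poisson regression of mutation rate on genomic covariates
#'
#' Per mutation class, counts are Poisson with exposure offset and log
#' rate eta = intercept + genotype effects + coefficients on RDH z,
#' expression z, head-on orientation and the configured interactions, all
#' with Normal(0, 2^2) priors. Each coefficient is summarised as an
#' \linkS4class{EffectPosterior} with ROPE-referenced Bayes factors. The
#' pointwise log-likelihood matrix is stored for PSIS-LOO comparison.
#'
#' @param counts result of \code{\link{mutationCounts}}.
#' @param terms covariate terms to include; any of \code{"rdh"},
#'   \code{"expr"}, \code{"head_on"}, \code{"rdh_x_head_on"},
#'   \code{"expr_x_head_on"}. Dropping \code{"rdh"} or \code{"expr"}
#'   yields the reduced models used for the leave-one-covariate-out
#'   robustness analysis.
#' @param rope ROPE half-width on the log-rate scale (default 0.05,
#'   about a 5% rate change; echoed on every effect).
#' @param priorSd coefficient prior SD (default 2).
#' @param nDraws,nChains,seed sampler controls (default 4000 draws).
#' @param classes mutation classes to fit (default: all present).
#' @return named list per class: \code{fit} (see
#'   \code{\link{fitBayesGLM}}) and \code{effects} (list of
#'   \linkS4class{EffectPosterior} per coefficient).
#' @export
fitMutationRegression <- function(counts,
        terms = c("rdh", "expr", "head_on", "rdh_x_head_on", "expr_x_head_on"),
        rope = 0.05, priorSd = 2, nDraws = 4000, nChains = 4, seed = 1,
        classes = NULL) {
    if (rope <= 0) stop("ROPE half-width must be positive")
    if (is.null(classes)) classes <- unique(counts$class)
    out <- list()
    for (cl in classes) {
        d <- counts[counts$class == cl, ]
        X <- cbind(intercept = rep(1, nrow(d)))
        genos <- unique(d$genotype)
        for (g in genos[-1])
            X <- cbind(X, as.numeric(d$genotype == g))
        colnames(X) <- c("intercept", if (length(genos) > 1)
            paste0("geno_", genos[-1]))
        termCols <- list(rdh = d$rdh_z, expr = d$expr_z,
            head_on = d$head_on, rdh_x_head_on = d$rdh_z * d$head_on,
            expr_x_head_on = d$expr_z * d$head_on)
        for (tm in terms) X <- cbind(X, setNames(termCols[tm], tm)[[1]])
        colnames(X) <- c("intercept",
            if (length(genos) > 1) paste0("geno_", genos[-1]), terms)
        fit <- fitBayesGLM(X, d$count, offset = log(d$exposure),
            family = "poisson", priorSd = priorSd, nDraws = nDraws,
            nChains = nChains, seed = seed + match(cl, classes))
        effects <- lapply(setdiff(colnames(X), "intercept"), function(tm)
            bayesFactors(fit$draws[, tm], prior = list(mean = 0, sd = priorSd),
                rope = rope, term = paste0(tm, ".", cl)))
        names(effects) <- setdiff(colnames(X), "intercept")
        out[[cl]] <- list(fit = fit, effects = effects)
    }
    out
}

#' Coefficient summary table of a mutation-regression fit
#'
#' @param fits result of \code{\link{fitMutationRegression}}.
#' @return data.frame with class, term, posterior mean, 90% interval,
#'   K, K0 and evidence categories.
#' @export
mutationEffectTable <- function(fits) {
    do.call(rbind, lapply(names(fits), function(cl) {
        do.call(rbind, lapply(names(fits[[cl]]$effects), function(tm) {
            e <- fits[[cl]]$effects[[tm]]
            data.frame(class = cl, term = tm, mean = mean(e@draws),
                q05 = unname(quantile(e@draws, 0.05)),
                q95 = unname(quantile(e@draws, 0.95)),
                K = e@K, K0 = e@K0, category = e@category,
                category0 = e@category0)
        }))
    }))
}
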