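## Bayesian inference of strand-specific log2 pull-down enrichment from
## paired extracted/input libraries, spike-in size factors, genotype
## contrasts and qPCR delta-delta-Cq quantitation.
##
## Count model, per genotype, strand and bin:
##     y_l ~ NegBin(mu_l, phi),  var = mu + mu^2/phi
##     log mu_l = log(c_l) + alpha_bin + ln(2) * beta_bin * 1[l extracted]
## with c_l the library size factor, alpha_bin the log input abundance and
## beta_bin the log2 enrichment of the pull-down over the input. Input
## libraries are unstranded and shared between the two strand models;
## extracted libraries are strand-resolved. phi is shared within a genotype.
##
## Priors: alpha ~ Normal(log mean depth, 3^2); beta ~ Normal(0, 2^2) on
## the log2 scale; overdispersion 1/phi ~ half-Normal(0, 5^2).
##
## The default "vi" engine is a Gaussian approximation at the per-bin
## posterior mode (the model is log-concave in (alpha, beta) given phi, so
## the bins decouple and a damped Newton solve is exact and fast); the
## "mcmc" engine runs a vectorised random-walk Metropolis sampler per bin
## for small genomes.

LN2 <- log(2)

#' Fit strand-specific log2 enrichment posteriors
#'
#' @param counts a \linkS4class{StrandedCountMatrix}.
#' @param genotypes genotypes to fit (default: all in \code{counts}).
#' @param engine \code{"vi"} (Gaussian approximation, default) or
#'   \code{"mcmc"} (random-walk Metropolis).
#' @param nDraws posterior draws per bin and strand (default 500).
#' @param seed integer seed; mandatory for reproducible draws.
#' @param mask optional \code{GRanges} of excluded intervals; masked bins
#'   yield flagged NA records rather than being dropped.
#' @param priors list with elements \code{alpha_sd}, \code{beta_sd},
#'   \code{disp_sd} overriding the defaults (3, 2, 5).
#' @return named list of \linkS4class{EnrichmentPosterior}, one per
#'   genotype.
#' @export
fitEnrichment <- function(counts, genotypes = NULL, engine = c("vi", "mcmc"),
                          nDraws = 500, seed = 1, mask = NULL,
                          priors = list()) {
    stopifnot(is(counts, "StrandedCountMatrix"))
    engine <- match.arg(engine)
    pr <- modifyList(list(alpha_sd = 3, beta_sd = 2, disp_sd = 5), priors)
    cd <- colData(counts)
    zeroLib <- colSums(assay(counts, "counts")) == 0
    if (any(zeroLib))
        stop("all-zero library: ", paste(rownames(cd)[zeroLib], collapse = ", "))
    if (is.null(genotypes)) genotypes <- unique(cd$genotype)
    spike <- rowData(counts)$spike
    if (is.null(spike)) spike <- rep(FALSE, nrow(counts))
    bins <- rowRanges(counts)[!spike]
    masked <- maskFlags(bins, mask)
    out <- list()
    for (gi in seq_along(genotypes)) {
        g <- genotypes[[gi]]
        inG <- cd$genotype == g
        if (!any(inG & cd$sample_type == "input") ||
            !any(inG & cd$sample_type == "extracted"))
            stop("genotype '", g, "' lacks input or extracted libraries")
        draws <- list()
        for (si in 1:2) {
            s <- c("+", "-")[si]
            libs <- which(inG & (cd$sample_type == "input" |
                (cd$sample_type == "extracted" & cd$strand == s)))
            y <- assay(counts, "counts")[!spike, libs, drop = FALSE]
            cc <- cd$size_factor[libs]
            isExt <- cd$sample_type[libs] == "extracted"
            set.seed(as.integer((seed + 7919L * gi + 104729L * si) %% .Machine$integer.max))
            fit <- fitEnrichmentBins(y, cc, isExt, pr, engine, nDraws,
                skip = masked)
            draws[[s]] <- fit$beta / LN2
        }
        out[[g]] <- new("EnrichmentPosterior", bins = granges(bins),
            genotype = g, draws = draws, masked = masked,
            engine = engine, seed = as.integer(seed))
    }
    out
}

## Core per-bin inference; y is bins x libraries. Returns draws of gamma
## (natural-log enrichment) as a bins x nDraws matrix with NA rows where
## `skip` is TRUE.
fitEnrichmentBins <- function(y, sizeFactors, isExt, pr, engine, nDraws,
                              skip = NULL) {
    n <- nrow(y); L <- ncol(y)
    if (is.null(skip)) skip <- rep(FALSE, n)
    a0 <- log(mean(y[!skip, !isExt, drop = FALSE]) + 0.5)
    sa2 <- pr$alpha_sd^2
    sg2 <- (pr$beta_sd * LN2)^2
    ## moment initialisation
    mInp <- pmax(rowSums(y[, !isExt, drop = FALSE]) / sum(sizeFactors[!isExt]), 0.25)
    mExt <- pmax(rowSums(y[, isExt, drop = FALSE]) / sum(sizeFactors[isExt]), 0.25)
    alpha <- log(mInp)
    gamma <- pmin(pmax(log(mExt / mInp), -6), 6)
    phi <- 100
    for (round in 1:3) {
        upd <- newtonAlphaGamma(y, sizeFactors, isExt, alpha, gamma, phi,
            a0, sa2, sg2, iter = 12L)
        alpha <- upd$alpha; gamma <- upd$gamma
        phi <- estimateDispersion(y[!skip, , drop = FALSE], sizeFactors,
            isExt, alpha[!skip], gamma[!skip], pr$disp_sd)
    }
    upd <- newtonAlphaGamma(y, sizeFactors, isExt, alpha, gamma, phi,
        a0, sa2, sg2, iter = 12L)
    alpha <- upd$alpha; gamma <- upd$gamma
    if (engine == "vi") {
        sdg <- sqrt(upd$varGamma)
        beta <- alpha2 <- NULL
        z <- matrix(rnorm(n * nDraws), n, nDraws)
        gd <- gamma + sdg * z
    } else {
        gd <- mcmcAlphaGamma(y, sizeFactors, isExt, alpha, gamma, phi,
            a0, sa2, sg2, sdA = sqrt(upd$varAlpha), sdG = sqrt(upd$varGamma),
            nDraws = nDraws)
    }
    gd[skip, ] <- NA_real_
    list(beta = gd, phi = phi)
}

## Damped Newton solve for (alpha, gamma) in every bin at once, with the
## Gaussian priors folded into the score and curvature. Returns posterior
## modes and the marginal variances from the inverse 2x2 Hessian.
newtonAlphaGamma <- function(y, cc, isExt, alpha, gamma, phi, a0, sa2, sg2,
                             iter = 10L) {
    xe <- as.numeric(isExt)
    for (it in seq_len(iter)) {
        eta <- outer(alpha, log(cc), "+") + outer(gamma, xe)
        mu <- exp(eta)
        g <- (y - mu) * phi / (mu + phi)
        h <- mu * phi * (phi + y) / (mu + phi)^2
        gA <- rowSums(g) - (alpha - a0) / sa2
        gG <- rowSums(g[, isExt, drop = FALSE]) - gamma / sg2
        A <- rowSums(h) + 1 / sa2
        B <- rowSums(h[, isExt, drop = FALSE])
        C <- B + 1 / sg2
        det <- A * C - B^2
        dA <- (gA * C - gG * B) / det
        dG <- (A * gG - B * gA) / det
        dA <- pmin(pmax(dA, -2), 2)
        dG <- pmin(pmax(dG, -2), 2)
        alpha <- alpha + dA
        gamma <- gamma + dG
        if (max(abs(dA), abs(dG)) < 1e-10) break
    }
    list(alpha = alpha, gamma = gamma, varAlpha = C / det, varGamma = A / det)
}

## Penalised profile estimate of the genotype-level NB size phi: maximise
## the likelihood at the current (alpha, gamma) over log overdispersion,
## with a half-Normal(0, dispSd^2) prior on 1/phi.
estimateDispersion <- function(y, cc, isExt, alpha, gamma, dispSd) {
    xe <- as.numeric(isExt)
    mu <- exp(outer(alpha, log(cc), "+") + outer(gamma, xe))
    obj <- function(logd) {
        d <- exp(logd)
        sum(dnbinom(y, size = 1 / d, mu = mu, log = TRUE)) +
            dnorm(d, 0, dispSd, log = TRUE) + logd
    }
    opt <- optimize(obj, lower = log(1e-6), upper = log(20), maximum = TRUE)
    1 / exp(opt$maximum)
}

## Vectorised random-walk Metropolis over all bins jointly (bins are
## conditionally independent). Proposal scales come from the Gaussian
## approximation; 500 warmup iterations then thinned draws.
mcmcAlphaGamma <- function(y, cc, isExt, alpha, gamma, phi, a0, sa2, sg2,
                           sdA, sdG, nDraws, warmup = 500L, thin = 2L) {
    n <- length(alpha)
    xe <- as.numeric(isExt)
    logpost <- function(al, ga) {
        mu <- exp(outer(al, log(cc), "+") + outer(ga, xe))
        rowSums(dnbinom(y, size = phi, mu = mu, log = TRUE)) -
            (al - a0)^2 / (2 * sa2) - ga^2 / (2 * sg2)
    }
    lp <- logpost(alpha, gamma)
    sc <- 2.4 / sqrt(2)
    out <- matrix(NA_real_, n, nDraws)
    col <- 0L
    niter <- warmup + nDraws * thin
    for (i in seq_len(niter)) {
        alProp <- alpha + rnorm(n, 0, sc * sdA)
        gaProp <- gamma + rnorm(n, 0, sc * sdG)
        lpProp <- logpost(alProp, gaProp)
        acc <- log(runif(n)) < lpProp - lp
        alpha[acc] <- alProp[acc]
        gamma[acc] <- gaProp[acc]
        lp[acc] <- lpProp[acc]
        if (i > warmup && (i - warmup) %% thin == 0L) {
            col <- col + 1L
            out[, col] <- gamma
        }
    }
    out
}

#' Spike-in size factors
#'
#' Library size factors from counts over flagged spike-in reference bins:
#' each library's spike total divided by the geometric mean of all
#' libraries' spike totals, so the factors are centred at 1 and independent
#' of genome-wide signal changes.
#'
#' @param counts a \linkS4class{StrandedCountMatrix} with flagged spike
#'   bins.
#' @return named positive numeric vector, one factor per library.
#' @export
sizeFactorsFromSpike <- function(counts) {
    spike <- rowData(counts)$spike
    if (is.null(spike) || !any(spike)) stop("no spike bins flagged")
    tot <- colSums(assay(counts, "counts")[spike, , drop = FALSE])
    if (any(tot == 0))
        stop("zero spike counts in library: ",
            paste(names(tot)[tot == 0], collapse = ", "))
    tot / exp(mean(log(tot)))
}

#' Apply size factors to a count matrix
#'
#' @param counts a \linkS4class{StrandedCountMatrix}.
#' @param sizeFactors named vector matching the library names.
#' @return the updated \code{StrandedCountMatrix}.
#' @export
applySizeFactors <- function(counts, sizeFactors) {
    stopifnot(all(colnames(counts) %in% names(sizeFactors)))
    colData(counts)$size_factor <- unname(sizeFactors[colnames(counts)])
    validObject(counts)
    counts
}

#' Posterior contrast between two genotypes
#'
#' Per-bin draws of the log2-enrichment difference a - b, paired by draw
#' index so posterior correlation structure within each fit is preserved.
#'
#' @param a,b \linkS4class{EnrichmentPosterior} objects on identical bins.
#' @return an \linkS4class{EnrichmentPosterior} labelled
#'   \code{"<a>_vs_<b>"}.
#' @export
contrast <- function(a, b) {
    if (length(a@bins) != length(b@bins))
        stop("bin mismatch between posteriors: ", length(a@bins),
            " vs ", length(b@bins), " bins")
    same <- seqnames(a@bins) == seqnames(b@bins) &
        start(a@bins) == start(b@bins) & end(a@bins) == end(b@bins)
    if (!all(same)) {
        first <- which(!same)[1]
        stop("bin mismatch between posteriors at bin ", first, ": ",
            as.character(granges(a@bins)[first]))
    }
    nd <- min(ncol(a@draws[["+"]]), ncol(b@draws[["+"]]))
    draws <- lapply(c("+", "-"), function(s)
        a@draws[[s]][, seq_len(nd), drop = FALSE] -
            b@draws[[s]][, seq_len(nd), drop = FALSE])
    names(draws) <- c("+", "-")
    new("EnrichmentPosterior", bins = a@bins,
        genotype = paste0(a@genotype, "_vs_", b@genotype), draws = draws,
        masked = a@masked | b@masked, engine = a@engine, seed = a@seed)
}

#' Posterior summary table of an enrichment fit
#'
#' @param ep an \linkS4class{EnrichmentPosterior}.
#' @return \code{data.frame} with contig, start, end, strand, posterior
#'   mean, 5% and 95% quantiles (the 90% interval) and the masked flag.
#' @export
enrichmentSummary <- function(ep) {
    do.call(rbind, lapply(c("+", "-"), function(s) {
        d <- ep@draws[[s]]
        data.frame(contig = as.character(seqnames(ep@bins)),
            start = start(ep@bins), end = end(ep@bins), strand = s,
            mean = rowMeans(d),
            q05 = apply(d, 1, quantile, 0.05, na.rm = FALSE),
            q95 = apply(d, 1, quantile, 0.95, na.rm = FALSE),
            masked = ep@masked)
    }))
}

#' Extract one summary statistic of an enrichment posterior as a track
#'
#' @param ep an \linkS4class{EnrichmentPosterior}.
#' @param strand \code{"+"} or \code{"-"}.
#' @param stat \code{"mean"}, \code{"q05"}, \code{"q95"} or \code{"z"}
#'   (robust z of the posterior mean).
#' @return \code{GRanges} track with a \code{score} column.
#' @export
enrichmentTrack <- function(ep, strand = c("+", "-"),
                            stat = c("mean", "q05", "q95", "z")) {
    strand <- match.arg(strand)
    stat <- match.arg(stat)
    d <- ep@draws[[strand]]
    v <- switch(stat,
        mean = rowMeans(d),
        q05 = apply(d, 1, quantile, 0.05),
        q95 = apply(d, 1, quantile, 0.95),
        z = robustZ(rowMeans(d)))
    out <- granges(ep@bins)
    mcols(out)$score <- v
    out
}

#' qPCR delta-delta-Cq relative to a spike-in reference locus
#'
#' Pull-down efficiency at a locus referenced to an unchanging spike-in
#' locus: \code{(Cq_pulldown - Cq_input)} at the target minus the same
#' difference at the reference, with replicate means and an SE propagated
#' from the replicate spread.
#'
#' @param table data.frame with columns \code{locus}, \code{genotype},
#'   \code{fraction} (\code{"pulldown"}/\code{"input"}), \code{replicate},
#'   \code{cq}.
#' @param locus target locus label.
#' @param genotype genotype label.
#' @param reference reference locus label.
#' @return list with \code{ddcq} (cycles) and \code{se}.
#' @export
#' @examples
#' tab <- data.frame(locus = rep(c("L", "ref"), each = 2),
#'     genotype = "WT", fraction = c("pulldown", "input"),
#'     replicate = 1, cq = c(20, 18, 22, 21))
#' ddcq(tab, "L", "WT", reference = "ref")$ddcq  # 1.0
ddcq <- function(table, locus, genotype, reference) {
    pick <- function(loc, frac) {
        v <- table$cq[table$locus == loc & table$genotype == genotype &
            table$fraction == frac]
        if (!length(v))
            stop("no ", frac, " Cq values for locus '", loc,
                "', genotype '", genotype, "'")
        v
    }
    parts <- list(pick(locus, "pulldown"), pick(locus, "input"),
        pick(reference, "pulldown"), pick(reference, "input"))
    est <- mean(parts[[1]]) - mean(parts[[2]]) -
        (mean(parts[[3]]) - mean(parts[[4]]))
    vr <- sum(vapply(parts, function(v)
        if (length(v) > 1) var(v) / length(v) else 0, numeric(1)))
    list(ddcq = est, se = sqrt(vr))
}
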