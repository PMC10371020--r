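## Shared Bayesian machinery: a mode + curvature independence sampler for
## log-concave GLM posteriors, split-Rhat / ESS diagnostics, Pareto-smoothed
## importance-sampling LOO, and ROPE-referenced Bayes factors.

logSumExp <- function(x) {
    m <- max(x)
    m + log(sum(exp(x - m)))
}

## Multivariate-t proposal centred at the posterior mode with scale from the
## inverse Hessian. For log-concave posteriors (Poisson/Gaussian GLMs with
## Normal priors) an independence Metropolis-Hastings chain with this
## proposal mixes rapidly and its acceptance rate is itself a diagnostic.
mvtPropose <- function(n, mu, cholSigma, df = 7) {
    p <- length(mu)
    z <- matrix(rnorm(n * p), n, p) %*% cholSigma
    u <- sqrt(df / rchisq_(n, df))
    sweep(z * u, 2, mu, "+")
}

rchisq_ <- function(n, df) 2 * rgamma(n, df / 2)

mvtLogDens <- function(x, mu, cholSigmaInv, logDetSigma, df = 7) {
    p <- length(mu)
    z <- sweep(x, 2, mu) %*% cholSigmaInv
    q <- rowSums(z^2)
    lgamma((df + p) / 2) - lgamma(df / 2) - (p / 2) * log(df * pi) -
        0.5 * logDetSigma - ((df + p) / 2) * log1p(q / df)
}

#' Sample a log-concave posterior by independence Metropolis-Hastings
#'
#' Finds the posterior mode and curvature with BFGS, builds a
#' multivariate-t proposal from the Laplace approximation, and runs several
#' independent chains of independence MH. Errors when the split-Rhat
#' convergence diagnostic exceeds \code{rhatMax}.
#'
#' @param logPost function(theta) returning the unnormalised log posterior.
#' @param init initial parameter vector (names kept for the draws).
#' @param nDraws total posterior draws across chains.
#' @param nChains number of chains (>= 2 for Rhat).
#' @param df proposal degrees of freedom.
#' @param rhatMax convergence threshold (default 1.05).
#' @param warmup per-chain draws discarded before keeping.
#' @return list with \code{draws} (nDraws x p matrix), \code{mode},
#'   \code{Sigma}, \code{accept}, \code{rhat}, \code{ess}.
#' @keywords internal
sampleIMH <- function(logPost, init, nDraws = 4000, nChains = 4, df = 7,
                      rhatMax = 1.05, warmup = 200) {
    p <- length(init)
    fit <- optim(init, function(th) -logPost(th), method = "BFGS",
        hessian = TRUE, control = list(maxit = 500, reltol = 1e-12))
    H <- fit$hessian
    Sigma <- tryCatch(solve(H), error = function(e)
        solve(H + diag(1e-8, p)))
    Sigma <- (Sigma + t(Sigma)) / 2
    ev <- eigen(Sigma, symmetric = TRUE)
    if (any(ev$values <= 0))
        Sigma <- ev$vectors %*% diag(pmax(ev$values, 1e-10), p) %*% t(ev$vectors)
    perChain <- ceiling(nDraws / nChains)
    ## widen the proposal progressively: skewed small-count posteriors need
    ## a fatter envelope than the Gaussian curvature suggests
    for (inflate in c(1.2, 3, 8)) {
        ch <- chol(Sigma * inflate)
        chInv <- solve(ch)
        logDet <- 2 * sum(log(diag(ch)))
        keep <- array(NA_real_, dim = c(perChain, nChains, p))
        acc <- 0L
        tot <- 0L
        for (cc in seq_len(nChains)) {
            niter <- warmup + perChain
            prop <- mvtPropose(niter, fit$par, ch, df)
            lq <- mvtLogDens(prop, fit$par, chInv, logDet, df)
            lp <- apply(prop, 1, logPost)
            x <- fit$par
            lpx <- logPost(x)
            lqx <- mvtLogDens(matrix(x, 1), fit$par, chInv, logDet, df)[1]
            lu <- log(runif(niter))
            for (i in seq_len(niter)) {
                if (is.finite(lp[i]) &&
                    lu[i] < (lp[i] - lq[i]) - (lpx - lqx)) {
                    x <- prop[i, ]; lpx <- lp[i]; lqx <- lq[i]
                    if (i > warmup) acc <- acc + 1L
                }
                if (i > warmup) keep[i - warmup, cc, ] <- x
            }
            tot <- tot + perChain
        }
        rhat <- vapply(seq_len(p), function(j) splitRhat(keep[, , j]), numeric(1))
        ess <- vapply(seq_len(p), function(j) essChains(keep[, , j]), numeric(1))
        if (all(rhat <= rhatMax, na.rm = TRUE)) break
    }
    if (any(rhat > rhatMax, na.rm = TRUE))
        stop(sprintf(
            "sampler did not converge: max split-Rhat %.3f > %.2f (ess min %.0f)",
            max(rhat, na.rm = TRUE), rhatMax, min(ess, na.rm = TRUE)))
    draws <- do.call(rbind, lapply(seq_len(nChains), function(cc) keep[, cc, , drop = TRUE]))
    draws <- matrix(draws, ncol = p)
    colnames(draws) <- names(init)
    draws <- draws[seq_len(min(nrow(draws), nDraws)), , drop = FALSE]
    list(draws = draws, mode = fit$par, Sigma = Sigma,
        accept = acc / tot, rhat = rhat, ess = ess)
}

## Split-Rhat of Gelman et al.: each chain halved, between/within variance
## ratio across the split chains.
splitRhat <- function(x) {  # iterations x chains
    n <- nrow(x) %/% 2L
    if (n < 2L) return(NA_real_)
    sp <- cbind(x[seq_len(n), , drop = FALSE],
        x[(n + 1L):(2L * n), , drop = FALSE])
    m <- ncol(sp)
    mu <- colMeans(sp)
    W <- mean(apply(sp, 2, var))
    B <- n * var(mu)
    if (W == 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
}

## Effective sample size via Geyer's initial positive sequence, pooled over
## chains.
essChains <- function(x) {
    n <- nrow(x); m <- ncol(x)
    if (var(as.vector(x)) == 0) return(n * m)
    rho <- rowMeans(vapply(seq_len(m), function(cc) {
        xc <- x[, cc] - mean(x[, cc])
        a <- stats::acf(xc, lag.max = min(n - 1L, 200L), plot = FALSE,
            demean = FALSE)$acf[, 1, 1]
        a
    }, numeric(min(n - 1L, 200L) + 1L)))
    ## a fully stuck chain yields NaN autocorrelations (0/0)
    rho[!is.finite(rho)] <- 0
    s <- 0
    t <- 1L
    while (t + 1L <= length(rho)) {
        pair <- rho[t] + rho[t + 1L]
        if (pair < 0) break
        s <- s + pair
        t <- t + 2L
    }
    max(1, n * m / (1 + 2 * max(0, s - rho[1])))
}

#' Pareto-smoothed importance-sampling LOO
#'
#' Computes the pointwise expected log predictive density under
#' leave-one-out cross-validation from a posterior log-likelihood matrix,
#' stabilising the importance weights by fitting a generalised Pareto
#' distribution to their upper tail.
#'
#' @param logLik draws x observations matrix of pointwise log-likelihoods.
#' @return list with \code{elpd} (total), \code{pointwise} vector,
#'   \code{se}, and \code{pareto_k} tail-shape diagnostics (values above
#'   0.7 flag unreliable observations and are reported in a warning).
#' @export
psisLoo <- function(logLik) {
    S <- nrow(logLik)
    n <- ncol(logLik)
    pointwise <- numeric(n)
    k <- numeric(n)
    M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
    for (i in seq_len(n)) {
        lw <- -logLik[, i]
        lw <- lw - max(lw)
        ord <- order(lw)
        tailIdx <- ord[(S - M + 1L):S]
        cutoff <- lw[ord[S - M]]
        exceed <- exp(lw[tailIdx]) - exp(cutoff)
        gp <- gpdFit(sort(exceed))
        k[i] <- gp$k
        if (is.finite(gp$k)) {
            pr <- (seq_len(M) - 0.5) / M
            sm <- log(exp(cutoff) + qGPD(pr, gp$k, gp$sigma))
            lw[tailIdx[order(lw[tailIdx])]] <- pmin(sm, 0)
        }
        pointwise[i] <- logSumExp(lw + logLik[, i]) - logSumExp(lw)
    }
    if (any(k > 0.7))
        warning(sum(k > 0.7), " observation(s) with Pareto k > 0.7: ",
            paste(head(which(k > 0.7), 10), collapse = ", "))
    list(elpd = sum(pointwise), pointwise = pointwise,
        se = sqrt(n) * sd(pointwise), pareto_k = k)
}

## Zhang & Stephens (2009) posterior-mean estimate of the generalised
## Pareto shape, as used for PSIS tail smoothing.
gpdFit <- function(x) {
    n <- length(x)
    if (n < 5L || all(x == x[1]))
        return(list(k = Inf, sigma = NA_real_))
    prior <- 3
    m <- 30L + floor(sqrt(n))
    jj <- seq_len(m)
    xstar <- x[max(1L, floor(n / 4 + 0.5))]
    theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / prior / xstar
    profLik <- vapply(theta, function(th) {
        kk <- -mean(log1p(-th * x))
        n * (log(th / kk) + kk - 1)
    }, numeric(1))
    w <- 1 / vapply(jj, function(j) sum(exp(profLik - profLik[j])), numeric(1))
    thetaHat <- sum(theta * w)
    k <- -mean(log1p(-thetaHat * x))
    list(k = k, sigma = k / thetaHat)
}

qGPD <- function(p, k, sigma) {
    if (abs(k) < 1e-12) return(-sigma * log1p(-p))
    sigma * expm1(-k * log1p(-p)) / k
}

#' Compare two fitted models by PSIS-LOO
#'
#' @param fitFull,fitReduced fit objects carrying a \code{logLik} draws x
#'   observations matrix on identical observations (as returned by
#'   \code{\link{fitMutationRegression}} or \code{\link{fitBayesGLM}}).
#' @return list with \code{elpd_diff} (full minus reduced), \code{se_diff},
#'   and the two \code{\link{psisLoo}} results.
#' @export
looCompare <- function(fitFull, fitReduced) {
    llF <- fitFull$logLik
    llR <- fitReduced$logLik
    if (ncol(llF) != ncol(llR))
        stop("models were fit on different observations (",
            ncol(llF), " vs ", ncol(llR), ")")
    looF <- psisLoo(llF)
    looR <- psisLoo(llR)
    d <- looF$pointwise - looR$pointwise
    list(elpd_diff = sum(d), se_diff = sqrt(length(d)) * sd(d),
        loo_full = looF, loo_reduced = looR)
}

#' Bayes factors for a substantial versus a near-zero effect
#'
#' Partitions the parameter line by a region of practical equivalence
#' (ROPE) of half-width \code{rope} around zero. \code{K} is the posterior
#' odds of a substantial effect -- the parameter beyond the ROPE on its
#' dominant posterior side -- against the near-zero hypothesis, divided by
#' the same odds under the prior. \code{K0} is the analogous evidence ratio
#' for the near-zero hypothesis against its complement. Posterior
#' probabilities are estimated from the draws; prior probabilities are
#' exact Normal tail areas. Draw cells that come up empty are clamped to
#' one draw's worth of mass (1/S) with a warning, bounding the estimable
#' Bayes factor by the draw count.
#'
#' @param draws posterior draws of the coefficient.
#' @param prior list with \code{mean} and \code{sd} of its Normal prior.
#' @param rope ROPE half-width (> 0) on the coefficient scale.
#' @param term coefficient name carried into the result.
#' @return an \linkS4class{EffectPosterior}.
#' @export
#' @examples
#' bayesFactors(rnorm(4000, 1, 0.1), prior = list(mean = 0, sd = 2),
#'     rope = 0.05)
bayesFactors <- function(draws, prior = list(mean = 0, sd = 2), rope = 0.05,
                         term = "beta") {
    if (rope <= 0) stop("ROPE half-width must be positive")
    S <- length(draws)
    clamp <- function(p) {
        if (p == 0) {
            warning("empty posterior cell clamped to 1/", S, " for '", term, "'")
            1 / S
        } else p
    }
    pPos <- mean(draws > rope)
    pNeg <- mean(draws < -rope)
    sgn <- if (pPos >= pNeg) 1 else -1
    postEff <- clamp(if (sgn > 0) pPos else pNeg)
    post0 <- clamp(mean(abs(draws) <= rope))
    prior0 <- pnorm(rope, prior$mean, prior$sd) -
        pnorm(-rope, prior$mean, prior$sd)
    priorEff <- if (sgn > 0) pnorm(rope, prior$mean, prior$sd, lower.tail = FALSE)
        else pnorm(-rope, prior$mean, prior$sd)
    K <- (postEff / post0) / (priorEff / prior0)
    postC <- clamp(1 - mean(abs(draws) <= rope))
    K0 <- (post0 / postC) / (prior0 / (1 - prior0))
    new("EffectPosterior", term = term, draws = as.numeric(draws),
        K = K, K0 = K0, category = evidenceCategory(K),
        category0 = evidenceCategory(K0), rope = rope, prior = prior)
}

#' Evidence category for a Bayes factor
#'
#' @param K Bayes factor.
#' @return \code{"none"} (K < 3), \code{"positive"} (3 <= K < 20),
#'   \code{"strong"} (20 <= K < 150) or \code{"very strong"} (K >= 150).
#' @export
evidenceCategory <- function(K) {
    cut(K, breaks = c(-Inf, 3, 20, 150, Inf), right = FALSE,
        labels = c("none", "positive", "strong", "very strong")) |>
        as.character()
}

#' Fit a Bayesian GLM by mode + curvature independence sampling
#'
#' Poisson regression with a log link and exposure offset, or a Gaussian
#' linear model with a half-Normal prior on the residual scale.
#' Coefficients get independent Normal(0, priorSd^2) priors. Posterior
#' draws come from \code{\link{sampleIMH}}; the pointwise log-likelihood
#' matrix needed for PSIS-LOO is stored on the fit.
#'
#' @param X design matrix (must be full column rank).
#' @param y response vector (counts for Poisson).
#' @param offset log-exposure offset (Poisson only).
#' @param family \code{"poisson"} or \code{"gaussian"}.
#' @param priorSd coefficient prior SD (default 2).
#' @param sigmaPriorSd half-Normal scale for the Gaussian residual SD.
#' @param nDraws,nChains,seed sampler controls.
#' @return list with \code{draws}, \code{logLik}, \code{diagnostics},
#'   \code{terms}, \code{family}.
#' @export
fitBayesGLM <- function(X, y, offset = NULL, family = c("poisson", "gaussian"),
                        priorSd = 2, sigmaPriorSd = 5,
                        nDraws = 4000, nChains = 4, seed = 1) {
    family <- match.arg(family)
    X <- as.matrix(X)
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
        stop("rank-deficient design; collinear column(s): ",
            paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]],
                collapse = ", "))
    n <- nrow(X); p <- ncol(X)
    if (is.null(offset)) offset <- rep(0, n)
    set.seed(seed)
    if (family == "poisson") {
        logPost <- function(th) {
            eta <- drop(X %*% th) + offset
            if (any(eta > 50)) return(-Inf)
            sum(y * eta - exp(eta)) + sum(dnorm(th, 0, priorSd, log = TRUE))
        }
        init <- qr.coef(qrX, log((y + 0.5) / exp(offset)))
        init[!is.finite(init)] <- 0
        names(init) <- colnames(X)
        fit <- sampleIMH(logPost, init, nDraws = nDraws, nChains = nChains)
        eta <- fit$draws %*% t(X)
        eta <- sweep(eta, 2, offset, "+")
        logLik <- matrix(dpois(rep(y, each = nrow(eta)), exp(eta), log = TRUE),
            nrow(eta), n)
    } else {
        init <- c(qr.coef(qrX, y), log_sigma = log(max(sd(y), 1e-3)))
        names(init) <- c(colnames(X), "log_sigma")
        logPost <- function(th) {
            beta <- th[seq_len(p)]
            sigma <- exp(th[p + 1L])
            r <- y - drop(X %*% beta)
            sum(dnorm(r, 0, sigma, log = TRUE)) +
                sum(dnorm(beta, 0, priorSd, log = TRUE)) +
                dnorm(sigma, 0, sigmaPriorSd, log = TRUE) + th[p + 1L]
        }
        fit <- sampleIMH(logPost, init, nDraws = nDraws, nChains = nChains)
        mu <- fit$draws[, seq_len(p), drop = FALSE] %*% t(X)
        sig <- exp(fit$draws[, p + 1L])
        logLik <- matrix(dnorm(rep(y, each = nrow(mu)), mu, sig, log = TRUE),
            nrow(mu), n)
    }
    list(draws = fit$draws, logLik = logLik,
        diagnostics = list(rhat = fit$rhat, ess = fit$ess,
            accept = fit$accept),
        terms = colnames(X), family = family, seed = seed)
}
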