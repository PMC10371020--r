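## Track-level transforms: robust z-scores, rolling medians, CPM coverage,
## replication slope profiling and event-density curves.
##
## Tracks are GRanges of sorted, uniform-width bins with a numeric `score`
## column; missing values are NA entries, never dropped rows. Most
## operations also accept a bare numeric vector.

#' Robust z-score of a track
#'
#' Centres on the median and scales by 1.4826 x MAD, the consistency-
#' corrected median absolute deviation, so that the score is comparable to
#' a standard z under normality but insensitive to heavy tails. Missing
#' values are ignored in the centre/scale and stay missing.
#'
#' @param x numeric vector, or a \code{GRanges} track with a \code{score}
#'   column.
#' @param scale \code{"mad"} (default) or \code{"iqr"}: when the MAD is
#'   exactly zero (e.g. a majority-constant track), \code{"mad"} errors and
#'   advises switching to the IQR-based scale (IQR/1.349).
#' @return same shape as \code{x}, z-scored.
#' @export
#' @examples
#' robustZ(c(1, 2, 3, 4, 100))
robustZ <- function(x, scale = c("mad", "iqr")) {
    scale <- match.arg(scale)
    if (is(x, "GRanges")) {
        mcols(x)$score <- robustZ(mcols(x)$score, scale = scale)
        return(x)
    }
    ok <- !is.na(x)
    if (sum(ok) < 2L) stop("need >= 2 non-missing values")
    med <- median(x[ok])
    s <- if (scale == "mad") {
        m <- median(abs(x[ok] - med))
        if (m == 0)
            stop("MAD is zero; rerun with scale = \"iqr\" for an IQR-based scale")
        1.4826 * m
    } else {
        iq <- IQR(x[ok])
        if (iq == 0) stop("IQR is zero; no robust scale available")
        iq / 1.349
    }
    (x - med) / s
}

#' Centered rolling median with truncated edges
#'
#' Smooths a binned track with a centered window of
#' \code{ceiling(window / binWidth)} bins, incremented to the next odd
#' count when even. Edge bins use the truncated (shrinking) window so the
#' output stays aligned with the input; missing values are excluded from
#' each window's median.
#'
#' @param x numeric vector or \code{GRanges} track.
#' @param window window span in bp (>= bin width).
#' @param binWidth bin width in bp; inferred from a \code{GRanges} input.
#' @return same shape as \code{x}, smoothed.
#' @export
#' @examples
#' rollingMedian(c(1, 5, 2, 8, 3), window = 3, binWidth = 1)
rollingMedian <- function(x, window, binWidth = NULL) {
    if (is(x, "GRanges")) {
        bw <- unique(width(x))
        stopifnot(length(bw) == 1L)
        mcols(x)$score <- rollingMedian(mcols(x)$score, window, binWidth = bw)
        return(x)
    }
    if (is.null(binWidth)) stop("binWidth required for numeric input")
    if (window < binWidth) stop("window must be >= bin width")
    k <- ceiling(window / binWidth)
    if (k %% 2 == 0) k <- k + 1L
    h <- (k - 1L) %/% 2L
    n <- length(x)
    vapply(seq_len(n), function(i) {
        w <- x[max(1L, i - h):min(n, i + h)]
        w <- w[!is.na(w)]
        if (length(w)) median(w) else NA_real_
    }, numeric(1))
}

#' Log2 counts-per-million coverage track
#'
#' Converts binned read counts to log2 CPM with a pseudocount (in reads)
#' added before scaling, so zero-count bins remain finite. The total
#' mapped-read count and pseudocount are recorded in the track metadata.
#'
#' @param bins \code{GRanges} of uniform-width bins.
#' @param counts non-negative read counts per bin.
#' @param pseudocount reads added to every bin before log2 (default 0.5).
#' @return \code{GRanges} track with \code{score} = log2 CPM.
#' @export
cpmTrack <- function(bins, counts, pseudocount = 0.5) {
    stopifnot(length(bins) == length(counts), all(counts >= 0))
    total <- sum(counts)
    mcols(bins)$score <- log2((counts + pseudocount) * 1e6 / total)
    metadata(bins)$total_reads <- total
    metadata(bins)$pseudocount <- pseudocount
    bins
}

#' Replication-slope z-score of a coverage profile
#'
#' In an exponentially replicating population, sequencing coverage decays
#' from origin to terminus; the local slope of smoothed log2 CPM along the
#' direction of fork travel is a proxy for replication speed, with steeply
#' negative slopes marking regions where forks progress with difficulty.
#' The coverage is first smoothed with \code{\link{rollingMedian}}, a
#' least-squares slope is fit in a centered window around every bin
#' (truncated and flagged at contig edges), the slope is signed along fork
#' travel using the replichore map, and the slope track is converted to
#' robust z-scores (falling back to an IQR scale, then to plain centring,
#' when the slope distribution is degenerate).
#'
#' @param cov \code{GRanges} coverage track of log2 CPM (see
#'   \code{\link{cpmTrack}}).
#' @param rep \linkS4class{ReplichoreMap}.
#' @param smoothBp rolling-median smoothing span (default 10 kb).
#' @param slopeBp slope-fitting window span (default 10 kb; must cover
#'   >= 3 bins).
#' @return \code{GRanges} with \code{score} = slope z, plus metadata columns
#'   \code{slope} (log2 CPM per kb along fork travel) and \code{truncated}.
#' @export
replicationSlopeZ <- function(cov, rep, smoothBp = 10000, slopeBp = 10000) {
    bw <- unique(width(cov))
    stopifnot(length(bw) == 1L)
    if (slopeBp < 3 * bw) stop("slope window must span >= 3 bins")
    sm <- rollingMedian(mcols(cov)$score, smoothBp, binWidth = bw)
    k <- ceiling(slopeBp / bw)
    if (k %% 2 == 0) k <- k + 1L
    h <- (k - 1L) %/% 2L
    n <- length(sm)
    pos <- (start(cov) + end(cov)) / 2
    slope <- numeric(n)
    trunc <- logical(n)
    for (i in seq_len(n)) {
        idx <- max(1L, i - h):min(n, i + h)
        trunc[i] <- length(idx) < k
        xi <- pos[idx]; yi <- sm[idx]
        ok <- !is.na(yi)
        if (sum(ok) < 3L) { slope[i] <- NA_real_; next }
        xc <- xi[ok] - mean(xi[ok]); yc <- yi[ok] - mean(yi[ok])
        slope[i] <- sum(xc * yc) / sum(xc^2)
    }
    slope <- slope * forkDirection(pos, rep) * 1000  # per kb along fork travel
    ## robust z with a floating-point-aware degeneracy guard: an exactly
    ## linear profile yields a constant slope whose MAD is numerical noise
    med <- median(slope, na.rm = TRUE)
    dev <- abs(slope - med)
    tol <- 1e-8 * (1 + abs(med))
    madS <- median(dev, na.rm = TRUE)
    iqrS <- IQR(slope, na.rm = TRUE) / 1.349
    z <- if (madS > tol) (slope - med) / (1.4826 * madS)
        else if (iqrS > tol) (slope - med) / iqrS
        else ifelse(dev <= tol, 0, slope - med)
    out <- granges(cov)
    mcols(out)$score <- z
    mcols(out)$slope <- slope
    mcols(out)$truncated <- trunc
    out
}

#' Gaussian kernel density of genomic event positions
#'
#' Density curve of point events (e.g. transversion positions) along the
#' genome, evaluated on a 512-point grid. The bandwidth is
#' \code{adjust} times the classical rule of thumb
#' 0.9 x min(sd, IQR/1.34) x n^(-1/5).
#'
#' @param positions numeric event positions (>= 2, not all identical).
#' @param genomeLength optional; when given, the grid spans
#'   \code{[0, genomeLength]}.
#' @param adjust bandwidth multiplier (default 0.2 for locus-scale detail).
#' @return data.frame with columns \code{x}, \code{y} and attribute
#'   \code{bw} (the bandwidth used).
#' @export
eventDensity <- function(positions, genomeLength = NULL, adjust = 0.2) {
    if (length(positions) < 2L) stop("need >= 2 positions")
    if (length(unique(positions)) == 1L)
        stop("all positions identical: bandwidth would be zero")
    args <- list(x = positions, adjust = adjust, n = 512)
    if (!is.null(genomeLength)) { args$from <- 0; args$to <- genomeLength }
    d <- do.call(density, args)
    out <- data.frame(x = d$x, y = d$y)
    attr(out, "bw") <- d$bw
    out
}

#' Write a track to bedGraph
#'
#' Missing-value bins are omitted in the file (bedGraph has no NA
#' representation); \code{\link{readTrack}} against the same bin set
#' restores them as NA.
#'
#' @param track \code{GRanges} with a \code{score} column.
#' @param path output path.
#' @export
writeTrack <- function(track, path) {
    keep <- !is.na(mcols(track)$score)
    rtracklayer::export(track[keep], path, format = "bedGraph")
    invisible(path)
}

#' Read a bedGraph track
#'
#' @param path bedGraph file.
#' @param bins optional \code{GRanges} bin set to align to; bins absent
#'   from the file get NA scores.
#' @return \code{GRanges} with a \code{score} column.
#' @export
readTrack <- function(path, bins = NULL) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (is.null(bins)) return(gr)
    hits <- findOverlaps(bins, gr, type = "equal", ignore.strand = TRUE)
    score <- rep(NA_real_, length(bins))
    score[queryHits(hits)] <- mcols(gr)$score[subjectHits(hits)]
    out <- granges(bins)
    mcols(out)$score <- score
    out
}
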