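## S4 class definitions. Coordinates follow the Bioconductor convention
## throughout (GRanges, 1-based closed); BED/bedGraph conversion happens at
## the rtracklayer import/export boundary.

#' Replichore geometry of a (circular) bacterial chromosome
#'
#' Stores the origin (\emph{oriC}) and terminus (\emph{ter}) positions that
#' split a chromosome into its two replichores. Replication forks travel from
#' \emph{oriC} towards \emph{ter} on both arcs; on the arc where fork travel
#' runs in the direction of increasing coordinate, plus-strand genes are
#' transcribed codirectionally with replication, and the converse holds on
#' the other arc.
#'
#' @slot contig chromosome name.
#' @slot length chromosome length in bp.
#' @slot oriC,ter 1-based positions of the replication origin and terminus.
#' @slot circular whether the chromosome is circular.
#' @exportClass ReplichoreMap
setClass("ReplichoreMap",
    representation(contig = "character", length = "numeric",
        oriC = "numeric", ter = "numeric", circular = "logical"),
    prototype(circular = TRUE))

setValidity("ReplichoreMap", function(object) {
    msg <- NULL
    if (length(object@contig) != 1L) msg <- c(msg, "'contig' must be a single name")
    if (object@length <= 0) msg <- c(msg, "'length' must be positive")
    if (object@oriC == object@ter)
        msg <- c(msg, "oriC and ter must differ: replication direction undefined")
    if (object@oriC < 1 || object@oriC > object@length ||
        object@ter < 1 || object@ter > object@length)
        msg <- c(msg, "oriC and ter must lie within [1, length]")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn ReplichoreMap-class Constructor.
#' @param contig,length,oriC,ter,circular see slot descriptions.
#' @return A \code{ReplichoreMap} object.
#' @export
#' @examples
#' ReplichoreMap("chr", 4e6, oriC = 1, ter = 2e6)
ReplichoreMap <- function(contig, length, oriC, ter, circular = TRUE) {
    new("ReplichoreMap", contig = as.character(contig), length = as.numeric(length),
        oriC = as.numeric(oriC), ter = as.numeric(ter), circular = circular)
}

setMethod("show", "ReplichoreMap", function(object) {
    cat("ReplichoreMap on", object@contig, "(", object@length, "bp )\n")
    cat("  oriC:", object@oriC, " ter:", object@ter,
        if (object@circular) " [circular]\n" else " [linear]\n")
})

#' Stranded per-bin count matrix for pull-down and input libraries
#'
#' A \linkS4class{RangedSummarizedExperiment} whose rows are fixed-width
#' genomic bins (plus, optionally, spike-in bins on a separate contig,
#' flagged in \code{rowData()$spike}) and whose columns are sequencing
#' libraries described by \code{colData()} columns \code{genotype},
#' \code{replicate}, \code{sample_type} (\code{"input"} or
#' \code{"extracted"}), \code{strand} (\code{"*"} for unstranded input,
#' \code{"+"}/\code{"-"} for strand-resolved pull-down counts) and
#' \code{size_factor}.
#'
#' @exportClass StrandedCountMatrix
setClass("StrandedCountMatrix",
    contains = "RangedSummarizedExperiment")

setValidity("StrandedCountMatrix", function(object) {
    msg <- NULL
    need <- c("genotype", "replicate", "sample_type", "strand", "size_factor")
    miss <- setdiff(need, colnames(colData(object)))
    if (length(miss))
        return(paste("missing colData columns:", paste(miss, collapse = ", ")))
    cnt <- assay(object, "counts")
    if (any(cnt < 0) || any(cnt != round(cnt)))
        msg <- c(msg, "counts must be non-negative integers")
    if (any(colData(object)$size_factor <= 0))
        msg <- c(msg, "size factors must be positive")
    if (!all(colData(object)$sample_type %in% c("input", "extracted")))
        msg <- c(msg, "sample_type must be 'input' or 'extracted'")
    ## uniform bin width within each contig
    w <- split(width(rowRanges(object)), as.character(seqnames(rowRanges(object))))
    if (any(vapply(w, function(x) length(unique(x)) > 1L, logical(1))))
        msg <- c(msg, "bin width must be uniform within each contig")
    for (g in unique(colData(object)$genotype)) {
        st <- colData(object)$sample_type[colData(object)$genotype == g]
        if (!all(c("input", "extracted") %in% st))
            msg <- c(msg, paste0("genotype '", g,
                "' needs at least one input and one extracted library"))
    }
    if (is.null(msg)) TRUE else msg
})

#' @describeIn StrandedCountMatrix-class Constructor.
#' @param bins \code{GRanges} of fixed-width bins.
#' @param counts integer matrix, bins x libraries.
#' @param libraries \code{data.frame}/\code{DataFrame} with columns
#'   \code{genotype}, \code{replicate}, \code{sample_type}, \code{strand} and
#'   optionally \code{size_factor} (default 1).
#' @param spike logical vector flagging spike-in reference bins
#'   (default: none).
#' @return A \code{StrandedCountMatrix}.
#' @export
StrandedCountMatrix <- function(bins, counts, libraries, spike = NULL) {
    libraries <- DataFrame(libraries)
    if (is.null(libraries$size_factor)) libraries$size_factor <- 1
    if (is.null(spike)) spike <- rep(FALSE, length(bins))
    mcols(bins)$spike <- spike
    rn <- libraries$name
    if (is.null(rn))
        rn <- paste(libraries$genotype, libraries$sample_type,
            libraries$strand, libraries$replicate, sep = ".")
    colnames(counts) <- rn
    rownames(libraries) <- rn
    se <- SummarizedExperiment(assays = list(counts = counts),
        rowRanges = bins, colData = libraries)
    new("StrandedCountMatrix", se)
}

#' Posterior log2-enrichment draws for one genotype (or a contrast)
#'
#' Per-bin, per-strand draws of the log2 enrichment coefficient beta from
#' the approximate posterior, with summaries derived only from the draws.
#'
#' @slot bins \code{GRanges} of the genomic bins (spike bins excluded).
#' @slot genotype label of the genotype, or \code{"a_vs_b"} for a contrast.
#' @slot draws named list with elements \code{"+"} and \code{"-"}, each a
#'   bins x draws matrix of log2 enrichment; masked bins are \code{NA}.
#' @slot masked logical flag per bin.
#' @slot engine \code{"vi"} or \code{"mcmc"}.
#' @slot seed integer seed the draws were generated with.
#' @exportClass EnrichmentPosterior
setClass("EnrichmentPosterior",
    representation(bins = "GRanges", genotype = "character",
        draws = "list", masked = "logical", engine = "character",
        seed = "integer"))

setValidity("EnrichmentPosterior", function(object) {
    msg <- NULL
    if (!all(c("+", "-") %in% names(object@draws)))
        msg <- c(msg, "draws must have '+' and '-' elements")
    for (s in c("+", "-"))
        if (nrow(object@draws[[s]]) != length(object@bins))
            msg <- c(msg, "draw matrices must have one row per bin")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "EnrichmentPosterior", function(object) {
    cat("EnrichmentPosterior for", object@genotype, "\n")
    cat(" ", length(object@bins), "bins x", ncol(object@draws[["+"]]),
        "draws per strand; engine:", object@engine, "\n")
    cat(" ", sum(object@masked), "masked bins\n")
})

#' Mutation-accumulation line dataset
#'
#' Holds MA-line metadata, per-line mutation events (transitions,
#' transversions, insertions, deletions), structural-variant (SV) calls from
#' an upstream caller, and the engineered-locus intervals of each line.
#'
#' @slot lines data.frame with columns \code{id}, \code{genotype},
#'   \code{generations}.
#' @slot events data.frame with columns \code{line_id}, \code{position},
#'   \code{ref}, \code{alt}, \code{class}.
#' @slot svs data.frame with columns \code{line_id}, \code{start},
#'   \code{end}, \code{type}.
#' @slot alterations data.frame with columns \code{line_id}, \code{start},
#'   \code{end}: the intended genetic alteration of each line.
#' @exportClass MALineDataset
setClass("MALineDataset",
    representation(lines = "data.frame", events = "data.frame",
        svs = "data.frame", alterations = "data.frame"))

setValidity("MALineDataset", function(object) {
    msg <- NULL
    if (nrow(object@lines) && any(object@lines$generations < 0))
        msg <- c(msg, "generations must be non-negative")
    ev <- object@events
    if (nrow(ev)) {
        sub <- nchar(ev$ref) == 1L & nchar(ev$alt) == 1L & ev$ref != "-" & ev$alt != "-"
        want <- classifyMutation(ev$ref[sub], ev$alt[sub])
        if (any(ev$class[sub] != want))
            msg <- c(msg, "substitution class inconsistent with ref/alt")
        if (!all(ev$class %in% c("transition", "transversion", "insertion", "deletion")))
            msg <- c(msg, "unknown mutation class")
        if (!all(ev$line_id %in% object@lines$id))
            msg <- c(msg, "events reference unknown line ids")
    }
    if (is.null(msg)) TRUE else msg
})

#' @describeIn MALineDataset-class Constructor; substitution classes are
#'   derived from ref/alt when the \code{class} column is absent.
#' @param lines,events,svs,alterations see slot descriptions.
#' @return A \code{MALineDataset}.
#' @export
MALineDataset <- function(lines, events, svs = NULL, alterations = NULL) {
    empty_sv <- data.frame(line_id = character(), start = numeric(),
        end = numeric(), type = character())
    empty_alt <- data.frame(line_id = character(), start = numeric(),
        end = numeric())
    if (is.null(svs) || !nrow(svs)) svs <- empty_sv
    if (is.null(alterations) || !nrow(alterations)) alterations <- empty_alt
    if (nrow(events) && is.null(events$class))
        events$class <- classifyMutation(events$ref, events$alt)
    new("MALineDataset", lines = as.data.frame(lines),
        events = as.data.frame(events), svs = as.data.frame(svs),
        alterations = as.data.frame(alterations))
}

setMethod("show", "MALineDataset", function(object) {
    cat("MALineDataset:", nrow(object@lines), "lines (",
        paste(unique(object@lines$genotype), collapse = ", "), ")\n")
    cat(" ", nrow(object@events), "mutation events;",
        nrow(object@svs), "SV calls\n")
    cat("  total generations:", sum(object@lines$generations), "\n")
})

#' Posterior evidence summary for one regression coefficient
#'
#' Posterior draws of a coefficient together with Bayes factors: \code{K}
#' weighs a substantial effect (|beta| beyond the region of practical
#' equivalence, ROPE, with the dominant posterior sign) against a
#' near-zero effect, and \code{K0} weighs the near-zero hypothesis against
#' its complement, both relative to the prior odds. Evidence categories
#' follow the conventional ladder: positive for K in [3, 20), strong for
#' [20, 150), very strong for K >= 150.
#'
#' @slot term coefficient name.
#' @slot draws numeric vector of posterior draws.
#' @slot K,K0 Bayes factors (non-negative).
#' @slot category,category0 evidence categories for K and K0.
#' @slot rope ROPE half-width on the coefficient scale.
#' @slot prior list with elements \code{mean} and \code{sd} of the Normal
#'   prior the Bayes factors are referenced to.
#' @exportClass EffectPosterior
setClass("EffectPosterior",
    representation(term = "character", draws = "numeric", K = "numeric",
        K0 = "numeric", category = "character", category0 = "character",
        rope = "numeric", prior = "list"))

setValidity("EffectPosterior", function(object) {
    if (object@K < 0 || object@K0 < 0) "Bayes factors must be non-negative"
    else if (object@rope <= 0) "ROPE half-width must be positive"
    else TRUE
})

setMethod("show", "EffectPosterior", function(object) {
    cat(sprintf("EffectPosterior '%s': mean %.3f [%.3f, %.3f]\n", object@term,
        mean(object@draws), quantile(object@draws, 0.05),
        quantile(object@draws, 0.95)))
    cat(sprintf("  K = %.3g (%s), K0 = %.3g (%s); ROPE +/- %.3g\n",
        object@K, object@category, object@K0, object@category0, object@rope))
})
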