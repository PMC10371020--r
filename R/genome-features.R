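## Feature annotation: orientation relative to replication, strand-aware
## sub-intervals, and rRNA-style interval masking.

FEATURE_TYPES <- c("CDS", "UTR5", "UTR3", "ncRNA", "rRNA", "tRNA")

#' Classify gene orientation relative to replication fork travel
#'
#' On the replichore where forks travel in the direction of increasing
#' coordinate (the arc running from \emph{oriC} to \emph{ter}), plus-strand
#' genes are codirectional with replication and minus-strand genes are
#' head-on; the assignment is reversed on the other replichore. Features
#' whose interval contains \emph{oriC} or \emph{ter} strictly inside are
#' classified by the arc containing their midpoint and flagged.
#'
#' @param features \code{GRanges}; strand \code{"+"}/\code{"-"} (features
#'   with strand \code{"*"} come back \code{"unassigned"}).
#' @param rep a \linkS4class{ReplichoreMap} for the features' contig.
#' @return \code{features} with added metadata columns \code{orientation}
#'   (\code{"head_on"}, \code{"codirectional"} or \code{"unassigned"}) and
#'   \code{spans_boundary}.
#' @export
#' @examples
#' rp <- ReplichoreMap("chr", 1000, oriC = 1, ter = 500)
#' gr <- GenomicRanges::GRanges("chr", IRanges::IRanges(250, 300), strand = "+")
#' classifyOrientation(gr, rp)
classifyOrientation <- function(features, rep) {
    stopifnot(is(rep, "ReplichoreMap"))
    on_contig <- as.character(seqnames(features)) == rep@contig
    if (!all(on_contig))
        stop("features on contig(s) ", paste(unique(
            as.character(seqnames(features))[!on_contig]), collapse = ","),
            " do not match ReplichoreMap contig '", rep@contig, "'")
    mid <- (start(features) + end(features)) / 2
    fwdArc <- onForwardArc(mid, rep)
    str <- as.character(strand(features))
    ori <- ifelse(str == "*", "unassigned",
        ifelse((str == "+") == fwdArc, "codirectional", "head_on"))
    inside <- function(p) start(features) < p & p < end(features)
    mcols(features)$orientation <- ori
    mcols(features)$spans_boundary <- inside(rep@oriC) | inside(rep@ter)
    features
}

## TRUE for positions on the arc oriC -> ter traversed with increasing
## coordinate (wrapping if oriC > ter); forks travel in + direction there.
onForwardArc <- function(pos, rep) {
    if (rep@oriC < rep@ter) pos >= rep@oriC & pos < rep@ter
    else pos >= rep@oriC | pos < rep@ter
}

#' Replication fork direction at given positions
#'
#' @param pos numeric positions (1-based).
#' @param rep a \linkS4class{ReplichoreMap}.
#' @return +1 where forks travel towards increasing coordinates, -1
#'   otherwise.
#' @export
forkDirection <- function(pos, rep) {
    ifelse(onForwardArc(pos, rep), 1, -1)
}

#' Strand-aware leading sub-interval of features
#'
#' Returns the first \code{n} bp of each feature in its direction of
#' transcription: from the 5' end on either strand, clipped to the feature
#' length.
#'
#' @param features \code{GRanges}.
#' @param n number of leading base pairs (>= 1).
#' @return \code{GRanges} of the clipped leading intervals.
#' @export
firstNbp <- function(features, n) {
    stopifnot(n >= 1)
    resize(features, width = pmin(n, width(features)), fix = "start")
}

#' Flag bins overlapping masked intervals
#'
#' Masked bins are flagged, never dropped, so downstream aggregation can
#' exclude them explicitly (mirroring the treatment of multi-copy rRNA
#' loci collapsed to a single consensus with chromosomal copies masked).
#'
#' @param bins \code{GRanges}.
#' @param mask \code{GRanges} (e.g. from a BED3 file) of excluded intervals.
#' @return logical vector: \code{TRUE} where a bin overlaps the mask.
#' @export
maskFlags <- function(bins, mask) {
    if (is.null(mask) || length(mask) == 0L) return(rep(FALSE, length(bins)))
    overlapsAny(bins, mask)
}

## Hits of bin midpoints inside features, exact for half-integer midpoints:
## both coordinates are doubled so a width-100 bin's true midpoint x.5
## becomes the integer 2x + 1.
midpointHits <- function(bins, features) {
    m2 <- start(bins) + end(bins)
    q <- GRanges(seqnames(bins), IRanges(m2, width = 1))
    s2 <- GRanges(seqnames(features),
        IRanges(2 * start(features), 2 * end(features)))
    findOverlaps(q, s2, ignore.strand = TRUE)
}

overlapsAny <- function(query, subject) {
    hits <- findOverlaps(query, subject, ignore.strand = TRUE)
    out <- rep(FALSE, length(query))
    out[queryHits(hits)] <- TRUE
    out
}

#' Read a feature annotation from GFF3 or BED
#'
#' Thin wrapper over \code{rtracklayer::import} that normalises the feature
#' type column to the recognised set (CDS, UTR5, UTR3, ncRNA, rRNA, tRNA);
#' rows of other types are skipped with a warning. For BED input, the type
#' is taken from the name column prefix (\code{"<type>:<id>"}) or defaults
#' to CDS.
#'
#' @param path file path.
#' @param format \code{"GFF3"} or \code{"BED"} (default: by extension).
#' @return \code{GRanges} with metadata columns \code{id} and \code{type}.
#' @export
readAnnotation <- function(path, format = NULL) {
    if (is.null(format))
        format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "BED" else "GFF3"
    format <- match.arg(toupper(format), c("GFF3", "BED"))
    gr <- rtracklayer::import(path, format = if (format == "GFF3") "gff3" else "bed")
    if (format == "GFF3") {
        ty <- as.character(gr$type)
        ty[ty == "five_prime_UTR"] <- "UTR5"
        ty[ty == "three_prime_UTR"] <- "UTR3"
        id <- gr$ID
        if (is.null(id)) id <- gr$Name
    } else {
        nm <- gr$name
        has <- grepl(":", nm)
        ty <- ifelse(has, sub(":.*", "", nm), "CDS")
        id <- ifelse(has, sub("^[^:]*:", "", nm), nm)
    }
    keep <- ty %in% FEATURE_TYPES
    if (any(!keep))
        warning(sum(!keep), " feature(s) of unrecognised type skipped: ",
            paste(unique(ty[!keep]), collapse = ", "))
    gr <- gr[keep]
    out <- granges(gr)
    mcols(out)$id <- as.character(id[keep])
    mcols(out)$type <- ty[keep]
    if (any(as.character(strand(out)) == "?"))
        stop("unknown strand in annotation")
    out
}

#' Write a feature annotation to GFF3 or BED
#'
#' Inverse of \code{\link{readAnnotation}}; write-then-read is the identity
#' on coordinates, strand, id and type.
#'
#' @param features \code{GRanges} with \code{id} and \code{type} columns.
#' @param path output path.
#' @param format \code{"GFF3"} or \code{"BED"} (default: by extension).
#' @export
writeAnnotation <- function(features, path, format = NULL) {
    if (is.null(format))
        format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "BED" else "GFF3"
    format <- match.arg(toupper(format), c("GFF3", "BED"))
    gr <- granges(features)
    if (format == "GFF3") {
        ty <- mcols(features)$type
        ty[ty == "UTR5"] <- "five_prime_UTR"
        ty[ty == "UTR3"] <- "three_prime_UTR"
        mcols(gr)$type <- ty
        mcols(gr)$ID <- mcols(features)$id
        mcols(gr)$source <- "rdhscape"
        mcols(gr)$phase <- ifelse(ty == "CDS", 0L, NA_integer_)
        rtracklayer::export(gr, path, format = "gff3")
    } else {
        mcols(gr)$name <- paste0(mcols(features)$type, ":", mcols(features)$id)
        mcols(gr)$score <- 0
        rtracklayer::export(gr, path, format = "bed")
    }
    invisible(path)
}

#' Classify substitutions as transitions or transversions
#'
#' A transition exchanges the two purines (A/G) or the two pyrimidines
#' (C/T); every other single-base substitution is a transversion. The
#' classification is strand-symmetric: complementing both alleles leaves
#' the class unchanged.
#'
#' @param ref,alt single reference and alternate bases.
#' @return character vector, \code{"transition"} or \code{"transversion"}.
#' @export
#' @examples
#' classifyMutation(c("A", "A"), c("G", "T"))
classifyMutation <- function(ref, alt) {
    purine <- function(b) b %in% c("A", "G")
    if (any(ref == alt)) stop("ref and alt must differ")
    ifelse(purine(ref) == purine(alt), "transition", "transversion")
}
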