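## Synthetic-data generator: every input the pipeline consumes, with planted
## ground truth, so downstream stages are testable without external data.
##
## The defaults emulate a gene-dense circular bacterial chromosome with a
## bidirectional replication origin, strand-specific hybrid enrichment that
## depends on feature class, expression and orientation, spike-in reference
## bins on a separate contig, mutation-accumulation lines with per-CDS
## Poisson mutation counts driven by planted regression coefficients, and
## replication coverage profiles with planted slow intervals.

#' Simulation configuration
#'
#' All knobs of the synthetic-data generator, validated up front. Defaults
#' describe the study conditions the generator emulates: a 200-kb circular
#' contig in 100-bp bins, oriC at 1 and ter at mid-chromosome, three
#' genotypes with two replicates at a mean input depth of 100 reads/bin,
#' near-Poisson library noise (NB size \code{nb_dispersion} = 1000 so
#' var = mu + mu^2/1000), a 25% head-on gene fraction, hybrid enrichment
#' strongest at rRNA/ncRNA and in 5'-UTRs, a steeper expression slope in
#' the RNase HIII deletion, a small positive head-on effect with a negative
#' head-on-by-expression interaction, and 72 MA lines per genotype at 3688
#' generations each (about 265,500 generations pooled).
#'
#' @slot genome_length,bin_width chromosome length and bin width (bp);
#'   length must be a multiple of the bin width.
#' @slot oriC_pos,ter_pos replication origin/terminus (1-based bp).
#' @slot genotypes genotype labels; the first is the reference.
#' @slot replicates libraries per genotype and sample type.
#' @slot nb_dispersion NB size phi (var = mu + mu^2/phi).
#' @slot mean_input_depth mean input reads per bin.
#' @slot head_on_prob probability a simulated gene is head-on.
#' @slot enrichment_effects list: \code{feature_log2} (named per type),
#'   \code{expression_slope} (named per genotype), \code{orientation_effect},
#'   \code{interaction_effect}, \code{spike_log2}.
#' @slot mutation_coeffs list per class (transition, transversion, indel)
#'   of named coefficients: \code{intercept} (log events per bp per
#'   generation) plus \code{geno_<label>}, \code{rdh}, \code{expr},
#'   \code{head_on}, \code{rdh_x_head_on}, \code{expr_x_head_on}.
#' @slot sv_rate structural variants per generation per line.
#' @slot n_features named integer vector (CDS, ncRNA, rRNA, tRNA); every
#'   CDS also receives a 5'- and a 3'-UTR.
#' @slot generations_per_line,n_lines MA-line design per genotype.
#' @slot spike_length spike-in contig length (0 disables the spike).
#' @slot seed integer seed; fixed seed means byte-identical outputs.
#' @exportClass SimConfig
setClass("SimConfig", representation(
    genome_length = "numeric", bin_width = "numeric",
    oriC_pos = "numeric", ter_pos = "numeric",
    genotypes = "character", replicates = "integer",
    nb_dispersion = "numeric", mean_input_depth = "numeric",
    head_on_prob = "numeric", enrichment_effects = "list",
    mutation_coeffs = "list", sv_rate = "numeric",
    n_features = "integer", generations_per_line = "numeric",
    n_lines = "integer", spike_length = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- NULL
    if (object@genome_length %% object@bin_width != 0)
        msg <- c(msg, "genome_length must be divisible by bin_width")
    if (object@oriC_pos < 1 || object@oriC_pos > object@genome_length ||
        object@ter_pos < 1 || object@ter_pos > object@genome_length)
        msg <- c(msg, "oriC_pos and ter_pos must lie within the genome")
    if (object@oriC_pos == object@ter_pos)
        msg <- c(msg, "oriC_pos and ter_pos must differ")
    if (object@mean_input_depth <= 0 || object@nb_dispersion <= 0)
        msg <- c(msg, "depth and dispersion must be positive")
    if (object@head_on_prob < 0 || object@head_on_prob > 1)
        msg <- c(msg, "head_on_prob must be in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn SimConfig-class Constructor with defaults; any slot can be
#'   overridden by name.
#' @param ... slot overrides, e.g. \code{genome_length = 5e4}.
#' @return A validated \code{SimConfig}.
#' @export
#' @examples
#' cfg <- simConfig(genome_length = 5e4, seed = 7)
simConfig <- function(...) {
    defaults <- list(
        genome_length = 2e5, bin_width = 100,
        oriC_pos = 1, ter_pos = 1e5,
        genotypes = c("WT", "dRnhB", "dRnhC"), replicates = 2L,
        nb_dispersion = 1000, mean_input_depth = 100,
        head_on_prob = 0.25,
        enrichment_effects = list(
            feature_log2 = c(CDS = 0.5, UTR5 = 1.5, UTR3 = 0.8,
                ncRNA = 2, rRNA = 4, tRNA = 1.5),
            expression_slope = c(WT = 0.3, dRnhB = 0.3, dRnhC = 0.8),
            orientation_effect = 0.2, interaction_effect = -0.2,
            gene_sd = 0.5, spike_log2 = 1),
        mutation_coeffs = list(
            transition = c(intercept = log(3e-10), geno_dRnhB = 0.5,
                geno_dRnhC = 0.3, rdh = 0, expr = 0.05, head_on = 0,
                rdh_x_head_on = 0, expr_x_head_on = -0.1),
            transversion = c(intercept = log(1.5e-10), geno_dRnhB = 0,
                geno_dRnhC = 0.7, rdh = 0, expr = -0.15, head_on = 0,
                rdh_x_head_on = 0, expr_x_head_on = 0),
            indel = c(intercept = log(1.5e-10), geno_dRnhB = 0,
                geno_dRnhC = 0.2, rdh = 0.5, expr = -0.1, head_on = 0,
                rdh_x_head_on = 0, expr_x_head_on = 0)),
        sv_rate = 5e-5,
        n_features = c(CDS = 120L, ncRNA = 12L, rRNA = 2L, tRNA = 15L),
        generations_per_line = 3688, n_lines = 72L,
        spike_length = 1e4, seed = 1L)
    args <- modifyList(defaults, list(...))
    args$replicates <- as.integer(args$replicates)
    args$n_lines <- as.integer(args$n_lines)
    args$n_features <- vapply(args$n_features, as.integer, integer(1))
    args$seed <- as.integer(args$seed)
    do.call(new, c(list(Class = "SimConfig"), args))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@genome_length, "bp genome,",
        object@bin_width, "bp bins\n")
    cat("  genotypes:", paste(object@genotypes, collapse = ", "),
        "x", object@replicates, "replicates; depth",
        object@mean_input_depth, "phi", object@nb_dispersion, "\n")
    cat("  MA lines:", object@n_lines, "x", object@generations_per_line,
        "generations; seed", object@seed, "\n")
})

#' Planted ground truth of a simulation
#'
#' Emitted alongside every simulated dataset so recovery tests can compare
#' inferred against planted quantities.
#'
#' @slot bins genomic bins (spike bins excluded).
#' @slot beta per-genotype list of per-strand true log2 enrichment vectors
#'   aligned 1:1 with \code{bins}.
#' @slot features annotated \code{GRanges} with orientation labels.
#' @slot rep the \linkS4class{ReplichoreMap}.
#' @slot expression per-gene data.frame: \code{id}, \code{log2_expr},
#'   \code{z}, and \code{rdh_dev}, the gene-specific hybrid propensity
#'   independent of expression.
#' @slot slow planted slow-replication intervals (\code{GRanges} with a
#'   \code{genotype} column).
#' @exportClass GroundTruth
setClass("GroundTruth", representation(bins = "GRanges", beta = "list",
    features = "GRanges", rep = "ReplichoreMap", expression = "data.frame",
    slow = "GRanges"))

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth:", length(object@bins), "bins,",
        length(object@features), "features,",
        length(object@slow), "slow interval(s)\n")
})

#' Simulate a genome annotation with planted enrichment truth
#'
#' Places non-overlapping gene cassettes (5'-UTR + CDS + 3'-UTR) and
#' standalone ncRNA/rRNA/tRNA features on both strands with random gaps,
#' assigns each gene head-on or codirectional orientation relative to the
#' replichore map (head-on with probability \code{head_on_prob}), draws
#' per-gene expression, and computes the per-bin true log2 enrichment for
#' every genotype and strand from the configured effects. Deterministic
#' given \code{cfg@seed}.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return a \linkS4class{GroundTruth}.
#' @export
simulateAnnotation <- function(cfg) {
    validObject(cfg)
    set.seed(cfg@seed)
    rep <- ReplichoreMap("chr", cfg@genome_length, cfg@oriC_pos, cfg@ter_pos)
    nf <- cfg@n_features
    ## unit = a cassette (UTR5+CDS+UTR3) or a standalone feature
    units <- list()
    for (i in seq_len(nf[["CDS"]])) {
        len <- round(rlnorm(1, log(900), 0.3))
        units[[length(units) + 1L]] <- list(kind = "cassette",
            u5 = sample(30:80, 1), cds = max(len, 90), u3 = sample(30:80, 1),
            id = sprintf("gene%04d", i))
    }
    singles <- c(rep("ncRNA", nf[["ncRNA"]]), rep("rRNA", nf[["rRNA"]]),
        rep("tRNA", nf[["tRNA"]]))
    lens <- c(ncRNA = 200, rRNA = 1500, tRNA = 80)
    for (i in seq_along(singles)) {
        ty <- singles[i]
        units[[length(units) + 1L]] <- list(kind = ty,
            len = round(lens[[ty]] * runif(1, 0.8, 1.2)),
            id = sprintf("%s%03d", tolower(ty), i))
    }
    span <- vapply(units, function(u)
        if (u$kind == "cassette") u$u5 + u$cds + u$u3 else u$len, numeric(1))
    slack <- cfg@genome_length - sum(span) - length(units)
    if (slack < 0)
        stop("requested features cannot be placed without overlap: total ",
            "feature span ", sum(span), " bp exceeds genome length ",
            cfg@genome_length, " bp")
    units <- units[sample(length(units))]
    span <- vapply(units, function(u)
        if (u$kind == "cassette") u$u5 + u$cds + u$u3 else u$len, numeric(1))
    gaps <- diff(c(0, sort(runif(length(units))))) * slack
    starts <- round(cumsum(gaps + 1) + cumsum(c(0, head(span, -1))))
    rows <- list()
    for (i in seq_along(units)) {
        u <- units[[i]]
        st <- starts[i]
        mid <- st + span[i] / 2
        fwd <- onForwardArc(mid, rep)
        headOn <- runif(1) < cfg@head_on_prob
        strandChr <- if (xor(fwd, headOn)) "+" else "-"
        if (u$kind == "cassette") {
            if (strandChr == "+") {
                part <- data.frame(
                    start = c(st, st + u$u5, st + u$u5 + u$cds),
                    end = c(st + u$u5 - 1, st + u$u5 + u$cds - 1,
                        st + u$u5 + u$cds + u$u3 - 1),
                    type = c("UTR5", "CDS", "UTR3"))
            } else {
                part <- data.frame(
                    start = c(st + u$u3 + u$cds, st + u$u3, st),
                    end = c(st + u$u3 + u$cds + u$u5 - 1,
                        st + u$u3 + u$cds - 1, st + u$u3 - 1),
                    type = c("UTR5", "CDS", "UTR3"))
            }
            part$id <- paste0(u$id, c("_5utr", "", "_3utr"))
            part$gene <- u$id
        } else {
            part <- data.frame(start = st, end = st + u$len - 1,
                type = u$kind, id = u$id, gene = u$id)
        }
        part$strand <- strandChr
        rows[[i]] <- part
    }
    tab <- do.call(rbind, rows)
    features <- GRanges("chr", IRanges(tab$start, tab$end),
        strand = tab$strand, id = tab$id, type = tab$type, gene = tab$gene)
    features <- classifyOrientation(features, rep)
    ## per-gene expression (shared across genotypes)
    genes <- unique(tab$gene)
    log2expr <- rnorm(length(genes), 5, 2)
    ## gene-specific hybrid propensity independent of expression (sequence
    ## context, GC skew, ...), so RDH and expression are correlated but not
    ## collinear across genes
    gsd <- cfg@enrichment_effects$gene_sd
    if (is.null(gsd)) gsd <- 0
    expr <- data.frame(id = genes, log2_expr = log2expr,
        z = robustZ(log2expr), rdh_dev = rnorm(length(genes), 0, gsd))
    ## planted slow-replication interval just upstream of ter on the
    ## forward replichore, attributed to the last genotype
    slowStart <- max(1, cfg@ter_pos - 15000)
    slow <- GRanges("chr", IRanges(slowStart, max(cfg@ter_pos - 1, slowStart + 1)))
    mcols(slow)$genotype <- tail(cfg@genotypes, 1)
    truth <- new("GroundTruth",
        bins = genomeBins(cfg), beta = list(), features = features,
        rep = rep, expression = expr, slow = slow)
    truth@beta <- plantedBeta(cfg, truth)
    truth
}

genomeBins <- function(cfg) {
    n <- cfg@genome_length / cfg@bin_width
    GRanges("chr", IRanges(start = (seq_len(n) - 1) * cfg@bin_width + 1,
        width = cfg@bin_width))
}

## True per-bin log2 enrichment per genotype and strand: a bin carries a
## feature's effect when its midpoint lies inside the feature and the
## feature sits on that strand.
plantedBeta <- function(cfg, truth) {
    eff <- cfg@enrichment_effects
    bins <- truth@bins
    out <- list()
    exprZ <- setNames(truth@expression$z, truth@expression$id)
    rdhDev <- if (is.null(truth@expression$rdh_dev))
        setNames(numeric(nrow(truth@expression)), truth@expression$id)
    else setNames(truth@expression$rdh_dev, truth@expression$id)
    for (g in cfg@genotypes) {
        perStrand <- list("+" = numeric(length(bins)),
            "-" = numeric(length(bins)))
        for (s in c("+", "-")) {
            fs <- truth@features[as.character(strand(truth@features)) == s]
            hits <- midpointHits(bins, fs)
            b <- numeric(length(bins))
            ty <- mcols(fs)$type[subjectHits(hits)]
            val <- eff$feature_log2[ty]
            isCDS <- ty == "CDS"
            if (any(isCDS)) {
                f <- fs[subjectHits(hits)]
                z <- exprZ[mcols(f)$gene]
                ho <- as.numeric(mcols(f)$orientation == "head_on")
                val[isCDS] <- val[isCDS] +
                    (eff$expression_slope[[g]] * z +
                     eff$orientation_effect * ho +
                     eff$interaction_effect * ho * z +
                     rdhDev[mcols(f)$gene])[isCDS]
            }
            b[queryHits(hits)] <- val
            perStrand[[s]] <- b
        }
        out[[g]] <- perStrand
    }
    out
}

#' Simulate stranded pull-down and input sequencing counts
#'
#' Input counts are negative binomial around the configured mean depth
#' modulated by a replication coverage gradient (log2-linear from oriC to
#' ter on each replichore); extracted counts multiply the input mean by
#' 2^(true log2 enrichment) on the library's strand. Spike-in bins on a
#' separate contig carry a constant reference enrichment for all
#' genotypes. Deterministic given \code{cfg@seed}.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param truth the matching \linkS4class{GroundTruth}.
#' @param poisson if TRUE, draw Poisson counts (the infinite-dispersion
#'   limit of the NB model).
#' @return a \linkS4class{StrandedCountMatrix}.
#' @export
simulateCounts <- function(cfg, truth, poisson = FALSE) {
    set.seed(cfg@seed + 1L)
    bins <- truth@bins
    mids <- (start(bins) + end(bins)) / 2
    profile <- 2^(replicationPhase(mids, truth@rep))
    profile <- profile / mean(profile)
    nSpike <- if (cfg@spike_length > 0) cfg@spike_length %/% cfg@bin_width else 0L
    allBins <- bins
    if (nSpike > 0) {
        spikeBins <- GRanges("spike", IRanges(
            start = (seq_len(nSpike) - 1) * cfg@bin_width + 1,
            width = cfg@bin_width))
        suppressWarnings(allBins <- c(bins, spikeBins))
    }
    spikeFlag <- c(rep(FALSE, length(bins)), rep(TRUE, nSpike))
    rdraw <- function(mu) {
        if (poisson) rpois(length(mu), mu)
        else rnbinom(length(mu), size = cfg@nb_dispersion, mu = mu)
    }
    libs <- list(); cols <- list()
    for (g in cfg@genotypes) {
        for (r in seq_len(cfg@replicates)) {
            muIn <- cfg@mean_input_depth * profile
            muSpk <- rep(cfg@mean_input_depth, nSpike)
            libs[[length(libs) + 1L]] <- c(rdraw(muIn), rdraw(muSpk))
            cols[[length(cols) + 1L]] <- data.frame(genotype = g,
                replicate = r, sample_type = "input", strand = "*")
            for (s in c("+", "-")) {
                muEx <- muIn * 2^truth@beta[[g]][[s]]
                muExSpk <- muSpk * 2^cfg@enrichment_effects$spike_log2
                libs[[length(libs) + 1L]] <- c(rdraw(muEx), rdraw(muExSpk))
                cols[[length(cols) + 1L]] <- data.frame(genotype = g,
                    replicate = r, sample_type = "extracted", strand = s)
            }
        }
    }
    counts <- do.call(cbind, libs)
    StrandedCountMatrix(allBins, counts, do.call(rbind, cols),
        spike = spikeFlag)
}

## log2 relative copy number: 1 at oriC decaying linearly to 0 at ter along
## each replichore (ori:ter coverage ratio of 2 in exponential growth).
replicationPhase <- function(pos, rep) {
    fwd <- onForwardArc(pos, rep)
    arcLen <- function(from, to, L) (to - from) %% L
    L <- rep@length
    dFwd <- arcLen(rep@oriC, pos, L) / max(arcLen(rep@oriC, rep@ter, L), 1)
    dRev <- arcLen(pos, rep@oriC, L) / max(arcLen(rep@ter, rep@oriC, L), 1)
    1 - ifelse(fwd, dFwd, dRev)
}

#' Simulate mutation-accumulation lines
#'
#' Per CDS, genotype and mutation class, event counts are Poisson with
#' mean length x pooled generations x exp(linear predictor) using the
#' planted coefficients on true RDH z, expression z, orientation and
#' genotype. Events are assigned to lines proportionally to their
#' generations and placed uniformly within the CDS with ref/alt alleles
#' consistent with the class. Structural variants arise per line at the
#' configured rate; each non-reference genotype carries an engineered
#' locus (its first CDS) recorded as the intended alteration.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param truth the matching \linkS4class{GroundTruth}.
#' @return list with \code{dataset} (a \linkS4class{MALineDataset}) and
#'   \code{covariates} (the per-CDS design used, for recovery tests).
#' @export
simulateMALines <- function(cfg, truth) {
    set.seed(cfg@seed + 2L)
    cds <- truth@features[mcols(truth@features)$type == "CDS"]
    exprZ <- setNames(truth@expression$z, truth@expression$id)
    covar <- data.frame(id = mcols(cds)$id,
        length = width(cds),
        start = start(cds), end = end(cds),
        head_on = as.numeric(mcols(cds)$orientation == "head_on"),
        expr_z = unname(exprZ[mcols(cds)$gene]))
    lines <- do.call(rbind, lapply(cfg@genotypes, function(g)
        data.frame(id = sprintf("%s_line%02d", g, seq_len(cfg@n_lines)),
            genotype = g, generations = cfg@generations_per_line)))
    events <- list(); svs <- list(); alts <- list()
    bases <- c("A", "C", "G", "T")
    transPartner <- c(A = "G", G = "A", C = "T", T = "C")
    for (g in cfg@genotypes) {
        gLines <- lines[lines$genotype == g, ]
        totGen <- sum(gLines$generations)
        zr <- trueRdhZ(cfg, truth, g)
        for (cl in names(cfg@mutation_coeffs)) {
            co <- cfg@mutation_coeffs[[cl]]
            eta <- co[["intercept"]] +
                (if (g != cfg@genotypes[1] &&
                     !is.null(co[[paste0("geno_", g)]]))
                    co[[paste0("geno_", g)]] else 0) +
                co[["rdh"]] * zr + co[["expr"]] * covar$expr_z +
                co[["head_on"]] * covar$head_on +
                co[["rdh_x_head_on"]] * zr * covar$head_on +
                co[["expr_x_head_on"]] * covar$expr_z * covar$head_on
            lambda <- covar$length * totGen * exp(eta)
            n <- rpois(length(lambda), lambda)
            for (i in which(n > 0)) {
                pos <- sample(covar$start[i]:covar$end[i], n[i], replace = TRUE)
                who <- sample(gLines$id, n[i], replace = TRUE,
                    prob = gLines$generations)
                if (cl == "indel") {
                    ins <- runif(n[i]) < 0.5
                    ref <- ifelse(ins, "A", "AT")
                    alt <- ifelse(ins, "AT", "A")
                    klass <- ifelse(ins, "insertion", "deletion")
                } else if (cl == "transition") {
                    ref <- sample(bases, n[i], replace = TRUE)
                    alt <- unname(transPartner[ref])
                    klass <- "transition"
                } else {
                    ref <- sample(bases, n[i], replace = TRUE)
                    alt <- vapply(ref, function(b)
                        sample(setdiff(bases, c(b, transPartner[[b]])), 1),
                        character(1))
                    klass <- "transversion"
                }
                events[[length(events) + 1L]] <- data.frame(line_id = who,
                    position = pos, ref = ref, alt = alt, class = klass)
            }
        }
        ## SVs and the engineered locus
        altLocus <- NULL
        if (g != cfg@genotypes[1]) {
            idx <- which(cfg@genotypes == g)
            altLocus <- cds[min(idx, length(cds))]
            alts[[length(alts) + 1L]] <- data.frame(line_id = gLines$id,
                start = start(altLocus), end = end(altLocus))
        }
        nSV <- rpois(nrow(gLines), cfg@sv_rate * gLines$generations)
        for (j in which(nSV > 0)) {
            st <- sample.int(cfg@genome_length - 5000L, nSV[j])
            svs[[length(svs) + 1L]] <- data.frame(line_id = gLines$id[j],
                start = st, end = st + pmin(rgeom(nSV[j], 1 / 2000) + 50L, 5000L),
                type = sample(c("DEL", "INS", "INV"), nSV[j], replace = TRUE))
        }
    }
    events <- if (length(events)) do.call(rbind, events) else
        data.frame(line_id = character(), position = numeric(),
            ref = character(), alt = character(), class = character())
    ds <- MALineDataset(lines, events,
        svs = if (length(svs)) do.call(rbind, svs) else NULL,
        alterations = if (length(alts)) do.call(rbind, alts) else NULL)
    list(dataset = ds, covariates = covar)
}

#' True per-CDS RDH z-score of a genotype
#'
#' Robust z, across CDSs, of the planted mean log2 enrichment within each
#' CDS on its own strand -- the ground-truth counterpart of aggregating an
#' inferred z track by feature.
#'
#' @param cfg,truth simulation config and ground truth.
#' @param genotype genotype label.
#' @return numeric vector aligned with the CDSs in
#'   \code{truth@features}.
#' @export
trueRdhZ <- function(cfg, truth, genotype) {
    cds <- truth@features[mcols(truth@features)$type == "CDS"]
    bins <- truth@bins
    val <- numeric(length(cds))
    for (s in c("+", "-")) {
        onS <- which(as.character(strand(cds)) == s)
        hits <- midpointHits(bins, cds[onS])
        b <- truth@beta[[genotype]][[s]]
        agg <- tapply(b[queryHits(hits)], subjectHits(hits), mean)
        val[onS[as.integer(names(agg))]] <- agg
    }
    robustZ(val)
}

#' Simulate a whole-genome coverage profile for replication profiling
#'
#' Log2 coverage declines linearly from oriC to ter along each replichore;
#' inside a planted slow interval attributed to the genotype the decline is
#' locally several-fold steeper, emulating impeded fork progression. Binned
#' counts are negative binomial around the profile.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param truth the matching \linkS4class{GroundTruth}.
#' @param genotype genotype label (slow intervals apply only to the
#'   genotype recorded in the truth).
#' @param covBin coverage bin width in bp (default 1000).
#' @param depth mean reads per coverage bin (default 500).
#' @param slowFactor slope multiplier inside slow intervals (default 6).
#' @return \code{GRanges} log2 CPM track from \code{\link{cpmTrack}}.
#' @export
simulateCoverage <- function(cfg, truth, genotype, covBin = 1000,
                             depth = 500, slowFactor = 6) {
    set.seed(cfg@seed + 3L + match(genotype, cfg@genotypes))
    n <- cfg@genome_length %/% covBin
    bins <- GRanges("chr", IRanges((seq_len(n) - 1) * covBin + 1,
        width = covBin))
    mids <- (start(bins) + end(bins)) / 2
    logProf <- replicationPhase(mids, truth@rep)
    slow <- truth@slow[mcols(truth@slow)$genotype == genotype]
    if (length(slow)) {
        ## steepen the decline inside the interval (in fork-travel order)
        for (k in seq_along(slow)) {
            inIv <- mids >= start(slow)[k] & mids <= end(slow)[k]
            if (!any(inIv)) next
            idx <- which(inIv)
            base <- logProf[idx]
            extra <- (slowFactor - 1) * (base[1] - base)
            logProf[idx] <- base[1] - slowFactor * (base[1] - base)
            after <- seq_along(logProf) > max(idx)
            logProf[after] <- logProf[after] - max(extra)
        }
    }
    mu <- depth * 2^logProf / mean(2^logProf)
    counts <- rnbinom(n, size = cfg@nb_dispersion, mu = mu)
    cpmTrack(bins, counts)
}

#' Simulate a qPCR Cq table
#'
#' Cq values for pull-down and input fractions at target loci and a
#' spike-in reference locus, with replicate noise; the true delta-delta-Cq
#' of a locus equals the spike reference log2 enrichment minus the locus'
#' true log2 enrichment (one cycle per twofold).
#'
#' @param cfg,truth simulation config and ground truth.
#' @param loci integer bin indices of target loci (plus strand).
#' @param reps technical replicates (default 3).
#' @param noiseSd replicate Cq noise (default 0.15 cycles).
#' @return data.frame in \code{\link{ddcq}} format; the reference locus is
#'   labelled \code{"spike_ref"}.
#' @export
simulateQPCR <- function(cfg, truth, loci, reps = 3, noiseSd = 0.15) {
    set.seed(cfg@seed + 11L)
    rows <- list()
    base <- 20
    for (g in cfg@genotypes) {
        beta <- c(truth@beta[[g]][["+"]][loci], cfg@enrichment_effects$spike_log2)
        labs <- c(sprintf("locus_bin%d", loci), "spike_ref")
        for (i in seq_along(labs)) for (r in seq_len(reps)) {
            rows[[length(rows) + 1L]] <- data.frame(
                locus = labs[i], genotype = g,
                fraction = c("input", "pulldown"), replicate = r,
                cq = c(base + rnorm(1, 0, noiseSd),
                    base - beta[i] + rnorm(1, 0, noiseSd)))
        }
    }
    do.call(rbind, rows)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running annotation, counts, expression, MA lines,
#' coverage and qPCR generation from one config.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return list with \code{truth}, \code{counts}, \code{ma},
#'   \code{coverage} (per genotype), \code{qpcr}.
#' @export
simulateDataset <- function(cfg) {
    truth <- simulateAnnotation(cfg)
    counts <- simulateCounts(cfg, truth)
    ma <- simulateMALines(cfg, truth)
    coverage <- lapply(setNames(nm = cfg@genotypes), function(g)
        simulateCoverage(cfg, truth, g))
    qpcr <- simulateQPCR(cfg, truth,
        loci = round(length(truth@bins) * c(0.1, 0.3)))
    list(truth = truth, counts = counts, ma = ma, coverage = coverage,
        qpcr = qpcr)
}

#' Write a simulated dataset to standard formats
#'
#' FASTA genome (random sequence of the configured length), GFF3
#' annotation, one bedGraph per library, TSVs for expression, MA lines,
#' SVs and per-bin ground truth, and a JSON echo of the configuration.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param sim result of \code{\link{simulateDataset}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSimulation <- function(cfg, sim, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    set.seed(cfg@seed + 5L)
    seq <- DNAStringSet(paste(sample(c("A", "C", "G", "T"),
        cfg@genome_length, replace = TRUE), collapse = ""))
    names(seq) <- "chr"
    writeXStringSet(seq, file.path(dir, "genome.fa"))
    writeAnnotation(sim$truth@features, file.path(dir, "features.gff3"))
    cd <- colData(sim$counts)
    for (j in seq_len(ncol(sim$counts))) {
        tr <- granges(rowRanges(sim$counts))
        mcols(tr)$score <- assay(sim$counts, "counts")[, j]
        writeTrack(tr, file.path(dir, paste0(colnames(sim$counts)[j],
            ".bedGraph")))
    }
    tsv <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
        quote = FALSE, row.names = FALSE)
    tsv(sim$truth@expression, "expression.tsv")
    tsv(sim$ma$dataset@lines, "ma_lines.tsv")
    tsv(sim$ma$dataset@events, "ma_events.tsv")
    tsv(sim$ma$dataset@svs, "ma_svs.tsv")
    tsv(sim$ma$dataset@alterations, "ma_alterations.tsv")
    bt <- do.call(rbind, lapply(names(sim$truth@beta), function(g)
        data.frame(genotype = g,
            bin_start = start(sim$truth@bins),
            beta_plus = sim$truth@beta[[g]][["+"]],
            beta_minus = sim$truth@beta[[g]][["-"]])))
    tsv(bt, "truth_beta.tsv")
    write_json(configAsList(cfg), file.path(dir, "config.json"),
        auto_unbox = TRUE, digits = NA)
    invisible(dir)
}

configAsList <- function(cfg) {
    sl <- slotNames(cfg)
    out <- lapply(setNames(nm = sl), function(s) slot(cfg, s))
    out$n_features <- as.list(out$n_features)
    out$enrichment_effects <- lapply(out$enrichment_effects, as.list)
    out$mutation_coeffs <- lapply(out$mutation_coeffs, as.list)
    out
}
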