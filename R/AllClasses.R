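#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end strand granges
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqinfo Seqinfo
NULL

#' GenomeAnnotation: ordered, ranked gene models
#'
#' Thin wrapper around a [GenomicRanges::GRanges] of gene bodies carrying the
#' metadata the duplication-mode rules need: `gene_id`, `exon_count` and the
#' per-chromosome gene `rank` (1-based order along each chromosome; assigned by
#' [assignRanks()], not parsed).  Chromosome lengths live in the `seqlengths`
#' of the GRanges.
#'
#' @slot genes A `GRanges` with metadata columns `gene_id` (unique character),
#'   `exon_count` (integer >= 1) and `rank` (integer, NA until assigned).
#'
#' @seealso [readAnnotation()], [assignRanks()], [extractPromoters()]
#' @export
setClass("GenomeAnnotation", representation(genes = "GRanges"))

setValidity("GenomeAnnotation", function(object) {
    gr <- object@genes
    msg <- character()
    need <- c("gene_id", "exon_count", "rank")
    if (!all(need %in% colnames(mcols(gr)))) {
        return(paste(
            "genes must carry metadata columns",
            paste(need, collapse = ", ")
        ))
    }
    if (anyDuplicated(mcols(gr)$gene_id)) {
        msg <- c(msg, "gene_id values must be unique")
    }
    if (length(gr) && any(mcols(gr)$exon_count < 1L, na.rm = TRUE)) {
        msg <- c(msg, "exon_count must be >= 1")
    }
    sl <- seqlengths(gr)
    if (length(gr) && !all(is.na(sl))) {
        len <- sl[as.character(seqnames(gr))]
        bad <- !is.na(len) & (end(gr) > len | start(gr) < 1L)
        if (any(bad)) {
            msg <- c(msg, "gene coordinates must lie within chromosome lengths")
        }
    }
    rk <- mcols(gr)$rank
    if (length(gr) && !anyNA(rk)) {
        byChrom <- split(rk, as.character(seqnames(gr)))
        ok <- vapply(
            byChrom,
            function(r) identical(sort(as.integer(r)), seq_along(r)),
            logical(1)
        )
        if (!all(ok)) {
            msg <- c(msg, "ranks per chromosome must be a permutation of 1..n")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a GenomeAnnotation
#'
#' @param chrom,start,end,strand,gene_id,exon_count Per-gene vectors
#'   (coordinates 1-based inclusive).
#' @param chromLengths Named numeric vector of chromosome lengths in bp.
#' @param rank Optional integer vector of precomputed ranks (normally left NA
#'   and filled by [assignRanks()]).
#' @return A [GenomeAnnotation-class] object.
#' @export
#' @examples
#' ga <- GenomeAnnotation(
#'     chrom = "chr1", start = c(100, 900), end = c(400, 1500),
#'     strand = c("+", "-"), gene_id = c("g1", "g2"), exon_count = c(3L, 1L),
#'     chromLengths = c(chr1 = 5000)
#' )
#' ga
GenomeAnnotation <- function(chrom, start, end, strand, gene_id, exon_count,
                             chromLengths = NULL, rank = NA_integer_) {
    gr <- GRanges(
        seqnames = chrom,
        ranges = IRanges(start = start, end = end),
        strand = strand
    )
    n <- length(gr)
    mcols(gr)$gene_id <- rep(as.character(gene_id), length.out = n)
    mcols(gr)$exon_count <- rep(as.integer(exon_count), length.out = n)
    mcols(gr)$rank <- rep(as.integer(rank), length.out = n)
    if (!is.null(chromLengths)) {
        # keep gene-free chromosomes in the seqinfo
        GenomeInfoDb::seqlevels(gr) <- union(
            seqlevels(gr),
            names(chromLengths)
        )
        seqlengths(gr) <- chromLengths[seqlevels(gr)]
    }
    new("GenomeAnnotation", genes = gr)
}

#' CollinearBlockSet: chained anchor pairs
#'
#' The result of [detectBlocks()]: collinear (syntenic) blocks, each an ordered
#' chain of anchor gene pairs between two chromosomes, plus a per-block summary
#' table (orientation, size, mean Ks once filled by [blockMeanKs()]).
#'
#' @slot anchors `DataFrame` with columns `block_id`, `gene_a`, `gene_b`,
#'   `rank_a`, `rank_b`, `chrom_a`, `chrom_b`.
#' @slot blocks `DataFrame` with columns `block_id`, `chrom_a`, `chrom_b`,
#'   `orientation` ("same"/"inverted"), `n_anchors`, `score`, `mean_ks`.
#' @export
setClass(
    "CollinearBlockSet",
    representation(anchors = "DataFrame", blocks = "DataFrame")
)

setValidity("CollinearBlockSet", function(object) {
    a <- object@anchors
    b <- object@blocks
    needA <- c(
        "block_id", "gene_a", "gene_b", "rank_a", "rank_b",
        "chrom_a", "chrom_b"
    )
    needB <- c(
        "block_id", "chrom_a", "chrom_b", "orientation", "n_anchors",
        "score", "mean_ks"
    )
    if (!all(needA %in% colnames(a))) {
        return("anchors is missing required columns")
    }
    if (!all(needB %in% colnames(b))) {
        return("blocks is missing required columns")
    }
    if (nrow(a) && !all(a$block_id %in% b$block_id)) {
        return("every anchor must belong to a summarised block")
    }
    if (nrow(b) && !all(b$orientation %in% c("same", "inverted"))) {
        return("orientation must be 'same' or 'inverted'")
    }
    TRUE
})

#' KsMixtureFit: two-component Gaussian mixture on log-Ks
#'
#' Returned by [fitKsMixture()].  Component means/sds are on the log-Ks scale;
#' `componentMedians()` gives the corresponding Ks-scale medians exp(mean).
#'
#' @slot means,sds,weights Numeric vectors of length k (means ascending;
#'   weights sum to 1).
#' @slot loglik Final log-likelihood.
#' @slot n_iter EM iterations of the best restart.
#' @slot loglik_trace Per-iteration log-likelihood of the best restart
#'   (non-decreasing).
#' @export
setClass("KsMixtureFit", representation(
    means = "numeric", sds = "numeric", weights = "numeric",
    loglik = "numeric", n_iter = "integer", loglik_trace = "numeric"
))

setValidity("KsMixtureFit", function(object) {
    if (length(object@means) != length(object@sds) ||
        length(object@means) != length(object@weights)) {
        return("means, sds and weights must have equal length")
    }
    if (abs(sum(object@weights) - 1) > 1e-6) {
        return("weights must sum to 1")
    }
    if (is.unsorted(object@means)) {
        return("means must be ascending")
    }
    TRUE
})

#' SimulationConfig: parameters of the synthetic duplicated genome
#'
#' Holds every knob of the simulator.  Defaults reproduce the reference study
#' conditions used throughout the test-suite: a 2-chromosome genome, a
#' whole-genome duplication with 80% gene retention, and a fixed budget of
#' single-gene duplication events of each mode.
#'
#' @slot n_chroms,genes_per_chrom Integer genome dimensions.
#' @slot n_events Named integer vector of planted single-gene events
#'   (names among TD, PD, RD, DD, DSD).
#' @slot wgd_retention Fraction of duplicated-chromosome genes retained.
#' @slot target_ks Named numeric: target synonymous divergence per event class
#'   (names WGD, TD, PD, RD, DD, DSD).
#' @slot target_ka_ks Target Ka/Ks of the substitution process.
#' @slot n_tissues Number of expression samples.
#' @slot promoter_shared_fraction Planted shared-motif coverage per pair.
#' @slot motif_min_len Minimum planted motif length (bp).
#' @slot seed Master seed.
#' @export
setClass("SimulationConfig", representation(
    n_chroms = "integer", genes_per_chrom = "integer",
    n_events = "integer", wgd_retention = "numeric",
    target_ks = "numeric", target_ka_ks = "numeric",
    n_tissues = "integer", promoter_shared_fraction = "numeric",
    motif_min_len = "integer", seed = "integer"
))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@n_chroms < 1L || object@genes_per_chrom < 1L) {
        msg <- c(msg, "n_chroms and genes_per_chrom must be >= 1")
    }
    if (any(object@n_events < 0L)) {
        msg <- c(msg, "event counts must be >= 0")
    }
    if (!all(names(object@n_events) %in% c("TD", "PD", "RD", "DD", "DSD"))) {
        msg <- c(msg, "n_events names must be among TD, PD, RD, DD, DSD")
    }
    if (object@wgd_retention < 0 || object@wgd_retention > 1) {
        msg <- c(msg, "wgd_retention must lie in [0, 1]")
    }
    if (object@promoter_shared_fraction < 0 ||
        object@promoter_shared_fraction > 1) {
        msg <- c(msg, "promoter_shared_fraction must lie in [0, 1]")
    }
    if (any(object@target_ks < 0)) {
        msg <- c(msg, "target_ks must be >= 0")
    }
    if (length(msg)) msg else TRUE
})

#' @rdname SimulationConfig-class
#' @param n_chroms,genes_per_chrom Genome dimensions.
#' @param n_events Named integer vector of single-gene event counts.
#' @param wgd_retention Retention fraction after the whole-genome duplication.
#' @param target_ks Named numeric target Ks per event class; a single unnamed
#'   value is recycled to all classes.
#' @param target_ka_ks Target Ka/Ks ratio of the substitution process.
#' @param n_tissues Number of expression samples to simulate.
#' @param promoter_shared_fraction Planted promoter shared-motif coverage.
#' @param motif_min_len Minimum planted motif length in bp.
#' @param seed Master seed (integer).
#' @export
#' @examples
#' cfg <- simulationConfig(n_chroms = 2L, genes_per_chrom = 50L, seed = 1L)
#' cfg
simulationConfig <- function(n_chroms = 2L, genes_per_chrom = 300L,
                             n_events = c(
                                 TD = 20L, PD = 20L, RD = 10L,
                                 DD = 10L, DSD = 20L
                             ),
                             wgd_retention = 0.8,
                             target_ks = c(
                                 WGD = 0.2, TD = 0.1, PD = 0.1,
                                 RD = 0.1, DD = 0.1, DSD = 0.3
                             ),
                             target_ka_ks = 0.3,
                             n_tissues = 12L,
                             promoter_shared_fraction = 0.4,
                             motif_min_len = 16L,
                             seed = 1L) {
    if (length(target_ks) == 1L && is.null(names(target_ks))) {
        target_ks <- stats::setNames(
            rep(target_ks, 6),
            c("WGD", "TD", "PD", "RD", "DD", "DSD")
        )
    }
    new("SimulationConfig",
        n_chroms = as.integer(n_chroms),
        genes_per_chrom = as.integer(genes_per_chrom),
        n_events = vapply(n_events, as.integer, integer(1)),
        wgd_retention = wgd_retention,
        target_ks = target_ks,
        target_ka_ks = target_ka_ks,
        n_tissues = as.integer(n_tissues),
        promoter_shared_fraction = promoter_shared_fraction,
        motif_min_len = as.integer(motif_min_len),
        seed = as.integer(seed)
    )
}

#' TruthSet: planted-event labels from the simulator
#'
#' @slot pairs `DataFrame` with one row per planted duplicate pair: `gene_a`,
#'   `gene_b`, `true_mode`, `true_ks`, `converted`.
#' @slot genes `DataFrame` with one row per gene carrying a planted mode:
#'   `gene`, `true_mode` (pair modes resolved by the WGD > TD > PD > RD > DD >
#'   DSD priority, like the classifier's gene-level labels).
#' @export
setClass(
    "TruthSet",
    representation(pairs = "DataFrame", genes = "DataFrame")
)

setValidity("TruthSet", function(object) {
    if (!all(c("gene_a", "gene_b", "true_mode", "true_ks", "converted") %in%
        colnames(object@pairs))) {
        return("pairs must have gene_a, gene_b, true_mode, true_ks, converted")
    }
    if (anyDuplicated(pairKey(object@pairs$gene_a, object@pairs$gene_b))) {
        return("every planted pair must appear exactly once")
    }
    if (!all(c("gene", "true_mode") %in% colnames(object@genes))) {
        return("genes must have columns gene, true_mode")
    }
    TRUE
})
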