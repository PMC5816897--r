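# Generics and accessors for the package's S4 classes.

#' @describeIn GenomeAnnotation-class Number of genes.
#' @param x,object A `GenomeAnnotation`.
#' @export
setMethod("length", "GenomeAnnotation", function(x) length(x@genes))

#' Accessors for GenomeAnnotation
#'
#' `genes()` returns the underlying `GRanges`; `geneIds()`, `geneRanks()` and
#' `exonCounts()` return named per-gene vectors; `chromLengths()` the named
#' chromosome lengths.
#'
#' @param x A [GenomeAnnotation-class] object.
#' @return See each accessor's description.
#' @name GenomeAnnotation-accessors
#' @aliases genes geneIds geneRanks exonCounts chromLengths
#' @examples
#' ga <- GenomeAnnotation(
#'     chrom = "chr1", start = c(100, 900), end = c(400, 1500),
#'     strand = "+", gene_id = c("g1", "g2"), exon_count = c(3L, 1L),
#'     chromLengths = c(chr1 = 5000)
#' )
#' geneIds(ga)
NULL

#' @rdname GenomeAnnotation-accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @rdname GenomeAnnotation-accessors
#' @export
setMethod("genes", "GenomeAnnotation", function(x) x@genes)

#' @rdname GenomeAnnotation-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname GenomeAnnotation-accessors
#' @export
setMethod("geneIds", "GenomeAnnotation", function(x) {
    S4Vectors::mcols(x@genes)$gene_id
})

#' @rdname GenomeAnnotation-accessors
#' @export
setGeneric("geneRanks", function(x) standardGeneric("geneRanks"))
#' @rdname GenomeAnnotation-accessors
#' @export
setMethod("geneRanks", "GenomeAnnotation", function(x) {
    stats::setNames(
        S4Vectors::mcols(x@genes)$rank,
        S4Vectors::mcols(x@genes)$gene_id
    )
})

#' @rdname GenomeAnnotation-accessors
#' @export
setGeneric("exonCounts", function(x) standardGeneric("exonCounts"))
#' @rdname GenomeAnnotation-accessors
#' @export
setMethod("exonCounts", "GenomeAnnotation", function(x) {
    stats::setNames(
        S4Vectors::mcols(x@genes)$exon_count,
        S4Vectors::mcols(x@genes)$gene_id
    )
})

#' @rdname GenomeAnnotation-accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))
#' @rdname GenomeAnnotation-accessors
#' @export
setMethod("chromLengths", "GenomeAnnotation", function(x) {
    GenomeInfoDb::seqlengths(x@genes)
})

setMethod("show", "GenomeAnnotation", function(object) {
    gr <- object@genes
    nChrom <- length(unique(as.character(GenomicRanges::seqnames(gr))))
    ranked <- !anyNA(S4Vectors::mcols(gr)$rank)
    cat(
        "GenomeAnnotation with", length(gr), "genes on", nChrom,
        "chromosome(s);", if (ranked) "ranks assigned\n" else "ranks unset\n"
    )
})

#' Accessors for CollinearBlockSet
#'
#' `anchors()` returns the per-anchor table, `blocks()` the per-block summary.
#' `length()` is the number of blocks.
#'
#' @param x A [CollinearBlockSet-class] object.
#' @name CollinearBlockSet-accessors
#' @aliases anchors blocks
NULL

#' @rdname CollinearBlockSet-accessors
#' @export
setGeneric("anchors", function(x) standardGeneric("anchors"))
#' @rdname CollinearBlockSet-accessors
#' @export
setMethod("anchors", "CollinearBlockSet", function(x) x@anchors)

#' @rdname CollinearBlockSet-accessors
#' @export
setGeneric("blocks", function(x) standardGeneric("blocks"))
#' @rdname CollinearBlockSet-accessors
#' @export
setMethod("blocks", "CollinearBlockSet", function(x) x@blocks)

#' @describeIn CollinearBlockSet-class Number of blocks.
#' @param x,object A `CollinearBlockSet`.
#' @export
setMethod("length", "CollinearBlockSet", function(x) nrow(x@blocks))

setMethod("show", "CollinearBlockSet", function(object) {
    cat(
        "CollinearBlockSet:", nrow(object@blocks), "block(s),",
        nrow(object@anchors), "anchor pair(s)\n"
    )
    if (nrow(object@blocks)) {
        utils::head(as.data.frame(object@blocks), 5) |> print()
    }
})

#' Component medians of a Ks mixture fit on the Ks scale
#'
#' The mixture is fitted on log-Ks, so exp(component mean) is the component
#' median on the Ks scale.
#'
#' @param x A [KsMixtureFit-class] object.
#' @return Numeric vector of per-component Ks medians, ascending.
#' @export
setGeneric("componentMedians", function(x) standardGeneric("componentMedians"))
#' @rdname componentMedians
#' @export
setMethod("componentMedians", "KsMixtureFit", function(x) exp(x@means))

setMethod("show", "KsMixtureFit", function(object) {
    cat("KsMixtureFit (Gaussian mixture on log-Ks)\n")
    cat("  Ks medians:", signif(exp(object@means), 4), "\n")
    cat("  weights:   ", signif(object@weights, 4), "\n")
    cat(
        "  loglik:", signif(object@loglik, 8), "after", object@n_iter,
        "iterations\n"
    )
})

#' Accessors for TruthSet
#'
#' @param x A [TruthSet-class] object.
#' @name TruthSet-accessors
#' @aliases truePairs trueGeneModes
NULL

#' @rdname TruthSet-accessors
#' @export
setGeneric("truePairs", function(x) standardGeneric("truePairs"))
#' @rdname TruthSet-accessors
#' @export
setMethod("truePairs", "TruthSet", function(x) x@pairs)

#' @rdname TruthSet-accessors
#' @export
setGeneric("trueGeneModes", function(x) standardGeneric("trueGeneModes"))
#' @rdname TruthSet-accessors
#' @export
setMethod("trueGeneModes", "TruthSet", function(x) {
    stats::setNames(x@genes$true_mode, x@genes$gene)
})

setMethod("show", "TruthSet", function(object) {
    cat("TruthSet:", nrow(object@pairs), "planted pair(s)\n")
    print(table(object@pairs$true_mode))
})

setMethod("show", "SimulationConfig", function(object) {
    cat(
        "SimulationConfig:", object@n_chroms, "chromosome(s) x",
        object@genes_per_chrom, "genes; WGD retention",
        object@wgd_retention, "\n"
    )
    cat("  single-gene events:", paste(names(object@n_events),
        object@n_events,
        sep = "=", collapse = " "
    ), "\n")
    cat("  seed:", object@seed, "\n")
})
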