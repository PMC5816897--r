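# Collinear (syntenic) block detection by chaining homology hits in gene-rank
# space, and block-level Ks summaries.
#
# Chaining: score-maximising DP per chromosome pair, score = n_anchors -
# gap_penalty * sum(rank gaps on both axes), strict monotonicity on both axes
# (rank_b increasing for "same" orientation, decreasing for "inverted"),
# per-step gap <= max_gap on both axes.  Non-overlapping chains are extracted
# greedily in descending score until no chain reaches min_block_size.

#' Detect collinear blocks
#'
#' Chains homology hits into collinear blocks in rank space, within one genome
#' (pass the same annotation twice) or between two genomes.  For intra-genome
#' input, hits are deduplicated to unordered pairs (best bit score kept) and
#' pairs are oriented so `gene_a` precedes `gene_b` in (chromosome, rank)
#' order, which suppresses self matches and mirror-image chains.
#'
#' @param hits `data.frame` from [readHomology()] (columns `query`, `subject`,
#'   `bitscore`; extra columns ignored).
#' @param annot_a,annot_b Ranked [GenomeAnnotation-class] objects (pass the
#'   same object twice for intra-genome detection).
#' @param min_block_size Minimum anchors per block (default 5).
#' @param max_gap Maximum rank gap between consecutive anchors on either axis
#'   (default 25).
#' @param gap_penalty Score penalty per skipped rank (default 0.05).
#' @param self_rank_min Intra-genome only: same-chromosome pairs separated by
#'   at most this many ranks are excluded from chaining (default `max_gap`),
#'   so tandem/proximal pairs near the self-comparison diagonal cannot form
#'   spurious blocks.
#' @return A [CollinearBlockSet-class]; blocks ordered by chromosome pair and
#'   first anchor rank.
#' @export
detectBlocks <- function(hits, annot_a, annot_b = annot_a,
                         min_block_size = 5L, max_gap = 25L,
                         gap_penalty = 0.05, self_rank_min = max_gap) {
    intra <- identical(annot_a, annot_b)
    infoA <- geneTable(annot_a)
    infoB <- geneTable(annot_b)
    h <- hits[hits$query %in% rownames(infoA) &
        hits$subject %in% rownames(infoB), , drop = FALSE]
    emptyResult <- function() {
        new("CollinearBlockSet",
            anchors = S4Vectors::DataFrame(
                block_id = integer(), gene_a = character(),
                gene_b = character(), rank_a = integer(), rank_b = integer(),
                chrom_a = character(), chrom_b = character()
            ),
            blocks = S4Vectors::DataFrame(
                block_id = integer(), chrom_a = character(),
                chrom_b = character(), orientation = character(),
                n_anchors = integer(), score = numeric(), mean_ks = numeric()
            )
        )
    }
    if (!nrow(h)) {
        return(emptyResult())
    }
    cand <- data.frame(
        gene_a = h$query, gene_b = h$subject,
        chrom_a = infoA[h$query, "chrom"], chrom_b = infoB[h$subject, "chrom"],
        rank_a = infoA[h$query, "rank"], rank_b = infoB[h$subject, "rank"],
        bitscore = if ("bitscore" %in% names(h)) h$bitscore else 0,
        stringsAsFactors = FALSE
    )
    cand <- cand[cand$gene_a != cand$gene_b | !intra, , drop = FALSE]
    if (intra) {
        cand <- cand[cand$gene_a != cand$gene_b, , drop = FALSE]
        # canonical orientation: gene_a first in (chrom, rank) order
        flip <- cand$chrom_a > cand$chrom_b |
            (cand$chrom_a == cand$chrom_b & cand$rank_a > cand$rank_b)
        cand[flip, c(
            "gene_a", "gene_b", "chrom_a", "chrom_b",
            "rank_a", "rank_b"
        )] <-
            cand[flip, c(
                "gene_b", "gene_a", "chrom_b", "chrom_a",
                "rank_b", "rank_a"
            )]
        key <- pairKey(cand$gene_a, cand$gene_b)
        ord <- order(key, -cand$bitscore)
        cand <- cand[ord[!duplicated(key[ord])], , drop = FALSE]
        # suppress the near-diagonal of chromosome self-comparison: local
        # (tandem/proximal-range) pairs would otherwise chain into spurious
        # blocks along the diagonal
        cand <- cand[cand$chrom_a != cand$chrom_b |
            cand$rank_b - cand$rank_a > self_rank_min, , drop = FALSE]
    }
    if (!nrow(cand)) {
        return(emptyResult())
    }
    cand <- cand[order(
        cand$chrom_a, cand$chrom_b, cand$rank_a, cand$rank_b,
        cand$gene_a, cand$gene_b
    ), , drop = FALSE]
    rownames(cand) <- NULL

    groups <- split(
        seq_len(nrow(cand)),
        paste(cand$chrom_a, cand$chrom_b, sep = "\r")
    )
    groups <- groups[order(names(groups))]
    anchorRows <- list()
    blockRows <- list()
    bid <- 0L
    for (g in groups) {
        sub <- cand[g, , drop = FALSE]
        used <- rep(FALSE, nrow(sub))
        repeat {
            avail <- which(!used)
            if (length(avail) < min_block_size) break
            best <- NULL
            for (orientation in c("same", "inverted")) {
                ch <- chainDP(
                    sub$rank_a[avail], sub$rank_b[avail],
                    orientation, max_gap, gap_penalty
                )
                if (is.null(best) || ch$score > best$score) {
                    ch$orientation <- orientation
                    ch$rows <- avail[ch$members]
                    best <- ch
                }
            }
            if (length(best$rows) < min_block_size) break
            bid <- bid + 1L
            chosen <- sub[best$rows, , drop = FALSE]
            anchorRows[[bid]] <- data.frame(
                block_id = bid, chosen[, c(
                    "gene_a", "gene_b", "rank_a",
                    "rank_b", "chrom_a", "chrom_b"
                )],
                stringsAsFactors = FALSE
            )
            blockRows[[bid]] <- data.frame(
                block_id = bid,
                chrom_a = chosen$chrom_a[1], chrom_b = chosen$chrom_b[1],
                orientation = best$orientation,
                n_anchors = nrow(chosen), score = best$score,
                mean_ks = NA_real_, stringsAsFactors = FALSE
            )
            used[best$rows] <- TRUE
        }
    }
    if (!bid) {
        return(emptyResult())
    }
    a <- do.call(rbind, anchorRows)
    b <- do.call(rbind, blockRows)
    # deterministic block order: chromosome pair, then first anchor rank
    firstRank <- vapply(
        split(a$rank_a, a$block_id),
        min, numeric(1)
    )[as.character(b$block_id)]
    ord <- order(b$chrom_a, b$chrom_b, firstRank)
    remap <- stats::setNames(seq_along(ord), b$block_id[ord])
    b <- b[ord, , drop = FALSE]
    b$block_id <- unname(remap[as.character(b$block_id)])
    a$block_id <- unname(remap[as.character(a$block_id)])
    a <- a[order(a$block_id, a$rank_a), , drop = FALSE]
    new("CollinearBlockSet",
        anchors = S4Vectors::DataFrame(a, row.names = NULL),
        blocks = S4Vectors::DataFrame(b, row.names = NULL)
    )
}

# (chrom, rank) lookup table keyed by gene id.
geneTable <- function(annotation) {
    gr <- genes(annotation)
    rk <- S4Vectors::mcols(gr)$rank
    if (length(gr) && anyNA(rk)) {
        stop("ranks not assigned; call assignRanks() first")
    }
    out <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        rank = rk, stringsAsFactors = FALSE
    )
    rownames(out) <- S4Vectors::mcols(gr)$gene_id
    out
}

# Best-scoring chain with strict monotonicity on both axes and bounded gaps.
# Returns member indices (into the input vectors) and the chain score.
chainDP <- function(ra, rb, orientation, max_gap, gap_penalty) {
    if (orientation == "inverted") rb <- -rb
    n <- length(ra)
    ord <- order(ra, rb)
    ra <- ra[ord]
    rb <- rb[ord]
    score <- rep(1, n)
    prev <- rep(0L, n)
    for (i in seq_len(n)) {
        for (j in seq_len(i - 1L)) {
            if (ra[j] >= ra[i] || rb[j] >= rb[i]) next
            gapA <- ra[i] - ra[j] - 1L
            gapB <- abs(rb[i] - rb[j]) - 1L
            if (gapA > max_gap || gapB > max_gap) next
            s <- score[j] + 1 - gap_penalty * (gapA + gapB)
            if (s > score[i] + 1e-12) {
                score[i] <- s
                prev[i] <- j
            }
        }
    }
    endAt <- which.max(score)
    members <- integer(0)
    i <- endAt
    while (i != 0L) {
        members <- c(i, members)
        i <- prev[i]
    }
    list(members = ord[members], score = score[endAt])
}

#' Fill per-block mean Ks
#'
#' The block mean is taken over anchors with finite Ks; anchors with missing
#' or saturated Ks are excluded.  Blocks with no finite-Ks anchor get
#' `mean_ks = NA`.
#'
#' @param blockset A [CollinearBlockSet-class].
#' @param pair_ks Named numeric vector of Ks keyed by unordered pair
#'   (`pairKey` format `"a|b"`, a < b) or a `data.frame` with `gene_a`,
#'   `gene_b`, `ks`.
#' @return The block set with `mean_ks` filled.
#' @export
blockMeanKs <- function(blockset, pair_ks) {
    if (is.data.frame(pair_ks)) {
        pair_ks <- stats::setNames(
            pair_ks$ks,
            pairKey(pair_ks$gene_a, pair_ks$gene_b)
        )
    }
    a <- anchors(blockset)
    ks <- unname(pair_ks[pairKey(a$gene_a, a$gene_b)])
    means <- tapply(ks, a$block_id, function(v) {
        v <- v[is.finite(v)]
        if (length(v)) mean(v) else NA_real_
    })
    b <- blocks(blockset)
    b$mean_ks <- unname(means[as.character(b$block_id)])
    initialize(blockset, blocks = b)
}

#' Select gene pairs from blocks in a Ks window
#'
#' Returns the union of anchor pairs of blocks whose mean Ks falls inside
#' `[ks_lo, ks_hi]` — e.g. a recent-WGD window around the younger Ks peak or
#' an ancient-WGD window around the older one.
#'
#' @param blockset A [CollinearBlockSet-class] with `mean_ks` filled.
#' @param ks_lo,ks_hi Window bounds (inclusive).
#' @return `data.frame` with columns `gene_a`, `gene_b`, `block_id`.
#' @export
selectBlocksByKs <- function(blockset, ks_lo, ks_hi) {
    if (ks_lo > ks_hi) {
        stop("ks_lo must not exceed ks_hi")
    }
    b <- blocks(blockset)
    keep <- b$block_id[!is.na(b$mean_ks) &
        b$mean_ks >= ks_lo & b$mean_ks <= ks_hi]
    a <- anchors(blockset)
    out <- as.data.frame(a[a$block_id %in% keep,
        c("gene_a", "gene_b", "block_id"),
        drop = FALSE
    ])
    rownames(out) <- NULL
    out
}
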