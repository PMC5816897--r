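# Assignment of every homologous gene pair, then every gene, to a duplication
# mode under the priority WGD > TD > PD > RD > DD > DSD.

#' Deduplicate directed hits to unordered pairs
#'
#' Reciprocal BLAST-style hits are collapsed to one row per unordered pair,
#' keeping the direction with the best bit score (ties: lower E-value).
#'
#' @param hits `data.frame` from [readHomology()].
#' @return `data.frame` with columns `gene_a`, `gene_b` (a < b
#'   lexicographically), `pct_identity`, `evalue`, `bitscore`.
#' @export
dedupeHits <- function(hits) {
    h <- hits[hits$query != hits$subject, , drop = FALSE]
    if (!nrow(h)) {
        return(data.frame(
            gene_a = character(), gene_b = character(),
            pct_identity = numeric(), evalue = numeric(), bitscore = numeric(),
            stringsAsFactors = FALSE
        ))
    }
    key <- pairKey(h$query, h$subject)
    ord <- order(key, -h$bitscore, h$evalue)
    h <- h[ord[!duplicated(key[ord])], , drop = FALSE]
    out <- data.frame(
        gene_a = pmin(h$query, h$subject),
        gene_b = pmax(h$query, h$subject),
        pct_identity = h$pct_identity,
        evalue = h$evalue,
        bitscore = h$bitscore,
        stringsAsFactors = FALSE
    )
    out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Classify WGD, tandem and proximal pairs
#'
#' Anchor pairs of collinear blocks are WGD; same-chromosome non-anchor pairs
#' with gene-rank difference 1 are tandem (TD); those with rank difference
#' strictly between 1 and `proximal_rank_max` are proximal (PD).  A pair that
#' is both an anchor and rank-adjacent is WGD (priority).  Everything else is
#' returned as the residual for the transposed/dispersed stages.
#'
#' @param hits Directed hits ([readHomology()]) or deduplicated pairs
#'   ([dedupeHits()]).
#' @param annotation Ranked [GenomeAnnotation-class].
#' @param blockset [CollinearBlockSet-class] detected on the same hit set.
#' @param proximal_rank_max Proximal window: rank difference must be strictly
#'   below this (default 20).
#' @return List with `pairs` (`data.frame`: `gene_a`, `gene_b`, `mode`,
#'   `parent`, plus hit statistics) and `residual` (unclassified pairs).
#' @export
classifyWgdTdPd <- function(hits, annotation, blockset,
                            proximal_rank_max = 20L) {
    pairs <- if (all(c("gene_a", "gene_b") %in% names(hits))) {
        hits
    } else {
        dedupeHits(hits)
    }
    info <- geneTable(annotation)
    pairs <- pairs[pairs$gene_a %in% rownames(info) &
        pairs$gene_b %in% rownames(info), , drop = FALSE]
    anchorKeys <- pairKey(anchors(blockset)$gene_a, anchors(blockset)$gene_b)
    key <- pairKey(pairs$gene_a, pairs$gene_b)
    sameChrom <- info[pairs$gene_a, "chrom"] == info[pairs$gene_b, "chrom"]
    rankDiff <- abs(info[pairs$gene_a, "rank"] - info[pairs$gene_b, "rank"])
    mode <- rep(NA_character_, nrow(pairs))
    mode[key %in% anchorKeys] <- "WGD"
    td <- is.na(mode) & sameChrom & rankDiff == 1L
    pd <- is.na(mode) & sameChrom & rankDiff > 1L &
        rankDiff < proximal_rank_max
    mode[td] <- "TD"
    mode[pd] <- "PD"
    labeled <- pairs[!is.na(mode), , drop = FALSE]
    labeled$mode <- mode[!is.na(mode)]
    labeled$parent <- NA_character_
    residual <- pairs[is.na(mode), , drop = FALSE]
    rownames(labeled) <- rownames(residual) <- NULL
    list(pairs = labeled, residual = residual)
}

#' Identify ancestral loci from outgroup synteny
#'
#' A focal gene is at an ancestral locus when it is an anchor of a collinear
#' block against at least one outgroup genome (union over outgroups).
#'
#' @param outgroup_blocks A [CollinearBlockSet-class] of focal-vs-outgroup
#'   blocks (focal genes on the `gene_a` side), or a list of them.
#' @return Character vector of ancestral focal gene ids.
#' @export
identifyAncestralLoci <- function(outgroup_blocks) {
    if (methods::is(outgroup_blocks, "CollinearBlockSet")) {
        outgroup_blocks <- list(outgroup_blocks)
    }
    anc <- unique(unlist(lapply(
        outgroup_blocks,
        function(b) anchors(b)$gene_a
    )))
    if (!length(anc)) {
        warning(
            "no focal-vs-outgroup blocks: ancestral set is empty, ",
            "transposed duplications cannot be called"
        )
        return(character(0))
    }
    sort(anc)
}

#' Classify transposed (RD/DD) pairs
#'
#' A residual pair with exactly one member at an ancestral locus is a
#' transposed candidate (ancestral member = parent, other = novel copy).  When
#' a novel gene has several ancestral candidates, the one with the highest
#' percent identity (ties: lower E-value, higher bit score, then id) is its
#' parent.  The chosen pair is retrotransposed (RD) when the parent has
#' `>= parent_exon_min` exons and the copy is intronless (1 exon); it is
#' dropped when both genes are single-exon; otherwise it is DNA-transposed
#' (DD).  A novel gene's non-parent candidate pairs, and pairs with both or
#' neither member ancestral, return in the residual.
#'
#' @param residual Residual pairs from [classifyWgdTdPd()].
#' @param ancestral_set Character vector from [identifyAncestralLoci()].
#' @param exon_counts Named integer vector (`gene id -> exon count`).
#' @param parent_exon_min Minimum parent exon count for an RD call
#'   (default 3).
#' @return List with `pairs` (RD/DD rows, `parent` filled), `removed`
#'   (single-exon/single-exon pairs) and `residual`.
#' @export
classifyTransposed <- function(residual, ancestral_set, exon_counts,
                               parent_exon_min = 3L) {
    if (!nrow(residual)) {
        return(list(
            pairs = cbind(residual, mode = character(0), parent = character(0)),
            removed = residual, residual = residual
        ))
    }
    aAnc <- residual$gene_a %in% ancestral_set
    bAnc <- residual$gene_b %in% ancestral_set
    isCand <- xor(aAnc, bAnc)
    cand <- residual[isCand, , drop = FALSE]
    rest <- residual[!isCand, , drop = FALSE]
    if (!nrow(cand)) {
        return(list(
            pairs = cbind(
                rest[0, , drop = FALSE],
                mode = character(0), parent = character(0)
            ),
            removed = rest[0, , drop = FALSE], residual = rest
        ))
    }
    candAAnc <- aAnc[isCand]
    cand$novel <- ifelse(candAAnc, cand$gene_b, cand$gene_a)
    cand$ancestor <- ifelse(candAAnc, cand$gene_a, cand$gene_b)
    # best parent per novel gene: identity desc, evalue asc, bitscore desc, id
    ord <- order(
        cand$novel, -cand$pct_identity, cand$evalue,
        -cand$bitscore, cand$ancestor
    )
    chosen <- ord[!duplicated(cand$novel[ord])]
    isParentPair <- seq_len(nrow(cand)) %in% chosen
    rest <- rbind(
        rest,
        cand[!isParentPair, !(names(cand) %in% c("novel", "ancestor")),
            drop = FALSE
        ]
    )
    par <- cand[isParentPair, , drop = FALSE]
    exNovel <- unname(exon_counts[par$novel])
    exParent <- unname(exon_counts[par$ancestor])
    isRd <- exParent >= parent_exon_min & exNovel == 1L
    isRemoved <- exParent == 1L & exNovel == 1L
    out <- par[, !(names(par) %in% c("novel", "ancestor")), drop = FALSE]
    out$mode <- ifelse(isRd, "RD", "DD")
    out$parent <- par$ancestor
    removed <- out[isRemoved, , drop = FALSE]
    out <- out[!isRemoved, , drop = FALSE]
    rest <- rest[order(rest$gene_a, rest$gene_b), , drop = FALSE]
    rownames(out) <- rownames(removed) <- rownames(rest) <- NULL
    list(pairs = out, removed = removed, residual = rest)
}

#' Classify remaining pairs as dispersed
#'
#' Every pair surviving the WGD/TD/PD and transposed stages is a dispersed
#' duplication (DSD).
#'
#' @param residual Residual pairs after [classifyTransposed()].
#' @return The residual with `mode = "DSD"` and an empty `parent` column.
#' @export
classifyDispersed <- function(residual) {
    residual$mode <- rep("DSD", nrow(residual))
    residual$parent <- rep(NA_character_, nrow(residual))
    residual
}

#' Resolve gene-level duplication modes
#'
#' Each gene receives the highest-priority mode among its classified pairs
#' (WGD > TD > PD > RD > DD > DSD); genes in no classified pair are
#' singletons.  Idempotent: re-running on its own output changes nothing.
#'
#' @param pairs Classified pair table (columns `gene_a`, `gene_b`, `mode`).
#' @param gene_ids All annotated gene ids.
#' @return Named character vector `gene id -> mode` covering every gene.
#' @export
finalizeGeneModes <- function(pairs, gene_ids) {
    prio <- stats::setNames(seq_along(modeLevels()), modeLevels())
    best <- rep(prio["SINGLETON"], length(gene_ids))
    names(best) <- gene_ids
    if (nrow(pairs)) {
        p <- prio[pairs$mode]
        for (side in c("gene_a", "gene_b")) {
            g <- pairs[[side]]
            keep <- g %in% gene_ids
            agg <- tapply(p[keep], g[keep], min)
            best[names(agg)] <- pmin(best[names(agg)], agg)
        }
    }
    stats::setNames(modeLevels()[best], names(best))
}

#' Per-window mode densities and their correlations
#'
#' Counts mode-labeled genes (by gene start) in sliding windows along each
#' chromosome and computes the Pearson correlation between the density
#' vectors of each mode pair per chromosome.  Correlations are NA when either
#' density vector is constant.
#'
#' @param gene_modes Named vector from [finalizeGeneModes()].
#' @param annotation Ranked [GenomeAnnotation-class] with chromosome lengths.
#' @param window_bp,step_bp Window and step size in bp
#'   (`window_bp >= step_bp > 0`); a chromosome shorter than the window gets
#'   a single window.
#' @return List with `density` (`data.frame`: chrom, window_start, one count
#'   column per mode) and `correlations` (`data.frame`: chrom, mode_a,
#'   mode_b, r).
#' @export
modeDensityProfile <- function(gene_modes, annotation, window_bp, step_bp) {
    stopifnot(window_bp >= step_bp, step_bp > 0)
    gr <- genes(annotation)
    sl <- chromLengths(annotation)
    modes <- setdiff(modeLevels(), "SINGLETON")
    chrom <- as.character(GenomicRanges::seqnames(gr))
    pos <- GenomicRanges::start(gr)
    gmode <- unname(gene_modes[S4Vectors::mcols(gr)$gene_id])
    densityRows <- list()
    corRows <- list()
    for (ch in names(sl)) {
        len <- sl[[ch]]
        starts <- if (len <= window_bp) {
            1L
        } else {
            seq(1L, len - window_bp + 1L, by = step_bp)
        }
        counts <- matrix(0L, length(starts), length(modes),
            dimnames = list(NULL, modes)
        )
        inChrom <- chrom == ch & gmode %in% modes
        for (w in seq_along(starts)) {
            inWin <- inChrom & pos >= starts[w] &
                pos < starts[w] + window_bp
            if (any(inWin)) {
                tb <- table(gmode[inWin])
                counts[w, names(tb)] <- as.integer(tb)
            }
        }
        densityRows[[ch]] <- data.frame(
            chrom = ch, window_start = starts, counts,
            stringsAsFactors = FALSE
        )
        for (i in seq_len(length(modes) - 1L)) {
            for (j in seq(i + 1L, length(modes))) {
                x <- counts[, i]
                y <- counts[, j]
                r <- if (length(x) > 1 && stats::sd(x) > 0 &&
                    stats::sd(y) > 0) {
                    stats::cor(x, y)
                } else {
                    NA_real_
                }
                corRows[[length(corRows) + 1L]] <- data.frame(
                    chrom = ch, mode_a = modes[i], mode_b = modes[j], r = r,
                    stringsAsFactors = FALSE
                )
            }
        }
    }
    list(
        density = do.call(rbind, c(densityRows, make.row.names = FALSE)),
        correlations = do.call(rbind, c(corRows, make.row.names = FALSE))
    )
}

#' Run the full pair-classification cascade
#'
#' Convenience wrapper: WGD/TD/PD by anchors and rank rules, then transposed
#' (RD/DD) against the ancestral-locus set, then dispersed (DSD), then
#' gene-level modes by priority.
#'
#' @param hits Directed homology hits within the focal genome.
#' @param annotation Ranked focal [GenomeAnnotation-class].
#' @param blockset Intra-genome [CollinearBlockSet-class] on the same hits.
#' @param ancestral_set Ancestral gene ids ([identifyAncestralLoci()]).
#' @param proximal_rank_max,parent_exon_min See [classifyWgdTdPd()] and
#'   [classifyTransposed()].
#' @return List with `pairs` (all classified pairs), `removed` (single-exon
#'   transposed pairs set aside) and `gene_modes` (named vector).
#' @export
classifyDuplicates <- function(hits, annotation, blockset, ancestral_set,
                               proximal_rank_max = 20L,
                               parent_exon_min = 3L) {
    stage1 <- classifyWgdTdPd(hits, annotation, blockset, proximal_rank_max)
    stage2 <- classifyTransposed(
        stage1$residual, ancestral_set,
        exonCounts(annotation), parent_exon_min
    )
    dsd <- classifyDispersed(stage2$residual)
    pairs <- rbind(stage1$pairs, stage2$pairs, dsd)
    pairs <- pairs[order(match(pairs$mode, modeLevels()), pairs$gene_a,
        pairs$gene_b), , drop = FALSE]
    rownames(pairs) <- NULL
    list(
        pairs = pairs,
        removed = stage2$removed,
        gene_modes = finalizeGeneModes(pairs, geneIds(annotation))
    )
}
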