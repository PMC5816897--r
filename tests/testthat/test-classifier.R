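# Mode classification: rank rules, ancestral-locus logic, transposed calls,
# gene-level priority and density profiles.

# a hand-built annotation: one chromosome, 30 genes at known ranks
clAnnot <- function(exons = NULL) {
    n <- 30L
    if (is.null(exons)) exons <- rep(1L, n)
    assignRanks(GenomeAnnotation(
        chrom = "chr1",
        start = seq(1000, by = 1000, length.out = n),
        end = seq(1000, by = 1000, length.out = n) + 500,
        strand = "+",
        gene_id = sprintf("g%02d", seq_len(n)),
        exon_count = exons,
        chromLengths = c(chr1 = 40000)
    ))
}

emptyBlocks <- function() {
    detectBlocks(
        data.frame(
            query = character(), subject = character(),
            pct_identity = numeric(), evalue = numeric(),
            bitscore = numeric()
        ),
        clAnnot()
    )
}

hit <- function(q, s, ident = 90, ev = 1e-30, bits = 100) {
    data.frame(
        query = q, subject = s, pct_identity = ident, evalue = ev,
        bitscore = bits, stringsAsFactors = FALSE
    )
}

test_that("rank rules assign TD and PD; anchors win as WGD", {
    ann <- clAnnot()
    h <- rbind(
        hit("g01", "g02"), # rank diff 1 -> TD
        hit("g05", "g15"), # rank diff 10 -> PD
        hit("g10", "g30") # rank diff 20 -> residual
    )
    res <- classifyWgdTdPd(h, ann, emptyBlocks())
    modes <- stats::setNames(res$pairs$mode, paste(
        res$pairs$gene_a,
        res$pairs$gene_b
    ))
    expect_equal(unname(modes["g01 g02"]), "TD")
    expect_equal(unname(modes["g05 g15"]), "PD")
    expect_equal(nrow(res$residual), 1L)

    # a pair that is an anchor AND rank-adjacent is WGD by priority
    annB <- makeRankAnnot(10, "c2", "h")
    annA <- clAnnot()
    diag <- data.frame(
        query = sprintf("g%02d", 1:5), subject = sprintf("g%02d", 2:6),
        pct_identity = 90, evalue = 1e-30, bitscore = 100
    )
    bs <- detectBlocks(diag, ann, self_rank_min = 0L)
    res2 <- classifyWgdTdPd(diag, ann, bs)
    expect_true(all(res2$pairs$mode == "WGD"))
})

test_that("transposed rules separate RD, DD and removed pairs", {
    exons <- rep(1L, 30)
    exons[4] <- 4L # g04 multi-exon
    exons[8] <- 4L
    exons[12] <- 3L
    exons[25] <- 3L # novel with introns
    ann <- clAnnot(exons)
    ancestral <- sprintf("g%02d", 1:15)
    residual <- dedupeHits(rbind(
        hit("g04", "g22"), # parent 4 exons, novel 1 exon -> RD
        hit("g08", "g25"), # parent 4 exons, novel 3 exons -> DD
        hit("g02", "g28"), # both single exon -> removed
        hit("g03", "g09"), # both ancestral -> residual (DSD)
        hit("g21", "g29") # both novel -> residual (DSD)
    ))
    res <- classifyTransposed(residual, ancestral, exonCounts(ann))
    modes <- stats::setNames(res$pairs$mode, paste(
        res$pairs$gene_a,
        res$pairs$gene_b
    ))
    expect_equal(unname(modes["g04 g22"]), "RD")
    expect_equal(unname(modes["g08 g25"]), "DD")
    expect_equal(res$pairs$parent, c("g04", "g08"))
    expect_equal(nrow(res$removed), 1L)
    expect_equal(nrow(res$residual), 2L)
    dsd <- classifyDispersed(res$residual)
    expect_true(all(dsd$mode == "DSD"))
    expect_equal(nrow(classifyDispersed(res$residual[0, ])), 0L)
})

test_that("the best-identity ancestral candidate becomes the parent", {
    exons <- rep(1L, 30)
    exons[c(4, 6)] <- 4L
    ann <- clAnnot(exons)
    residual <- dedupeHits(rbind(
        hit("g04", "g22", ident = 95),
        hit("g06", "g22", ident = 85)
    ))
    res <- classifyTransposed(residual, c("g04", "g06"), exonCounts(ann))
    expect_equal(nrow(res$pairs), 1L)
    expect_equal(res$pairs$parent, "g04")
    # the non-parent candidate falls back to the residual
    expect_equal(nrow(res$residual), 1L)
})

test_that("ancestral loci are the union of outgroup anchors", {
    sim <- smallSim()
    ob <- detectBlocks(
        sim$outgroup_hits, sim$annotation,
        sim$outgroup$annotation
    )
    anc <- identifyAncestralLoci(ob)
    expect_true(all(grepl("^chr[12]_g[0-9]+$", anc)))
    truth <- as.data.frame(truePairs(sim$truth))
    daughters <- truth$gene_b[truth$true_mode == "RD"]
    expect_false(any(daughters %in% anc))
    # union over two outgroups
    anc2 <- identifyAncestralLoci(list(ob, ob))
    expect_setequal(anc, anc2)
    expect_warning(
        empty <- identifyAncestralLoci(emptyBlocks()),
        "empty"
    )
    expect_length(empty, 0L)
})

test_that("gene-level modes follow priority, cover all genes, idempotent", {
    pairs <- data.frame(
        gene_a = c("x", "x", "y"),
        gene_b = c("w", "t", "t"),
        mode = c("WGD", "TD", "PD"),
        stringsAsFactors = FALSE
    )
    gm <- finalizeGeneModes(pairs, c("x", "w", "t", "y", "lonely"))
    expect_equal(unname(gm["x"]), "WGD")
    expect_equal(unname(gm["t"]), "TD")
    expect_equal(unname(gm["y"]), "PD")
    expect_equal(unname(gm["lonely"]), "SINGLETON")
    expect_equal(sum(table(gm)), 5L)
    # idempotence: rebuilding from gene-level labels changes nothing
    gm2 <- finalizeGeneModes(pairs, names(gm))
    expect_identical(gm, gm2)
})

test_that("every input hit ends in exactly one category", {
    sim <- smallSim()
    bs <- detectBlocks(sim$hits, sim$annotation)
    ob <- detectBlocks(
        sim$outgroup_hits, sim$annotation,
        sim$outgroup$annotation
    )
    cls <- classifyDuplicates(
        sim$hits, sim$annotation, bs,
        identifyAncestralLoci(ob)
    )
    inPairs <- dedupeHits(sim$hits)
    keysIn <- pairKey(inPairs$gene_a, inPairs$gene_b)
    keysOut <- c(
        pairKey(cls$pairs$gene_a, cls$pairs$gene_b),
        pairKey(cls$removed$gene_a, cls$removed$gene_b)
    )
    expect_setequal(keysIn, keysOut)
    expect_false(anyDuplicated(keysOut) > 0)
    # gene-level conservation: mode counts + singletons = total genes
    expect_equal(sum(table(cls$gene_modes)), length(sim$annotation))
})

test_that("planted modes are recovered on a decoy-free simulation", {
    sim <- smallSim()
    bs <- detectBlocks(sim$hits, sim$annotation)
    ob <- detectBlocks(
        sim$outgroup_hits, sim$annotation,
        sim$outgroup$annotation
    )
    cls <- classifyDuplicates(
        sim$hits, sim$annotation, bs,
        identifyAncestralLoci(ob)
    )
    tg <- trueGeneModes(sim$truth)
    gm <- cls$gene_modes
    common <- intersect(names(tg), names(gm))
    expect_gte(mean(gm[common] == tg[common]), 0.95)
    for (m in c("WGD", "TD", "PD")) {
        g <- common[tg[common] == m]
        expect_equal(mean(gm[g] == m), 1, info = m)
    }
})

test_that("density profiles report the expected correlations", {
    n <- 40L
    ann <- assignRanks(GenomeAnnotation(
        chrom = "chr1",
        start = seq(500, by = 1000, length.out = n),
        end = seq(500, by = 1000, length.out = n) + 400,
        strand = "+", gene_id = sprintf("d%02d", 1:n), exon_count = 1L,
        chromLengths = c(chr1 = 41000)
    ))
    # complementary halves: WGD genes left, DSD genes right -> negative r
    gm <- stats::setNames(
        c(rep("WGD", 20), rep("DSD", 20)),
        sprintf("d%02d", 1:n)
    )
    prof <- modeDensityProfile(gm, ann, window_bp = 5000L, step_bp = 5000L)
    r <- prof$correlations
    expect_lt(r$r[r$mode_a == "WGD" & r$mode_b == "DSD"], 0)
    # identical density vectors -> r = 1 (TD planted alongside WGD)
    gm2 <- gm
    gm2[seq(2, 20, 2)] <- "TD"
    gm2[seq(1, 19, 2)] <- "WGD"
    prof2 <- modeDensityProfile(gm2, ann, 10000L, 10000L)
    r2 <- prof2$correlations
    expect_equal(r2$r[r2$mode_a == "WGD" & r2$mode_b == "TD"], 1)
    # a mode absent everywhere gives a missing correlation
    expect_true(is.na(r$r[r$mode_a == "TD" & r$mode_b == "PD"]))
    # chromosome shorter than the window: a single window
    prof3 <- modeDensityProfile(gm, ann, 100000L, 50000L)
    expect_equal(nrow(prof3$density), 1L)
})
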