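# The synthetic-genome simulator: planted events, sequence evolution,
# outgroup, expression and promoter generation.

test_that("base genome has the configured size, gaps and determinism", {
    cfg <- simulationConfig(n_chroms = 2L, genes_per_chrom = 30L, seed = 5L)
    base <- simulateBaseGenome(cfg)
    expect_equal(length(base$annotation), 60L)
    gr <- genes(base$annotation)
    for (ch in c("chr1", "chr2")) {
        sub <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
        sub <- sub[order(GenomicRanges::start(sub))]
        gaps <- GenomicRanges::start(sub)[-1] -
            GenomicRanges::end(sub)[-length(sub)]
        expect_true(all(gaps >= 1L))
    }
    base2 <- simulateBaseGenome(cfg)
    expect_identical(as.character(base$cds), as.character(base2$cds))
    expect_identical(as.character(base$genome), as.character(base2$genome))
    expect_equal(
        GenomicRanges::start(genes(base$annotation)),
        GenomicRanges::start(genes(base2$annotation))
    )
})

test_that("evolvePair hits its divergence targets and edge cases", {
    set.seed(99)
    a <- randomCds(200)
    expect_identical(evolvePair(a, 0, 0.3), a)
    expect_error(evolvePair(a, -0.1, 0.3), "target_ks")
    # target_ka_ks = 0: synonymous changes only, protein unchanged
    b <- evolvePair(a, 0.3, 0, seed = 7L)
    expect_false(identical(a, b))
    expect_identical(
        as.character(Biostrings::translate(Biostrings::DNAString(a))),
        as.character(Biostrings::translate(Biostrings::DNAString(b)))
    )
    # NG86 recovers the target Ks on average (reduced replicate count here;
    # the full 200-replicate check runs in the acceptance suite)
    ks <- replicate(40, {
        x <- randomCds(300)
        ng86(alignCodons(x, evolvePair(x, 0.2, 0.3)))$ks
    })
    expect_lt(abs(mean(ks) - 0.2), 0.03)
})

test_that("planted events match their definitions and the truth set", {
    sim <- smallSim()
    truth <- as.data.frame(truePairs(sim$truth))
    expect_equal(
        unname(table(truth$true_mode)[c("TD", "PD", "RD", "DD", "DSD")]),
        c(8L, 8L, 4L, 4L, 8L),
        ignore_attr = TRUE
    )
    expect_false(anyDuplicated(paste(truth$gene_a, truth$gene_b)) > 0)
    rk <- geneRanks(sim$annotation)
    ex <- exonCounts(sim$annotation)
    gr <- genes(sim$annotation)
    chrom <- stats::setNames(
        as.character(GenomicRanges::seqnames(gr)),
        geneIds(sim$annotation)
    )
    td <- truth[truth$true_mode == "TD", ]
    expect_true(all(abs(rk[td$gene_a] - rk[td$gene_b]) == 1L))
    pd <- truth[truth$true_mode == "PD", ]
    dpd <- abs(rk[pd$gene_a] - rk[pd$gene_b])
    expect_true(all(dpd > 1L & dpd < 20L))
    rd <- truth[truth$true_mode == "RD", ]
    expect_true(all(ex[rd$gene_b] == 1L))
    expect_true(all(ex[rd$gene_a] >= 3L))
    dd <- truth[truth$true_mode == "DD", ]
    expect_true(all(ex[dd$gene_b] >= 2L))
    dsd <- truth[truth$true_mode == "DSD", ]
    expect_true(all(
        chrom[dsd$gene_a] != chrom[dsd$gene_b] |
            abs(rk[dsd$gene_a] - rk[dsd$gene_b]) >= 25L
    ))
})

test_that("full WGD retention gives every base gene a partner", {
    cfg <- simulationConfig(
        n_chroms = 1L, genes_per_chrom = 25L,
        n_events = c(TD = 0L, PD = 0L, RD = 0L, DD = 0L, DSD = 0L),
        wgd_retention = 1.0, seed = 3L
    )
    planted <- plantEvents(simulateBaseGenome(cfg), cfg)
    truth <- as.data.frame(truePairs(planted$truth))
    expect_equal(sum(truth$true_mode == "WGD"), 25L)
    expect_setequal(truth$gene_a, sprintf("chr1_g%04d", 1:25))
})

test_that("outgroup preserves ancestral order and omits planted copies", {
    sim <- smallSim()
    og <- simulateOutgroup(
        list(records = sim$records), simCache$cfg,
        ortholog_ks = 0.3
    )
    # every ancestral gene has exactly one ortholog, in conserved order
    expect_equal(nrow(og$ortholog_map), 240L)
    expect_true(all(grepl("^og_", og$ortholog_map$ortholog)))
    truth <- as.data.frame(truePairs(sim$truth))
    daughters <- truth$gene_b[truth$true_mode %in% c("RD", "DD", "TD", "PD")]
    expect_false(any(daughters %in% og$ortholog_map$gene))
    expect_false(any(grepl("_w$", og$ortholog_map$gene)))
    # conserved 1:1 order: outgroup ranks follow focal base-gene order
    ogRanks <- geneRanks(og$annotation)
    focRanks <- geneRanks(sim$annotation)
    m <- og$ortholog_map
    for (ch in c("chr1", "chr2")) {
        sub <- m[grepl(paste0("^", ch, "_"), m$gene), ]
        expect_false(is.unsorted(ogRanks[sub$ortholog][order(focRanks[sub$gene])]))
    }
    # ortholog divergence is centred on the target
    ksVals <- vapply(seq_len(12), function(i) {
        g <- m$gene[i]
        ng86(alignCodons(
            as.character(sim$cds[[g]]),
            as.character(og$cds[[m$ortholog[i]]])
        ))$ks
    }, numeric(1))
    expect_lt(abs(mean(ksVals) - 0.3), 0.06)
})

test_that("expression simulation honours correlation targets and background", {
    pairs <- data.frame(
        gene_a = sprintf("a%d", 1:40), gene_b = sprintf("b%d", 1:40),
        stringsAsFactors = FALSE
    )
    # r = 1 with no noise: exact affine duplicates
    ex1 <- simulateExpression(pairs[1, ], 1, n_tissues = 12L, noise_sd = 0,
        seed = 2L)
    expect_equal(stats::cor(ex1$tpm["a1", ], ex1$tpm["b1", ]), 1)
    # r = 0: mean sample correlation near zero
    ex0 <- simulateExpression(pairs, 0, n_tissues = 12L, seed = 3L)
    rs <- vapply(seq_len(40), function(i) {
        stats::cor(ex0$tpm[pairs$gene_a[i], ], ex0$tpm[pairs$gene_b[i], ])
    }, numeric(1))
    expect_lt(abs(mean(rs)), 0.1) # 40 pairs; the 10k-pair check is analytic
    # intergenic background sits far below genic levels in every sample
    med <- apply(ex0$intergenic_tpm, 2, stats::median)
    gen <- apply(ex0$tpm, 2, stats::median)
    expect_true(all(med < gen))
    expect_lt(abs(mean(med) - 0.715), 0.25)
    expect_error(
        simulateExpression(pairs, 1.5, n_tissues = 12L),
        "target_r"
    )
    expect_error(simulateExpression(pairs, 0, n_tissues = 2L), "n_tissues")
})

test_that("promoter simulation plants the requested shared coverage", {
    pairs <- data.frame(gene_a = "pa", gene_b = "pb")
    p1 <- simulatePromoters(pairs, 1, seed = 4L)
    expect_identical(as.character(p1[["pa"]]), as.character(p1[["pb"]]))
    p0 <- simulatePromoters(pairs, 0, seed = 4L)
    expect_equal(
        sharedMotifSimilarity(p0[["pa"]], p0[["pb"]])$s_ls, 0
    )
    p4 <- simulatePromoters(pairs, 0.4, seed = 4L)
    s <- sharedMotifSimilarity(p4[["pa"]], p4[["pb"]])$s_ls
    expect_lt(abs(s - 0.4), 0.05)
    expect_error(simulatePromoters(pairs, 1.2), "shared_fraction")
})

test_that("simulated genome embeds promoters recoverable from sequence", {
    sim <- smallSim()
    got <- extractPromoters(sim$annotation, sim$genome, 1000L)
    ids <- geneIds(sim$annotation)[1:25]
    expect_identical(
        as.character(got[ids]),
        as.character(sim$promoters[ids])
    )
})

test_that("whole-simulation output is byte-identical under one seed", {
    cfg <- simulationConfig(
        n_chroms = 2L, genes_per_chrom = 40L,
        n_events = c(TD = 2L, PD = 2L, RD = 1L, DD = 1L, DSD = 2L),
        seed = 17L
    )
    d1 <- tempfile()
    d2 <- tempfile()
    writeSimulation(simulateDuplicatome(cfg), d1)
    writeSimulation(simulateDuplicatome(cfg), d2)
    for (f in list.files(d1)) {
        expect_identical(
            readLines(file.path(d1, f)),
            readLines(file.path(d2, f)),
            info = f
        )
    }
})
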