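# Expression and promoter divergence with resampling nulls.

test_that("expression threshold is the mean of per-sample medians", {
    m <- rbind(c(0.70, 0.73), c(0.70, 0.73), c(0.70, 0.73))
    expect_equal(expressionThreshold(m), 0.715)
    expect_equal(expressionThreshold(matrix(0, 5, 3)), 0)
    expect_error(expressionThreshold(matrix(0, 0, 0)), "empty")
})

test_that("pair filtering requires both copies expressed somewhere", {
    tpm <- rbind(
        low = c(0.1, 0.5, 0.2),
        hi1 = c(5, 0.1, 0.1),
        hi2 = c(0.1, 0.1, 7),
        hi3 = c(2, 2, 2)
    )
    pairs <- data.frame(
        gene_a = c("low", "hi1", "hi1", "ghost"),
        gene_b = c("hi3", "hi2", "hi3", "hi3"),
        stringsAsFactors = FALSE
    )
    expect_warning(kept <- filterExpressedPairs(pairs, tpm, 0.715), "dropped")
    # low-expressed and absent genes fall out; expression in different
    # samples still counts (the rule is per-gene)
    expect_equal(
        paste(kept$gene_a, kept$gene_b),
        c("hi1 hi2", "hi1 hi3")
    )
})

test_that("the random-pair null cutoff matches the analytic quantile", {
    set.seed(61)
    genes <- sprintf("g%03d", 1:200)
    tpm <- matrix(rnorm(200 * 12, 50, 10),
        nrow = 200,
        dimnames = list(genes, NULL)
    )
    cut <- randomPairCutoff(genes, tpm, "pearson_r", n = 3000L, seed = 8L)
    expect_lt(abs(cut - nullRQuantile(0.95, 12)), 0.04)
    # determinism and q = 1 giving the sample maximum
    expect_identical(
        cut,
        randomPairCutoff(genes, tpm, "pearson_r", n = 3000L, seed = 8L)
    )
    cutMax <- randomPairCutoff(genes, tpm, "pearson_r",
        n = 200L, q = 1,
        seed = 8L
    )
    expect_gte(cutMax, cut)
    # s_ls null on unrelated promoters concentrates at zero
    proms <- stats::setNames(
        vapply(1:40, function(i) randomDna(1000L), character(1)),
        sprintf("p%02d", 1:40)
    )
    cutS <- randomPairCutoff(names(proms), proms, "s_ls",
        n = 150L,
        seed = 9L
    )
    expect_lt(cutS, 0.05)
    expect_warning(
        randomPairCutoff(genes, tpm, "pearson_r", n = 50L, seed = 1L),
        "unstable"
    )
})

test_that("expression divergence follows the strict-cutoff rule", {
    tpm <- rbind(
        a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1),
        z = c(5, 5, 5)
    )
    pairs <- data.frame(
        gene_a = c("a", "a", "a"), gene_b = c("b", "c", "z"),
        stringsAsFactors = FALSE
    )
    res <- expressionDivergence(pairs, tpm, cutoff = 0.89)
    expect_equal(res$r[1], 1) # affine profiles
    expect_false(res$diverged[1])
    expect_equal(res$r[2], -1)
    expect_true(res$diverged[2])
    expect_true(is.na(res$r[3])) # zero-variance profile: missing, not 0
    expect_true(is.na(res$diverged[3]))
    # boundary: r equal to the cutoff is NOT diverged (rule is r < cutoff)
    tpm2 <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
    p2 <- expressionDivergence(
        data.frame(gene_a = "a", gene_b = "b"), tpm2,
        cutoff = 1
    )
    expect_false(p2$diverged)
    expect_error(
        expressionDivergence(pairs, tpm[, 1:2], 0.89),
        "3 samples"
    )
    # Pearson r is invariant to affine rescaling
    tpm3 <- tpm
    tpm3["b", ] <- 100 + 7 * tpm3["b", ]
    res3 <- expressionDivergence(pairs[1, ], tpm3, 0.89)
    expect_equal(res3$r, 1)
})

test_that("shared-motif similarity equals the diagonal-run oracle", {
    set.seed(71)
    # identical, unrelated and planted-block promoters
    pa <- randomDna(1000L)
    expect_equal(sharedMotifSimilarity(pa, pa)$s_ls, 1)
    pb <- randomDna(1000L)
    expect_equal(sharedMotifSimilarity(pa, pb)$s_ls, 0)
    pc <- randomDna(1000L)
    substr(pc, 301, 400) <- substr(pa, 301, 400)
    flip <- function(b) c(A = "C", C = "A", G = "T", T = "G")[[b]]
    substr(pc, 300, 300) <- flip(substr(pa, 300, 300))
    substr(pc, 401, 401) <- flip(substr(pa, 401, 401))
    expect_equal(sharedMotifSimilarity(pa, pc)$s_ls, 0.1)
    # symmetry
    s1 <- sharedMotifSimilarity(pa, pc)
    s2 <- sharedMotifSimilarity(pc, pa)
    expect_equal(s1$s_ls, s2$s_ls)
    # oracle equality on random structured cases, varying min_len
    for (rep in 1:10) {
        x <- randomDna(300L)
        y <- randomDna(300L)
        nBlocks <- sample(0:3, 1)
        for (b in seq_len(nBlocks)) {
            len <- sample(16:60, 1)
            s <- sample(300L - len, 1)
            substr(y, s, s + len - 1L) <- substr(x, s, s + len - 1L)
        }
        ml <- sample(c(12L, 16L, 20L), 1)
        expect_equal(
            sharedMotifSimilarity(x, y, ml)$s_ls,
            oracleSharedCoverage(x, y, ml),
            tolerance = 1e-12
        )
    }
    expect_warning(
        short <- sharedMotifSimilarity("ACGT", "ACGT"),
        "shorter"
    )
    expect_equal(short$s_ls, 0)
})

test_that("promoter divergence uses the strict s_LS cutoff", {
    base <- randomDna(1000L)
    conserved <- randomDna(1000L)
    substr(conserved, 1, 800) <- substr(base, 1, 800) # s_ls ~ 0.8
    diverged <- randomDna(1000L)
    proms <- c(a = base, b = conserved, c = diverged, d = base)
    pairs <- data.frame(
        gene_a = c("a", "a", "a", "a"),
        gene_b = c("b", "c", "d", "missing"),
        stringsAsFactors = FALSE
    )
    expect_warning(res <- promoterDivergence(pairs, proms, 0.60), "skipped")
    expect_equal(nrow(res), 3L)
    expect_false(res$diverged[1]) # ~0.8 conserved
    expect_true(res$diverged[2]) # ~0 diverged
    expect_false(res$diverged[3]) # identical conserved at any cutoff <= 1
    expect_equal(res$s_ls + res$d_sm, rep(1, 3))
})

test_that("divergence summary tabulates modes and contrasts WGD ages", {
    pairs <- data.frame(
        gene_a = sprintf("a%d", 1:6), gene_b = sprintf("b%d", 1:6),
        mode = c("WGD", "WGD", "TD", "TD", "RD", "RD"),
        expr_diverged = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
        prom_diverged = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE),
        stringsAsFactors = FALSE
    )
    s <- divergenceSummary(pairs)
    expect_equal(s$per_mode$frac_expr_diverged, c(1, 1, 1))
    expect_equal(
        s$per_mode$frac_prom_diverged[s$per_mode$mode == "WGD"], 0.5
    )
    # identical groups: rank-sum p ~ 1; planted shift: p < 0.001
    set.seed(81)
    n <- 200L
    mk <- function(ka) {
        data.frame(
            gene_a = sprintf("r%03d", seq_len(n)),
            gene_b = sprintf("s%03d", seq_len(n)),
            mode = "WGD", ka = ka, stringsAsFactors = FALSE
        )
    }
    recent <- mk(rnorm(n, 0.05, 0.01))
    same <- recent
    same$gene_a <- sprintf("t%03d", seq_len(n))
    ancient <- mk(rnorm(n, 0.30, 0.05))
    ancient$gene_a <- sprintf("u%03d", seq_len(n))
    all <- rbind(recent, same, ancient)
    keys <- function(df) pairKey(df$gene_a, df$gene_b)
    sIdent <- divergenceSummary(all,
        recent_keys = keys(recent),
        ancient_keys = keys(same)
    )
    expect_gt(sIdent$wgd_comparison$p_value[1], 0.5)
    sShift <- divergenceSummary(all,
        recent_keys = keys(recent),
        ancient_keys = keys(ancient)
    )
    expect_lt(sShift$wgd_comparison$p_value[1], 0.001)
    # tiny groups give a missing p
    sTiny <- divergenceSummary(all,
        recent_keys = keys(recent[1:2, ]),
        ancient_keys = keys(ancient)
    )
    expect_true(is.na(sTiny$wgd_comparison$p_value[1]))
})
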