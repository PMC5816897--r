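# Codon alignment, NG86 estimation, selection classing, mixture fit and
# curve smoothing.

# brute-force affine global alignment score (exhaustive recursion)
oracleAlignScore <- function(a, b, open = 10, ext = 0.5) {
    mat <- ParalogModes:::blosum62()
    na <- nchar(a)
    nb <- nchar(b)
    rec <- function(i, j, state) {
        if (i > na && j > nb) {
            return(0)
        }
        best <- -Inf
        if (i <= na && j <= nb) {
            best <- max(best, mat[substr(a, i, i), substr(b, j, j)] +
                rec(i + 1L, j + 1L, 0L))
        }
        if (i <= na) {
            pen <- if (state == 1L) ext else open + ext
            best <- max(best, -pen + rec(i + 1L, j, 1L))
        }
        if (j <= nb) {
            pen <- if (state == 2L) ext else open + ext
            best <- max(best, -pen + rec(i, j + 1L, 2L))
        }
        best
    }
    rec(1L, 1L, 0L)
}

test_that("codon alignment handles identity, stops and back-translation", {
    aln <- alignCodons("ATGGCTTTT", "ATGGCTTTT")
    expect_equal(aln$codons_a, aln$codons_b)
    expect_true(all(aln$counted))
    # terminal stop trimmed, internal stop rejected
    aln2 <- alignCodons("ATGGCTTAA", "ATGGCATGA")
    expect_length(aln2$codons_a, 2L)
    expect_error(alignCodons("ATGTAAGCT", "ATGGCTTTT"), "internal stop")
    # protein cross-check
    expect_error(
        alignCodons("ATGGCT", "ATGGCT", protein_a = "MK"),
        "does not match"
    )
    # an indel introduces a gap column that is excluded from counting
    aln3 <- alignCodons(
        paste0("ATG", "AAA", "CCC", "GGG", "TTT"),
        paste0("ATG", "AAA", "GGG", "TTT")
    )
    expect_equal(sum(!aln3$counted), 1L)
})

test_that("protein alignment score matches the exhaustive recursion oracle", {
    set.seed(31)
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    for (rep in 1:6) {
        a <- paste(sample(aas, 5, TRUE), collapse = "")
        b <- paste(sample(aas, 4, TRUE), collapse = "")
        got <- Biostrings::pairwiseAlignment(
            Biostrings::AAString(a), Biostrings::AAString(b),
            substitutionMatrix = ParalogModes:::blosum62(),
            gapOpening = 10, gapExtension = 0.5, type = "global"
        )
        expect_equal(Biostrings::score(got), oracleAlignScore(a, b),
            tolerance = 1e-9
        )
    }
})

test_that("NG86 sign structure is right on forced cases", {
    r0 <- ng86(alignCodons(
        strrep("ATGGCTTTTAAA", 25),
        strrep("ATGGCTTTTAAA", 25)
    ))
    expect_equal(r0$ka, 0)
    expect_equal(r0$ks, 0)
    expect_false(r0$saturated)
    # single synonymous difference: TTT <-> TTC
    r1 <- ng86(alignCodons("TTTAAAGGG", "TTCAAAGGG"))
    expect_equal(r1$ka, 0)
    expect_gt(r1$ks, 0)
    # single nonsynonymous difference
    r2 <- ng86(alignCodons("TTTAAAGGG", "TCTAAAGGG"))
    expect_equal(r2$ks, 0)
    expect_gt(r2$ka, 0)
    expect_true(is.na(r2$ka_ks)) # Ka/Ks undefined at Ks = 0
})

test_that("NG86 counts equal the pathway-enumeration oracle", {
    tab <- ParalogModes:::ng86Tables()
    sense <- tab$codons[!tab$isStop]
    # site counts for every sense codon
    for (cod in sense) {
        expect_equal(tab$synSites[tab$index[cod]], oracleSynSites(cod),
            tolerance = 1e-12, info = cod
        )
    }
    # difference counts on a random sample of codon pairs (the full 61x61
    # sweep runs in the acceptance suite)
    set.seed(11)
    idx <- cbind(sample(sense, 150, TRUE), sample(sense, 150, TRUE))
    for (i in seq_len(nrow(idx))) {
        o <- oraclePathwayDiffs(idx[i, 1], idx[i, 2])
        expect_equal(
            tab$sdMat[idx[i, 1], idx[i, 2]], unname(o["sd"]),
            tolerance = 1e-12, info = paste(idx[i, ], collapse = "-")
        )
        expect_equal(
            tab$ndMat[idx[i, 1], idx[i, 2]], unname(o["nd"]),
            tolerance = 1e-12, info = paste(idx[i, ], collapse = "-")
        )
    }
})

test_that("NG86 is symmetric and sites sum to three per codon column", {
    set.seed(12)
    for (rep in 1:5) {
        a <- randomCds(120)
        b <- evolvePair(a, 0.4, 0.5)
        r1 <- ng86(alignCodons(a, b))
        r2 <- ng86(alignCodons(b, a))
        expect_identical(r1$ks, r2$ks)
        expect_identical(r1$ka, r2$ka)
        expect_equal(r1$n_sites + r1$s_sites, 3 * 120, tolerance = 1e-9)
    }
})

test_that("saturation is flagged outside the correction domain", {
    # lysine vs glycine at every column forces a nonsynonymous
    # proportion >= 3/4 (constructed alignment: such columns would be
    # gap-separated by the affine aligner)
    aln <- structure(
        list(
            codons_a = rep("AAA", 60), codons_b = rep("GGG", 60),
            counted = rep(TRUE, 60)
        ),
        class = "CodonAlignment"
    )
    r <- ng86(aln)
    expect_true(r$saturated)
    expect_true(is.na(r$ka))
})

test_that("selection classes follow the neutral band", {
    expect_equal(classifySelection(list(ka_ks = 0.2)), "purifying")
    expect_equal(classifySelection(list(ka_ks = 1.0)), "neutral")
    expect_equal(classifySelection(list(ka_ks = 2.5)), "positive")
    expect_equal(classifySelection(list(ka_ks = NA_real_)), "undefined")
    expect_equal(
        classifySelection(list(ka_ks = 1.2, saturated = TRUE)),
        "undefined"
    )
})

test_that("the Ks mixture EM recovers planted components", {
    set.seed(41)
    x <- c(
        exp(rnorm(400, log(0.2), 0.15)),
        exp(rnorm(400, log(1.5), 0.15))
    )
    fit <- fitKsMixture(x, seed = 9L)
    med <- componentMedians(fit)
    expect_lt(abs(med[1] - 0.2), 0.05)
    expect_lt(abs(med[2] - 1.5), 0.2)
    expect_equal(sum(fit@weights), 1, tolerance = 1e-9)
    # per-iteration log-likelihood is non-decreasing
    expect_true(all(diff(fit@loglik_trace) >= -1e-8))
    # permuting the input under the same seed gives the same fit
    fit2 <- fitKsMixture(sample(x), seed = 9L)
    expect_equal(fit@means, fit2@means, tolerance = 1e-12)
    # independent cross-check against mclust
    if (requireNamespace("mclust", quietly = TRUE)) {
        suppressMessages(library(mclust))
        mc <- Mclust(log(x), G = 2, modelNames = "V", verbose = FALSE)
        expect_equal(
            sort(exp(mc$parameters$mean)), med,
            tolerance = 0.05, ignore_attr = TRUE
        )
    }
})

test_that("mixture EM handles degenerate input and rejects tiny samples", {
    set.seed(5)
    x <- exp(rnorm(100, log(0.3), 0.1))
    fit <- fitKsMixture(x, seed = 2L)
    expect_equal(sum(fit@weights), 1, tolerance = 1e-9)
    expect_error(fitKsMixture(rep(0.2, 5)), "at least")
})

test_that("smoothCurve reproduces constants and lines, beats the mean", {
    x <- seq(0, 2, length.out = 200)
    cst <- smoothCurve(x, rep(3, 200))
    expect_lt(max(abs(cst$y - 3)), 1e-9)
    lin <- smoothCurve(x, x)
    expect_lt(max(abs(lin$y - lin$x)), 1e-6)
    expect_error(smoothCurve(x[1:5], x[1:5], df = 10), "at least")
    set.seed(21)
    xs <- runif(500, -3, 3)
    ys <- plogis(2 * xs) + rnorm(500, 0, 0.05)
    fit <- smoothCurve(xs, ys)
    pred <- approx(fit$x, fit$y, xout = xs)$y
    rmseFit <- sqrt(mean((ys - pred)^2))
    rmseMean <- sqrt(mean((ys - mean(ys))^2))
    expect_lte(rmseFit, rmseMean)
})
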