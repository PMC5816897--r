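# Expression and promoter (regulatory) divergence between duplicate pairs,
# with resampling-based significance cutoffs.
#
# Conventions: a pair is "diverged" strictly below the cutoff (r < cutoff,
# s_LS < cutoff); zero-variance expression profiles give a missing r, never 0.

#' Data-derived expression threshold from intergenic background
#'
#' Per-sample median of the intergenic TPM rows, averaged across samples.
#' A gene with TPM above this background level in at least one sample counts
#' as expressed.
#'
#' @param intergenic_tpm Matrix (intergenic regions x samples) of TPM values.
#' @return A single numeric threshold.
#' @export
#' @examples
#' expressionThreshold(rbind(c(0.70, 0.73), c(0.70, 0.73))) # 0.715
expressionThreshold <- function(intergenic_tpm) {
    intergenic_tpm <- as.matrix(intergenic_tpm)
    if (!nrow(intergenic_tpm) || !ncol(intergenic_tpm)) {
        stop("intergenic TPM matrix is empty")
    }
    mean(apply(intergenic_tpm, 2, stats::median))
}

#' Filter pairs to those with both copies expressed
#'
#' Keeps pairs in which each gene has TPM above `threshold` in at least one
#' sample (the rule is per-gene; the samples need not coincide).  Pairs with
#' a gene absent from the matrix are dropped with a warning.
#'
#' @param pairs `data.frame` with `gene_a`, `gene_b`.
#' @param tpm Genes x samples TPM matrix with gene-id rownames.
#' @param threshold Expression threshold (e.g. from [expressionThreshold()]).
#' @return The subset of `pairs` with both copies expressed.
#' @export
filterExpressedPairs <- function(pairs, tpm, threshold) {
    present <- pairs$gene_a %in% rownames(tpm) &
        pairs$gene_b %in% rownames(tpm)
    if (any(!present)) {
        warning(sum(!present), " pair(s) with a gene absent from the TPM ",
            "matrix were dropped")
    }
    pairs <- pairs[present, , drop = FALSE]
    if (!nrow(pairs)) {
        return(pairs)
    }
    maxTpm <- apply(tpm, 1, max)
    keep <- maxTpm[pairs$gene_a] > threshold & maxTpm[pairs$gene_b] > threshold
    out <- pairs[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Null cutoff from random gene pairs
#'
#' Samples `n` random unordered gene pairs (excluding known duplicate pairs),
#' computes the chosen statistic for each, and returns its `q`-quantile — the
#' significance cutoff above which a duplicate pair's similarity exceeds what
#' unrelated genes show.
#'
#' @param genes Character vector of eligible gene ids.
#' @param data For `statistic = "pearson_r"`, the genes x samples TPM matrix;
#'   for `statistic = "s_ls"`, a named `DNAStringSet`/character vector of
#'   promoters.
#' @param statistic `"pearson_r"` or `"s_ls"`.
#' @param n Number of random pairs (default 10000; below 100 warns).
#' @param q Quantile (default 0.95).
#' @param seed Integer seed.
#' @param exclude_pairs Optional `data.frame` (`gene_a`, `gene_b`) of known
#'   duplicate pairs to exclude from sampling.
#' @param min_len Motif length for `s_ls` (default 16).
#' @return The `q`-quantile of the null statistic distribution.
#' @export
randomPairCutoff <- function(genes, data, statistic = c("pearson_r", "s_ls"),
                             n = 10000L, q = 0.95, seed = 1L,
                             exclude_pairs = NULL, min_len = 16L) {
    statistic <- match.arg(statistic)
    if (length(genes) < 2L) {
        stop("need at least 2 eligible genes")
    }
    if (n < 100L) {
        warning("n < 100 random pairs gives an unstable cutoff")
    }
    excl <- if (!is.null(exclude_pairs) && nrow(exclude_pairs)) {
        pairKey(exclude_pairs$gene_a, exclude_pairs$gene_b)
    } else {
        character(0)
    }
    if (statistic == "s_ls") {
        data <- stats::setNames(as.character(data), names(data))
    }
    withSeed(seed, {
        vals <- numeric(n)
        got <- 0L
        guard <- 0L
        while (got < n && guard < 50L * n) {
            guard <- guard + 1L
            idx <- sample.int(length(genes), 2L)
            a <- genes[idx[1L]]
            b <- genes[idx[2L]]
            if (pairKey(a, b) %in% excl) next
            v <- if (statistic == "pearson_r") {
                pa <- data[a, ]
                pb <- data[b, ]
                if (stats::sd(pa) == 0 || stats::sd(pb) == 0) {
                    NA_real_
                } else {
                    stats::cor(pa, pb)
                }
            } else {
                sharedMotifSimilarity(data[[a]], data[[b]], min_len)$s_ls
            }
            if (is.na(v)) next # statistic undefined: resample
            got <- got + 1L
            vals[got] <- v
        }
        if (got < n) {
            stop("could not draw ", n, " valid random pairs")
        }
        unname(stats::quantile(vals, q))
    })
}

#' Expression divergence of duplicate pairs
#'
#' Pearson correlation between the two copies' TPM profiles across all
#' samples; a pair has diverged in expression when `r < cutoff`.
#' Zero-variance profiles give missing `r` and missing `diverged`.
#'
#' @param pairs `data.frame` with `gene_a`, `gene_b` (ideally pre-filtered by
#'   [filterExpressedPairs()]).
#' @param tpm Genes x samples TPM matrix (>= 3 samples).
#' @param cutoff Correlation cutoff (e.g. from [randomPairCutoff()]).
#' @return `pairs` with columns `r`, `diverged`, `cutoff_used` appended.
#' @export
expressionDivergence <- function(pairs, tpm, cutoff) {
    if (ncol(tpm) < 3L) {
        stop("need >= 3 samples for a stable correlation")
    }
    r <- vapply(seq_len(nrow(pairs)), function(i) {
        pa <- tpm[pairs$gene_a[i], ]
        pb <- tpm[pairs$gene_b[i], ]
        if (stats::sd(pa) == 0 || stats::sd(pb) == 0) {
            return(NA_real_)
        }
        stats::cor(pa, pb)
    }, numeric(1))
    pairs$r <- r
    pairs$diverged <- r < cutoff
    pairs$cutoff_used <- cutoff
    pairs
}

#' Shared-motif similarity of two promoters
#'
#' Finds all maximal exact shared substrings of length >= `min_len` between
#' the two sequences and measures the fraction of positions they cover,
#' averaged over the two sequences: `s_LS`.  The shared-motif divergence is
#' its complement, `d_SM = 1 - s_LS`.  A position is covered exactly when
#' some `min_len`-mer window containing it occurs in the other sequence, so
#' coverage is computed by k-mer set matching.
#'
#' @param prom_a,prom_b Promoter sequences (character or `DNAString`),
#'   uppercase DNA.
#' @param min_len Minimum shared-substring length (default 16).
#' @return List with `s_ls`, `d_sm`, `cov_a`, `cov_b` (per-sequence covered
#'   fractions).
#' @export
#' @examples
#' p <- paste(rep("ACGT", 250), collapse = "")
#' sharedMotifSimilarity(p, p)$s_ls # 1
sharedMotifSimilarity <- function(prom_a, prom_b, min_len = 16L) {
    a <- toupper(as.character(prom_a))
    b <- toupper(as.character(prom_b))
    na <- nchar(a)
    nb <- nchar(b)
    if (na < min_len || nb < min_len) {
        warning("promoter shorter than min_len; s_ls set to 0")
        return(list(s_ls = 0, d_sm = 1, cov_a = 0, cov_b = 0))
    }
    kmers <- function(x, n) {
        substring(x, seq_len(n - min_len + 1L), seq(min_len, n))
    }
    ka <- kmers(a, na)
    kb <- kmers(b, nb)
    covFrac <- function(hit, n) {
        if (!any(hit)) {
            return(0)
        }
        cov <- logical(n)
        for (i in which(hit)) {
            cov[i:(i + min_len - 1L)] <- TRUE
        }
        mean(cov)
    }
    covA <- covFrac(ka %in% kb, na)
    covB <- covFrac(kb %in% ka, nb)
    sLs <- (covA + covB) / 2
    list(s_ls = sLs, d_sm = 1 - sLs, cov_a = covA, cov_b = covB)
}

#' Promoter divergence of duplicate pairs
#'
#' Computes `s_LS` ([sharedMotifSimilarity()]) per pair; a pair has diverged
#' in its promoter region when `s_LS < cutoff`.  Pairs with a missing
#' promoter are skipped with a warning.
#'
#' @param pairs `data.frame` with `gene_a`, `gene_b`.
#' @param promoters Named `DNAStringSet`/character vector of promoters.
#' @param cutoff Similarity cutoff (default 0.60).
#' @param min_len Minimum shared-substring length (default 16).
#' @return `pairs` (skipped rows removed) with `s_ls`, `d_sm`, `diverged`,
#'   `cutoff_used` appended.
#' @export
promoterDivergence <- function(pairs, promoters, cutoff = 0.60,
                               min_len = 16L) {
    proms <- stats::setNames(as.character(promoters), names(promoters))
    present <- pairs$gene_a %in% names(proms) & pairs$gene_b %in% names(proms)
    if (any(!present)) {
        warning(sum(!present), " pair(s) with a missing promoter skipped")
    }
    pairs <- pairs[present, , drop = FALSE]
    sls <- vapply(seq_len(nrow(pairs)), function(i) {
        sharedMotifSimilarity(
            proms[[pairs$gene_a[i]]], proms[[pairs$gene_b[i]]], min_len
        )$s_ls
    }, numeric(1))
    pairs$s_ls <- sls
    pairs$d_sm <- 1 - sls
    pairs$diverged <- sls < cutoff
    pairs$cutoff_used <- cutoff
    rownames(pairs) <- NULL
    pairs
}

#' Per-mode divergence summary and recent-vs-ancient WGD comparison
#'
#' Tabulates the fraction of diverged pairs (expression and promoter) per
#' duplication mode, and compares recent vs ancient WGD pair sets (as
#' returned by [selectBlocksByKs()] windows) on Ka, expression divergence
#' (1 - r) and promoter divergence (d_SM) with two-sided Wilcoxon rank-sum
#' tests.  Groups smaller than 3 give a missing p-value.
#'
#' @param pairs Pair table carrying `mode` and any of `ka`, `r`, `s_ls`,
#'   and the `diverged` flags as `expr_diverged` / `prom_diverged` (or a
#'   single `diverged` column if only one assay was run).
#' @param recent_keys,ancient_keys Character vectors of unordered pair keys
#'   (`pairKey()`) defining the recent/ancient WGD pair sets; NULL to skip
#'   the comparison.
#' @return List with `per_mode` (`data.frame`) and `wgd_comparison`
#'   (`data.frame` of statistics and p-values, or NULL).
#' @export
divergenceSummary <- function(pairs, recent_keys = NULL,
                              ancient_keys = NULL) {
    modes <- intersect(modeLevels(), unique(pairs$mode))
    perMode <- do.call(rbind, lapply(modes, function(m) {
        sub <- pairs[pairs$mode == m, , drop = FALSE]
        fr <- function(col) {
            if (!col %in% names(sub)) {
                return(NA_real_)
            }
            v <- sub[[col]]
            if (!sum(!is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
        }
        data.frame(
            mode = m, n_pairs = nrow(sub),
            frac_expr_diverged = fr("expr_diverged"),
            frac_prom_diverged = fr("prom_diverged"),
            stringsAsFactors = FALSE
        )
    }))
    wgdCmp <- NULL
    if (!is.null(recent_keys) && !is.null(ancient_keys)) {
        key <- pairKey(pairs$gene_a, pairs$gene_b)
        rec <- pairs[key %in% recent_keys, , drop = FALSE]
        anc <- pairs[key %in% ancient_keys, , drop = FALSE]
        cmpOne <- function(stat, recV, ancV) {
            recV <- recV[is.finite(recV)]
            ancV <- ancV[is.finite(ancV)]
            p <- if (length(recV) < 3L || length(ancV) < 3L) {
                NA_real_
            } else {
                stats::wilcox.test(recV, ancV, exact = FALSE)$p.value
            }
            data.frame(
                statistic = stat, n_recent = length(recV),
                n_ancient = length(ancV),
                median_recent = stats::median(recV),
                median_ancient = stats::median(ancV),
                p_value = p, stringsAsFactors = FALSE
            )
        }
        grab <- function(df, col) {
            if (col %in% names(df)) df[[col]] else numeric(0)
        }
        wgdCmp <- rbind(
            cmpOne("ka", grab(rec, "ka"), grab(anc, "ka")),
            cmpOne(
                "expr_divergence",
                1 - grab(rec, "r"), 1 - grab(anc, "r")
            ),
            cmpOne("d_sm", grab(rec, "d_sm"), grab(anc, "d_sm"))
        )
    }
    list(per_mode = perMode, wgd_comparison = wgdCmp)
}
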