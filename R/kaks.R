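# Codon-level alignment, NG86 Ka/Ks estimation, selection classing, Ks mixture
# decomposition and divergence-vs-Ks smoothing.
#
# Estimator: Nei & Gojobori (1986) pathway counting with Jukes-Cantor multiple
# hit correction.  Conventions fixed here: substitutions that would create a
# stop codon count toward the nonsynonymous site total (so S + N = 3 * codons
# exactly), and substitution pathways passing through a stop-codon intermediate
# are excluded from the difference averaging (all pathways are used if every
# pathway is excluded).

ng86Cache <- new.env(parent = emptyenv())

# Precompute (lazily, once per session) the per-codon synonymous site counts
# and the per-codon-pair averaged synonymous/nonsynonymous difference counts
# over all minimal substitution pathways.
ng86Tables <- function() {
    if (!is.null(ng86Cache$tab)) {
        return(ng86Cache$tab)
    }
    gc <- Biostrings::GENETIC_CODE
    codons <- names(gc)
    aa <- unname(gc)
    isStop <- aa == "*"
    nt <- c("A", "C", "G", "T")
    codonChars <- do.call(rbind, strsplit(codons, ""))

    synSites <- rep(NA_real_, 64L)
    for (ci in seq_len(64L)) {
        if (isStop[ci]) next
        s <- 0
        for (p in 1:3) {
            for (b in setdiff(nt, codonChars[ci, p])) {
                mut <- codonChars[ci, ]
                mut[p] <- b
                if (gc[[paste(mut, collapse = "")]] == aa[ci]) {
                    s <- s + 1 / 3
                }
            }
        }
        synSites[ci] <- s
    }

    perms <- list(
        matrix(1L, 1, 1),
        rbind(c(1L, 2L), c(2L, 1L)),
        rbind(
            c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
            c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)
        )
    )
    sdMat <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
    ndMat <- sdMat
    for (i in seq_len(64L)) {
        if (isStop[i]) next
        for (j in seq_len(64L)) {
            if (isStop[j]) next
            diffPos <- which(codonChars[i, ] != codonChars[j, ])
            k <- length(diffPos)
            if (k == 0L) {
                sdMat[i, j] <- 0
                ndMat[i, j] <- 0
                next
            }
            pm <- perms[[k]]
            sAll <- nAll <- numeric(0)
            sOk <- nOk <- numeric(0)
            for (r in seq_len(nrow(pm))) {
                cur <- codonChars[i, ]
                sCnt <- nCnt <- 0
                valid <- TRUE
                for (step in seq_len(k)) {
                    p <- diffPos[pm[r, step]]
                    aaFrom <- gc[[paste(cur, collapse = "")]]
                    cur[p] <- codonChars[j, p]
                    codTo <- paste(cur, collapse = "")
                    aaTo <- gc[[codTo]]
                    if (aaTo == "*" && step < k) valid <- FALSE
                    if (aaFrom == aaTo) sCnt <- sCnt + 1 else nCnt <- nCnt + 1
                }
                sAll <- c(sAll, sCnt)
                nAll <- c(nAll, nCnt)
                if (valid) {
                    sOk <- c(sOk, sCnt)
                    nOk <- c(nOk, nCnt)
                }
            }
            if (length(sOk)) {
                sdMat[i, j] <- mean(sOk)
                ndMat[i, j] <- mean(nOk)
            } else {
                sdMat[i, j] <- mean(sAll)
                ndMat[i, j] <- mean(nAll)
            }
        }
    }
    ng86Cache$tab <- list(
        codons = codons, aa = aa, isStop = isStop,
        synSites = synSites, sdMat = sdMat, ndMat = ndMat,
        index = stats::setNames(seq_len(64L), codons)
    )
    ng86Cache$tab
}

# Split a nucleotide string into codon triplets.
splitCodons <- function(x) {
    x <- toupper(as.character(x))
    n <- nchar(x)
    if (n %% 3L != 0L) {
        stop("sequence length not divisible by 3")
    }
    substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
}

# Drop a terminal stop codon if present.
trimTerminalStop <- function(x) {
    x <- toupper(as.character(x))
    n <- nchar(x)
    if (n >= 3L && n %% 3L == 0L) {
        last <- substr(x, n - 2L, n)
        if (last %in% c("TAA", "TAG", "TGA")) {
            x <- substr(x, 1L, n - 3L)
        }
    }
    x
}

#' Align two coding sequences at the codon level
#'
#' Globally aligns the two protein translations (BLOSUM62, affine gaps) with
#' [Biostrings::pairwiseAlignment] and back-translates the alignment to
#' codons.  Terminal stop codons are trimmed first; an internal stop codon is
#' an error.  When protein sequences are supplied they must match the CDS
#' translations exactly.
#'
#' @param cds_a,cds_b Coding sequences (character or `DNAString`), lengths
#'   divisible by 3 after terminal-stop trimming.
#' @param protein_a,protein_b Optional amino-acid sequences to cross-check
#'   against `translate(cds)`.
#' @param ids Length-2 character used in error messages.
#' @return A `CodonAlignment`: list with `codons_a`, `codons_b` (aligned codon
#'   vectors, `"---"` at protein gaps) and `counted` (logical, columns without
#'   gaps in either sequence).
#' @export
#' @examples
#' aln <- alignCodons("ATGGCTTTT", "ATGGCATTC")
#' ng86(aln)
alignCodons <- function(cds_a, cds_b, protein_a = NULL, protein_b = NULL,
                        ids = c("seq_a", "seq_b")) {
    cds_a <- trimTerminalStop(cds_a)
    cds_b <- trimTerminalStop(cds_b)
    pa <- translateCds(cds_a, ids[1])
    pb <- translateCds(cds_b, ids[2])
    if (!is.null(protein_a) && toupper(as.character(protein_a)) != pa) {
        stop("CDS translation does not match supplied protein for ", ids[1])
    }
    if (!is.null(protein_b) && toupper(as.character(protein_b)) != pb) {
        stop("CDS translation does not match supplied protein for ", ids[2])
    }
    if (pa == pb) {
        # identical proteins: alignment is the identity, skip the aligner
        alnA <- pa
        alnB <- pb
    } else {
        pw <- Biostrings::pairwiseAlignment(
            Biostrings::AAString(pa), Biostrings::AAString(pb),
            substitutionMatrix = blosum62(),
            gapOpening = 10, gapExtension = 0.5, type = "global"
        )
        alnA <- as.character(Biostrings::alignedPattern(pw))
        alnB <- as.character(Biostrings::alignedSubject(pw))
    }
    chA <- strsplit(alnA, "")[[1]]
    chB <- strsplit(alnB, "")[[1]]
    codA <- splitCodons(cds_a)
    codB <- splitCodons(cds_b)
    outA <- outB <- character(length(chA))
    iA <- iB <- 0L
    for (k in seq_along(chA)) {
        if (chA[k] == "-") {
            outA[k] <- "---"
        } else {
            iA <- iA + 1L
            outA[k] <- codA[iA]
        }
        if (chB[k] == "-") {
            outB[k] <- "---"
        } else {
            iB <- iB + 1L
            outB[k] <- codB[iB]
        }
    }
    structure(
        list(
            codons_a = outA, codons_b = outB,
            counted = outA != "---" & outB != "---"
        ),
        class = "CodonAlignment"
    )
}

# BLOSUM62 scoring matrix, loaded once per session.
blosum62 <- function() {
    if (is.null(ng86Cache$blosum62)) {
        e <- new.env()
        utils::data("BLOSUM62", package = "Biostrings", envir = e)
        ng86Cache$blosum62 <- e$BLOSUM62
    }
    ng86Cache$blosum62
}

translateCds <- function(cds, id) {
    if (nchar(cds) %% 3L != 0L) {
        stop("CDS length not divisible by 3 for ", id)
    }
    p <- as.character(Biostrings::translate(
        Biostrings::DNAString(cds),
        if.fuzzy.codon = "X"
    ))
    if (grepl("\\*", p)) {
        stop("internal stop codon in CDS for ", id)
    }
    p
}

# Per counted column: synonymous/nonsynonymous sites (averaged over the two
# codons) and pathway-averaged difference counts.  The workhorse behind both
# ng86() and the conversion bootstrap.
ng86Profile <- function(alignment) {
    tab <- ng86Tables()
    keep <- alignment$counted
    ia <- tab$index[alignment$codons_a[keep]]
    ib <- tab$index[alignment$codons_b[keep]]
    ok <- !is.na(ia) & !is.na(ib) & !tab$isStop[ia] & !tab$isStop[ib]
    ia <- ia[ok]
    ib <- ib[ok]
    sSites <- (tab$synSites[ia] + tab$synSites[ib]) / 2
    data.frame(
        s_sites = unname(sSites),
        n_sites = 3 - unname(sSites),
        sd = tab$sdMat[cbind(ia, ib)],
        nd = tab$ndMat[cbind(ia, ib)]
    )
}

#' Ka/Ks by the Nei-Gojobori (1986) method
#'
#' Counts synonymous and nonsynonymous sites per codon (mutations to stop
#' codons count as nonsynonymous) and averages substitution counts over all
#' minimal pathways between differing codons (pathways through stop
#' intermediates excluded), then applies the Jukes-Cantor correction to the
#' proportions.  `saturated` is TRUE when either proportion is >= 3/4, outside
#' the correction's domain; `ka`/`ks` are NA there.
#'
#' @param alignment A `CodonAlignment` from [alignCodons()].
#' @return Named list: `ka`, `ks`, `ka_ks`, `n_sites`, `s_sites`, `n_diffs`,
#'   `s_diffs`, `saturated`.
#' @export
#' @examples
#' ng86(alignCodons("TTTAAAGGG", "TTCAAAGGG"))$ks # one synonymous change
ng86 <- function(alignment) {
    prof <- ng86Profile(alignment)
    if (!nrow(prof)) {
        stop("no counted codon columns in alignment")
    }
    ng86FromCounts(
        S = sum(prof$s_sites), N = sum(prof$n_sites),
        Sd = sum(prof$sd), Nd = sum(prof$nd)
    )
}

ng86FromCounts <- function(S, N, Sd, Nd) {
    pS <- if (S > 0) Sd / S else NA_real_
    pN <- if (N > 0) Nd / N else NA_real_
    ks <- jcCorrect(pS)
    ka <- jcCorrect(pN)
    saturated <- (is.finite(pS) && pS >= 0.75) ||
        (is.finite(pN) && pN >= 0.75)
    kaks <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_
    list(
        ka = unname(ka), ks = unname(ks), ka_ks = unname(kaks),
        n_sites = unname(N), s_sites = unname(S),
        n_diffs = unname(Nd), s_diffs = unname(Sd),
        saturated = saturated
    )
}

#' Ka/Ks for a table of gene pairs
#'
#' Convenience wrapper running [alignCodons()] + [ng86()] over a pair table.
#'
#' @param pairs `data.frame` with columns `gene_a`, `gene_b`.
#' @param cds Named `DNAStringSet` (or character vector) of coding sequences.
#' @return `pairs` with columns `ka`, `ks`, `ka_ks`, `saturated`, `selection`
#'   appended.
#' @export
kaksForPairs <- function(pairs, cds) {
    n <- nrow(pairs)
    ka <- ks <- kk <- rep(NA_real_, n)
    sat <- rep(NA, n)
    seqs <- as.character(cds)
    for (i in seq_len(n)) {
        a <- pairs$gene_a[i]
        b <- pairs$gene_b[i]
        if (is.na(seqs[a]) || is.na(seqs[b])) next
        res <- ng86(alignCodons(seqs[[a]], seqs[[b]], ids = c(a, b)))
        ka[i] <- res$ka
        ks[i] <- res$ks
        kk[i] <- res$ka_ks
        sat[i] <- res$saturated
    }
    pairs$ka <- ka
    pairs$ks <- ks
    pairs$ka_ks <- kk
    pairs$saturated <- sat
    pairs$selection <- vapply(
        kk,
        function(x) classifySelection(list(ka_ks = x, saturated = FALSE)),
        character(1)
    )
    pairs$selection[is.na(sat) | sat] <- "undefined"
    pairs
}

#' Classify selection pressure from a Ka/Ks ratio
#'
#' @param result A list with at least `ka_ks` and optionally `saturated`
#'   (e.g. the output of [ng86()]).
#' @param neutral_band Ratios inside this closed band are "neutral"
#'   (operationalises Ka/Ks = 1 for floating point).
#' @return One of "positive", "neutral", "purifying", "undefined".
#' @export
#' @examples
#' classifySelection(list(ka_ks = 0.2)) # "purifying"
classifySelection <- function(result, neutral_band = c(0.99, 1.01)) {
    kk <- result$ka_ks
    if (is.null(kk) || is.na(kk) || isTRUE(result$saturated)) {
        return("undefined")
    }
    if (kk > neutral_band[2]) {
        "positive"
    } else if (kk < neutral_band[1]) {
        "purifying"
    } else {
        "neutral"
    }
}

#' Fit a Gaussian mixture to log-Ks values by EM
#'
#' Decomposes a Ks distribution into `k` components on the log scale (Ks peaks
#' from successive whole-genome duplications are approximately log-normal).
#' Multiple seeded restarts (quantile-split initialisation, jittered) guard
#' against local optima; the best log-likelihood wins.  Values outside
#' `(0, ks_cap]` are dropped as saturated/invalid.
#'
#' @param ks_values Numeric Ks values.
#' @param k Number of components (default 2).
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @param seed Integer seed for restart initialisation.
#' @param restarts Number of EM restarts (default 10).
#' @param ks_cap Values above this are excluded (default 5).
#' @return A [KsMixtureFit-class].
#' @export
fitKsMixture <- function(ks_values, k = 2L, max_iter = 500L, tol = 1e-8,
                         seed = 1L, restarts = 10L, ks_cap = 5) {
    x <- ks_values[is.finite(ks_values) & ks_values > 0 & ks_values <= ks_cap]
    if (length(x) < 10L * k) {
        stop(
            "need at least ", 10L * k, " usable Ks values in (0, ks_cap]; got ",
            length(x)
        )
    }
    lx <- sort(log(x))
    n <- length(lx)
    bestFit <- NULL
    withSeed(seed, {
        for (r in seq_len(restarts)) {
            # quantile-split initialisation, jittered after the first restart
            grp <- cut(seq_len(n), breaks = k, labels = FALSE)
            mu <- tapply(lx, grp, mean)
            sg <- pmax(tapply(lx, grp, stats::sd), 1e-3)
            sg[is.na(sg)] <- stats::sd(lx)
            w <- rep(1 / k, k)
            if (r > 1L) {
                mu <- mu + stats::rnorm(k, 0, stats::sd(lx))
            }
            fit <- emGaussian(lx, mu, sg, w, max_iter, tol)
            if (is.null(bestFit) || fit$loglik > bestFit$loglik) {
                bestFit <- fit
            }
        }
    })
    ord <- order(bestFit$mu)
    new("KsMixtureFit",
        means = unname(bestFit$mu[ord]),
        sds = unname(bestFit$sg[ord]),
        weights = unname(bestFit$w[ord]),
        loglik = bestFit$loglik,
        n_iter = bestFit$n_iter,
        loglik_trace = bestFit$trace
    )
}

emGaussian <- function(x, mu, sg, w, max_iter, tol) {
    n <- length(x)
    k <- length(mu)
    trace <- numeric(0)
    ll <- -Inf
    iter <- 0L
    repeat {
        iter <- iter + 1L
        dens <- vapply(
            seq_len(k),
            function(j) w[j] * stats::dnorm(x, mu[j], sg[j]),
            numeric(n)
        )
        dens <- matrix(dens, nrow = n)
        rowTot <- rowSums(dens)
        rowTot[rowTot == 0] <- .Machine$double.xmin
        newLl <- sum(log(rowTot))
        trace <- c(trace, newLl)
        resp <- dens / rowTot
        nk <- colSums(resp)
        nk[nk == 0] <- 1e-12
        mu <- colSums(resp * x) / nk
        dev2 <- (matrix(x, n, k) - matrix(mu, n, k, byrow = TRUE))^2
        sg <- sqrt(pmax(colSums(resp * dev2) / nk, 1e-8))
        w <- nk / n
        if (iter >= max_iter || (newLl - ll) < tol * (1 + abs(newLl))) {
            ll <- newLl
            break
        }
        ll <- newLl
    }
    list(mu = mu, sg = sg, w = w, loglik = ll, n_iter = iter, trace = trace)
}

#' Smooth a divergence-vs-Ks relationship
#'
#' Fits a smoothing spline with the requested equivalent degrees of freedom
#' and evaluates it on a 100-point grid spanning the observed x range.
#'
#' @param x,y Numeric vectors (x finite; at least `df + 2` points).
#' @param df Spline degrees of freedom (default 10).
#' @return `data.frame` with columns `x`, `y` (100 grid points).
#' @export
smoothCurve <- function(x, y, df = 10) {
    keep <- is.finite(x) & is.finite(y)
    x <- x[keep]
    y <- y[keep]
    if (length(x) < df + 2) {
        stop("need at least df + 2 = ", df + 2, " finite points; got ", length(x))
    }
    nUnique <- length(unique(x))
    fit <- stats::smooth.spline(x, y, df = min(df, nUnique - 1))
    grid <- seq(min(x), max(x), length.out = 100L)
    pred <- stats::predict(fit, grid)
    data.frame(x = pred$x, y = pred$y)
}
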