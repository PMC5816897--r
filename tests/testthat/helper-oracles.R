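# Independent oracles used to validate the package's core computations.
# Each is coded in a deliberately different style from the implementation
# (strings and recursion rather than precomputed lookup matrices).

GENETIC_CODE_TAB <- Biostrings::GENETIC_CODE

# --- NG86 oracle: per-codon synonymous sites ------------------------------
# Changes to stop codons count as nonsynonymous (same convention as the
# implementation; the oracle verifies the counting, not the convention).
oracleSynSites <- function(codon) {
    nts <- c("A", "C", "G", "T")
    s <- 0
    for (p in 1:3) {
        orig <- substr(codon, p, p)
        for (b in setdiff(nts, orig)) {
            mut <- codon
            substr(mut, p, p) <- b
            if (GENETIC_CODE_TAB[[mut]] != "*" &&
                GENETIC_CODE_TAB[[mut]] == GENETIC_CODE_TAB[[codon]]) {
                s <- s + 1 / 3
            }
        }
    }
    s
}

allPerms <- function(v) {
    if (length(v) <= 1L) {
        return(list(v))
    }
    out <- list()
    for (i in seq_along(v)) {
        for (rest in allPerms(v[-i])) {
            out[[length(out) + 1L]] <- c(v[i], rest)
        }
    }
    out
}

# --- NG86 oracle: pathway-averaged differences ----------------------------
oraclePathwayDiffs <- function(c1, c2) {
    ch1 <- strsplit(c1, "")[[1]]
    ch2 <- strsplit(c2, "")[[1]]
    pos <- which(ch1 != ch2)
    if (!length(pos)) {
        return(c(sd = 0, nd = 0))
    }
    valid <- list()
    all <- list()
    for (ord in allPerms(pos)) {
        cur <- c1
        sCnt <- 0
        nCnt <- 0
        ok <- TRUE
        for (step in seq_along(ord)) {
            nxt <- cur
            substr(nxt, ord[step], ord[step]) <- ch2[ord[step]]
            if (GENETIC_CODE_TAB[[nxt]] == "*" && step < length(ord)) {
                ok <- FALSE
            }
            if (GENETIC_CODE_TAB[[nxt]] == GENETIC_CODE_TAB[[cur]]) {
                sCnt <- sCnt + 1
            } else {
                nCnt <- nCnt + 1
            }
            cur <- nxt
        }
        all[[length(all) + 1L]] <- c(sCnt, nCnt)
        if (ok) valid[[length(valid) + 1L]] <- c(sCnt, nCnt)
    }
    use <- if (length(valid)) valid else all
    m <- colMeans(do.call(rbind, use))
    c(sd = m[1], nd = m[2])
}

# --- chaining oracle: memoised recursion over "best chain starting here" --
oracleBestChainScore <- function(ra, rb, max_gap = 25L, gap_penalty = 0.05) {
    oneOrientation <- function(ra, rb) {
        n <- length(ra)
        memo <- rep(NA_real_, n)
        bestFrom <- function(i) {
            if (!is.na(memo[i])) {
                return(memo[i])
            }
            best <- 1
            for (j in seq_len(n)) {
                if (ra[j] > ra[i] && rb[j] > rb[i] &&
                    ra[j] - ra[i] - 1 <= max_gap &&
                    rb[j] - rb[i] - 1 <= max_gap) {
                    cand <- 1 + bestFrom(j) -
                        gap_penalty * ((ra[j] - ra[i] - 1) +
                            (rb[j] - rb[i] - 1))
                    if (cand > best) best <- cand
                }
            }
            memo[i] <<- best
            best
        }
        if (!n) {
            return(-Inf)
        }
        max(vapply(seq_len(n), bestFrom, numeric(1)))
    }
    max(oneOrientation(ra, rb), oneOrientation(ra, -rb))
}

# --- shared-substring coverage oracle: diagonal run lengths ---------------
oracleSharedCoverage <- function(a, b, min_len = 16L) {
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    na <- length(ca)
    nb <- length(cb)
    covA <- logical(na)
    covB <- logical(nb)
    for (d in (-(nb - 1L)):(na - 1L)) {
        i0 <- max(1L, 1L + d)
        j0 <- i0 - d
        len <- min(na - i0, nb - j0) + 1L
        if (len < min_len) next
        eq <- ca[i0:(i0 + len - 1L)] == cb[j0:(j0 + len - 1L)]
        r <- rle(eq)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (t in which(r$values & r$lengths >= min_len)) {
            covA[(i0 + starts[t] - 1L):(i0 + ends[t] - 1L)] <- TRUE
            covB[(j0 + starts[t] - 1L):(j0 + ends[t] - 1L)] <- TRUE
        }
    }
    (mean(covA) + mean(covB)) / 2
}

# --- Fisher oracle: explicit hypergeometric tail via choose() -------------
oracleFisherGreaterP <- function(k, s, m, N) {
    ks <- k:min(s, m)
    sum(choose(m, ks) * choose(N - m, s - ks)) / choose(N, s)
}

# --- closed-form null quantile of Pearson r for independent normals -------
nullRQuantile <- function(q, n) {
    t <- stats::qt(q, n - 2)
    t / sqrt(n - 2 + t^2)
}

# --- small shared simulation, built once per test run ---------------------
simCache <- new.env()
smallSim <- function() {
    if (is.null(simCache$sim)) {
        cfg <- simulationConfig(
            n_chroms = 2L, genes_per_chrom = 120L,
            n_events = c(TD = 8L, PD = 8L, RD = 4L, DD = 4L, DSD = 8L),
            seed = 11L
        )
        simCache$sim <- simulateDuplicatome(cfg)
        simCache$cfg <- cfg
    }
    simCache$sim
}
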