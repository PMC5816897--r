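# Synthetic duplicated-genome simulator with a machine-readable truth set.
#
# Internal representation during simulation: a "records" data.frame with one
# row per gene (id, chrom, exon_count, cds), ordered by position along each
# chromosome.  Coordinates, strands and the genome sequence are generated by
# layoutGenome() at the end; the 1000 bp upstream of each gene embeds that
# gene's promoter sequence so extractPromoters() recovers planted promoters.

senseCodons <- function() {
    gc <- Biostrings::GENETIC_CODE
    names(gc)[gc != "*"]
}

#' Random coding sequence
#'
#' Uniform i.i.d. sense codons (no internal stops).  Uses the current RNG
#' stream.
#'
#' @param n_codons Number of codons.
#' @return A character string of length `3 * n_codons`.
#' @export
randomCds <- function(n_codons) {
    paste(sample(senseCodons(), n_codons, replace = TRUE), collapse = "")
}

#' Simulate a base (pre-duplication) genome
#'
#' Places `genes_per_chrom` genes per chromosome, each with a random sense
#' codon CDS (no internal stops, 100-300 codons) and 1-6 exons, separated by
#' random intergenic gaps of at least 2200 bp.  Deterministic under the
#' config seed.
#'
#' @param config A [SimulationConfig-class].
#' @return List with `annotation` ([GenomeAnnotation-class], ranks assigned),
#'   `cds` (`DNAStringSet`), `genome` (`DNAStringSet`) and `records` (the
#'   internal per-gene table other simulator stages consume).
#' @export
simulateBaseGenome <- function(config) {
    methods::validObject(config)
    withSeed(deriveSeed(config@seed, 1L), {
        chroms <- sprintf("chr%d", seq_len(config@n_chroms))
        n <- config@genes_per_chrom
        recs <- do.call(rbind, lapply(chroms, function(ch) {
            data.frame(
                id = sprintf("%s_g%04d", ch, seq_len(n)),
                chrom = ch,
                exon_count = sample(1:6, n, replace = TRUE),
                cds = vapply(
                    sample(100:300, n, replace = TRUE),
                    randomCds, character(1)
                ),
                stringsAsFactors = FALSE
            )
        }))
        lay <- layoutGenome(recs)
        list(
            annotation = lay$annotation, cds = lay$cds, genome = lay$genome,
            records = recs
        )
    })
}

# Lay out gene records into coordinates, strands and a genome sequence.
# Gaps are 2200-3000 bp so a full 1000 bp promoter fits on either side of
# every gene; promoter sequences (named by gene id) are embedded upstream of
# each gene's TSS on its strand.
layoutGenome <- function(records, promoters = NULL, promoter_len = 1000L) {
    chroms <- unique(records$chrom)
    annRows <- list()
    chromSeqs <- stats::setNames(vector("list", length(chroms)), chroms)
    chromLens <- stats::setNames(numeric(length(chroms)), chroms)
    for (ch in chroms) {
        rows <- which(records$chrom == ch)
        n <- length(rows)
        cdsLens <- nchar(records$cds[rows])
        bodyLens <- cdsLens + 20L * (records$exon_count[rows] - 1L)
        gaps <- sample(2200:3000, n + 1L, replace = TRUE)
        starts <- integer(n)
        ends <- integer(n)
        pos <- 0L
        for (i in seq_len(n)) {
            starts[i] <- pos + gaps[i] + 1L
            ends[i] <- starts[i] + bodyLens[i] - 1L
            pos <- ends[i]
        }
        chromLen <- pos + gaps[n + 1L]
        strands <- sample(c("+", "-"), n, replace = TRUE)
        seqChars <- sample(c("A", "C", "G", "T"), chromLen, replace = TRUE)
        for (i in seq_len(n)) {
            body <- geneBodySeq(
                records$cds[rows[i]], records$exon_count[rows[i]],
                bodyLens[i]
            )
            if (strands[i] == "-") {
                body <- as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(body)
                ))
            }
            seqChars[starts[i]:ends[i]] <- strsplit(body, "")[[1]]
            gid <- records$id[rows[i]]
            prom <- if (!is.null(promoters) && gid %in% names(promoters)) {
                promoters[[gid]]
            }
            if (!is.null(prom)) {
                prom <- as.character(prom)
                if (strands[i] == "+") {
                    from <- starts[i] - nchar(prom)
                    seqChars[from:(starts[i] - 1L)] <- strsplit(prom, "")[[1]]
                } else {
                    rc <- as.character(Biostrings::reverseComplement(
                        Biostrings::DNAString(prom)
                    ))
                    seqChars[(ends[i] + 1L):(ends[i] + nchar(rc))] <-
                        strsplit(rc, "")[[1]]
                }
            }
        }
        chromSeqs[[ch]] <- paste(seqChars, collapse = "")
        chromLens[ch] <- chromLen
        annRows[[ch]] <- data.frame(
            id = records$id[rows], chrom = ch, start = starts, end = ends,
            strand = strands, exon_count = records$exon_count[rows],
            stringsAsFactors = FALSE
        )
    }
    ann <- do.call(rbind, annRows)
    annotation <- assignRanks(GenomeAnnotation(
        chrom = ann$chrom, start = ann$start, end = ann$end,
        strand = ann$strand, gene_id = ann$id, exon_count = ann$exon_count,
        chromLengths = chromLens
    ))
    cds <- Biostrings::DNAStringSet(stats::setNames(
        records$cds,
        records$id
    ))
    genome <- Biostrings::DNAStringSet(unlist(chromSeqs))
    list(annotation = annotation, cds = cds, genome = genome)
}

# Spliced gene body: CDS split into exon_count chunks (matching the GFF3
# writer's even layout) joined by random 20 bp introns.
geneBodySeq <- function(cds, n_exons, body_len) {
    ex <- evenExonLayout(1L, body_len, n_exons)
    if (nrow(ex) == 1L) {
        return(cds)
    }
    widths <- ex[, 2] - ex[, 1] + 1L
    stops <- cumsum(widths)
    startsC <- c(1L, stops[-length(stops)] + 1L)
    chunks <- substring(cds, startsC, stops)
    introns <- vapply(
        seq_len(n_exons - 1L),
        function(i) randomDna(20L), character(1)
    )
    paste0(paste0(chunks[-n_exons], introns, collapse = ""), chunks[n_exons])
}

#' Evolve a coding sequence to a target synonymous divergence
#'
#' Applies random single-nucleotide substitutions (uniform over positions and
#' alternative bases) until the number of accepted synonymous changes reaches
#' `target_ks` times the sequence's NG86 synonymous site count.  Synonymous
#' proposals are always accepted; nonsynonymous proposals are accepted with
#' probability `target_ka_ks`; proposals creating a stop codon are rejected.
#' The realised NG86 Ks of (input, output) is therefore centred on
#' `target_ks` (the Jukes-Cantor correction undoes multiple hits) with
#' Ka/Ks close to `target_ka_ks`.
#'
#' @param cds Coding sequence (character or `DNAString`), length divisible by
#'   3, no internal stops.
#' @param target_ks Target synonymous substitutions per synonymous site
#'   (>= 0).
#' @param target_ka_ks Acceptance probability for nonsynonymous changes in
#'   `[0, 1]`.
#' @param seed Optional integer seed (NULL to use the current RNG stream).
#' @return The mutated coding sequence (character).
#' @export
#' @examples
#' mut <- evolvePair(randomCds(100), target_ks = 0.2, target_ka_ks = 0, seed = 7)
evolvePair <- function(cds, target_ks, target_ka_ks, seed = NULL) {
    if (target_ks < 0) {
        stop("target_ks must be >= 0")
    }
    cds <- toupper(as.character(cds))
    if (target_ks == 0) {
        return(cds)
    }
    withSeed(seed, {
        gc <- Biostrings::GENETIC_CODE
        tab <- ng86Tables()
        codons <- splitCodons(cds)
        if (any(gc[codons] == "*")) {
            stop("internal stop codon in input CDS")
        }
        s0 <- sum(tab$synSites[tab$index[codons]])
        nSynTarget <- round(target_ks * s0)
        if (nSynTarget == 0L) {
            return(cds)
        }
        nt <- c("A", "C", "G", "T")
        L <- length(codons) * 3L
        synCount <- 0L
        guard <- 0L
        guardMax <- 200L * nSynTarget + 10000L
        while (synCount < nSynTarget && guard < guardMax) {
            guard <- guard + 1L
            pos <- sample.int(L, 1L)
            ci <- (pos - 1L) %/% 3L + 1L
            off <- (pos - 1L) %% 3L + 1L
            cod <- codons[ci]
            cur <- substr(cod, off, off)
            alt <- sample(nt[nt != cur], 1L)
            newCod <- cod
            substr(newCod, off, off) <- alt
            aaNew <- gc[[newCod]]
            if (aaNew == "*") next
            if (aaNew == gc[[cod]]) {
                codons[ci] <- newCod
                synCount <- synCount + 1L
            } else if (target_ka_ks > 0 && stats::runif(1L) < target_ka_ks) {
                codons[ci] <- newCod
            }
        }
        paste(codons, collapse = "")
    })
}

#' Plant duplication events of all six modes
#'
#' Starting from a base genome, appends a whole-genome duplication (each
#' chromosome copied as a new chromosome, per-gene retention sampled at
#' `wgd_retention`), then plants the configured single-gene events: tandem
#' (adjacent copy), proximal (copy with 2-9 intervening genes),
#' retrotransposed (single-exon copy of a >= 3 exon parent on another
#' chromosome), DNA-transposed (multi-exon copy on another chromosome) and
#' dispersed (the CDS of a distant ancestral-locus gene without a retained
#' WGD copy is replaced by a diverged copy of the source, so both members sit
#' at ancestral loci).  Copies diverge from their parents by [evolvePair()]
#' at the per-class target Ks.
#'
#' @param base Output of [simulateBaseGenome()].
#' @param config The [SimulationConfig-class] used for the base genome.
#' @return List with `annotation`, `cds`, `genome` (relaid-out genome
#'   including the new genes), `records`, `truth` (a [TruthSet-class]) and
#'   `retained` (named logical: base gene has a retained WGD copy).
#' @export
plantEvents <- function(base, config) {
    records <- base$records
    ev <- c(TD = 0L, PD = 0L, RD = 0L, DD = 0L, DSD = 0L)
    ev[names(config@n_events)] <- config@n_events
    tks <- config@target_ks
    kaks <- config@target_ka_ks
    withSeed(deriveSeed(config@seed, 2L), {
        baseChroms <- unique(records$chrom)
        localIdx <- split(seq_len(nrow(records)), records$chrom)[baseChroms]
        nPerChrom <- lengths(localIdx)
        free <- rep(TRUE, nrow(records))
        # protected "after-slots" per chromosome: no stray insertion may land
        # between the genes of a planted tandem/proximal pair
        protectedAfter <- stats::setNames(
            rep(list(integer(0)), length(baseChroms)), baseChroms
        )
        retained <- stats::setNames(
            stats::runif(nrow(records)) < config@wgd_retention,
            records$id
        )

        truthPairs <- list()
        inserts <- list() # (chrom, after_local, record row)
        overwrites <- list() # (row, new cds)

        pickParent <- function(regionLen, needExonMin = 1L,
                               avoidChrom = NULL) {
            for (try in seq_len(5000L)) {
                ch <- sample(setdiff(baseChroms, avoidChrom), 1L)
                n <- nPerChrom[[ch]]
                if (n < regionLen + 1L) next
                s <- sample.int(n - regionLen, 1L)
                span <- s:(s + regionLen - 1L)
                rows <- localIdx[[ch]][span]
                if (!all(free[rows])) next
                if (records$exon_count[rows[1L]] < needExonMin) next
                if (any(span %in% protectedAfter[[ch]])) next
                free[rows] <<- FALSE
                return(list(chrom = ch, local = s, row = rows[1L]))
            }
            NULL
        }
        pickParentOrStop <- function(mode, regionLen, needExonMin = 1L) {
            p <- pickParent(regionLen, needExonMin)
            if (is.null(p) || !is.list(p)) {
                stop(
                    "could not place a ", mode, " event; ",
                    "increase genes_per_chrom or reduce event counts"
                )
            }
            p
        }
        freeAfterSlot <- function(ch, excludeLocal = NULL) {
            n <- nPerChrom[[ch]]
            allowed <- setdiff(0:n, protectedAfter[[ch]])
            if (!is.null(excludeLocal)) {
                allowed <- allowed[abs(allowed - excludeLocal) >= 25L]
            }
            if (!length(allowed)) stop("no free insertion slot on ", ch)
            allowed[sample.int(length(allowed), 1L)]
        }
        copyRecord <- function(row, suffix, ks, exon_count = NULL) {
            data.frame(
                id = paste0(records$id[row], suffix),
                chrom = NA_character_,
                exon_count = if (is.null(exon_count)) {
                    records$exon_count[row]
                } else {
                    exon_count
                },
                cds = evolvePair(records$cds[row], ks, kaks),
                stringsAsFactors = FALSE
            )
        }
        addTruth <- function(a, b, mode) {
            truthPairs[[length(truthPairs) + 1L]] <<- data.frame(
                gene_a = a, gene_b = b, true_mode = mode,
                true_ks = unname(tks[mode]), converted = FALSE,
                stringsAsFactors = FALSE
            )
        }

        # tandem: copy immediately after the parent (rank difference 1)
        for (k in seq_len(ev[["TD"]])) {
            p <- pickParentOrStop("TD", 1L)
            rec <- copyRecord(p$row, sprintf("_td%d", k), tks[["TD"]])
            inserts[[length(inserts) + 1L]] <- list(
                chrom = p$chrom, after = p$local, rec = rec
            )
            protectedAfter[[p$chrom]] <- c(protectedAfter[[p$chrom]], p$local)
            addTruth(records$id[p$row], rec$id, "TD")
        }
        # proximal: copy with 2-9 pre-existing intervening genes
        for (k in seq_len(ev[["PD"]])) {
            m <- sample(2:9, 1L)
            p <- pickParentOrStop("PD", m + 1L)
            rec <- copyRecord(p$row, sprintf("_pd%d", k), tks[["PD"]])
            inserts[[length(inserts) + 1L]] <- list(
                chrom = p$chrom, after = p$local + m, rec = rec
            )
            protectedAfter[[p$chrom]] <- c(
                protectedAfter[[p$chrom]],
                p$local:(p$local + m)
            )
            addTruth(records$id[p$row], rec$id, "PD")
        }
        # retrotransposed: single-exon copy of a multi-exon parent, planted on
        # a different chromosome (a novel, non-ancestral locus)
        if (ev[["RD"]] > 0L &&
            !any(records$exon_count >= 3L & free)) {
            stop("RD events requested but no free multi-exon parents")
        }
        for (k in seq_len(ev[["RD"]])) {
            p <- pickParentOrStop("RD", 1L, needExonMin = 3L)
            rec <- copyRecord(p$row, sprintf("_rd%d", k), tks[["RD"]],
                exon_count = 1L
            )
            ch2 <- if (length(baseChroms) > 1L) {
                sample(setdiff(baseChroms, p$chrom), 1L)
            } else {
                p$chrom
            }
            after <- freeAfterSlot(
                ch2,
                if (ch2 == p$chrom) p$local else NULL
            )
            inserts[[length(inserts) + 1L]] <- list(
                chrom = ch2, after = after, rec = rec
            )
            addTruth(records$id[p$row], rec$id, "RD")
        }
        # DNA-transposed: multi-exon copy on a different chromosome
        for (k in seq_len(ev[["DD"]])) {
            p <- pickParentOrStop("DD", 1L)
            rec <- copyRecord(p$row, sprintf("_dd%d", k), tks[["DD"]],
                exon_count = max(2L, records$exon_count[p$row])
            )
            ch2 <- if (length(baseChroms) > 1L) {
                sample(setdiff(baseChroms, p$chrom), 1L)
            } else {
                p$chrom
            }
            after <- freeAfterSlot(
                ch2,
                if (ch2 == p$chrom) p$local else NULL
            )
            inserts[[length(inserts) + 1L]] <- list(
                chrom = ch2, after = after, rec = rec
            )
            addTruth(records$id[p$row], rec$id, "DD")
        }
        # dispersed: overwrite a distant ancestral-locus gene (without a
        # retained WGD copy) with a diverged copy of the source
        for (k in seq_len(ev[["DSD"]])) {
            src <- pickParentOrStop("DSD", 1L)
            tgt <- NULL
            for (try in seq_len(5000L)) {
                chT <- if (length(baseChroms) > 1L) {
                    sample(setdiff(baseChroms, src$chrom), 1L)
                } else {
                    src$chrom
                }
                sT <- sample.int(nPerChrom[[chT]], 1L)
                rowT <- localIdx[[chT]][sT]
                if (!free[rowT] || retained[records$id[rowT]]) next
                if (chT == src$chrom && abs(sT - src$local) < 25L) next
                free[rowT] <- FALSE
                tgt <- list(chrom = chT, local = sT, row = rowT)
                break
            }
            if (is.null(tgt)) {
                stop(
                    "could not place a DSD event; increase genes_per_chrom ",
                    "or wgd gene losses"
                )
            }
            overwrites[[length(overwrites) + 1L]] <- list(
                row = tgt$row,
                cds = evolvePair(records$cds[src$row], tks[["DSD"]], kaks)
            )
            addTruth(records$id[src$row], records$id[tgt$row], "DSD")
        }

        for (ow in overwrites) {
            records$cds[ow$row] <- ow$cds
        }

        # whole-genome duplication: each chromosome appended as a new "<chr>d"
        # chromosome carrying the retained copies in order
        wgdRecs <- list()
        for (ch in baseChroms) {
            rows <- localIdx[[ch]]
            keep <- rows[retained[records$id[rows]]]
            if (!length(keep)) next
            wgdRecs[[ch]] <- data.frame(
                id = paste0(records$id[keep], "_w"),
                chrom = paste0(ch, "d"),
                exon_count = records$exon_count[keep],
                cds = vapply(
                    records$cds[keep],
                    function(s) evolvePair(s, tks[["WGD"]], kaks),
                    character(1), USE.NAMES = FALSE
                ),
                stringsAsFactors = FALSE
            )
            for (r in keep) {
                addTruth(records$id[r], paste0(records$id[r], "_w"), "WGD")
            }
        }

        # materialise insertions per base chromosome
        outRecs <- list()
        for (ch in baseChroms) {
            rows <- localIdx[[ch]]
            ins <- Filter(function(x) x$chrom == ch, inserts)
            pieces <- vector("list", length(rows) + 1L)
            for (slot in 0:length(rows)) {
                here <- Filter(function(x) x$after == slot, ins)
                recHere <- if (length(here)) {
                    do.call(rbind, lapply(here, function(x) {
                        x$rec$chrom <- ch
                        x$rec
                    }))
                }
                baseRow <- if (slot > 0L) records[rows[slot], , drop = FALSE]
                pieces[[slot + 1L]] <- rbind(baseRow, recHere)
            }
            outRecs[[ch]] <- do.call(rbind, pieces)
        }
        newRecords <- do.call(rbind, c(outRecs, wgdRecs))
        rownames(newRecords) <- NULL

        truthDf <- do.call(rbind, truthPairs)
        truth <- new("TruthSet",
            pairs = S4Vectors::DataFrame(truthDf, row.names = NULL),
            genes = S4Vectors::DataFrame(
                truthGeneModes(truthDf, newRecords$id),
                row.names = NULL
            )
        )
        lay <- layoutGenome(newRecords)
        list(
            annotation = lay$annotation, cds = lay$cds, genome = lay$genome,
            records = newRecords, truth = truth, retained = retained
        )
    })
}

# Gene-level truth modes: per gene, the highest-priority mode among its
# planted pairs (same priority rule the classifier uses); SINGLETON otherwise.
truthGeneModes <- function(truthDf, all_ids) {
    modes <- finalizeGeneModes(
        data.frame(
            gene_a = truthDf$gene_a, gene_b = truthDf$gene_b,
            mode = truthDf$true_mode, stringsAsFactors = FALSE
        ),
        all_ids
    )
    data.frame(
        gene = names(modes), true_mode = unname(modes),
        stringsAsFactors = FALSE
    )
}

#' Simulate an outgroup genome of the ancestral loci
#'
#' The outgroup preserves the gene order of the focal genome's ancestral
#' (pre-event) loci only: one chromosome per base chromosome, one ortholog
#' per base gene, diverged to `ortholog_ks`.  Planted copies (tandem,
#' proximal, transposed daughters and WGD chromosomes) are absent, so focal
#' genes present in focal-vs-outgroup collinear blocks are exactly the
#' ancestral loci.
#'
#' @param planted Output of [plantEvents()] (or [simulateBaseGenome()]; any
#'   list with a `records` table whose base-chromosome genes are the
#'   ancestral loci).
#' @param config The [SimulationConfig-class] used upstream.
#' @param ortholog_ks Target Ks between each ancestral gene and its ortholog
#'   (default 0.3).
#' @return List with `annotation`, `cds`, `genome` for the outgroup and
#'   `ortholog_map` (`data.frame`: `gene`, `ortholog`).
#' @export
simulateOutgroup <- function(planted, config, ortholog_ks = 0.3) {
    records <- planted$records
    baseChroms <- grep("^chr[0-9]+$", unique(records$chrom), value = TRUE)
    # ancestral loci: genes of the base chromosomes that predate the planted
    # events (inserted copies carry event suffixes)
    isBase <- records$chrom %in% baseChroms &
        !grepl("_(td|pd|rd|dd)[0-9]+$|_w$", records$id)
    anc <- records[isBase, , drop = FALSE]
    withSeed(deriveSeed(config@seed, 3L), {
        og <- data.frame(
            id = paste0("og_", anc$id),
            chrom = paste0("og_", anc$chrom),
            exon_count = anc$exon_count,
            cds = vapply(
                anc$cds,
                function(s) evolvePair(s, ortholog_ks, config@target_ka_ks),
                character(1), USE.NAMES = FALSE
            ),
            stringsAsFactors = FALSE
        )
        lay <- layoutGenome(og)
        list(
            annotation = lay$annotation, cds = lay$cds, genome = lay$genome,
            ortholog_map = data.frame(
                gene = anc$id, ortholog = og$id, ks = ortholog_ks,
                stringsAsFactors = FALSE
            )
        )
    })
}

#' Simulate expression profiles with controlled pair correlation
#'
#' Each gene's profile across `n_tissues` samples is Gaussian around a
#' gene-specific mean; for every duplicate pair the two profiles are drawn
#' from a bivariate normal whose population correlation equals the pair's
#' `target_r` (pairs are processed in order, the second member's profile
#' being re-drawn against the first's).  Values are floored at zero (means
#' are large enough that this is almost never binding).  Intergenic rows are
#' exponential with per-sample median ~0.715, emulating the low transcription
#' background used to derive the expression threshold.
#'
#' @param pairs `data.frame` with `gene_a`, `gene_b`.
#' @param target_r Numeric vector (length 1 or `nrow(pairs)`) of target
#'   Pearson correlations in `[-1, 1]`.
#' @param n_tissues Number of samples (>= 3).
#' @param noise_sd Extra independent noise SD folded into the bivariate model
#'   (inflates variance without changing the correlation target).
#' @param seed Integer seed.
#' @param genes All gene ids needing a profile (defaults to the pair genes).
#' @param n_intergenic Number of intergenic background rows (default 200).
#' @return List with `tpm` (genes x samples matrix) and `intergenic_tpm`.
#' @export
simulateExpression <- function(pairs, target_r, n_tissues = 12L,
                               noise_sd = 1, seed = 1L, genes = NULL,
                               n_intergenic = 200L) {
    if (n_tissues < 3L) {
        stop("n_tissues must be >= 3")
    }
    if (any(abs(target_r) > 1)) {
        stop("|target_r| must be <= 1")
    }
    if (length(target_r) == 1L) {
        target_r <- rep(target_r, nrow(pairs))
    }
    stopifnot(length(target_r) == nrow(pairs))
    if (is.null(genes)) {
        genes <- unique(c(pairs$gene_a, pairs$gene_b))
    }
    withSeed(seed, {
        sdTot <- sqrt(100 + noise_sd^2)
        mu <- stats::setNames(stats::runif(length(genes), 40, 80), genes)
        z <- matrix(stats::rnorm(length(genes) * n_tissues),
            nrow = length(genes), dimnames = list(genes, NULL)
        )
        for (i in seq_len(nrow(pairs))) {
            a <- pairs$gene_a[i]
            b <- pairs$gene_b[i]
            if (!(a %in% genes) || !(b %in% genes)) next
            r <- target_r[i]
            z[b, ] <- r * z[a, ] + sqrt(1 - r^2) * stats::rnorm(n_tissues)
        }
        tpm <- pmax(mu + sdTot * z, 0)
        colnames(tpm) <- sprintf("tissue%02d", seq_len(n_tissues))
        inter <- matrix(
            stats::rexp(n_intergenic * n_tissues, rate = log(2) / 0.715),
            nrow = n_intergenic,
            dimnames = list(
                sprintf("intergenic_%03d", seq_len(n_intergenic)),
                colnames(tpm)
            )
        )
        list(tpm = tpm, intergenic_tpm = inter)
    })
}

#' Simulate promoter pairs with planted shared-motif coverage
#'
#' Every gene gets a random promoter; for each pair, the second member's
#' promoter is rebuilt so that identical blocks (each >= `motif_min_len` bp,
#' at identical positions in both sequences) cover `shared_fraction` of
#' positions, the rest being independent random sequence.
#'
#' @param pairs `data.frame` with `gene_a`, `gene_b`.
#' @param shared_fraction Numeric (length 1 or `nrow(pairs)`) in `[0, 1]`.
#' @param length Promoter length in bp (default 1000).
#' @param motif_min_len Minimum planted block length (default 16).
#' @param seed Integer seed.
#' @param genes Optional additional gene ids to give random promoters.
#' @return A `DNAStringSet` named by gene id.
#' @export
simulatePromoters <- function(pairs, shared_fraction, length = 1000L,
                              motif_min_len = 16L, seed = 1L, genes = NULL) {
    if (any(shared_fraction < 0 | shared_fraction > 1)) {
        stop("shared_fraction must lie in [0, 1]")
    }
    if (base::length(shared_fraction) == 1L) {
        shared_fraction <- rep(shared_fraction, nrow(pairs))
    }
    withSeed(seed, {
        ids <- unique(c(pairs$gene_a, pairs$gene_b, genes))
        proms <- stats::setNames(
            vapply(ids, function(i) randomDna(length), character(1)), ids
        )
        for (i in seq_len(nrow(pairs))) {
            a <- pairs$gene_a[i]
            b <- pairs$gene_b[i]
            f <- shared_fraction[i]
            if (f <= 0) next
            if (f >= 1) {
                proms[b] <- proms[a]
                next
            }
            total <- round(f * length)
            if (total < motif_min_len) next
            blockLen <- max(motif_min_len, 50L)
            nb <- max(1L, floor(total / blockLen))
            lens <- rep(blockLen, nb)
            lens[nb] <- total - blockLen * (nb - 1L)
            if (lens[nb] < motif_min_len) {
                lens[nb - 1L] <- lens[nb - 1L] + lens[nb]
                lens <- lens[-nb]
                nb <- nb - 1L
            }
            gapTotal <- length - sum(lens)
            cuts <- sort(sample.int(gapTotal + 1L, nb) - 1L)
            starts <- cuts + cumsum(c(0L, lens[-nb])) + 1L
            pb <- proms[b]
            for (j in seq_len(nb)) {
                substr(pb, starts[j], starts[j] + lens[j] - 1L) <-
                    substr(proms[a], starts[j], starts[j] + lens[j] - 1L)
            }
            proms[b] <- pb
        }
        Biostrings::DNAStringSet(proms)
    })
}

# Monotone map from divergence to a plausible percent identity for the
# emitted homology table.
identityFromKs <- function(ks) {
    pmax(30, 100 - 40 * ks)
}

#' Simulate a complete duplicated genome with every pipeline input
#'
#' One-stop wrapper: base genome, planted events, promoters embedded in the
#' genome sequence, outgroup genome with ortholog map, expression matrices,
#' and the homology tables (true pairs plus optional decoys) that stand in
#' for an all-vs-all protein search.
#'
#' @param config A [SimulationConfig-class].
#' @param ortholog_ks Focal-outgroup divergence (default 0.3).
#' @param n_decoys Number of random decoy hits with non-significant E-values
#'   appended to the homology table (default 0).
#' @return List: `annotation`, `cds`, `genome`, `promoters`, `truth`,
#'   `hits` (intra-genome, directed), `outgroup` (list with `annotation`,
#'   `cds`, `genome`), `ortholog_map`, `outgroup_hits`, `expression`
#'   (list `tpm`, `intergenic_tpm`), `records`.
#' @export
simulateDuplicatome <- function(config, ortholog_ks = 0.3, n_decoys = 0L) {
    base <- simulateBaseGenome(config)
    planted <- plantEvents(base, config)
    truthDf <- as.data.frame(truePairs(planted$truth))

    proms <- simulatePromoters(
        truthDf,
        shared_fraction = config@promoter_shared_fraction,
        motif_min_len = config@motif_min_len,
        seed = deriveSeed(config@seed, 4L),
        genes = planted$records$id
    )
    lay <- withSeed(
        deriveSeed(config@seed, 5L),
        layoutGenome(planted$records, promoters = as.character(proms))
    )
    outgroup <- simulateOutgroup(planted, config, ortholog_ks)

    exprTargets <- withSeed(
        deriveSeed(config@seed, 6L),
        stats::runif(nrow(truthDf), -0.2, 0.95)
    )
    expr <- simulateExpression(
        truthDf,
        target_r = exprTargets,
        n_tissues = config@n_tissues,
        seed = deriveSeed(config@seed, 7L),
        genes = planted$records$id
    )

    hits <- withSeed(deriveSeed(config@seed, 8L), {
        h <- data.frame(
            query = c(truthDf$gene_a, truthDf$gene_b),
            subject = c(truthDf$gene_b, truthDf$gene_a),
            pct_identity = rep(identityFromKs(truthDf$true_ks), 2L),
            evalue = 1e-30,
            bitscore = rep(pmax(50, 500 - 100 * truthDf$true_ks), 2L),
            length = 300L,
            stringsAsFactors = FALSE
        )
        if (n_decoys > 0L) {
            ids <- planted$records$id
            d1 <- sample(ids, n_decoys, replace = TRUE)
            d2 <- sample(ids, n_decoys, replace = TRUE)
            keep <- d1 != d2
            h <- rbind(h, data.frame(
                query = d1[keep], subject = d2[keep],
                pct_identity = 25, evalue = 1e-3, bitscore = 40,
                length = 100L, stringsAsFactors = FALSE
            ))
        }
        h
    })
    outHits <- data.frame(
        query = outgroup$ortholog_map$gene,
        subject = outgroup$ortholog_map$ortholog,
        pct_identity = identityFromKs(ortholog_ks),
        evalue = 1e-30,
        bitscore = pmax(50, 500 - 100 * ortholog_ks),
        length = 300L,
        stringsAsFactors = FALSE
    )
    list(
        annotation = lay$annotation, cds = lay$cds, genome = lay$genome,
        promoters = proms, truth = planted$truth, hits = hits,
        outgroup = outgroup[c("annotation", "cds", "genome")],
        ortholog_map = outgroup$ortholog_map,
        outgroup_hits = outHits,
        expression = expr,
        records = planted$records
    )
}

#' Write a simulated data set to disk
#'
#' Emits every pipeline input as plain text: GFF3 + FASTA (genome, CDS,
#' protein) for the focal and outgroup genomes, m8 homology tables, TPM and
#' intergenic-TPM TSVs, promoter FASTA, ortholog map TSV and the truth
#' tables.  Deterministic: the same simulation writes byte-identical files.
#'
#' @param sim Output of [simulateDuplicatome()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(...) file.path(dir, ...)
    writeAnnotationGff3(sim$annotation, p("focal.gff3"))
    Biostrings::writeXStringSet(sim$genome, p("focal_genome.fa"))
    Biostrings::writeXStringSet(sim$cds, p("focal_cds.fa"))
    prot <- Biostrings::translate(sim$cds, if.fuzzy.codon = "X")
    Biostrings::writeXStringSet(prot, p("focal_protein.fa"))
    Biostrings::writeXStringSet(sim$promoters, p("focal_promoters.fa"))
    writeHomologyM8(sim$hits, p("focal_selfhits.m8"))
    writeAnnotationGff3(sim$outgroup$annotation, p("outgroup.gff3"))
    Biostrings::writeXStringSet(sim$outgroup$genome, p("outgroup_genome.fa"))
    Biostrings::writeXStringSet(sim$outgroup$cds, p("outgroup_cds.fa"))
    writeHomologyM8(sim$outgroup_hits, p("focal_vs_outgroup.m8"))
    writeTsv(sim$ortholog_map, p("ortholog_map.tsv"))
    writeTsv(
        data.frame(gene = rownames(sim$expression$tpm),
            sim$expression$tpm, check.names = FALSE),
        p("tpm.tsv")
    )
    writeTsv(
        data.frame(region = rownames(sim$expression$intergenic_tpm),
            sim$expression$intergenic_tpm, check.names = FALSE),
        p("intergenic_tpm.tsv")
    )
    writeTsv(as.data.frame(truePairs(sim$truth)), p("truth_pairs.tsv"))
    writeTsv(as.data.frame(sim$truth@genes), p("truth_genes.tsv"))
    invisible(dir)
}
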