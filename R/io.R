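# Readers/writers for the standard formats the pipeline touches, gene ranking,
# and promoter/intergenic extraction.
#
# Coordinate conventions: GFF3 is parsed/written 1-based inclusive, internal
# arithmetic on GRanges follows the same convention (IRanges closed intervals),
# and intergenic intervals are emitted as BED (0-based half-open).

#' Read a genome annotation from GFF3
#'
#' Parses gene models from a GFF3 file.  One gene record is produced per
#' `gene` feature; `exon_count` is the number of exon features of the gene's
#' longest annotated mRNA (by summed exon width).  Genes without any annotated
#' exon get `exon_count = 1` with a warning.  Chromosome lengths are taken
#' from `##sequence-region` pragmas when present.
#'
#' @param path Path to a GFF3 file.
#' @return A [GenomeAnnotation-class] (ranks unset; see [assignRanks()]).
#' @export
#' @examples
#' cfg <- simulationConfig(n_chroms = 1L, genes_per_chrom = 8L, seed = 1L)
#' base <- simulateBaseGenome(cfg)
#' gff <- tempfile(fileext = ".gff3")
#' writeAnnotationGff3(base$annotation, gff)
#' readAnnotation(gff)
readAnnotation <- function(path) {
    if (!file.exists(path)) {
        stop("GFF3 file not found: ", path)
    }
    gr <- tryCatch(
        rtracklayer::import(path, format = "gff3"),
        error = function(e) {
            stop("malformed GFF3 in ", path, ": ", conditionMessage(e))
        }
    )
    md <- S4Vectors::mcols(gr)
    type <- as.character(md$type)
    geneIdx <- which(type == "gene")
    if (!length(geneIdx)) {
        return(GenomeAnnotation(
            chrom = character(), start = integer(), end = integer(),
            strand = character(), gene_id = character(),
            exon_count = integer(),
            chromLengths = seqLengthsFromGff(path)
        ))
    }
    geneId <- as.character(md$ID[geneIdx])
    geneId[is.na(geneId)] <- sprintf("gene_%d", seq_along(geneId))[is.na(geneId)]

    parentOf <- function(i) {
        p <- md$Parent[[i]]
        if (length(p)) as.character(p)[1] else NA_character_
    }
    mrnaIdx <- which(type %in% c("mRNA", "transcript"))
    exonIdx <- which(type == "exon")
    if (!length(exonIdx)) {
        exonIdx <- which(type == "CDS")
    }
    mrnaId <- as.character(md$ID[mrnaIdx])
    mrnaParent <- vapply(mrnaIdx, parentOf, character(1))
    exonParent <- vapply(exonIdx, parentOf, character(1))
    exonWidth <- GenomicRanges::width(gr)[exonIdx]

    # exon count of the longest mRNA (by summed exon width) per gene; exons
    # parented directly on the gene count as a single implicit transcript
    exonCount <- stats::setNames(rep(NA_integer_, length(geneId)), geneId)
    if (length(exonIdx)) {
        byTx <- split(seq_along(exonIdx), exonParent)
        txLen <- vapply(byTx, function(i) sum(exonWidth[i]), numeric(1))
        txN <- lengths(byTx)
        txGene <- stats::setNames(mrnaParent, mrnaId)[names(byTx)]
        direct <- is.na(txGene) & names(byTx) %in% geneId
        txGene[direct] <- names(byTx)[direct]
        keep <- !is.na(txGene)
        if (any(keep)) {
            ord <- order(txGene[keep], -txLen[keep])
            g <- txGene[keep][ord]
            n <- txN[keep][ord]
            first <- !duplicated(g)
            exonCount[g[first]] <- as.integer(n[first])
        }
    }
    if (anyNA(exonCount)) {
        warning(
            sum(is.na(exonCount)),
            " gene(s) without exon features; exon_count set to 1"
        )
        exonCount[is.na(exonCount)] <- 1L
    }

    GenomeAnnotation(
        chrom = as.character(GenomicRanges::seqnames(gr))[geneIdx],
        start = GenomicRanges::start(gr)[geneIdx],
        end = GenomicRanges::end(gr)[geneIdx],
        strand = as.character(GenomicRanges::strand(gr))[geneIdx],
        gene_id = geneId,
        exon_count = unname(exonCount[geneId]),
        chromLengths = seqLengthsFromGff(path)
    )
}

# ##sequence-region pragmas -> named chromosome lengths (NULL if absent).
seqLengthsFromGff <- function(path) {
    hdr <- readLines(path, n = 500L)
    sr <- grep("^##sequence-region", hdr, value = TRUE)
    if (!length(sr)) {
        return(NULL)
    }
    parts <- strsplit(trimws(sr), "\\s+")
    stats::setNames(
        vapply(parts, function(p) as.numeric(p[4]), numeric(1)),
        vapply(parts, function(p) p[2], character(1))
    )
}

#' Write a GenomeAnnotation as GFF3
#'
#' Deterministic writer producing gene, mRNA and exon features (one mRNA per
#' gene; the exon chain splits the gene body into `exon_count` pieces with
#' fixed-length introns, matching the simulator's layout).  Byte-stable:
#' writing the same annotation twice yields identical files.
#'
#' @param annotation A [GenomeAnnotation-class].
#' @param path Output path.
#' @param exonStructure Optional named list `gene_id -> matrix(start, end)` of
#'   explicit exon coordinates; when NULL exons are laid out by splitting the
#'   gene body evenly.
#' @return `path`, invisibly.
#' @export
writeAnnotationGff3 <- function(annotation, path, exonStructure = NULL) {
    gr <- genes(annotation)
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    sl <- chromLengths(annotation)
    if (length(sl) && !all(is.na(sl))) {
        writeLines(
            sprintf("##sequence-region %s 1 %d", names(sl), as.integer(sl)),
            con
        )
    }
    if (!length(gr)) {
        return(invisible(path))
    }
    ord <- order(
        as.character(GenomicRanges::seqnames(gr)),
        GenomicRanges::start(gr), GenomicRanges::end(gr),
        S4Vectors::mcols(gr)$gene_id
    )
    gr <- gr[ord]
    md <- S4Vectors::mcols(gr)
    lines <- character(0)
    for (i in seq_along(gr)) {
        chrom <- as.character(GenomicRanges::seqnames(gr))[i]
        s <- GenomicRanges::start(gr)[i]
        e <- GenomicRanges::end(gr)[i]
        st <- as.character(GenomicRanges::strand(gr))[i]
        if (st == "*") st <- "+"
        id <- md$gene_id[i]
        nEx <- md$exon_count[i]
        if (!is.null(exonStructure) && !is.null(exonStructure[[id]])) {
            ex <- exonStructure[[id]]
        } else {
            ex <- evenExonLayout(s, e, nEx)
        }
        lines <- c(
            lines,
            sprintf(
                "%s\tParalogModes\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                chrom, s, e, st, id
            ),
            sprintf(
                "%s\tParalogModes\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                chrom, s, e, st, id, id
            ),
            sprintf(
                "%s\tParalogModes\texon\t%d\t%d\t.\t%s\t.\tID=%s.t1.exon%d;Parent=%s.t1",
                chrom, ex[, 1], ex[, 2], st, id, seq_len(nrow(ex)), id
            )
        )
    }
    writeLines(lines, con)
    invisible(path)
}

# Split [s, e] into n exons separated by introns of >= 20 bp where room allows.
evenExonLayout <- function(s, e, n) {
    len <- e - s + 1
    if (n <= 1L || len < 2L * n + 20L * (n - 1L)) {
        return(matrix(c(s, e), ncol = 2))
    }
    intron <- 20L
    exTotal <- len - intron * (n - 1L)
    sizes <- rep(exTotal %/% n, n)
    sizes[n] <- sizes[n] + exTotal %% n
    starts <- s + cumsum(c(0L, sizes[-n] + intron))
    cbind(starts, starts + sizes - 1L)
}

#' Read all-vs-all homology hits from BLAST tabular (m8 / outfmt 6) output
#'
#' Drops self-hits, applies an E-value ceiling and keeps at most `top_n`
#' subjects per query (best bit score first).
#'
#' @param path 12-column tab-separated hit file.
#' @param evalue_max Maximum E-value retained (default 1e-5).
#' @param top_n Maximum subjects per query (default 5).
#' @return `data.frame` with columns `query`, `subject`, `pct_identity`,
#'   `evalue`, `bitscore`, ordered by query then descending bit score.
#' @export
readHomology <- function(path, evalue_max = 1e-5, top_n = 5L) {
    raw <- utils::read.table(path,
        sep = "\t", header = FALSE,
        stringsAsFactors = FALSE, comment.char = "#", quote = ""
    )
    if (ncol(raw) < 12L) {
        stop("m8 file must have 12 tab-separated columns: ", path)
    }
    if (!is.numeric(raw[[11]]) || !is.numeric(raw[[12]])) {
        stop("non-numeric E-value or bit-score column in ", path)
    }
    hits <- data.frame(
        query = as.character(raw[[1]]),
        subject = as.character(raw[[2]]),
        pct_identity = as.numeric(raw[[3]]),
        evalue = as.numeric(raw[[11]]),
        bitscore = as.numeric(raw[[12]]),
        stringsAsFactors = FALSE
    )
    hits <- hits[hits$query != hits$subject & hits$evalue <= evalue_max, ,
        drop = FALSE
    ]
    if (!nrow(hits)) {
        rownames(hits) <- NULL
        return(hits)
    }
    ord <- order(hits$query, -hits$bitscore, hits$evalue, hits$subject)
    hits <- hits[ord, , drop = FALSE]
    keep <- unlist(lapply(
        split(seq_len(nrow(hits)), hits$query),
        function(i) i[seq_len(min(length(i), top_n))]
    ), use.names = FALSE)
    hits <- hits[sort(keep), , drop = FALSE]
    rownames(hits) <- NULL
    hits
}

#' Write homology hits in BLAST tabular (m8) format
#'
#' Emits the standard 12 columns; alignment-detail columns the pipeline does
#' not model (mismatches, gap opens, coordinates) are filled deterministically
#' from the hit length.
#'
#' @param hits `data.frame` with `query`, `subject`, `pct_identity`, `evalue`,
#'   `bitscore`, and optionally `length`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeHomologyM8 <- function(hits, path) {
    len <- if ("length" %in% names(hits)) hits$length else rep(300L, nrow(hits))
    m8 <- data.frame(
        hits$query, hits$subject, sprintf("%.2f", hits$pct_identity),
        len, 0L, 0L, 1L, len, 1L, len,
        formatC(hits$evalue, format = "e", digits = 2),
        sprintf("%.1f", hits$bitscore)
    )
    utils::write.table(m8, path,
        sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE
    )
    invisible(path)
}

#' Assign per-chromosome gene ranks
#'
#' Per chromosome, genes sorted by start (ties: by end, then gene id
#' lexicographically) receive ranks 1..n.  Rank difference is the distance
#' measure of the tandem/proximal rules.
#'
#' @param annotation A [GenomeAnnotation-class].
#' @return The annotation with the `rank` column filled.
#' @export
assignRanks <- function(annotation) {
    gr <- genes(annotation)
    if (!length(gr)) {
        return(annotation)
    }
    chrom <- as.character(GenomicRanges::seqnames(gr))
    rk <- integer(length(gr))
    for (ch in unique(chrom)) {
        i <- which(chrom == ch)
        ord <- order(
            GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i],
            S4Vectors::mcols(gr)$gene_id[i]
        )
        rk[i[ord]] <- seq_along(i)
    }
    S4Vectors::mcols(gr)$rank <- rk
    initialize(annotation, genes = gr)
}

#' Extract promoter sequences
#'
#' The promoter is the `length` bp upstream of the transcriptional start site,
#' taken as the 5'-most genomic coordinate of the gene on its strand: for a
#' `+` gene, `[start - length, start - 1]`; for a `-` gene, the reverse
#' complement of `[end + 1, end + length]`.  Promoters are truncated at
#' chromosome boundaries and may be shorter than `length`.
#'
#' @param annotation A [GenomeAnnotation-class].
#' @param genome A [Biostrings::DNAStringSet] of chromosome sequences.
#' @param length Promoter length in bp (default 1000).
#' @return A `DNAStringSet` named by gene id.
#' @export
extractPromoters <- function(annotation, genome, length = 1000L) {
    gr <- genes(annotation)
    chrom <- as.character(GenomicRanges::seqnames(gr))
    missing <- setdiff(unique(chrom), names(genome))
    if (length(missing)) {
        bad <- S4Vectors::mcols(gr)$gene_id[chrom %in% missing][1]
        stop(
            "chromosome missing from genome for gene ", bad, ": ",
            missing[1]
        )
    }
    n <- base::length(gr)
    out <- vector("list", n)
    strand <- as.character(GenomicRanges::strand(gr))
    starts <- GenomicRanges::start(gr)
    ends <- GenomicRanges::end(gr)
    for (i in seq_len(n)) {
        chromSeq <- genome[[chrom[i]]]
        cl <- base::length(chromSeq)
        if (strand[i] == "-") {
            from <- ends[i] + 1L
            to <- min(ends[i] + length, cl)
            s <- if (from > to) {
                Biostrings::DNAString("")
            } else {
                Biostrings::reverseComplement(
                    Biostrings::subseq(chromSeq, from, to)
                )
            }
        } else {
            from <- max(1L, starts[i] - length)
            to <- starts[i] - 1L
            s <- if (from > to) {
                Biostrings::DNAString("")
            } else {
                Biostrings::subseq(chromSeq, from, to)
            }
        }
        out[[i]] <- s
    }
    res <- Biostrings::DNAStringSet(out)
    names(res) <- S4Vectors::mcols(gr)$gene_id
    res
}

#' Extract intergenic intervals
#'
#' Per chromosome, the maximal intervals not overlapped by any gene body
#' (overlapping genes are unioned first).  Returned as a `GRanges`; together
#' with the reduced gene bodies these tile each chromosome exactly.
#'
#' @param annotation A [GenomeAnnotation-class] with chromosome lengths set.
#' @return A `GRanges` of intergenic intervals (1-based inclusive; use
#'   [writeIntergenicBed()] for 0-based half-open BED output).
#' @export
extractIntergenic <- function(annotation) {
    gr <- genes(annotation)
    sl <- chromLengths(annotation)
    if (!length(sl) || all(is.na(sl))) {
        stop("annotation must carry chromosome lengths")
    }
    full <- GRanges(
        seqnames = names(sl),
        ranges = IRanges(start = 1L, end = as.integer(sl))
    )
    GenomeInfoDb::seqlevels(full) <- names(sl)
    GenomeInfoDb::seqlengths(full) <- sl
    body <- GenomicRanges::reduce(granges(gr), ignore.strand = TRUE)
    GenomeInfoDb::seqlevels(body) <- names(sl)
    out <- GenomicRanges::setdiff(full, body, ignore.strand = TRUE)
    sort(out)
}

#' Write intervals as BED (0-based half-open)
#'
#' @param gr A `GRanges` (1-based inclusive, as returned by
#'   [extractIntergenic()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeIntergenicBed <- function(gr, path) {
    bed <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr) - 1L,
        end = GenomicRanges::end(gr),
        name = sprintf("intergenic_%d", seq_along(gr))
    )
    utils::write.table(bed, path,
        sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE
    )
    invisible(path)
}
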