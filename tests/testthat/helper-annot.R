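# Small hand-built annotations and hit tables shared across test files.

makeRankAnnot <- function(n, chrom = "c1", prefix = "g") {
    assignRanks(GenomeAnnotation(
        chrom = rep(chrom, n),
        start = seq(1000, by = 1000, length.out = n),
        end = seq(1000, by = 1000, length.out = n) + 500,
        strand = "+",
        gene_id = sprintf("%s%03d", prefix, seq_len(n)),
        exon_count = 1L,
        chromLengths = stats::setNames(1000 * n + 1000, chrom)
    ))
}

makeHits <- function(ra, rb, prefixA = "g", prefixB = "h", bits = NULL) {
    data.frame(
        query = sprintf("%s%03d", prefixA, ra),
        subject = sprintf("%s%03d", prefixB, rb),
        pct_identity = 90, evalue = 1e-30,
        bitscore = if (is.null(bits)) rep(100, length(ra)) else bits,
        stringsAsFactors = FALSE
    )
}
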