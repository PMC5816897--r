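# Term enrichment per duplication mode, term-frequency comparison, gene
# family membership and per-family mode composition.

#' Fisher enrichment of annotation terms in a gene set
#'
#' One-sided (over-representation) Fisher's exact test per term on the 2x2
#' table (study genes with term, study without, background with, background
#' without), with Benjamini-Hochberg q-values.  `significant = q < alpha`.
#' The one-sided p is computed as the upper hypergeometric tail
#' (`phyper`), which is identical to `fisher.test(alternative = "greater")`.
#'
#' @param study Character vector of study gene ids (must be a subset of
#'   `population`).
#' @param population Character vector of background gene ids.
#' @param annotation Named list `term id -> character vector of gene ids`, or
#'   a `data.frame` with columns `gene`, `term`.
#' @param alpha Significance level on the q-value (default 0.05).
#' @return `data.frame` per term: counts, `p`, `q`, `significant`, ordered by
#'   `p`.
#' @export
fisherEnrichment <- function(study, population, annotation, alpha = 0.05) {
    if (!length(study)) {
        stop("study set is empty")
    }
    if (!all(study %in% population)) {
        stop("study must be a subset of population")
    }
    terms <- annotationToList(annotation)
    study <- unique(study)
    population <- unique(population)
    nStudy <- length(study)
    nPop <- length(population)
    rows <- lapply(names(terms), function(tm) {
        withTerm <- intersect(terms[[tm]], population)
        k <- sum(study %in% withTerm)
        m <- length(withTerm)
        p <- fisherGreaterP(k, nStudy, m, nPop)
        data.frame(
            term = tm, study_with_term = k, study_size = nStudy,
            pop_with_term = m, pop_size = nPop, p = p,
            stringsAsFactors = FALSE
        )
    })
    out <- do.call(rbind, rows)
    out$q <- stats::p.adjust(out$p, method = "BH")
    out$significant <- out$q < alpha
    out <- out[order(out$p, out$term), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' One-sided Fisher p-value for over-representation
#'
#' Upper hypergeometric tail `P(X >= k)` for `k` study genes with the term,
#' study size `s`, `m` population genes with the term, population size `N`
#' (equal to `fisher.test(alternative = "greater")` on the 2x2 table).
#' Vectorised over all arguments.
#'
#' @param k,s,m,N Table counts as above.
#' @return Numeric p-value(s).
#' @export
fisherGreaterP <- function(k, s, m, N) {
    stats::phyper(k - 1, m, N - m, s, lower.tail = FALSE)
}

annotationToList <- function(annotation) {
    if (is.data.frame(annotation)) {
        split(annotation$gene, annotation$term)
    } else {
        annotation
    }
}

#' Term frequencies per duplication mode vs the whole genome
#'
#' For each term and each mode, the proportion of that mode's genes carrying
#' the term, alongside the whole-genome proportion, plus the top-`k` terms
#' per mode by frequency.
#'
#' @param mode_gene_sets Named list `mode -> character vector of gene ids`.
#' @param annotation Term annotation (list or `data.frame`, see
#'   [fisherEnrichment()]).
#' @param all_genes Character vector of all genes (the genome baseline).
#' @param top_k Rows of the per-mode top table (default 10).
#' @return List with `proportions` (`data.frame`: term, one column per mode,
#'   `genome`) and `top` (`data.frame`: mode, term, proportion, rank).
#' @export
termFrequencyComparison <- function(mode_gene_sets, annotation, all_genes,
                                    top_k = 10L) {
    terms <- annotationToList(annotation)
    prop <- function(genes) {
        vapply(
            terms,
            function(tg) {
                if (!length(genes)) 0 else mean(genes %in% tg)
            },
            numeric(1)
        )
    }
    cols <- lapply(mode_gene_sets, prop)
    props <- data.frame(
        term = names(terms), cols, genome = prop(all_genes),
        check.names = FALSE, stringsAsFactors = FALSE
    )
    rownames(props) <- NULL
    top <- do.call(rbind, lapply(names(mode_gene_sets), function(m) {
        v <- sort(props[[m]], decreasing = TRUE)
        ord <- order(-props[[m]], props$term)
        k <- min(top_k, nrow(props))
        data.frame(
            mode = m, term = props$term[ord[seq_len(k)]],
            proportion = props[[m]][ord[seq_len(k)]],
            rank = seq_len(k), stringsAsFactors = FALSE
        )
    }))
    list(proportions = props, top = top)
}

#' Assign genes to families by homology search hits
#'
#' A gene joins every family whose query protein hits it at an E-value at or
#' below the cutoff; genes joining several families are flagged.
#'
#' @param query_hits `data.frame` of family-query-vs-focal hits (`query` =
#'   family id, `subject` = gene id, `evalue`).
#' @param evalue_max E-value cutoff (default 1e-10).
#' @return List with `families` (named list `family -> gene set`) and
#'   `multi_family_genes` (character).
#' @export
assignFamilyMembers <- function(query_hits, evalue_max = 1e-10) {
    keep <- query_hits[query_hits$evalue <= evalue_max, , drop = FALSE]
    fams <- lapply(
        split(keep$subject, keep$query),
        function(g) sort(unique(g))
    )
    counts <- table(unlist(fams))
    list(
        families = fams,
        multi_family_genes = sort(names(counts)[counts > 1L])
    )
}

#' Per-family composition of duplication modes
#'
#' Histogram of gene-level duplication modes within each family; per-family
#' counts sum to family size (singletons tallied in their own column).
#'
#' @param families Named list `family -> gene set`.
#' @param gene_modes Named vector from [finalizeGeneModes()].
#' @return `data.frame`: family, family_size, one count column per mode
#'   (including SINGLETON).
#' @export
familyModeComposition <- function(families, gene_modes) {
    lv <- modeLevels()
    rows <- lapply(names(families), function(f) {
        g <- families[[f]]
        m <- gene_modes[g]
        m[is.na(m)] <- "SINGLETON"
        tb <- table(factor(m, levels = lv))
        cbind(
            data.frame(
                family = f, family_size = length(g),
                stringsAsFactors = FALSE
            ),
            as.data.frame(t(as.matrix(tb)))
        )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
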