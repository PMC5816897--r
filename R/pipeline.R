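# End-to-end orchestration: simulate (optional) -> homology filter ->
# collinearity -> mode classification -> Ka/Ks -> divergence -> conversion ->
# enrichment -> JSON run report.

pipelineDefaults <- function() {
    list(
        out_dir = NULL,
        seed = 1L,
        evalue_max = 1e-5,
        top_n = 5L,
        min_block_size = 5L,
        max_gap = 25L,
        proximal_rank = 20L,
        parent_exon_min = 3L,
        tpm_threshold = "auto",
        r_cutoff = "auto",
        sls_cutoff = 0.60,
        motif_min_len = 16L,
        n_random_pairs = 2000L,
        ks_recent = c(0.15, 0.25),
        ks_ancient = c(1.2, 1.5),
        ks_cap = 5,
        n_bootstrap = 1000L,
        support_min = 0.95,
        density_window_bp = 200000L,
        density_step_bp = 100000L,
        outgroup_ks = 0.3,
        n_decoys = 0L
    )
}

#' Run the full duplication-mode pipeline
#'
#' Executes every stage on either a simulated genome (give `simulate` as a
#' list of [simulationConfig()] arguments) or on files on disk (give the
#' `paths` entries below), writes all result tables plus a JSON run report
#' recording every parameter, seed, count and data-derived cutoff used, and
#' returns the report.  Fully deterministic under the configured seeds.
#'
#' @param config A list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{simulate}{list of arguments to [simulationConfig()]; when
#'       present the pipeline simulates its inputs and writes them under
#'       `out_dir/sim/` before reading them back through the parsers.}
#'     \item{paths}{alternatively, named paths: `gff3`, `m8`, `cds_fasta`,
#'       `genome_fasta`, `outgroup_gff3`, `outgroup_m8`, `outgroup_cds_fasta`,
#'       `tpm_tsv`, `intergenic_tsv`, `ortholog_map_tsv`, and optionally
#'       `promoters_fasta`, `annotation_tsv` (gene-term table).}
#'     \item{out_dir}{output directory (required).}
#'     \item{params}{overrides of the pipeline defaults: `evalue_max`,
#'       `top_n`, `min_block_size`, `max_gap`, `proximal_rank`,
#'       `parent_exon_min`, `tpm_threshold` (number or "auto"), `r_cutoff`
#'       (number or "auto"), `sls_cutoff` (number or "auto"),
#'       `motif_min_len`, `n_random_pairs`, `ks_recent`, `ks_ancient`,
#'       `ks_cap`, `n_bootstrap`, `support_min`, `density_window_bp`,
#'       `density_step_bp`, `outgroup_ks`, `n_decoys`, `seed`.}
#'   }
#' @return The run report (list), invisibly; also written to
#'   `out_dir/report.json`.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) {
        config <- yaml::read_yaml(config)
    }
    if (is.null(config$out_dir)) {
        stop("config field missing: out_dir")
    }
    par <- utils::modifyList(pipelineDefaults(), config$params %||% list())
    outDir <- config$out_dir
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    report <- list(parameters = par, stages = list())
    truth <- NULL

    if (!is.null(config$simulate)) {
        simCfg <- do.call(simulationConfig, config$simulate)
        sim <- simulateDuplicatome(
            simCfg,
            ortholog_ks = par$outgroup_ks, n_decoys = par$n_decoys
        )
        simDir <- file.path(outDir, "sim")
        writeSimulation(sim, simDir)
        truth <- sim$truth
        config$paths <- list(
            gff3 = file.path(simDir, "focal.gff3"),
            m8 = file.path(simDir, "focal_selfhits.m8"),
            cds_fasta = file.path(simDir, "focal_cds.fa"),
            genome_fasta = file.path(simDir, "focal_genome.fa"),
            outgroup_gff3 = file.path(simDir, "outgroup.gff3"),
            outgroup_m8 = file.path(simDir, "focal_vs_outgroup.m8"),
            outgroup_cds_fasta = file.path(simDir, "outgroup_cds.fa"),
            tpm_tsv = file.path(simDir, "tpm.tsv"),
            intergenic_tsv = file.path(simDir, "intergenic_tpm.tsv"),
            ortholog_map_tsv = file.path(simDir, "ortholog_map.tsv"),
            promoters_fasta = file.path(simDir, "focal_promoters.fa")
        )
        report$stages$simulate <- list(
            seed = simCfg@seed,
            n_genes = length(sim$annotation),
            n_truth_pairs = nrow(truePairs(truth))
        )
    }
    paths <- config$paths
    need <- c(
        "gff3", "m8", "cds_fasta", "outgroup_gff3", "outgroup_m8",
        "tpm_tsv", "ortholog_map_tsv"
    )
    missing <- setdiff(need, names(paths))
    if (length(missing)) {
        stop("config paths missing: ", paste(missing, collapse = ", "))
    }

    # --- inputs -------------------------------------------------------------
    annot <- assignRanks(readAnnotation(paths$gff3))
    outAnnot <- assignRanks(readAnnotation(paths$outgroup_gff3))
    hits <- readHomology(paths$m8, par$evalue_max, par$top_n)
    outHits <- readHomology(paths$outgroup_m8, par$evalue_max, par$top_n)
    cds <- Biostrings::readDNAStringSet(paths$cds_fasta)
    names(cds) <- sub("\\s.*$", "", names(cds))
    tpmDf <- readTsv(paths$tpm_tsv)
    tpm <- as.matrix(tpmDf[, -1, drop = FALSE])
    rownames(tpm) <- tpmDf[[1]]
    orthoMap <- readTsv(paths$ortholog_map_tsv)
    report$stages$inputs <- list(
        n_genes = length(annot), n_hits = nrow(hits),
        n_outgroup_genes = length(outAnnot)
    )

    # --- collinearity and classification ------------------------------------
    blockset <- detectBlocks(hits, annot,
        min_block_size = par$min_block_size, max_gap = par$max_gap
    )
    outBlocks <- detectBlocks(outHits, annot, outAnnot,
        min_block_size = par$min_block_size, max_gap = par$max_gap
    )
    ancestral <- identifyAncestralLoci(outBlocks)
    cls <- classifyDuplicates(
        hits, annot, blockset, ancestral,
        proximal_rank_max = par$proximal_rank,
        parent_exon_min = par$parent_exon_min
    )
    pairs <- cls$pairs
    geneModes <- cls$gene_modes
    report$stages$classification <- list(
        n_blocks = length(blockset),
        n_ancestral = length(ancestral),
        pair_counts = as.list(table(pairs$mode)),
        gene_mode_counts = as.list(table(geneModes)),
        n_removed_single_exon = nrow(cls$removed),
        proximal_definition = sprintf(
            "same chromosome, 1 < rank difference < %d", par$proximal_rank
        )
    )

    # --- Ka/Ks, Ks windows, mixture ----------------------------------------
    pairs <- kaksForPairs(pairs, cds)
    blockset <- blockMeanKs(blockset, pairs)
    recent <- selectBlocksByKs(blockset, par$ks_recent[1], par$ks_recent[2])
    ancient <- selectBlocksByKs(blockset, par$ks_ancient[1], par$ks_ancient[2])
    ksUsable <- pairs$ks[is.finite(pairs$ks) & pairs$ks > 0 &
        pairs$ks <= par$ks_cap]
    mix <- if (length(ksUsable) >= 20L) {
        fitKsMixture(ksUsable, seed = deriveSeed(par$seed, 11L),
            ks_cap = par$ks_cap)
    }
    report$stages$kaks <- list(
        n_pairs_with_ks = sum(is.finite(pairs$ks)),
        n_saturated = sum(pairs$saturated, na.rm = TRUE),
        selection_counts = as.list(table(pairs$selection)),
        recent_wgd_pairs = nrow(recent),
        ancient_wgd_pairs = nrow(ancient),
        ks_mixture = if (!is.null(mix)) {
            list(
                medians = componentMedians(mix), weights = mix@weights,
                loglik = mix@loglik
            )
        }
    )

    # --- expression divergence ----------------------------------------------
    tpmThreshold <- par$tpm_threshold
    if (identical(tpmThreshold, "auto")) {
        tpmThreshold <- if (!is.null(paths$intergenic_tsv)) {
            interDf <- readTsv(paths$intergenic_tsv)
            inter <- as.matrix(interDf[, -1, drop = FALSE])
            expressionThreshold(inter)
        } else {
            0.715 # background threshold when no intergenic data are given
        }
    }
    expressed <- filterExpressedPairs(pairs, tpm, tpmThreshold)
    rCutoff <- par$r_cutoff
    if (identical(rCutoff, "auto")) {
        rCutoff <- randomPairCutoff(
            rownames(tpm), tpm, "pearson_r",
            n = par$n_random_pairs, seed = deriveSeed(par$seed, 12L),
            exclude_pairs = pairs
        )
    }
    exprDiv <- expressionDivergence(expressed, tpm, rCutoff)
    names(exprDiv)[names(exprDiv) == "diverged"] <- "expr_diverged"
    pairs <- merge(
        pairs,
        exprDiv[, c("gene_a", "gene_b", "r", "expr_diverged")],
        by = c("gene_a", "gene_b"), all.x = TRUE, sort = FALSE
    )
    report$stages$expression <- list(
        tpm_threshold = tpmThreshold,
        n_pairs_expressed = nrow(expressed),
        r_cutoff = rCutoff,
        frac_diverged = if (nrow(exprDiv)) {
            mean(exprDiv$expr_diverged, na.rm = TRUE)
        } else {
            NA
        }
    )

    # --- promoter divergence ------------------------------------------------
    promoters <- if (!is.null(paths$promoters_fasta)) {
        Biostrings::readDNAStringSet(paths$promoters_fasta)
    } else if (!is.null(paths$genome_fasta)) {
        genome <- Biostrings::readDNAStringSet(paths$genome_fasta)
        names(genome) <- sub("\\s.*$", "", names(genome))
        extractPromoters(annot, genome)
    }
    if (!is.null(promoters)) {
        names(promoters) <- sub("\\s.*$", "", names(promoters))
        slsCutoff <- par$sls_cutoff
        if (identical(slsCutoff, "auto")) {
            slsCutoff <- randomPairCutoff(
                names(promoters), promoters, "s_ls",
                n = par$n_random_pairs, seed = deriveSeed(par$seed, 13L),
                exclude_pairs = pairs, min_len = par$motif_min_len
            )
        }
        promDiv <- promoterDivergence(pairs[, c("gene_a", "gene_b")],
            promoters,
            cutoff = slsCutoff, min_len = par$motif_min_len
        )
        names(promDiv)[names(promDiv) == "diverged"] <- "prom_diverged"
        pairs <- merge(
            pairs,
            promDiv[, c("gene_a", "gene_b", "s_ls", "d_sm", "prom_diverged")],
            by = c("gene_a", "gene_b"), all.x = TRUE, sort = FALSE
        )
        report$stages$promoter <- list(
            sls_cutoff = slsCutoff,
            frac_diverged = mean(promDiv$prom_diverged, na.rm = TRUE)
        )
    }

    # --- divergence summary -------------------------------------------------
    summary <- divergenceSummary(
        pairs,
        recent_keys = pairKey(recent$gene_a, recent$gene_b),
        ancient_keys = pairKey(ancient$gene_a, ancient$gene_b)
    )
    report$stages$divergence_summary <- list(
        per_mode = summary$per_mode,
        wgd_comparison = summary$wgd_comparison
    )

    # --- gene conversion ----------------------------------------------------
    if (!is.null(paths$outgroup_cds_fasta)) {
        ocds <- Biostrings::readDNAStringSet(paths$outgroup_cds_fasta)
        names(ocds) <- sub("\\s.*$", "", names(ocds))
        qb <- buildQuartets(pairs, orthoMap)
        conv <- conversionScan(qb$quartets, cds, ocds,
            n_bootstrap = par$n_bootstrap, support_min = par$support_min,
            seed = deriveSeed(par$seed, 14L)
        )
        report$stages$conversion <- list(
            n_quartets = nrow(conv), n_excluded = qb$n_excluded,
            n_converted = sum(conv$converted, na.rm = TRUE),
            converted_by_mode = if (nrow(conv)) {
                as.list(table(conv$mode[which(conv$converted)]))
            } else {
                list()
            }
        )
        writeTsv(conv, file.path(outDir, "conversion.tsv"))
        convKeys <- pairKey(
            conv$gene_a[which(conv$converted)],
            conv$gene_b[which(conv$converted)]
        )
        pairs$converted <- pairKey(pairs$gene_a, pairs$gene_b) %in% convKeys
    }

    # --- enrichment ---------------------------------------------------------
    if (!is.null(paths$annotation_tsv)) {
        termTab <- readTsv(paths$annotation_tsv)
        modeSets <- split(names(geneModes), geneModes)
        modeSets <- modeSets[setdiff(names(modeSets), "SINGLETON")]
        enr <- do.call(rbind, lapply(names(modeSets), function(m) {
            e <- fisherEnrichment(modeSets[[m]], names(geneModes), termTab)
            e$mode <- m
            e
        }))
        writeTsv(enr, file.path(outDir, "enrichment.tsv"))
        report$stages$enrichment <- list(
            n_terms = length(unique(termTab$term)),
            n_significant = sum(enr$significant)
        )
    }

    # --- density profile ----------------------------------------------------
    dens <- modeDensityProfile(
        geneModes, annot,
        par$density_window_bp, par$density_step_bp
    )
    writeTsv(dens$density, file.path(outDir, "mode_density.tsv"))
    writeTsv(dens$correlations, file.path(outDir, "density_correlations.tsv"))

    # --- recovery vs truth (simulation runs) --------------------------------
    if (!is.null(truth)) {
        tg <- trueGeneModes(truth)
        common <- intersect(names(tg), names(geneModes))
        report$stages$recovery <- list(
            gene_mode_accuracy = mean(geneModes[common] == tg[common]),
            per_mode_accuracy = lapply(
                split(common, tg[common]),
                function(g) mean(geneModes[g] == tg[g])
            )
        )
    }

    # --- outputs ------------------------------------------------------------
    writeTsv(pairs, file.path(outDir, "pairs.tsv"))
    writeTsv(
        data.frame(gene = names(geneModes), mode = unname(geneModes)),
        file.path(outDir, "gene_modes.tsv")
    )
    writeTsv(as.data.frame(blocks(blockset)), file.path(outDir, "blocks.tsv"))
    writeTsv(as.data.frame(anchors(blockset)), file.path(outDir, "anchors.tsv"))
    jsonlite::write_json(
        report, file.path(outDir, "report.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE
    )
    invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
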