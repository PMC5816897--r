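# Term enrichment, term-frequency comparison, family membership and
# per-family mode composition.

test_that("Fisher enrichment matches the choose()-sum oracle", {
    # the worked 2x2 table (8,2,2,8): study 10 of population 20, term 10
    pop <- sprintf("g%02d", 1:20)
    study <- pop[1:10]
    term <- pop[c(1:8, 11, 12)] # 8 in study, 2 outside
    ann <- list(T1 = term)
    res <- fisherEnrichment(study, pop, ann)
    expect_equal(res$p, oracleFisherGreaterP(8, 10, 10, 20), tolerance = 1e-12)
    # and agrees with fisher.test, the reference implementation
    ft <- stats::fisher.test(
        matrix(c(8, 2, 2, 8), 2),
        alternative = "greater"
    )
    expect_equal(res$p, ft$p.value, tolerance = 1e-9)
})

test_that("extreme and null tables behave as expected", {
    pop <- sprintf("g%02d", 1:30)
    study <- pop[1:10]
    ann <- list(
        allStudy = study, # covers all of study, none of background
        everything = pop
    )
    res <- fisherEnrichment(study, pop, ann, alpha = 0.05)
    pAll <- res$p[res$term == "allStudy"]
    expect_equal(pAll, 1 / choose(30, 10), tolerance = 1e-12)
    expect_true(res$significant[res$term == "allStudy"])
    # study == population: every p is 1
    resEq <- fisherEnrichment(pop, pop, ann)
    expect_true(all(resEq$p == 1))
    expect_error(fisherEnrichment(character(0), pop, ann), "empty")
    expect_error(fisherEnrichment(c("zz"), pop, ann), "subset")
})

test_that("BH q-values are monotone in p and never smaller than p", {
    set.seed(101)
    pop <- sprintf("g%03d", 1:60)
    study <- sample(pop, 20)
    ann <- lapply(1:25, function(i) sample(pop, sample(5:30, 1)))
    names(ann) <- sprintf("T%02d", 1:25)
    res <- fisherEnrichment(study, pop, ann)
    expect_true(all(res$q >= res$p - 1e-12))
    expect_false(is.unsorted(res$q[order(res$p)]))
})

test_that("term frequencies recover planted enrichment ratios", {
    set.seed(102)
    genes <- sprintf("g%03d", 1:600)
    modes <- stats::setNames(
        rep(c("WGD", "TD", "DSD"), each = 200), genes
    )
    # plant a term at twice the base rate among TD genes
    base <- 0.2
    hasTerm <- ifelse(modes == "TD",
        runif(600) < 2 * base, runif(600) < base
    )
    ann <- list(T1 = genes[hasTerm])
    sets <- split(genes, modes)
    tf <- termFrequencyComparison(sets, ann, genes, top_k = 1L)
    ratio <- tf$proportions$TD / mean(tf$proportions[c("WGD", "DSD")] |>
        unlist())
    expect_lt(abs(ratio - 2), 0.5)
    expect_true(all(unlist(tf$proportions[-1]) >= 0 &
        unlist(tf$proportions[-1]) <= 1))
    # genome column is the weighted average of the mode columns
    wavg <- sum(vapply(
        names(sets),
        function(m) length(sets[[m]]) * tf$proportions[[m]],
        numeric(1)
    )) / 600
    expect_equal(tf$proportions$genome, wavg, tolerance = 1e-12)
    # a term present only in TD genes is zero elsewhere
    ann2 <- list(T2 = sets$TD[1:50])
    tf2 <- termFrequencyComparison(sets, ann2, genes)
    expect_equal(tf2$proportions$WGD, 0)
    expect_gt(tf2$proportions$TD, 0)
})

test_that("family membership honours the E-value cutoff", {
    hits <- data.frame(
        query = c("famA", "famA", "famA", "famB"),
        subject = c("g1", "g2", "g3", "g2"),
        evalue = c(1e-12, 1e-8, 1e-30, 1e-15),
        stringsAsFactors = FALSE
    )
    fam <- assignFamilyMembers(hits, evalue_max = 1e-10)
    expect_setequal(fam$families$famA, c("g1", "g3")) # 1e-8 misses the cutoff
    expect_equal(fam$families$famB, "g2")
    expect_equal(fam$multi_family_genes, character(0))
    # multi-family flagging
    hits2 <- rbind(hits, data.frame(
        query = "famB", subject = "g1",
        evalue = 1e-20
    ))
    expect_equal(assignFamilyMembers(hits2)$multi_family_genes, "g1")
    # no hits under cutoff: empty family set
    expect_length(
        assignFamilyMembers(hits[hits$evalue > 1e-5, , drop = FALSE])$families,
        0L
    )
})

test_that("family mode composition conserves family sizes", {
    fams <- list(
        sorbitol_like = c("g1", "g2", "g3", "g4"),
        mixed = c("g5", "g6", "g7")
    )
    gm <- c(
        g1 = "TD", g2 = "TD", g3 = "PD", g4 = "TD",
        g5 = "WGD", g6 = "DSD", g7 = "SINGLETON"
    )
    comp <- familyModeComposition(fams, gm)
    expect_equal(comp$family_size, c(4L, 3L))
    modeCols <- modeLevels()
    expect_equal(rowSums(comp[, modeCols]), comp$family_size,
        ignore_attr = TRUE
    )
    # a family planted with TD/PD expansion shows a TD+PD majority
    expect_gt(
        comp[1, "TD"] + comp[1, "PD"],
        comp$family_size[1] / 2
    )
    # all-WGD family counts only WGD
    comp2 <- familyModeComposition(
        list(f = c("g5")), c(g5 = "WGD")
    )
    expect_equal(comp2[1, "WGD"], 1L)
    expect_equal(sum(comp2[, setdiff(modeCols, "WGD")]), 0L)
})
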