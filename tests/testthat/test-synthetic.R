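truth <- smallTruth()

test_that("generation is deterministic under a fixed seed", {
    t1 <- generateExpressionSamples(truth)
    t2 <- generateExpressionSamples(smallTruth())
    expect_identical(t1[[1]]@genes, t2[[1]]@genes)
    expect_identical(t1[[2]]@genes, t2[[2]]@genes)
    e1 <- generateEdgeTable(truth)
    e2 <- generateEdgeTable(smallTruth())
    expect_identical(e1$edges, e2$edges)
    # a different seed changes the draws
    t3 <- generateExpressionSamples(smallTruth(seed = 8L))
    expect_false(identical(t1[[1]]@genes$tpm, t3[[1]]@genes$tpm))
})

test_that("generated samples respect the TPM budget and the planted partition", {
    tabs <- generateExpressionSamples(truth)
    for (tab in tabs) {
        expect_equal(sum(tpm(tab)), 1e6, tolerance = 1e-9)
        cut <- applyExpressionCutoff(tab, 0.5)
        expect_equal(nGenes(tab) - nGenes(cut), 50L)  # subthreshold decoys
    }
    expect_equal(nGenes(applyExpressionCutoff(tabs[[1]], 0.5)), 1000L)
    expect_equal(nGenes(applyExpressionCutoff(tabs[[2]], 0.5)), 950L)
})

test_that("infeasible planted fractions are rejected", {
    expect_error(syntheticTruth(n_left = 1000, shared_fraction = 89.95),
                 "integer")
    expect_error(syntheticTruth(n_left = 100, n_right = 50,
                                shared_fraction = 89,
                                n_subthreshold = 0), "exceed")
    expect_error(new("SyntheticTruth", seed = 1L,
                     samples = list(list(), list()),
                     sharedFraction = 150, nOrthologBridges = 0L,
                     categorySizes = integer(), network = list(),
                     cutoff = 0.5), "percentage")
})

test_that("planted overlap percentages are recovered exactly", {
    dat <- generateSyntheticData(truth)
    left <- applyExpressionCutoff(dat$tables[[1]], 0.5)
    right <- applyExpressionCutoff(dat$tables[[2]], 0.5)
    res <- overlapStats(left, right, catalog = dat$catalog,
                        orthologs = dat$orthologs,
                        annot_terms = "transport activity",
                        annot_side = "right")
    expect_equal(res@pctSharedLeft, 89)
    expect_equal(res@pctSharedLeft, dat$truth$pct_shared_left)
    expect_equal(res@pctSharedRight, dat$truth$pct_shared_right)
    expect_equal(res@tpmShareNonsharedLeft,
                 dat$truth$tpm_share_nonshared_left, tolerance = 1e-12)
    expect_equal(res@tpmShareNonsharedRight,
                 dat$truth$tpm_share_nonshared_right, tolerance = 1e-12)
    expect_equal(unname(res@annotFractionNonshared["transport activity"]),
                 dat$truth$annot_fraction_transport_right)
    # planted 100%: identical universes share everything
    full <- generateSyntheticData(
        syntheticTruth(seed = 3L, n_left = 500L, n_right = 500L,
                       shared_fraction = 100, n_subthreshold = 10L,
                       n_ortholog_bridges = 20L))
    fl <- applyExpressionCutoff(full$tables[[1]], 0.5)
    fr <- applyExpressionCutoff(full$tables[[2]], 0.5)
    expect_equal(overlapStats(fl, fr,
                              orthologs = full$orthologs)@pctSharedLeft,
                 100)
})

test_that("category rules recover the planted memberships exactly", {
    dat <- generateSyntheticData(truth)
    rules <- rulesFromSources(dat$sources)
    sets <- suppressMessages(assembleCatalog(rules, dat$catalog))
    for (nm in names(dat$truth$categories))
        expect_setequal(setSymbols(sets[[nm]], dat$catalog),
                        dat$truth$categories[[nm]])
    # every decoy branch was exercised: no decoy symbol in any set
    decoys <- c("SLC25A1", "SLC25A99", "ATP5F1", "ATP6V0A1", "NMPM1",
                "NMPM2", "NMPM3", "NMPM4", "CHDEC1", "PDEX1", "HK1",
                "KDEC1", "ALP1")
    all_members <- unlist(lapply(sets, function(s)
        setSymbols(s, dat$catalog)))
    expect_length(intersect(decoys, all_members), 0)
})

test_that("planted discovery order and supercategory sums are recovered", {
    dat <- generateSyntheticData(truth)
    left <- applyExpressionCutoff(dat$tables[[1]], 0.5)
    e <- catalogEntries(dat$catalog)
    tp_ids <- e$gene_id[match(dat$truth$categories$transporters_pumps,
                              e$symbol)]
    dt <- rankGenes(left, GeneSet("transporters_pumps", tp_ids),
                    catalog = dat$catalog)
    expect_equal(discoveryRows(dt)$symbol,
                 dat$truth$transporter_order_left)

    slc_ids <- e$gene_id[match(dat$truth$pm_slc_symbols, e$symbol)]
    sm <- summarizeSupercategories(left, GeneSet("pm_slc", slc_ids))
    expect_equal(sm$supercategory, names(dat$truth$supercategory_sums))
    expect_equal(sm$accumulated_tpm,
                 unname(unlist(dat$truth$supercategory_sums)),
                 tolerance = 1e-12)
    expect_equal(sm$n_genes,
                 unname(unlist(dat$truth$supercategory_counts)))
    expect_equal(sum(sm$accumulated_tpm),
                 sum(tpm(left)[slc_ids]), tolerance = 1e-12)
})

test_that("the planted network is recovered with no distractors", {
    dat <- generateSyntheticData(truth)
    f <- tempfile(fileext = ".txt")
    utils::write.table(dat$edge_table, f, sep = " ", quote = FALSE,
                       row.names = FALSE)
    ed <- filterEvidence(loadAssociationEdges(f))
    regs <- dat$truth$categories[intersect(regulatorCategories(),
                                           names(dat$truth$categories))]
    net <- buildBipartiteNetwork(ed,
                                 dat$truth$categories$transporters_pumps,
                                 regs, score_interval = c(0.6, 1))
    got <- networkEdges(net)
    want <- dat$truth$network_edges
    want <- want[order(want$target, want$regulator), ]
    rownames(want) <- NULL
    expect_equal(got, want)
})

test_that("synthetic inputs write to disk and read back through the pipeline ops", {
    dir <- tempfile()
    dat <- writeSyntheticInputs(truth, dir)
    expect_true(file.exists(file.path(dir, "truth.json")))
    tab <- readQuantTable(dat$paths$samples[[1]], names(dat$tables)[1])
    expect_equal(nGenes(tab), nGenes(dat$tables[[1]]))
    expect_equal(unname(tpm(tab)), unname(tpm(dat$tables[[1]])),
                 tolerance = 1e-6)
    cat2 <- readGeneCatalog(dat$paths$catalog)
    expect_equal(nGenes(cat2), nGenes(dat$catalog))
    orth <- readOrthologMap(dat$paths$orthologs)
    expect_equal(nrow(orth), nrow(dat$orthologs))
    # TPM recomputed from the emitted counts/lengths matches the file TPM
    g <- tab@genes
    expect_equal(computeTpm(g$expected_count, g$effective_length), g$tpm,
                 tolerance = 1e-9)
})
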