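test_that("category sources load by family, EC prefix and symbol prefix", {
    gt <- writeTsv(data.frame(symbol = c("SLC12A2", "KCNJ13"),
                              family = c("transporters",
                                         "other ion channels")))
    expect_equal(loadCategorySource(gt, "gtopdb_family", "transporters"),
                 "SLC12A2")
    expect_warning(
        got <- loadCategorySource(gt, "gtopdb_family", "nothing"),
        "matched nothing")
    expect_length(got, 0)

    # EC selector admits exact matches and dotted sub-categories only
    ke <- writeTsv(data.frame(symbol = c("K1", "K2", "K3", "K4"),
                              ec = c("EC 2.7.11", "EC 2.7.11.22",
                                     "EC 2.7.1.1", "EC 2.7.112")))
    expect_equal(sort(loadCategorySource(ke, "kegg_ec", "EC 2.7.11")),
                 c("K1", "K2"))

    cat <- makeCatalog(c("PDE6D", "PDZD11", "PDEX", "PDE4DIP"))
    expect_equal(sort(loadCategorySource(NULL, "symbol_prefix", "PDE",
                                         catalog = cat)),
                 c("PDE4DIP", "PDE6D"))

    expect_error(loadCategorySource(gt, "mystery", "x"), "unknown source kind")
    expect_error(loadCategorySource("/nope/missing.tsv", "kegg_ec", "EC 1"),
                 "not found")
})

test_that("plasma-membrane filter implements the two-conjunct rule with exclusions", {
    cat <- makeCatalog(
        c("KEEP1", "KEEP2", "MITO", "PMONLY", "MEMONLY", "LYSO"),
        go = list(c("plasma membrane", "integral component of membrane"),
                  c("integral component of plasma membrane",
                    "transmembrane"),
                  c("plasma membrane", "integral component of membrane",
                    "mitochondrion"),
                  "plasma membrane",
                  "integral component of membrane",
                  c("plasma membrane", "transmembrane", "lysosomal")))
    got <- plasmaMembraneFilter(c("KEEP1", "KEEP2", "MITO", "PMONLY",
                                  "MEMONLY", "LYSO"), cat)
    expect_equal(sort(got), c("KEEP1", "KEEP2"))

    # exact label matching: a compound label must not trip an exclusion
    cat2 <- makeCatalog("ER", go = list(c("plasma membrane",
                                          "transmembrane",
                                          "endoplasmic reticulum")))
    expect_equal(plasmaMembraneFilter("ER", cat2), "ER")

    expect_warning(out <- plasmaMembraneFilter(c("KEEP1", "GHOST"), cat),
                   "GHOST")
    expect_equal(out, "KEEP1")
})

test_that("plasma-membrane filter never admits an exclusion-term gene", {
    set.seed(99)
    excl <- pmFilterTerms()$exclude
    pool <- c(pmFilterTerms()$pm_any, pmFilterTerms()$membrane_any,
              excl, "cytoplasm", "nucleus")
    syms <- sprintf("R%03d", 1:300)
    go <- lapply(syms, function(s)
        sample(pool, sample(1:5, 1)))
    cat <- makeCatalog(syms, go = go)
    kept <- plasmaMembraneFilter(syms, cat)
    carries_excl <- vapply(go, function(t) any(excl %in% t), logical(1))
    expect_length(intersect(kept, syms[carries_excl]), 0)
    # and every kept gene satisfies both positive conjuncts
    for (s in kept) {
        t <- go[[match(s, syms)]]
        expect_true(any(pmFilterTerms()$pm_any %in% t))
        expect_true(any(pmFilterTerms()$membrane_any %in% t))
    }
})

test_that("buildCategory applies prefix exclusions, GO filters and resolution", {
    cat <- makeCatalog(
        c("SLC12A2", "SLC25A1", "ATP5F1", "ATP6V0A1", "KIN1", "KIN2"),
        go = list(c("plasma membrane", "integral component of membrane"),
                  c("plasma membrane", "integral component of membrane"),
                  c("plasma membrane", "integral component of membrane"),
                  c("plasma membrane", "integral component of membrane"),
                  "protein kinase activity",
                  "ATP binding"))
    gt <- writeTsv(data.frame(
        symbol = c("SLC12A2", "SLC25A1", "ATP5F1", "ATP6V0A1"),
        family = "transporters"))
    rule <- CategoryRule("transporters_pumps",
        source_lists = list(list(path = gt, kind = "gtopdb_family",
                                 selector = "transporters")),
        exclude_family_prefixes = c("SLC25", "ATP5", "ATP6V"),
        apply_pm_filter = TRUE)
    gs <- buildCategory(rule, cat)
    expect_equal(members(gs), "id_SLC12A2")
    expect_true(all(!startsWith(setSymbols(gs, cat),
                                c("SLC25"))))
    expect_true(grepl("gtopdb_family",
                      paste(gs@provenance[["id_SLC12A2"]], collapse = ";")))

    ke <- writeTsv(data.frame(symbol = c("KIN1", "KIN2"),
                              ec = "EC 2.7.11.1"))
    krule <- CategoryRule("kinase",
        source_lists = list(list(path = ke, kind = "kegg_ec",
                                 selector = "EC 2.7.11")),
        require_go_any = "protein kinase activity")
    expect_equal(members(buildCategory(krule, cat)), "id_KIN1")

    # empty sources give an empty set; missing file is a config error
    expect_length(members(buildCategory(CategoryRule("empty"), cat)), 0)
    badrule <- CategoryRule("bad",
        source_lists = list(list(path = "/nope.tsv", kind = "kegg_ec",
                                 selector = "EC 1")))
    expect_error(buildCategory(badrule, cat), "not found")
})

test_that("symbol resolution falls back to aliases, case-insensitively", {
    cat <- GeneCatalog(c("g1", "g2"), c("NKCC1", "AQP1"),
                       alias = c("SLC12A2|BSC2", NA),
                       go_terms = list())
    gt <- writeTsv(data.frame(symbol = c("slc12a2", "aqp1", "GHOST"),
                              family = "transporters"))
    rule <- CategoryRule("t", source_lists = list(
        list(path = gt, kind = "gtopdb_family", selector = "transporters")))
    expect_warning(gs <- buildCategory(rule, cat), "GHOST")
    expect_setequal(members(gs), c("g1", "g2"))
    expect_equal(attr(gs, "unresolved"), "GHOST")
})

test_that("buildCategory is deterministic", {
    dat <- generateAnnotationSources(smallTruth())
    rules <- rulesFromSources(dat$sources)
    a <- buildCategory(rules$transporters_pumps, dat$catalog)
    b <- buildCategory(rules$transporters_pumps, dat$catalog)
    expect_identical(members(a), members(b))
    expect_identical(a@provenance, b@provenance)
})

test_that("assembleCatalog returns every category plus the regulator union", {
    dat <- generateAnnotationSources(smallTruth())
    rules <- rulesFromSources(dat$sources)
    sets <- suppressMessages(assembleCatalog(rules, dat$catalog))
    expect_setequal(names(sets),
                    c("transporters_pumps", "channels",
                      regulatorCategories(), "regulators"))
    reg_union <- sort(unique(unlist(lapply(sets[regulatorCategories()],
                                           members))))
    expect_equal(sort(members(sets$regulators)), reg_union)

    # a declared subset works too
    sub <- suppressMessages(
        assembleCatalog(rules[c("transporters_pumps", "channels")],
                        dat$catalog))
    expect_setequal(names(sub), c("transporters_pumps", "channels"))
})
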