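test_that("gene matching by symbol and ortholog bridges", {
    a <- makeTable(1:3, c(1, 1, 1), "a", symbols = c("A", "B", "C"))
    b <- makeTable(4:6, c(1, 1, 1), "b", symbols = c("B", "C", "D"))
    m <- matchGenes(a, b)
    expect_equal(m$shared_left, c("2", "3"))
    expect_equal(m$left_only, "1")
    expect_equal(m$right_only, "6")

    # ortholog bridge
    l <- makeTable("x", 1, "l", symbols = "A")
    r <- makeTable("y", 1, "r", symbols = "A2")
    orth <- data.frame(left = "A", right = "A2")
    m2 <- matchGenes(l, r, orth)
    expect_length(m2$shared_left, 1)
    expect_length(m2$shared_right, 1)

    # many-to-many: per-side "has a partner" counting
    l3 <- makeTable(c("1", "2"), c(1, 1), "l", symbols = c("A", "B"))
    r3 <- makeTable("9", 1, "r", symbols = "B2")
    orth3 <- data.frame(left = c("A", "B"), right = c("B2", "B2"))
    m3 <- matchGenes(l3, r3, orth3)
    expect_length(m3$shared_left, 2)
    expect_length(m3$right_only, 0)
})

test_that("overlap statistics match hand arithmetic", {
    a <- makeTable(c("1", "2"), c(90, 10), "a", symbols = c("A", "B"))
    b <- makeTable("3", 1, "b", symbols = "A")
    res <- overlapStats(a, b)
    expect_equal(res@pctSharedLeft, 50.0)
    expect_equal(res@tpmShareNonsharedLeft, 10.0)
    expect_equal(res@tpmShareNonsharedRight, 0.0)
    expect_equal(res@nSharedRight, 1)

    ident <- overlapStats(a, a)
    expect_equal(ident@pctSharedLeft, 100)
    expect_equal(ident@pctSharedRight, 100)
    expect_equal(ident@tpmShareNonsharedLeft, 0)
})

test_that("annotation fractions are computed over the designated side's non-shared genes", {
    a <- makeTable("1", 1, "a", symbols = "A")
    b <- makeTable(c("2", "3", "4"), c(1, 1, 1), "b",
                   symbols = c("A", "X", "Y"))
    cat <- GeneCatalog(c("2", "3", "4"), c("A", "X", "Y"),
                       go_terms = list(character(), "transport activity",
                                       character()))
    res <- overlapStats(a, b, catalog = cat,
                        annot_terms = "transport activity",
                        annot_side = "right")
    expect_equal(unname(res@annotFractionNonshared["transport activity"]),
                 50)
})

test_that("overlap is symmetric, monotone and restriction-consistent", {
    set.seed(21)
    pool <- sprintf("S%03d", 1:80)
    for (i in 1:10) {
        ls <- sample(pool, 40); rs <- sample(pool, 35)
        a <- makeTable(ls, stats::rlnorm(40, 1, 1), "a", symbols = ls)
        b <- makeTable(rs, stats::rlnorm(35, 1, 1), "b", symbols = rs)
        ab <- overlapStats(a, b); ba <- overlapStats(b, a)
        expect_equal(ab@nSharedLeft, ba@nSharedRight)
        expect_equal(ab@nSharedRight, ba@nSharedLeft)

        # adding a gene to both sides never decreases sharing
        newsym <- "ZZZ1"
        a2 <- makeTable(c(ls, newsym), c(tpm(a), 1), "a",
                        symbols = c(ls, newsym))
        b2 <- makeTable(c(rs, newsym), c(tpm(b), 1), "b",
                        symbols = c(rs, newsym))
        expect_gte(overlapStats(a2, b2)@nSharedLeft, ab@nSharedLeft)

        # restriction to a gene set == overlap of pre-restricted tables
        keep <- sample(pool, 30)
        gs <- GeneSet("sub", keep)
        r1 <- overlapStats(a, b, restrict = gs)
        a_r <- makeTable(intersect(ls, keep),
                         tpm(a)[intersect(ls, keep)], "a",
                         symbols = intersect(ls, keep))
        b_r <- makeTable(intersect(rs, keep),
                         tpm(b)[intersect(rs, keep)], "b",
                         symbols = intersect(rs, keep))
        r2 <- overlapStats(a_r, b_r)
        expect_equal(r1@nSharedLeft, r2@nSharedLeft)
        expect_equal(r1@tpmShareNonsharedLeft, r2@tpmShareNonsharedLeft)
    }
})

test_that("degenerate restriction yields an explicit marker", {
    a <- makeTable("1", 1, "a", symbols = "A")
    res <- overlapStats(a, a, restrict = GeneSet("none", "QQQ"))
    expect_true(res@degenerate)
    expect_true(is.na(res@pctSharedLeft))
    expect_error(renderOverlapReport(res), "degenerate")
})

test_that("overlap reports render Venn counts and rounded percentages", {
    a <- makeTable(sprintf("g%03d", 1:100), rep(1, 100), "a")
    shared <- sprintf("g%03d", 1:97)
    b <- makeTable(c(shared, "h1", "h2", "h3"), rep(1, 100), "b")
    rep <- renderOverlapReport(overlapStats(a, b))
    expect_equal(unname(rep$counts),
                 c(3, 97, 3))
    expect_equal(unname(rep$display_pct["left"]), "97%")

    # rounding is half away from zero: 89.6 -> 90%, and 0 stays disjoint
    a2 <- makeTable(sprintf("x%03d", 1:1000), rep(1, 1000), "a")
    b2 <- makeTable(sprintf("x%03d", 1:896), rep(1, 896), "b")
    rep2 <- renderOverlapReport(overlapStats(a2, b2))
    expect_equal(unname(rep2$display_pct["left"]), "90%")
    expect_equal(unname(rep2$display_pct_1dp["left"]), "89.6%")
    disj <- renderOverlapReport(overlapStats(
        makeTable("1", 1, "a", symbols = "AA"),
        makeTable("2", 1, "b", symbols = "BB")))
    expect_true(disj$disjoint)
    expect_equal(unname(disj$display_pct["left"]), "0%")
})
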