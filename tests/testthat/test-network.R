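edgeFile <- function(df) {
    p <- tempfile(fileext = ".txt")
    utils::write.table(df, p, sep = " ", quote = FALSE, row.names = FALSE)
    p
}

test_that("edge loading normalizes scores, collapses duplicates, drops self-edges", {
    f <- edgeFile(data.frame(protein1 = c("t1", "A", "B", "A"),
                             protein2 = c("r1", "B", "A", "A"),
                             experiments = c(400, 0, 100, 10),
                             databases = c(0, 300, 0, 0),
                             combined_score = c(650, 700, 900, 900)))
    ed <- loadAssociationEdges(f)
    expect_equal(nrow(ed), 2L)          # A-A dropped, A-B/B-A collapsed
    ab <- ed[ed$protein_a %in% c("A", "B") | ed$protein_b %in% c("A", "B"), ]
    expect_equal(ab$combined_score, 0.9)
    expect_equal(ab$experiments, 0.1)   # channels travel with the max row
    t1 <- ed[ed$protein_a == "T1" | ed$protein_b == "T1", ]
    expect_equal(t1$combined_score, 0.65)
    expect_equal(t1$experiments, 0.4)

    nosc <- edgeFile(data.frame(protein1 = "a", protein2 = "b", x = 1))
    expect_error(loadAssociationEdges(nosc), "combined_score")
})

test_that("evidence filtering keeps database- or experiment-supported edges", {
    ed <- data.frame(protein_a = c("A", "B", "C"),
                     protein_b = c("X", "Y", "Z"),
                     combined_score = c(0.9, 0.9, 0.9),
                     experiments = c(0.4, 0, 0),
                     databases = c(0, 0.2, 0),
                     textmining = c(0, 0, 0.9))
    kept <- filterEvidence(ed)
    expect_equal(kept$protein_a, c("A", "B"))
    expect_equal(nrow(filterEvidence(ed[0, , drop = FALSE])), 0L)
    expect_error(filterEvidence(ed[, 1:3]), "experiments")
})

test_that("bipartite construction applies the three rules", {
    ed <- data.frame(protein_a = c("T1", "R1", "T1"),
                     protein_b = c("R1", "R2", "R2"),
                     combined_score = c(0.65, 0.9, 0.5),
                     experiments = c(0.4, 0, 0),
                     databases = c(0, 0.5, 0.5))
    ed <- filterEvidence(ed)
    net <- buildBipartiteNetwork(ed, "T1",
                                 list(kinase = c("R1", "R2")),
                                 score_interval = c(0.6, 1))
    expect_equal(nrow(networkEdges(net)), 1L)
    expect_equal(networkEdges(net)$target, "T1")
    expect_equal(networkEdges(net)$regulator, "R1")
    expect_equal(nrow(networkNodes(net)), 2L)   # isolated R2 pruned

    empty <- buildBipartiteNetwork(ed, "T1", list(kinase = c("R1", "R2")),
                                   score_interval = c(0.7, 1))
    expect_equal(nrow(networkEdges(empty)), 0L)

    # target-target edges excluded by default, retained under the flag
    tt <- data.frame(protein_a = "T1", protein_b = "T2",
                     combined_score = 0.8, experiments = 0.5,
                     databases = 0)
    net_tt <- buildBipartiteNetwork(tt, c("T1", "T2"), list(kinase = "R9"))
    expect_equal(nrow(networkEdges(net_tt)), 0L)
    net_tt2 <- buildBipartiteNetwork(tt, c("T1", "T2"),
                                     list(kinase = "R9"),
                                     keep_target_target = TRUE)
    expect_equal(nrow(networkEdges(net_tt2)), 1L)
    expect_true(all(networkNodes(net_tt2)$role == "target"))

    # overlap between targets and regulators: treated as target, warned.
    # T1-R1 becomes target-target (dropped); R1-R2 is now target-regulator
    expect_warning(
        ov <- buildBipartiteNetwork(ed, c("T1", "R1"),
                                    list(kinase = c("R1", "R2"))),
        "treated as targets")
    expect_equal(networkEdges(ov)$target, "R1")
    expect_equal(networkEdges(ov)$regulator, "R2")
})

test_that("regulator class uses the documented precedence order", {
    ed <- data.frame(protein_a = "T1", protein_b = "R1",
                     combined_score = 0.8, experiments = 0.5,
                     databases = 0)
    net <- buildBipartiteNetwork(ed, "T1",
        list(gpcr = "R1", kinase = "R1"))
    nd <- networkNodes(net)
    expect_equal(nd$regulator_class[nd$role == "regulator"], "gpcr")
})

test_that("constructed network equals the brute-force oracle on random graphs", {
    set.seed(77)
    for (i in 1:8) {
        tg <- sprintf("T%02d", 1:sample(5:30, 1))
        rg <- sprintf("R%02d", 1:sample(5:40, 1))
        other <- sprintf("X%02d", 1:10)
        all_syms <- c(tg, rg, other)
        n_e <- sample(50:200, 1)
        a <- sample(all_syms, n_e, replace = TRUE)
        b <- sample(all_syms, n_e, replace = TRUE)
        keep <- a != b
        a <- a[keep]; b <- b[keep]
        key <- ifelse(a < b, paste(a, b), paste(b, a))
        first <- !duplicated(key)
        a <- a[first]; b <- b[first]
        ed <- data.frame(protein_a = a, protein_b = b,
                         combined_score = round(stats::runif(length(a)),
                                                3),
                         experiments = sample(c(0, 0.4), length(a),
                                              replace = TRUE),
                         databases = sample(c(0, 0.3), length(a),
                                            replace = TRUE),
                         stringsAsFactors = FALSE)
        iv <- c(0.6, 1)
        net <- buildBipartiteNetwork(filterEvidence(ed), tg,
                                     list(kinase = rg),
                                     score_interval = iv)
        # independent brute force: three rules applied per edge
        oracle <- character()
        for (k in seq_len(nrow(ed))) {
            e <- ed[k, ]
            ev_ok <- e$experiments > 0 || e$databases > 0
            sc_ok <- e$combined_score >= iv[1] & e$combined_score <= iv[2]
            bip <- (e$protein_a %in% tg && e$protein_b %in% rg) ||
                   (e$protein_b %in% tg && e$protein_a %in% rg)
            if (ev_ok && sc_ok && bip) {
                t <- if (e$protein_a %in% tg) e$protein_a else e$protein_b
                r <- if (e$protein_a %in% tg) e$protein_b else e$protein_a
                oracle <- c(oracle, paste(t, r, e$combined_score))
            }
        }
        got <- with(networkEdges(net),
                    paste(target, regulator, combined_score))
        expect_setequal(got, oracle)
        # bipartiteness holds on the constructed network
        nd <- networkNodes(net)
        role <- stats::setNames(nd$role, nd$symbol)
        expect_true(all(role[networkEdges(net)$target] == "target"))
        expect_true(all(role[networkEdges(net)$regulator] == "regulator"))
    }
})

test_that("shrinking the score interval never adds edges", {
    set.seed(13)
    tg <- sprintf("T%d", 1:10); rg <- sprintf("R%d", 1:10)
    ed <- data.frame(protein_a = sample(tg, 60, TRUE),
                     protein_b = sample(rg, 60, TRUE),
                     combined_score = stats::runif(60),
                     experiments = 0.5, databases = 0)
    wide <- buildBipartiteNetwork(ed, tg, list(kinase = rg),
                                  score_interval = c(0.5, 1))
    narrow <- buildBipartiteNetwork(ed, tg, list(kinase = rg),
                                    score_interval = c(0.7, 0.9))
    wk <- with(networkEdges(wide), paste(target, regulator))
    nk <- with(networkEdges(narrow), paste(target, regulator))
    expect_true(all(nk %in% wk))
})

test_that("node bins honor the legend boundaries", {
    ed <- data.frame(protein_a = c("T1", "T2", "T3"),
                     protein_b = c("R1", "R1", "R1"),
                     combined_score = 0.8, experiments = 0.5,
                     databases = 0)
    net <- buildBipartiteNetwork(ed, c("T1", "T2", "T3"),
                                 list(kinase = "R1"))
    expr <- makeTable(c("t1", "t2", "t3", "r1"), c(268, 10, 50, 150),
                      symbols = c("T1", "T2", "T3", "R1"))
    b1 <- assignNodeBins(net, expr, c(10, 200))
    nd <- networkNodes(b1)
    bins <- stats::setNames(nd$size_bin, nd$symbol)
    expect_equal(unname(bins[c("T1", "T2", "T3", "R1")]),
                 c(3L, 1L, 2L, 2L))
    b2 <- assignNodeBins(net, expr, c(10, 50))
    nd2 <- networkNodes(b2)
    expect_equal(unname(stats::setNames(nd2$size_bin,
                                        nd2$symbol)["T3"]), 3L)
    expect_error(assignNodeBins(net, expr, c(50, 10)), "config error")
    # missing node -> bin 1 with a warning
    expr2 <- makeTable(c("t1", "r1"), c(5, 5), symbols = c("T1", "R1"))
    expect_warning(b3 <- assignNodeBins(net, expr2, c(10, 200)), "T2")
    nd3 <- networkNodes(b3)
    expect_equal(unname(stats::setNames(nd3$size_bin, nd3$symbol)["T2"]),
                 1L)
})

test_that("GraphML export round-trips nodes, edges and attributes", {
    ed <- data.frame(protein_a = c("T1", "T2"), protein_b = c("R1", "R2"),
                     combined_score = c(0.8, 0.72), experiments = 0.5,
                     databases = 0)
    net <- buildBipartiteNetwork(ed, c("T1", "T2"),
                                 list(gpcr = "R1", kinase = "R2"),
                                 score_interval = c(0.7, 1))
    expr <- makeTable(c("a", "b", "c", "d"), c(300, 20, 5, 80),
                      symbols = c("T1", "T2", "R1", "R2"))
    net <- assignNodeBins(net, expr, c(10, 200))
    p <- tempfile(fileext = ".graphml")
    exportNetwork(net, p, "graphml")
    back <- importNetworkGraphml(p, targets_name = "transporters_pumps",
                                 score_interval = c(0.7, 1))
    expect_equal(networkEdges(back), networkEdges(net))
    expect_equal(networkNodes(back), networkNodes(net))

    sif <- tempfile(fileext = ".sif")
    exportNetwork(net, sif, "sif")
    expect_equal(readLines(sif), c("T1 assoc R1", "T2 assoc R2"))
    expect_true(file.exists(paste0(sif, ".nodes.tsv")))

    empty <- buildBipartiteNetwork(ed[0, ], "T1", list(kinase = "R1"))
    expect_error(exportNetwork(empty, tempfile(), "sif"), "empty network")
    expect_error(exportNetwork(net, tempfile(), "dot"), "config error")
})
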