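# Self-contained synthetic inputs with planted ground truth: expression
# tables with a constructed shared fraction, annotation sources that the
# category rules recover exactly (with decoys exercising every exclusion
# branch), an ortholog map, and a STRING-style edge table with planted
# bipartite structure.

#' Describe a synthetic study with planted ground truth
#'
#' Defaults emulate the profiled study conditions: a ~13,500-gene
#' choroid-plexus-like sample compared against a second species' sample at
#' a planted 89% left-perspective sharing, heavy-tailed TPM from a
#' log-normal (meanlog 1, sdlog 2) floored at the 0.5 TPM cutoff, eight
#' planted functional categories, and a planted bipartite
#' transporter-regulator association network. The shared fraction is
#' constructed by explicit set partition, not sampled, so downstream
#' recovery is exact.
#'
#' @param seed integer RNG seed; all generation is deterministic given it.
#' @param n_left,n_right expressed (above-cutoff) gene counts per sample.
#'   `shared_fraction/100 * n_left` must be an integer.
#' @param shared_fraction planted left-perspective shared percentage.
#' @param sample_ids labels of the two samples.
#' @param meanlog,sdlog log-normal TPM parameters.
#' @param n_subthreshold decoy genes per sample planted below the cutoff.
#' @param n_ortholog_bridges shared genes linked only through the ortholog
#'   map (different symbols on each side).
#' @param category_sizes named integer vector over the eight categories.
#' @param n_network_edges planted bipartite association edges.
#' @param network_score_range closed combined-score interval for planted
#'   edges.
#' @param n_distractors distractor edges per violation type (low score,
#'   textmining-only, regulator-regulator, target-target).
#' @param cutoff TPM expression cutoff the construction guarantees
#'   against.
#' @return A [SyntheticTruth-class].
#' @export
syntheticTruth <- function(seed = 1L, n_left = 13500L, n_right = 13000L,
                           shared_fraction = 89,
                           sample_ids = c("rat_cp", "human_cp"),
                           meanlog = 1, sdlog = 2, n_subthreshold = 500L,
                           n_ortholog_bridges = 300L,
                           category_sizes = c(transporters_pumps = 40L,
                                              channels = 25L, gpcr = 20L,
                                              rtk = 15L, kinase = 25L,
                                              phosphatase = 20L, pde = 10L,
                                              cyclase = 8L),
                           n_network_edges = 60L,
                           network_score_range = c(0.6, 1),
                           n_distractors = 12L, cutoff = 0.5) {
    n_shared <- shared_fraction / 100 * n_left
    if (abs(n_shared - round(n_shared)) > 1e-9)
        stop("spec error: shared_fraction of n_left must be an integer ",
             "number of genes (got ", n_shared, ")", call. = FALSE)
    n_shared <- as.integer(round(n_shared))
    if (n_shared > n_right)
        stop("spec error: planted shared genes exceed n_right",
             call. = FALSE)
    samples <- list(
        list(sample_id = sample_ids[1], n_genes = as.integer(n_left),
             meanlog = meanlog, sdlog = sdlog,
             n_subthreshold = as.integer(n_subthreshold)),
        list(sample_id = sample_ids[2], n_genes = as.integer(n_right),
             meanlog = meanlog, sdlog = sdlog,
             n_subthreshold = as.integer(n_subthreshold)))
    new("SyntheticTruth", seed = as.integer(seed), samples = samples,
        sharedFraction = shared_fraction,
        nOrthologBridges = as.integer(n_ortholog_bridges),
        categorySizes = stats::setNames(as.integer(category_sizes),
                                        names(category_sizes)),
        network = list(n_edges = as.integer(n_network_edges),
                       score_range = network_score_range,
                       n_distractors = as.integer(n_distractors)),
        cutoff = cutoff)
}

# category member symbols, deterministic by index
.categorySymbols <- function(sizes) {
    out <- list()
    if (!is.na(n <- sizes["transporters_pumps"])) {
        n_slco <- if (n >= 8L) 2L else 0L
        n_atp <- if (n >= 12L) 4L else 0L
        n_slc <- n - n_slco - n_atp
        fams <- c(4L, 12L, 9L, 22L, 16L, 13L, 2L, 5L, 38L, 30L, 39L, 31L)
        i <- seq_len(n_slc)
        out$transporters_pumps <- c(
            sprintf("SLC%dA%d", fams[(i - 1L) %% length(fams) + 1L],
                    (i - 1L) %/% length(fams) + 1L),
            if (n_slco) sprintf("SLCO%dA1", seq_len(n_slco)),
            if (n_atp) c("ATP1A1", "ATP1B1", "ATP2B1", "ATP11A")[seq_len(n_atp)])
    }
    if (!is.na(n <- sizes["channels"])) {
        n_aqp <- min(3L, n)
        out$channels <- c(sprintf("AQP%d", seq_len(n_aqp)),
                          if (n > n_aqp) sprintf("KCN%d",
                                                 seq_len(n - n_aqp)))
    }
    if (!is.na(n <- sizes["gpcr"]))
        out$gpcr <- sprintf("GPR%d", 100L + seq_len(n))
    if (!is.na(n <- sizes["rtk"]))
        out$rtk <- sprintf("RTK%d", seq_len(n))
    if (!is.na(n <- sizes["kinase"]))
        out$kinase <- sprintf("STK%d", seq_len(n))
    if (!is.na(n <- sizes["phosphatase"]))
        out$phosphatase <- sprintf("PTP%d", seq_len(n))
    if (!is.na(n <- sizes["pde"]))
        out$pde <- sprintf("PDE%dA", seq_len(n))
    if (!is.na(n <- sizes["cyclase"]))
        out$cyclase <- sprintf("ADCY%d", seq_len(n))
    out[!vapply(out, is.null, logical(1))]
}

# deterministic universe plan: symbols, gene ids, side membership,
# category/decoy assignment, GO annotation. No randomness here.
.syntheticPlan <- function(truth) {
    stopifnot(is(truth, "SyntheticTruth"))
    sA <- truth@samples[[1]]; sB <- truth@samples[[2]]
    n_left <- sA$n_genes; n_right <- sB$n_genes
    n_shared <- as.integer(round(truth@sharedFraction / 100 * n_left))
    n_bridge <- min(truth@nOrthologBridges, n_shared)
    cats <- .categorySymbols(truth@categorySizes)
    cat_syms <- unlist(cats, use.names = FALSE)
    decoys <- list(
        prefix = c("SLC25A1", "SLC25A99", "ATP5F1", "ATP6V0A1"),
        pm_near_miss = c("NMPM1", "NMPM2", "NMPM3", "NMPM4"),
        channel_go = "CHDEC1", pde_prefix = "PDEX1",
        kinase_ec = "HK1", kinase_go = "KDEC1", phosphatase_go = "ALP1")
    decoy_syms <- unlist(decoys, use.names = FALSE)
    n_special <- length(cat_syms) + length(decoy_syms)
    n_plain <- n_shared - n_bridge - n_special
    if (n_plain < 0L)
        stop("spec error: shared pool too small for planted categories",
             call. = FALSE)
    shared_same <- c(cat_syms, decoy_syms,
                     sprintf("SHR%05d", seq_len(n_plain)))
    bridge_left <- sprintf("ORTHL%05d", seq_len(n_bridge))
    bridge_right <- sprintf("ORTHR%05d", seq_len(n_bridge))
    left_only <- sprintf("LFT%05d", seq_len(n_left - n_shared))
    right_only <- sprintf("RGT%05d", seq_len(n_right - n_shared))
    sub_left <- sprintf("SUBL%04d", seq_len(sA$n_subthreshold))
    sub_right <- sprintf("SUBR%04d", seq_len(sB$n_subthreshold))
    all_syms <- c(shared_same, bridge_left, bridge_right, left_only,
                  right_only, sub_left, sub_right)
    gene_id <- stats::setNames(sprintf("G%06d", seq_along(all_syms)),
                               all_syms)
    # GO annotation per symbol
    go <- stats::setNames(rep(list(character()), length(all_syms)),
                          all_syms)
    pm_even <- c("plasma membrane", "integral component of membrane")
    pm_odd <- c("integral component of plasma membrane", "transmembrane")
    assign_pm <- function(syms, extra = character()) {
        for (k in seq_along(syms))
            go[[syms[k]]] <<- c(if (k %% 2L == 0L) pm_even else pm_odd,
                                extra)
    }
    assign_pm(cats$transporters_pumps, "transport activity")
    assign_pm(cats$channels)
    for (s in decoys$prefix) go[[s]] <- pm_even
    go[["NMPM1"]] <- "plasma membrane"
    go[["NMPM2"]] <- c("plasma membrane", "integral component of membrane",
                       "mitochondrion")
    go[["NMPM3"]] <- "integral component of membrane"
    go[["NMPM4"]] <- c("plasma membrane", "transmembrane", "lysosomal")
    go[["CHDEC1"]] <- c("plasma membrane", "integral component of membrane",
                        "endosome membrane")
    for (s in cats$kinase) go[[s]] <- "protein kinase activity"
    go[["HK1"]] <- "protein kinase activity"
    go[["KDEC1"]] <- "ATP binding"
    for (s in cats$phosphatase)
        go[[s]] <- "phosphoprotein phosphatase activity"
    go[["ALP1"]] <- "cytoplasm"
    # a deterministic sliver of right-only genes carries 'transport
    # activity', planting the non-shared annotation fraction
    annot_right <- right_only[seq_along(right_only) %% 20L == 0L]
    for (s in annot_right) go[[s]] <- "transport activity"
    list(n_shared = n_shared, n_bridge = n_bridge, cats = cats,
         decoys = decoys, shared_same = shared_same,
         bridge_left = bridge_left, bridge_right = bridge_right,
         left_only = left_only, right_only = right_only,
         sub_left = sub_left, sub_right = sub_right,
         left_expressed = c(shared_same, bridge_left, left_only),
         right_expressed = c(shared_same, bridge_right, right_only),
         all_syms = all_syms, gene_id = gene_id, go = go,
         annot_right = annot_right)
}

# floor-at-cutoff log-normal TPM: strictly above `cutoff` for expressed
# genes, sub-threshold decoys in [0, cutoff), total exactly 1e6
.drawTpm <- function(n_expr, n_sub, meanlog, sdlog, cutoff) {
    sub <- if (n_sub) stats::runif(n_sub, 0, cutoff * 0.98) else numeric()
    y <- stats::rlnorm(n_expr, meanlog, sdlog)
    budget <- 1e6 - sum(sub) - cutoff * n_expr
    if (budget <= 0)
        stop("spec error: cutoff floor exceeds the TPM budget",
             call. = FALSE)
    list(expressed = cutoff + y * budget / sum(y), sub = sub)
}

#' Generate the synthetic expression samples
#'
#' Per sample, expressed-gene TPMs are drawn log-normal, floored at the
#' cutoff and renormalized so the table (including the planted
#' sub-threshold decoy genes) sums to exactly one million; gene universes
#' are constructed by explicit set partition so that the post-cutoff
#' pairwise shared fraction (left perspective) equals the planted
#' percentage exactly. RSEM-compatible `expected_count` and
#' `effective_length` columns are emitted consistently with the TPMs.
#'
#' @param truth a [SyntheticTruth-class].
#' @return Named list of two [ExpressionTable-class] objects.
#' @export
generateExpressionSamples <- function(truth) {
    plan <- .syntheticPlan(truth)
    sA <- truth@samples[[1]]; sB <- truth@samples[[2]]
    set.seed(truth@seed + 1L)
    mk <- function(spec, expressed, sub) {
        d <- .drawTpm(length(expressed), length(sub), spec$meanlog,
                      spec$sdlog, truth@cutoff)
        syms <- c(expressed, sub)
        tpms <- c(d$expressed, d$sub)
        ExpressionTable(spec$sample_id, unname(plan$gene_id[syms]), tpms,
                        symbol = syms, expected_count = tpms,
                        effective_length = 1000)
    }
    out <- list(mk(sA, plan$left_expressed, plan$sub_left),
                mk(sB, plan$right_expressed, plan$sub_right))
    stats::setNames(out, c(sA$sample_id, sB$sample_id))
}

#' Generate the synthetic annotation sources
#'
#' Builds the [GeneCatalog-class] covering the whole synthetic universe,
#' the category source tables (Guide-to-Pharmacology-style family list,
#' HGNC-style group list, KEGG-style EC lists) and the ortholog map, such
#' that the category rules recover the planted memberships exactly. Decoy
#' genes carry near-miss annotations (plasma membrane without a membrane
#' term, organelle exclusion terms, SLC25/ATP5/ATP6V prefixes, a PDE
#' symbol without a following digit, EC or GO near-misses) so every
#' exclusion branch is exercised.
#'
#' @param truth a [SyntheticTruth-class].
#' @return list with `catalog` ([GeneCatalog-class]), `sources` (named
#'   list of data.frames: `gtopdb`, `hgnc`, `kegg_kinase`,
#'   `kegg_phosphatase`, `kegg_cyclase`) and `orthologs` (data.frame
#'   `left`/`right`).
#' @export
generateAnnotationSources <- function(truth) {
    plan <- .syntheticPlan(truth)
    syms <- plan$all_syms
    catalog <- GeneCatalog(unname(plan$gene_id[syms]), syms,
                           alias = paste0(syms, "_alias"),
                           biotype = "protein_coding",
                           seqname = as.character((seq_along(syms) %% 20L)
                                                  + 1L),
                           go_terms = unname(plan$go[syms]))
    cats <- plan$cats; dec <- plan$decoys
    chan_fams <- c("voltage-gated ion channels", "ligand-gated ion channels",
                   "other ion channels")
    gtopdb <- rbind(
        data.frame(symbol = c(cats$transporters_pumps, dec$prefix,
                              dec$pm_near_miss),
                   family = "transporters", stringsAsFactors = FALSE),
        data.frame(symbol = c(cats$channels, dec$channel_go),
                   family = chan_fams[(seq_len(length(cats$channels) + 1L)
                                       - 1L) %% 3L + 1L],
                   stringsAsFactors = FALSE),
        data.frame(symbol = cats$gpcr, family = "gpcr",
                   stringsAsFactors = FALSE))
    hgnc <- data.frame(symbol = cats$rtk, group = "receptor tyrosine kinase",
                       stringsAsFactors = FALSE)
    kin <- cats$kinase
    kegg_kinase <- data.frame(
        symbol = c(kin, dec$kinase_ec, dec$kinase_go),
        ec = c(sprintf("EC 2.7.11.%d", (seq_along(kin) - 1L) %% 25L + 1L),
               "EC 2.7.1.1", "EC 2.7.11.1"),
        stringsAsFactors = FALSE)
    pho <- cats$phosphatase
    kegg_phosphatase <- data.frame(
        symbol = c(pho, dec$phosphatase_go),
        ec = c(sprintf("EC 3.1.3.%d", (seq_along(pho) - 1L) %% 16L + 1L),
               "EC 3.1.3.1"),
        stringsAsFactors = FALSE)
    cyc <- cats$cyclase
    kegg_cyclase <- data.frame(
        symbol = cyc,
        ec = rep_len(c("EC 4.6.1.1", "EC 4.6.1.2"), length(cyc)),
        stringsAsFactors = FALSE)
    orthologs <- data.frame(left = plan$bridge_left,
                            right = plan$bridge_right,
                            stringsAsFactors = FALSE)
    list(catalog = catalog,
         sources = list(gtopdb = gtopdb, hgnc = hgnc,
                        kegg_kinase = kegg_kinase,
                        kegg_phosphatase = kegg_phosphatase,
                        kegg_cyclase = kegg_cyclase),
         orthologs = orthologs)
}

#' Generate the synthetic STRING-style edge table
#'
#' Plants `n_edges` true bipartite transporter-regulator associations with
#' combined scores inside the planted interval and experiments/databases
#' evidence, plus distractor edges violating exactly one construction rule
#' each (score below the interval, textmining-only evidence,
#' regulator-regulator, target-target), a self-edge and reversed
#' lower-score duplicates of planted edges (exercising undirected
#' collapse). Scores are emitted on the STRING 0-1000 integer scale.
#'
#' @param truth a [SyntheticTruth-class].
#' @return list with `edges` (raw data.frame in file layout: `protein1`,
#'   `protein2`, `experiments`, `databases`, `textmining`,
#'   `combined_score`, integer 0-1000 scores) and `planted` (data.frame
#'   `target`, `regulator`, `combined_score` on the [0, 1] scale).
#' @export
generateEdgeTable <- function(truth) {
    plan <- .syntheticPlan(truth)
    set.seed(truth@seed + 2L)
    tgt <- plan$cats$transporters_pumps
    regs <- unlist(plan$cats[intersect(regulatorCategories(),
                                       names(plan$cats))],
                   use.names = FALSE)
    nw <- truth@network
    lo <- as.integer(ceiling(nw$score_range[1] * 1000))
    hi <- as.integer(floor(nw$score_range[2] * 1000))
    # planted pairs from the first halves, distractors from the rest:
    # guaranteed disjoint
    t1 <- tgt[seq_len(ceiling(length(tgt) / 2))]
    t2 <- setdiff(tgt, t1)
    r1 <- regs[seq_len(ceiling(length(regs) / 2))]
    r2 <- setdiff(regs, r1)
    grid <- expand.grid(t = t1, r = r1, stringsAsFactors = FALSE)
    n_e <- min(nw$n_edges, nrow(grid))
    pick <- sort(sample.int(nrow(grid), n_e))
    planted <- data.frame(target = grid$t[pick], regulator = grid$r[pick],
                          combined_score = sample(lo:hi, n_e,
                                                  replace = TRUE) / 1000,
                          stringsAsFactors = FALSE)
    row_of <- function(a, b, comb, exp, db, tm)
        data.frame(protein1 = a, protein2 = b, experiments = exp,
                   databases = db, textmining = tm,
                   combined_score = comb, stringsAsFactors = FALSE)
    ev_exp <- sample(c(TRUE, FALSE), n_e, replace = TRUE)
    raw <- row_of(planted$target, planted$regulator,
                  as.integer(planted$combined_score * 1000),
                  exp = ifelse(ev_exp, sample(200:900, n_e, replace = TRUE),
                               0L),
                  db = ifelse(ev_exp, 0L, sample(200:900, n_e,
                                                 replace = TRUE)),
                  tm = sample(0:500, n_e, replace = TRUE))
    nd <- nw$n_distractors
    d_pairs <- function(xs, ys, n) {
        g <- expand.grid(a = xs, b = ys, stringsAsFactors = FALSE)
        g <- g[g$a != g$b, , drop = FALSE]
        g[sort(sample.int(nrow(g), min(n, nrow(g)))), , drop = FALSE]
    }
    if (nd > 0 && length(t2) && length(r2)) {
        low <- d_pairs(t2, r2, nd)
        raw <- rbind(raw, row_of(low$a, low$b,
                                 sample(150:(lo - 1L), nrow(low),
                                        replace = TRUE),
                                 exp = sample(200:900, nrow(low),
                                              replace = TRUE),
                                 db = 0L, tm = 0L))
        txt <- d_pairs(t2, r2, nd)
        raw <- rbind(raw, row_of(txt$a, txt$b,
                                 sample(lo:hi, nrow(txt), replace = TRUE),
                                 exp = 0L, db = 0L,
                                 tm = sample(400:900, nrow(txt),
                                             replace = TRUE)))
    }
    if (nd > 0 && length(r2) > 1) {
        rr <- d_pairs(r2, r2, nd)
        raw <- rbind(raw, row_of(rr$a, rr$b,
                                 sample(lo:hi, nrow(rr), replace = TRUE),
                                 exp = sample(200:900, nrow(rr),
                                              replace = TRUE),
                                 db = 0L, tm = 0L))
    }
    if (nd > 0 && length(t2) > 1) {
        tt <- d_pairs(t2, t2, nd)
        raw <- rbind(raw, row_of(tt$a, tt$b,
                                 sample(lo:hi, nrow(tt), replace = TRUE),
                                 exp = 0L,
                                 db = sample(200:900, nrow(tt),
                                             replace = TRUE),
                                 tm = 0L))
    }
    raw <- rbind(raw, row_of(tgt[1], tgt[1], 900L, 500L, 0L, 0L))
    n_rev <- min(3L, nrow(planted))
    if (n_rev > 0) {
        rev_score <- pmax(lo, as.integer(planted$combined_score[
            seq_len(n_rev)] * 1000) - 50L)
        raw <- rbind(raw, row_of(planted$regulator[seq_len(n_rev)],
                                 planted$target[seq_len(n_rev)],
                                 rev_score,
                                 exp = 300L, db = 0L, tm = 0L))
    }
    rownames(raw) <- NULL
    list(edges = raw, planted = planted)
}

#' Generate the full synthetic data set with its truth record
#'
#' Runs all three generators under one seed and assembles the planted
#' truth manifest from the generator's own bookkeeping (never from the
#' analysis functions): shared counts and percentages, realized
#' non-shared TPM shares and annotation fractions, category memberships,
#' plasma-membrane SLC supercategory sums (under the shipped grouping),
#' the transporter discovery-table order of the left sample, and the
#' planted network edge set.
#'
#' @param truth a [SyntheticTruth-class].
#' @param grouping family -> supercategory map used for the planted
#'   supercategory sums; see [readSlcGrouping()].
#' @return list with `tables`, `catalog`, `sources`, `orthologs`,
#'   `edge_table` (raw file-layout data.frame) and `truth` (the manifest
#'   list).
#' @export
generateSyntheticData <- function(truth, grouping = readSlcGrouping()) {
    plan <- .syntheticPlan(truth)
    tables <- generateExpressionSamples(truth)
    ann <- generateAnnotationSources(truth)
    net <- generateEdgeTable(truth)
    left <- tables[[1]]; right <- tables[[2]]
    tpmL <- stats::setNames(left@genes$tpm, left@genes$symbol)
    tpmR <- stats::setNames(right@genes$tpm, right@genes$symbol)
    expL <- tpmL[plan$left_expressed]; expR <- tpmR[plan$right_expressed]
    # supercategory sums from the generator's own family assignment
    slc_syms <- plan$cats$transporters_pumps[
        startsWith(plan$cats$transporters_pumps, "SLC")]
    fam <- ifelse(startsWith(slc_syms, "SLCO"), "SLCO",
                  sub("^(SLC[0-9]+).*$", "\\1", slc_syms))
    sc <- unname(grouping[fam])
    sc[is.na(sc)] <- "ungrouped"
    sums <- tapply(unname(tpmL[slc_syms]), sc, sum)
    counts <- tapply(slc_syms, sc, length)
    ord <- order(-sums)
    disc_syms <- plan$cats$transporters_pumps
    disc_order <- disc_syms[order(-unname(tpmL[disc_syms]), disc_syms)]
    truth_rec <- list(
        seed = truth@seed,
        sample_ids = names(tables),
        n_left = length(expL), n_right = length(expR),
        n_shared = plan$n_shared,
        pct_shared_left = 100 * plan$n_shared / length(expL),
        pct_shared_right = 100 * plan$n_shared / length(expR),
        tpm_share_nonshared_left =
            100 * sum(expL[plan$left_only]) / sum(expL),
        tpm_share_nonshared_right =
            100 * sum(expR[plan$right_only]) / sum(expR),
        annot_fraction_transport_right =
            100 * length(plan$annot_right) / length(plan$right_only),
        categories = plan$cats,
        pm_slc_symbols = slc_syms,
        supercategory_sums = as.list(sums[ord]),
        supercategory_counts = as.list(counts[ord]),
        transporter_order_left = disc_order,
        network_edges = net$planted)
    list(tables = tables, catalog = ann$catalog, sources = ann$sources,
         orthologs = ann$orthologs, edge_table = net$edges,
         truth = truth_rec)
}

#' Write synthetic inputs to a directory tree
#'
#' Emits exactly the file formats the real pipeline consumes: RSEM-style
#' `<sample>.genes.results` per sample, `catalog.tsv`, the category source
#' TSVs under `sources/`, `orthologs.tsv`, a STRING-style
#' `string_edges.txt`, and `truth.json` recording the planted manifest.
#'
#' @param truth a [SyntheticTruth-class].
#' @param dir output directory (created if needed).
#' @param grouping forwarded to [generateSyntheticData()].
#' @return Invisibly, the `generateSyntheticData()` result with an added
#'   `paths` element.
#' @export
writeSyntheticInputs <- function(truth, dir,
                                 grouping = readSlcGrouping()) {
    dat <- generateSyntheticData(truth, grouping)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "sources"), showWarnings = FALSE)
    wt <- function(df, path)
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    paths <- list(samples = list())
    for (nm in names(dat$tables)) {
        g <- dat$tables[[nm]]@genes
        rsem <- data.frame(gene_id = g$gene_id,
                           "transcript_id(s)" = g$gene_id,
                           length = g$effective_length + 100,
                           effective_length = g$effective_length,
                           expected_count = g$expected_count,
                           TPM = g$tpm, check.names = FALSE,
                           stringsAsFactors = FALSE)
        p <- file.path(dir, paste0(nm, ".genes.results"))
        wt(rsem, p)
        paths$samples[[nm]] <- p
    }
    e <- dat$catalog@entries
    cat_df <- data.frame(gene_id = e$gene_id, symbol = e$symbol,
                         alias = e$alias, biotype = e$biotype,
                         seqname = e$seqname,
                         go_terms = vapply(e$go_terms, paste, "",
                                           collapse = "|"),
                         cell_type_tags = vapply(e$cell_type_tags, paste,
                                                 "", collapse = "|"),
                         stringsAsFactors = FALSE)
    paths$catalog <- file.path(dir, "catalog.tsv")
    wt(cat_df, paths$catalog)
    paths$sources <- list()
    for (nm in names(dat$sources)) {
        p <- file.path(dir, "sources", paste0(nm, ".tsv"))
        wt(dat$sources[[nm]], p)
        paths$sources[[nm]] <- p
    }
    paths$orthologs <- file.path(dir, "orthologs.tsv")
    wt(stats::setNames(dat$orthologs, c("left_symbol", "right_symbol")),
       paths$orthologs)
    paths$edges <- file.path(dir, "string_edges.txt")
    utils::write.table(dat$edge_table, paths$edges, sep = " ",
                       quote = FALSE, row.names = FALSE)
    paths$truth <- file.path(dir, "truth.json")
    jsonlite::write_json(dat$truth, paths$truth, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    dat$paths <- paths
    invisible(dat)
}
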