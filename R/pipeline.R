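# End-to-end orchestration: validated run configuration, the eight
# default category rules, and the full pipeline producing discovery
# tables, overlap reports, the SLC supercategory summary, association
# networks and a run manifest.

.KINASE_GO <- c("protein kinase activity",
                "protein serine/threonine kinase activity",
                "protein serine kinase activity",
                "protein threonine kinase activity",
                "protein tyrosine kinase activity", "map kinase activity")
.PHOSPHATASE_GO <- c("phosphoprotein phosphatase activity",
                     "protein serine/threonine phosphatase activity",
                     "protein serine phosphatase activity",
                     "protein threonine phosphatase activity",
                     "protein tyrosine phosphatase activity")

#' The eight default category rules
#'
#' Builds the standard rule set over user-supplied source files:
#' transporters and pumps (Guide-to-Pharmacology-style 'transporters'
#' family, minus the mitochondrial and vacuolar SLC25/ATP5/ATP6V
#' families, plasma-membrane filtered), water and ion channels (the three
#' ion-channel families, plasma-membrane filtered), GPCRs, receptor
#' tyrosine kinases (HGNC-style groups including ephrin receptors and the
#' ErbB family), kinases (KEGG-style EC 2.7.10.2 / 2.7.11 / 2.7.12 with
#' sub-categories, GO-filtered for protein kinase activity, with a
#' configurable manual exclusion list), phosphatases (EC 3.1.3 with
#' sub-categories, GO-filtered for protein-interacting phosphatases),
#' phosphodiesterases (symbols starting with PDE followed by a digit) and
#' cyclases (EC 4.6.1.1 and 4.6.1.2).
#'
#' @param sources named list of file paths: `gtopdb`, `hgnc`,
#'   `kegg_kinase`, `kegg_phosphatase`, `kegg_cyclase`.
#' @param kinase_exclusions manual symbol exclusion list for kinases
#'   involved solely in transcription or cell-cycle modulation
#'   (configuration, not code; default empty).
#' @return named list of eight [CategoryRule-class] objects.
#' @export
defaultCategoryRules <- function(sources, kinase_exclusions = character()) {
    need <- c("gtopdb", "hgnc", "kegg_kinase", "kegg_phosphatase",
              "kegg_cyclase")
    missing <- setdiff(need, names(sources))
    if (length(missing))
        stop("config error: missing source paths: ",
             paste(missing, collapse = ", "), call. = FALSE)
    list(
        transporters_pumps = CategoryRule("transporters_pumps",
            source_lists = list(list(path = sources$gtopdb,
                                     kind = "gtopdb_family",
                                     selector = "transporters")),
            exclude_family_prefixes = c("SLC25", "ATP5", "ATP6V"),
            apply_pm_filter = TRUE),
        channels = CategoryRule("channels",
            source_lists = list(list(path = sources$gtopdb,
                                     kind = "gtopdb_family",
                                     selector = c("voltage-gated ion channels",
                                                  "ligand-gated ion channels",
                                                  "other ion channels"))),
            apply_pm_filter = TRUE),
        gpcr = CategoryRule("gpcr",
            source_lists = list(list(path = sources$gtopdb,
                                     kind = "gtopdb_family",
                                     selector = "gpcr"))),
        rtk = CategoryRule("rtk",
            source_lists = list(list(path = sources$hgnc,
                                     kind = "hgnc_group",
                                     selector = c("receptor tyrosine kinase",
                                                  "ephrin receptors",
                                                  "erbb family")))),
        kinase = CategoryRule("kinase",
            source_lists = list(list(path = sources$kegg_kinase,
                                     kind = "kegg_ec",
                                     selector = c("EC 2.7.10.2",
                                                  "EC 2.7.12",
                                                  "EC 2.7.11"))),
            require_go_any = .KINASE_GO,
            exclude_symbols = kinase_exclusions),
        phosphatase = CategoryRule("phosphatase",
            source_lists = list(list(path = sources$kegg_phosphatase,
                                     kind = "kegg_ec",
                                     selector = "EC 3.1.3")),
            require_go_any = .PHOSPHATASE_GO),
        pde = CategoryRule("pde",
            source_lists = list(list(path = NULL, kind = "symbol_prefix",
                                     selector = "PDE"))),
        cyclase = CategoryRule("cyclase",
            source_lists = list(list(path = sources$kegg_cyclase,
                                     kind = "kegg_ec",
                                     selector = c("EC 4.6.1.1",
                                                  "EC 4.6.1.2")))))
}

#' Build / read / write a run configuration
#'
#' A run configuration names every input (sample quantification tables,
#' catalog, category sources, SLC grouping, ortholog maps, edge table),
#' the analysis parameters with their study defaults (0.5 TPM cutoff,
#' confidence intervals 0.6-1 for transporters and 0.7-1 for channels,
#' node-size bin edges 10/200 and 10/50), the comparisons to run, and the
#' output directory. It round-trips losslessly through YAML.
#'
#' @param samples named list/character of sample table paths.
#' @param catalog catalog TSV path.
#' @param sources named list of category source paths, see
#'   [defaultCategoryRules()].
#' @param edges association edge table path (optional: `NULL` skips the
#'   network stage).
#' @param out_dir output directory.
#' @param comparisons list of `list(left=, right=, orthologs=)` sample-id
#'   pairs; `orthologs` optional per comparison.
#' @param ortholog_maps named list of ortholog TSV paths referenced by
#'   comparisons.
#' @param grouping SLC grouping TSV path (`NULL`: shipped default).
#' @param cutoff TPM expression cutoff.
#' @param score_intervals named list of closed confidence intervals per
#'   target set.
#' @param bin_edges named list of node-size bin edges per target set.
#' @param top_n discovery-table truncation.
#' @param kinase_exclusions manual kinase exclusion symbols.
#' @return a validated `transportome_config` list.
#' @export
runConfig <- function(samples, catalog, sources, edges = NULL,
                      out_dir = "transportome_out", comparisons = list(),
                      ortholog_maps = list(), grouping = NULL,
                      cutoff = 0.5,
                      score_intervals = list(transporters_pumps = c(0.6, 1),
                                             channels = c(0.7, 1)),
                      bin_edges = list(transporters_pumps = c(10, 200),
                                       channels = c(10, 50)),
                      top_n = 20, kinase_exclusions = character()) {
    cfg <- list(samples = as.list(samples), catalog = catalog,
                sources = as.list(sources), edges = edges,
                out_dir = out_dir, comparisons = comparisons,
                ortholog_maps = as.list(ortholog_maps),
                grouping = grouping, cutoff = cutoff,
                score_intervals = score_intervals, bin_edges = bin_edges,
                top_n = top_n,
                kinase_exclusions = as.character(kinase_exclusions))
    class(cfg) <- "transportome_config"
    validateRunConfig(cfg)
    cfg
}

#' @rdname runConfig
#' @param config a `transportome_config` list.
#' @return `validateRunConfig`: the config, invisibly; errors describe the
#'   offending field. Validation happens before any I/O.
#' @export
validateRunConfig <- function(config) {
    err <- function(...) stop("config error: ", ..., call. = FALSE)
    if (!length(config$samples) || is.null(names(config$samples)) ||
        any(!nzchar(names(config$samples))))
        err("samples must be a non-empty named list of paths")
    if (!is.numeric(config$cutoff) || length(config$cutoff) != 1L ||
        is.na(config$cutoff) || config$cutoff < 0)
        err("cutoff must be a single non-negative number")
    for (nm in names(config$score_intervals)) {
        iv <- config$score_intervals[[nm]]
        if (length(iv) != 2L || iv[1] > iv[2] || iv[1] < 0 || iv[2] > 1)
            err("score interval for '", nm,
                "' must be a closed sub-interval of [0, 1]")
    }
    for (nm in names(config$bin_edges)) {
        be <- config$bin_edges[[nm]]
        if (length(be) != 2L || !(be[1] < be[2]))
            err("bin edges for '", nm, "' must be strictly increasing")
    }
    if (!is.numeric(config$top_n) || config$top_n < 1)
        err("top_n must be a positive integer")
    for (cmp in config$comparisons) {
        if (is.null(cmp$left) || is.null(cmp$right))
            err("each comparison needs 'left' and 'right' sample ids")
        for (side in c(cmp$left, cmp$right))
            if (!side %in% names(config$samples))
                err("comparison references unknown sample '", side, "'")
        if (!is.null(cmp$orthologs) &&
            !cmp$orthologs %in% names(config$ortholog_maps))
            err("comparison references unknown ortholog map '",
                cmp$orthologs, "'")
    }
    invisible(config)
}

#' @rdname runConfig
#' @param path YAML file path.
#' @return `readRunConfig`: the validated config; `writeRunConfig`:
#'   `path`, invisibly.
#' @export
readRunConfig <- function(path) {
    raw <- yaml::read_yaml(path)
    do.call(runConfig, raw)
}

#' @rdname runConfig
#' @export
writeRunConfig <- function(config, path) {
    yaml::write_yaml(unclass(config), path)
    invisible(path)
}

# run one stage with a labeled error boundary
.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

.logCounts <- function(log, stage, n_in, n_out) {
    message(sprintf("[%s] %d in -> %d retained", stage, n_in, n_out))
    rbind(log, data.frame(stage = stage, n_in = n_in, n_out = n_out,
                          stringsAsFactors = FALSE))
}

#' Run the full transportome pipeline
#'
#' Executes every stage over a validated configuration: ingest and
#' cutoff-filter the sample tables, assemble the eight categories, write
#' per-category discovery tables with cross-sample ranks, run the
#' configured overlap comparisons, summarise plasma-membrane SLC
#' supercategories, and build the transporter and channel association
#' networks. All outputs are written under `config$out_dir` as
#' deterministically sorted TSV/JSON (plus GraphML for networks) together
#' with a manifest recording package version, parameters and input MD5
#' checksums; inputs are never mutated. Stage failures abort with the
#' stage name and offending input.
#'
#' @param config a `transportome_config`, see [runConfig()].
#' @return Invisibly, a list with the in-memory results (`tables`,
#'   `categories`, `discovery`, `overlaps`, `slc`, `networks`,
#'   `manifest`).
#' @export
runFullPipeline <- function(config) {
    validateRunConfig(config)
    for (p in c(unlist(config$samples), config$catalog,
                unlist(config$sources), config$edges,
                unlist(config$ortholog_maps), config$grouping))
        if (!is.null(p) && !file.exists(p))
            stop("config error: input file not found: ", p, call. = FALSE)
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    log <- data.frame(stage = character(), n_in = integer(),
                      n_out = integer(), stringsAsFactors = FALSE)

    catalog <- .stage("catalog", readGeneCatalog(config$catalog))
    tables <- list()
    for (nm in names(config$samples)) {
        raw <- .stage(paste0("ingest:", nm),
                      readQuantTable(config$samples[[nm]], nm))
        raw <- annotateSymbols(raw, catalog)
        cut <- applyExpressionCutoff(raw, config$cutoff)
        log <- .logCounts(log, paste0("cutoff:", nm), nGenes(raw),
                          nGenes(cut))
        tables[[nm]] <- cut
    }

    rules <- defaultCategoryRules(config$sources, config$kinase_exclusions)
    sets <- .stage("categorize", assembleCatalog(rules, catalog))
    for (nm in setdiff(names(sets), "regulators"))
        log <- .logCounts(log, paste0("category:", nm), NA_integer_,
                          nGenes(sets[[nm]]))

    discovery <- list()
    for (cat_nm in setdiff(names(sets), "regulators")) {
        for (snm in names(tables)) {
            dt <- .stage(paste0("rank:", cat_nm, ":", snm),
                suppressWarnings(rankGenes(tables[[snm]], sets[[cat_nm]],
                                           top_n = config$top_n,
                                           catalog = catalog)))
            for (other in setdiff(names(tables), snm))
                dt <- crossRank(dt, tables[[other]], sets[[cat_nm]], other)
            discovery[[paste(cat_nm, snm, sep = ".")]] <- dt
            writeDiscoveryTable(dt,
                file.path(config$out_dir,
                          paste0("discovery_", cat_nm, "_", snm, ".tsv")))
        }
    }

    overlaps <- list()
    for (cmp in config$comparisons) {
        orth <- if (!is.null(cmp$orthologs))
            readOrthologMap(config$ortholog_maps[[cmp$orthologs]])
        key <- paste(cmp$left, cmp$right, sep = "_vs_")
        res <- .stage(paste0("compare:", key),
            overlapStats(tables[[cmp$left]], tables[[cmp$right]],
                         catalog = catalog, orthologs = orth,
                         annot_terms = "transport activity"))
        overlaps[[key]] <- res
        rep <- renderOverlapReport(res)
        jsonlite::write_json(
            list(left = cmp$left, right = cmp$right,
                 counts = as.list(rep$counts),
                 pct_shared = as.list(rep$pct_shared),
                 display = as.list(rep$display_pct),
                 tpm_share_nonshared = as.list(
                     c(left = res@tpmShareNonsharedLeft,
                       right = res@tpmShareNonsharedRight)),
                 annot_fraction_nonshared =
                     as.list(res@annotFractionNonshared)),
            file.path(config$out_dir, paste0("overlap_", key, ".json")),
            auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }

    grouping <- if (is.null(config$grouping)) readSlcGrouping()
                else readSlcGrouping(config$grouping)
    slc <- NULL
    if ("transporters_pumps" %in% names(sets)) {
        tp <- sets[["transporters_pumps"]]
        e <- catalog@entries
        slc_ids <- members(tp)[!is.na(parseSlcFamily(
            e$symbol[match(members(tp), e$gene_id)]))]
        pm_slc <- GeneSet("pm_slc", slc_ids)
        slc <- .stage("slc", suppressWarnings(
            summarizeSupercategories(tables[[1]], pm_slc, grouping,
                                     cutoff = config$cutoff)))
        utils::write.table(slc,
                           file.path(config$out_dir,
                                     "slc_supercategories.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }

    networks <- list()
    if (!is.null(config$edges) &&
        all(c("transporters_pumps", "regulators") %in% names(sets))) {
        ed <- .stage("network:load", loadAssociationEdges(config$edges))
        ev <- filterEvidence(ed)
        log <- .logCounts(log, "network:evidence", nrow(ed), nrow(ev))
        e <- catalog@entries
        set_syms <- function(gs)
            e$symbol[match(members(gs), e$gene_id)]
        reg_syms <- lapply(sets[intersect(regulatorCategories(),
                                          names(sets))], set_syms)
        for (tgt_nm in intersect(c("transporters_pumps", "channels"),
                                 names(sets))) {
            iv <- config$score_intervals[[tgt_nm]]
            if (is.null(iv)) iv <- c(0.6, 1)
            net <- .stage(paste0("network:", tgt_nm),
                buildBipartiteNetwork(ev, set_syms(sets[[tgt_nm]]),
                                      reg_syms, score_interval = iv,
                                      targets_name = tgt_nm))
            be <- config$bin_edges[[tgt_nm]]
            if (is.null(be)) be <- c(10, 200)
            net <- suppressWarnings(assignNodeBins(net, tables[[1]], be))
            networks[[tgt_nm]] <- net
            if (nrow(networkEdges(net)))
                exportNetwork(net,
                    file.path(config$out_dir,
                              paste0("network_", tgt_nm, ".graphml")),
                    format = "graphml")
            log <- .logCounts(log, paste0("network:", tgt_nm), nrow(ev),
                              nrow(networkEdges(net)))
        }
    }

    inputs <- c(unlist(config$samples), catalog = config$catalog,
                unlist(config$sources),
                if (!is.null(config$edges)) c(edges = config$edges))
    manifest <- list(
        package_version = as.character(utils::packageVersion("transportome")),
        parameters = list(cutoff = config$cutoff,
                          top_n = config$top_n,
                          score_intervals = config$score_intervals,
                          bin_edges = config$bin_edges),
        input_md5 = as.list(tools::md5sum(unlist(inputs))),
        filter_log = log)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(tables = tables, categories = sets,
                   discovery = discovery, overlaps = overlaps, slc = slc,
                   networks = networks, manifest = manifest))
}
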