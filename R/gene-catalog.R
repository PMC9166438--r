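# Assembly of the eight functional gene categories from annotation-source
# files: Guide-to-Pharmacology-style family lists, HGNC-style group lists,
# KEGG-style EC-number lists and symbol-prefix rules, followed by GO-term
# filtering including the plasma-membrane filter.

# GO labels of the plasma-membrane filter. Matching is by exact label,
# case-insensitive: substring matching would conflate 'plasma membrane'
# with 'integral component of plasma membrane'.
.PM_ANY <- c("integral component of plasma membrane", "plasma membrane")
.MEMBRANE_ANY <- c("integral component of membrane", "transmembrane")
.PM_EXCLUDE <- c("lysosome", "endosome membrane", "lysosomal",
                 "mitochondrion", "mitochondrial", "golgi apparatus",
                 "vacuolar", "endoplasmic")

#' GO label sets of the plasma-membrane filter
#'
#' @return A list with elements `pm_any`, `membrane_any` and `exclude`:
#'   the two required any-of label sets and the exclusion label set used by
#'   [plasmaMembraneFilter()].
#' @export
pmFilterTerms <- function()
    list(pm_any = .PM_ANY, membrane_any = .MEMBRANE_ANY,
         exclude = .PM_EXCLUDE)

#' Read a gene annotation catalog from TSV
#'
#' Expected tab-separated columns: `gene_id`, `symbol`, and optionally
#' `alias`, `biotype`, `seqname`, `go_terms` (pipe-separated labels/IDs)
#' and `cell_type_tags` (pipe-separated). `#`-prefixed lines are ignored.
#'
#' @param path TSV path.
#' @return A [GeneCatalog-class].
#' @export
readGeneCatalog <- function(path) {
    if (!file.exists(path))
        stop("catalog file not found: ", path, call. = FALSE)
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                             comment.char = "#", colClasses = "character",
                             check.names = FALSE, stringsAsFactors = FALSE)
    for (col in c("gene_id", "symbol"))
        if (!col %in% names(raw))
            stop("format error in '", path, "': missing required column '",
                 col, "'", call. = FALSE)
    opt <- function(col) if (col %in% names(raw)) raw[[col]] else NA_character_
    GeneCatalog(trimws(raw$gene_id), trimws(raw$symbol),
                alias = opt("alias"), biotype = opt("biotype"),
                seqname = opt("seqname"),
                go_terms = if ("go_terms" %in% names(raw)) raw$go_terms
                           else list(),
                cell_type_tags = if ("cell_type_tags" %in% names(raw))
                                     raw$cell_type_tags else list())
}

#' Merge GO annotation from a GAF 2.x file into a catalog
#'
#' Reads a Gene Association File (GAF 2.x: 17 tab-separated columns,
#' `!`-prefixed header lines) and appends its GO IDs (column 5) to the
#' catalog entries matched by DB object symbol (column 3,
#' case-insensitive).
#'
#' @param catalog a [GeneCatalog-class].
#' @param path GAF file path.
#' @return The augmented [GeneCatalog-class]; symbols not present in the
#'   catalog are ignored.
#' @export
addGafAnnotation <- function(catalog, path) {
    stopifnot(is(catalog, "GeneCatalog"))
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
    if (!length(lines)) return(catalog)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ok <- lengths(parts) >= 5L
    if (!all(ok)) stop("format error in '", path,
                       "': GAF rows need >= 5 columns", call. = FALSE)
    sym <- toupper(vapply(parts, `[[`, "", 3L))
    goid <- vapply(parts, `[[`, "", 5L)
    e <- catalog@entries
    idx <- match(sym, toupper(e$symbol))
    for (i in which(!is.na(idx))) {
        j <- idx[i]
        e$go_terms[[j]] <- unique(c(e$go_terms[[j]], goid[i]))
    }
    new("GeneCatalog", entries = e)
}

# normalize a gene's GO term vector for matching: lower-case labels,
# optionally mapping GO IDs to labels through an equivalence table
.goNorm <- function(terms, go_aliases = NULL) {
    if (!is.null(go_aliases)) {
        hit <- match(terms, names(go_aliases))
        terms[!is.na(hit)] <- go_aliases[hit[!is.na(hit)]]
    }
    unique(tolower(terms))
}

# named list symbol(upper) -> GO terms, and symbol/alias -> gene_id lookup
.catalogGo <- function(catalog, go_aliases = NULL) {
    e <- catalog@entries
    stats::setNames(lapply(e$go_terms, .goNorm, go_aliases = go_aliases),
                    toupper(e$symbol))
}

# resolve symbols to gene_ids: symbol first, then alias (pipe-separated),
# both case-insensitive; unresolved symbols are reported, never invented
.resolveSymbols <- function(symbols, catalog) {
    e <- catalog@entries
    up <- toupper(symbols)
    hit <- match(up, toupper(e$symbol))
    if (anyNA(hit)) {
        alias_tab <- data.frame(
            alias = toupper(unlist(strsplit(ifelse(is.na(e$alias), "",
                                                   e$alias),
                                            "|", fixed = TRUE))),
            gene_id = rep(e$gene_id,
                          lengths(strsplit(ifelse(is.na(e$alias), "",
                                                  e$alias),
                                           "|", fixed = TRUE))),
            stringsAsFactors = FALSE)
        miss <- which(is.na(hit))
        ai <- match(up[miss], alias_tab$alias)
        ids <- ifelse(is.na(hit), NA_character_, e$gene_id[hit])
        ids[miss[!is.na(ai)]] <- alias_tab$gene_id[ai[!is.na(ai)]]
    } else ids <- e$gene_id[hit]
    stats::setNames(ids, symbols)
}

#' Load one category source list
#'
#' Reads a category source file and returns the gene symbols selected from
#' it. Supported kinds:
#' \describe{
#'   \item{gtopdb_family}{TSV with columns `symbol`, `family`; returns
#'     symbols whose family is in `selector`.}
#'   \item{hgnc_group}{TSV with columns `symbol`, `group`; analogous.}
#'   \item{kegg_ec}{TSV with columns `symbol`, `ec`; a selector label
#'     admits exact matches and all sub-categories, i.e. `"EC 2.7.11"`
#'     also admits `"EC 2.7.11.1"`.}
#'   \item{symbol_prefix}{no file; returns catalog symbols matching the
#'     selector prefix followed by a digit, case-insensitively (so a
#'     `"PDE"` selector admits PDE6D but not PDZ-domain genes).}
#' }
#' Family/group/EC matching is case-insensitive. A selector that matches
#' nothing yields an empty set with a warning, not an error.
#'
#' @param path source file path (`NULL` for `symbol_prefix`).
#' @param kind one of `"gtopdb_family"`, `"hgnc_group"`, `"kegg_ec"`,
#'   `"symbol_prefix"`.
#' @param selector character vector of family/group/EC labels, or the
#'   prefix text.
#' @param catalog a [GeneCatalog-class]; required for `symbol_prefix`.
#' @return character vector of gene symbols (unique, original case).
#' @export
loadCategorySource <- function(path, kind, selector, catalog = NULL) {
    kinds <- c("gtopdb_family", "hgnc_group", "kegg_ec", "symbol_prefix")
    if (!kind %in% kinds)
        stop("config error: unknown source kind '", kind, "'", call. = FALSE)
    if (kind == "symbol_prefix") {
        if (is.null(catalog))
            stop("config error: symbol_prefix requires a catalog",
                 call. = FALSE)
        syms <- catalog@entries$symbol
        pat <- paste0("^(", paste0(gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1",
                                        selector),
                                   collapse = "|"), ")[0-9]")
        out <- syms[grepl(pat, syms, ignore.case = TRUE)]
        if (!length(out))
            warning("symbol prefix '", paste(selector, collapse = ","),
                    "' matched no catalog symbols")
        return(unique(out))
    }
    if (is.null(path) || !file.exists(path))
        stop("config error: source file not found: ", path, call. = FALSE)
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                             comment.char = "#", colClasses = "character",
                             check.names = FALSE, stringsAsFactors = FALSE)
    label_col <- switch(kind, gtopdb_family = "family", hgnc_group = "group",
                        kegg_ec = "ec")
    # tolerate the generic column name "annotation" in exported lists
    if (!label_col %in% names(raw) && "annotation" %in% names(raw))
        label_col <- "annotation"
    for (col in c("symbol", label_col))
        if (!col %in% names(raw))
            stop("format error in '", path, "': missing column '", col, "'",
                 call. = FALSE)
    lab <- tolower(trimws(raw[[label_col]]))
    sel <- tolower(trimws(selector))
    keep <- if (kind == "kegg_ec") {
        vapply(lab, function(x)
            any(x == sel | startsWith(x, paste0(sel, "."))), logical(1))
    } else lab %in% sel
    out <- unique(trimws(raw$symbol[keep]))
    if (!length(out))
        warning("selector {", paste(selector, collapse = ", "),
                "} matched nothing in '", path, "'")
    out
}

#' Plasma-membrane GO filter
#'
#' Keeps a gene iff its GO annotation contains 'integral component of
#' plasma membrane' or 'plasma membrane', AND contains 'integral component
#' of membrane' or 'transmembrane', AND contains none of the organelle
#' exclusion labels ('lysosome', 'endosome membrane', 'lysosomal',
#' 'mitochondrion', 'mitochondrial', 'golgi apparatus', 'vacuolar',
#' 'endoplasmic'). Labels are matched exactly, case-insensitively.
#'
#' @param symbols gene symbols to filter.
#' @param catalog a [GeneCatalog-class]; symbols not resolvable in it are
#'   dropped with a warning.
#' @param go_aliases optional named character vector mapping GO IDs to
#'   labels before matching.
#' @return The subset of `symbols` passing the filter.
#' @export
plasmaMembraneFilter <- function(symbols, catalog, go_aliases = NULL) {
    stopifnot(is(catalog, "GeneCatalog"))
    if (!length(symbols)) return(character())
    go <- .catalogGo(catalog, go_aliases)
    known <- toupper(symbols) %in% names(go)
    if (any(!known))
        warning("dropping symbols not in catalog: ",
                paste(utils::head(symbols[!known], 10L), collapse = ", "))
    symbols <- symbols[known]
    keep <- vapply(toupper(symbols), function(s) {
        terms <- go[[s]]
        any(tolower(.PM_ANY) %in% terms) &&
            any(tolower(.MEMBRANE_ANY) %in% terms) &&
            !any(tolower(.PM_EXCLUDE) %in% terms)
    }, logical(1))
    symbols[keep]
}

# any-of GO filter over symbols; empty label set disables the filter
.goAnyFilter <- function(symbols, go, labels, negate = FALSE) {
    if (!length(labels)) return(symbols)
    lab <- tolower(labels)
    hit <- vapply(toupper(symbols), function(s) {
        terms <- go[[s]]
        !is.null(terms) && any(lab %in% terms)
    }, logical(1))
    if (negate) symbols[!hit] else symbols[hit]
}

#' Build one functional gene category from its rule
#'
#' Runs the rule pipeline: union of the source lists, drop of excluded
#' family prefixes (e.g. the mitochondrial and vacuolar transport families
#' SLC25, ATP5, ATP6V), required/excluded GO-term filters, the optional
#' plasma-membrane filter, manual symbol exclusions, and finally resolution
#' of symbols to gene_ids (symbol then alias, case-insensitive).
#' Provenance of the admitting steps is recorded per member.
#'
#' @param rule a [CategoryRule-class].
#' @param catalog a [GeneCatalog-class].
#' @param go_aliases optional GO ID-to-label map, see
#'   [plasmaMembraneFilter()].
#' @return A [GeneSet-class] of gene_ids. Symbols that survive filtering
#'   but cannot be resolved to a gene_id are reported in a warning and the
#'   `unresolved` attribute.
#' @export
buildCategory <- function(rule, catalog, go_aliases = NULL) {
    stopifnot(is(rule, "CategoryRule"), is(catalog, "GeneCatalog"))
    steps <- list()
    syms <- character()
    for (src in rule@sourceLists) {
        got <- loadCategorySource(src$path, src$kind, src$selector,
                                  catalog = catalog)
        step <- paste0("source:", src$kind, "[",
                       paste(src$selector, collapse = ","), "]")
        for (s in got) steps[[toupper(s)]] <- c(steps[[toupper(s)]], step)
        syms <- union(syms, got)
    }
    syms <- syms[!duplicated(toupper(syms))]
    if (length(rule@excludeFamilyPrefixes) && length(syms)) {
        pref <- toupper(rule@excludeFamilyPrefixes)
        drop <- vapply(toupper(syms),
                       function(s) any(startsWith(s, pref)), logical(1))
        syms <- syms[!drop]
    }
    go <- .catalogGo(catalog, go_aliases)
    syms <- .goAnyFilter(syms, go, rule@requireGoAny)
    syms <- .goAnyFilter(syms, go, rule@requireGoAny2)
    syms <- .goAnyFilter(syms, go, rule@excludeGoAny, negate = TRUE)
    if (rule@applyPmFilter)
        syms <- plasmaMembraneFilter(syms, catalog, go_aliases)
    if (length(rule@excludeSymbols))
        syms <- syms[!toupper(syms) %in% toupper(rule@excludeSymbols)]
    ids <- .resolveSymbols(syms, catalog)
    unresolved <- names(ids)[is.na(ids)]
    if (length(unresolved))
        warning("category '", rule@name, "': unresolved symbols: ",
                paste(utils::head(unresolved, 10L), collapse = ", "))
    keep <- !is.na(ids)
    memb <- unname(ids[keep])
    prov <- stats::setNames(lapply(toupper(names(ids)[keep]), function(s)
        c(steps[[s]], "resolved")), memb)
    # a symbol pair may resolve to one id; keep first, merge provenance
    if (anyDuplicated(memb)) {
        um <- unique(memb)
        prov <- stats::setNames(lapply(um, function(m)
            unique(unlist(prov[memb == m], use.names = FALSE))), um)
        memb <- um
    }
    out <- new("GeneSet", name = rule@name, members = memb,
               provenance = as.list(prov))
    attr(out, "unresolved") <- unresolved
    out
}

.REGULATOR_CATEGORIES <- c("gpcr", "rtk", "kinase", "phosphatase",
                           "pde", "cyclase")

#' Regulator category names, in precedence order
#'
#' The six regulator categories in the fixed precedence order used when a
#' gene belongs to several (GPCR > RTK > kinase > phosphatase > PDE >
#' cyclase); the precedence affects only node-class metadata.
#' @return character vector of the six category names.
#' @export
regulatorCategories <- function() .REGULATOR_CATEGORIES

#' Assemble a full category catalog from rules
#'
#' Builds every supplied [CategoryRule-class] into a [GeneSet-class] and
#' also materializes the regulator union (GPCR, RTK, kinase, phosphatase,
#' PDE and cyclase sets combined) for the network stage. A gene may
#' legitimately belong to several categories; overlaps are reported via
#' `message()`.
#'
#' @param rules list of [CategoryRule-class] objects (the eight categories
#'   or a declared subset).
#' @param catalog a [GeneCatalog-class].
#' @param go_aliases optional GO ID-to-label map.
#' @return Named list of [GeneSet-class] objects, one per rule, plus
#'   `"regulators"`: the union of whichever regulator categories are
#'   present.
#' @export
assembleCatalog <- function(rules, catalog, go_aliases = NULL) {
    stopifnot(is.list(rules))
    sets <- list()
    for (rule in rules) {
        gs <- buildCategory(rule, catalog, go_aliases)
        if (setName(gs) %in% names(sets))
            stop("config error: duplicate category name '", setName(gs), "'",
                 call. = FALSE)
        sets[[setName(gs)]] <- gs
    }
    nm <- names(sets)
    for (i in seq_along(sets)) for (j in seq_len(i - 1L)) {
        ov <- intersect(members(sets[[i]]), members(sets[[j]]))
        if (length(ov))
            message("categories '", nm[i], "' and '", nm[j], "' overlap in ",
                    length(ov), " gene(s)")
    }
    reg <- intersect(.REGULATOR_CATEGORIES, names(sets))
    if (length(reg)) {
        memb <- unique(unlist(lapply(sets[reg], members), use.names = FALSE))
        sets[["regulators"]] <- GeneSet("regulators", memb,
            provenance = stats::setNames(rep(list("regulator union"),
                                             length(memb)), memb))
    }
    sets
}
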