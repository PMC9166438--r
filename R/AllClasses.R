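#' @import methods
NULL

#' ExpressionTable: one sample's gene-level abundances
#'
#' Container for a single sample's gene-level expression estimates in
#' transcripts per million (TPM), optionally carrying the RSEM expected
#' counts and effective lengths they were derived from. Gene identity is the
#' stable \code{gene_id} (e.g. an Ensembl ID); symbols are display and
#' matching metadata.
#'
#' @slot sampleId single character, the sample label.
#' @slot genes \code{data.frame} with columns \code{gene_id}, \code{symbol},
#'   \code{tpm} and (optionally populated, \code{NA} otherwise)
#'   \code{expected_count}, \code{effective_length}.
#'
#' @section Validity:
#' \code{gene_id} values must be unique; every \code{tpm} must be a finite
#' non-negative number; \code{effective_length}, where present, must be
#' positive.
#'
#' @seealso [readQuantTable()], [applyExpressionCutoff()], [restrictUniverse()]
#' @export
setClass("ExpressionTable",
    representation(sampleId = "character", genes = "data.frame"))

setValidity("ExpressionTable", function(object) {
    g <- object@genes
    msg <- character()
    if (length(object@sampleId) != 1L || is.na(object@sampleId) ||
        !nzchar(object@sampleId))
        msg <- c(msg, "sampleId must be a single non-empty string")
    need <- c("gene_id", "symbol", "tpm", "expected_count", "effective_length")
    if (!all(need %in% names(g)))
        msg <- c(msg, paste("genes must have columns:",
                            paste(setdiff(need, names(g)), collapse = ", ")))
    else {
        dup <- g$gene_id[duplicated(g$gene_id)]
        if (length(dup))
            msg <- c(msg, paste0("duplicate gene_id: ",
                                 paste(unique(dup), collapse = ", ")))
        if (any(!is.finite(g$tpm)) || any(g$tpm < 0))
            msg <- c(msg, "tpm must be finite and >= 0 for every gene")
        el <- g$effective_length
        if (any(!is.na(el) & el <= 0))
            msg <- c(msg, "effective_length must be > 0 where present")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionTable
#'
#' @param sample_id sample label.
#' @param gene_id character vector of unique gene identifiers.
#' @param tpm numeric vector of TPM values (non-negative).
#' @param symbol gene symbols; defaults to `gene_id`.
#' @param expected_count,effective_length optional RSEM columns; `NA` when
#'   unavailable.
#' @return An [ExpressionTable-class] object.
#' @examples
#' et <- ExpressionTable("s1", c("g1", "g2"), c(5, 0.2))
#' nGenes(et)
#' @export
ExpressionTable <- function(sample_id, gene_id, tpm, symbol = gene_id,
                            expected_count = NA_real_,
                            effective_length = NA_real_) {
    n <- length(gene_id)
    g <- data.frame(gene_id = as.character(gene_id),
                    symbol = as.character(symbol),
                    tpm = as.numeric(tpm),
                    expected_count = rep_len(as.numeric(expected_count), n),
                    effective_length = rep_len(as.numeric(effective_length), n),
                    stringsAsFactors = FALSE)
    rownames(g) <- NULL
    new("ExpressionTable", sampleId = as.character(sample_id), genes = g)
}

#' GeneCatalog: per-gene annotation
#'
#' Per-gene annotation across the analysis universe: symbol, alias, biotype,
#' seqname (chromosome), Gene Ontology term set and optional cell-type tags.
#' GO terms and cell-type tags are list columns (character vectors per gene);
#' a gene with no GO annotation is legal.
#'
#' @slot entries \code{data.frame} with character columns \code{gene_id},
#'   \code{symbol}, \code{alias}, \code{biotype}, \code{seqname} and list
#'   columns \code{go_terms}, \code{cell_type_tags}.
#' @seealso [readGeneCatalog()], [plasmaMembraneFilter()]
#' @export
setClass("GeneCatalog", representation(entries = "data.frame"))

setValidity("GeneCatalog", function(object) {
    e <- object@entries
    msg <- character()
    need <- c("gene_id", "symbol", "alias", "biotype", "seqname",
              "go_terms", "cell_type_tags")
    if (!all(need %in% names(e)))
        return(paste("entries must have columns:",
                     paste(setdiff(need, names(e)), collapse = ", ")))
    if (anyDuplicated(e$gene_id))
        msg <- c(msg, "gene_id must be unique")
    if (any(is.na(e$symbol) | !nzchar(e$symbol)))
        msg <- c(msg, "symbol must be non-empty for every gene")
    if (!is.list(e$go_terms) || !is.list(e$cell_type_tags))
        msg <- c(msg, "go_terms and cell_type_tags must be list columns")
    if (length(msg)) msg else TRUE
})

#' Construct a GeneCatalog
#'
#' @param gene_id,symbol character vectors (required, same length).
#' @param alias,biotype,seqname character vectors; recycled, `NA` allowed.
#' @param go_terms list of character vectors (or pipe-separated strings) of
#'   GO term labels/IDs per gene.
#' @param cell_type_tags list of character vectors (or pipe-separated
#'   strings) per gene.
#' @return A [GeneCatalog-class] object.
#' @examples
#' cat <- GeneCatalog(c("g1", "g2"), c("SLC12A2", "KCNJ13"),
#'                    biotype = "protein_coding", seqname = "1",
#'                    go_terms = list(c("plasma membrane",
#'                                      "integral component of membrane"),
#'                                    "plasma membrane"))
#' @export
GeneCatalog <- function(gene_id, symbol, alias = NA_character_,
                        biotype = NA_character_, seqname = NA_character_,
                        go_terms = list(), cell_type_tags = list()) {
    n <- length(gene_id)
    norm_list <- function(x) {
        if (length(x) == 0L) return(rep(list(character()), n))
        if (!is.list(x)) x <- as.list(x)
        x <- rep_len(x, n)
        lapply(x, function(v) {
            if (length(v) == 0L || all(is.na(v))) return(character())
            v <- as.character(v)
            v <- unlist(strsplit(v, "|", fixed = TRUE), use.names = FALSE)
            unique(v[nzchar(v)])
        })
    }
    e <- data.frame(gene_id = as.character(gene_id),
                    symbol = as.character(symbol),
                    alias = rep_len(as.character(alias), n),
                    biotype = rep_len(as.character(biotype), n),
                    seqname = rep_len(as.character(seqname), n),
                    stringsAsFactors = FALSE)
    e$go_terms <- norm_list(go_terms)
    e$cell_type_tags <- norm_list(cell_type_tags)
    rownames(e) <- NULL
    new("GeneCatalog", entries = e)
}

#' CategoryRule: declarative recipe for one functional gene category
#'
#' A rule describes how one of the eight functional categories (e.g.
#' "transporters_pumps") is assembled: which source lists seed it, which
#' family prefixes are excluded, which GO-term filters apply, whether the
#' plasma-membrane filter runs, and any manual symbol exclusions.
#'
#' @slot name category name, unique within a configuration.
#' @slot sourceLists list of \code{list(path=, kind=, selector=)} entries;
#'   \code{kind} is one of \code{gtopdb_family}, \code{hgnc_group},
#'   \code{kegg_ec}, \code{symbol_prefix}.
#' @slot excludeFamilyPrefixes symbol prefixes dropped up front (e.g.
#'   \code{SLC25}, \code{ATP5}, \code{ATP6V}).
#' @slot requireGoAny,requireGoAny2 two conjunctive any-of GO label sets
#'   (empty = filter disabled).
#' @slot excludeGoAny GO labels whose presence drops a gene.
#' @slot excludeSymbols manual exclusion list (configuration, not code).
#' @slot applyPmFilter logical: run [plasmaMembraneFilter()].
#' @seealso [buildCategory()]
#' @export
setClass("CategoryRule",
    representation(name = "character", sourceLists = "list",
                   excludeFamilyPrefixes = "character",
                   requireGoAny = "character", requireGoAny2 = "character",
                   excludeGoAny = "character", excludeSymbols = "character",
                   applyPmFilter = "logical"),
    prototype(excludeFamilyPrefixes = character(),
              requireGoAny = character(), requireGoAny2 = character(),
              excludeGoAny = character(), excludeSymbols = character(),
              applyPmFilter = FALSE))

setValidity("CategoryRule", function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "name must be a single non-empty string")
    kinds <- c("gtopdb_family", "hgnc_group", "kegg_ec", "symbol_prefix")
    for (src in object@sourceLists) {
        if (!is.list(src) || is.null(src$kind))
            msg <- c(msg, "each source list needs a 'kind'")
        else if (!src$kind %in% kinds)
            msg <- c(msg, paste0("unknown source kind: ", src$kind))
    }
    if (any(!nzchar(object@excludeFamilyPrefixes)))
        msg <- c(msg, "excludeFamilyPrefixes must be non-empty strings")
    if (length(object@applyPmFilter) != 1L || is.na(object@applyPmFilter))
        msg <- c(msg, "applyPmFilter must be TRUE or FALSE")
    if (length(msg)) msg else TRUE
})

#' Construct a CategoryRule
#'
#' @param name category name.
#' @param source_lists list of \code{list(path=, kind=, selector=)}.
#' @param exclude_family_prefixes,require_go_any,require_go_any_2,exclude_go_any,exclude_symbols
#'   character vectors, see [CategoryRule-class].
#' @param apply_pm_filter logical.
#' @return A [CategoryRule-class] object.
#' @export
CategoryRule <- function(name, source_lists = list(),
                         exclude_family_prefixes = character(),
                         require_go_any = character(),
                         require_go_any_2 = character(),
                         exclude_go_any = character(),
                         exclude_symbols = character(),
                         apply_pm_filter = FALSE) {
    new("CategoryRule", name = name, sourceLists = source_lists,
        excludeFamilyPrefixes = as.character(exclude_family_prefixes),
        requireGoAny = as.character(require_go_any),
        requireGoAny2 = as.character(require_go_any_2),
        excludeGoAny = as.character(exclude_go_any),
        excludeSymbols = as.character(exclude_symbols),
        applyPmFilter = apply_pm_filter)
}

#' GeneSet: a resolved functional category membership
#'
#' @slot name category name.
#' @slot members character vector of gene_ids.
#' @slot provenance named list (one entry per member) of the rule steps that
#'   admitted the gene.
#' @seealso [buildCategory()], [assembleCatalog()]
#' @export
setClass("GeneSet",
    representation(name = "character", members = "character",
                   provenance = "list"))

setValidity("GeneSet", function(object) {
    msg <- character()
    if (anyDuplicated(object@members))
        msg <- c(msg, "members must be unique")
    if (length(object@provenance) &&
        !setequal(names(object@provenance), object@members))
        msg <- c(msg, "provenance must be defined for exactly the members")
    if (length(msg)) msg else TRUE
})

#' Construct a GeneSet
#' @param name set name.
#' @param members character vector of gene_ids.
#' @param provenance named list of admitting rule steps per member; defaults
#'   to a constant "manual" record.
#' @return A [GeneSet-class] object.
#' @export
GeneSet <- function(name, members, provenance = NULL) {
    members <- unique(as.character(members))
    if (is.null(provenance))
        provenance <- stats::setNames(rep(list("manual"), length(members)),
                                      members)
    new("GeneSet", name = name, members = members, provenance = provenance)
}

#' DiscoveryTable: a TPM-ranked, category-restricted gene list
#'
#' The discovery-table format: genes of one functional category in one
#' sample, sorted by TPM (descending, ties broken by ascending symbol),
#' ranked 1..n, optionally truncated, and carrying cross-sample rank columns
#' (\code{rank.<label>}) where \code{NA} means the gene fell below the
#' expression cutoff in that sample.
#'
#' @slot category category name.
#' @slot sampleId sample label.
#' @slot table \code{data.frame} with columns \code{gene_id}, \code{symbol},
#'   \code{alias}, \code{tpm}, \code{rank} and zero or more
#'   \code{rank.<label>} cross-rank columns.
#' @seealso [rankGenes()], [crossRank()], [topNContainment()]
#' @export
setClass("DiscoveryTable",
    representation(category = "character", sampleId = "character",
                   table = "data.frame"))

setValidity("DiscoveryTable", function(object) {
    tb <- object@table
    msg <- character()
    need <- c("gene_id", "symbol", "alias", "tpm", "rank")
    if (!all(need %in% names(tb)))
        return(paste("table must have columns:",
                     paste(setdiff(need, names(tb)), collapse = ", ")))
    if (nrow(tb)) {
        if (is.unsorted(-tb$tpm))
            msg <- c(msg, "rows must be sorted by tpm non-increasing")
        if (!identical(as.integer(tb$rank), seq_len(nrow(tb))))
            msg <- c(msg, "ranks must be 1..n in order")
    }
    if (length(msg)) msg else TRUE
})

#' OverlapResult: two-sample shared/non-shared gene statistics
#'
#' Shared-gene counts are per perspective: a left gene is shared when it has
#' at least one name- or ortholog-matched partner on the right (and vice
#' versa), so under many-to-many orthology the two perspectives may count
#' differently. Percentages follow the respective side's denominator.
#'
#' @slot nLeft,nRight,nSharedLeft,nSharedRight gene counts.
#' @slot pctSharedLeft,pctSharedRight 100 * nShared<side> / n<side>.
#' @slot tpmShareNonsharedLeft,tpmShareNonsharedRight percentage of the
#'   side's total TPM carried by its non-shared genes.
#' @slot annotFractionNonshared named numeric: per queried GO label, the
#'   percentage of the designated side's non-shared genes carrying it.
#' @slot annotSide which side `annotFractionNonshared` refers to.
#' @slot restrictedTo category name the comparison was restricted to, or
#'   `NA`.
#' @slot degenerate TRUE when a side was empty and percentages are `NA`.
#' @seealso [overlapStats()], [renderOverlapReport()]
#' @export
setClass("OverlapResult",
    representation(nLeft = "numeric", nRight = "numeric",
                   nSharedLeft = "numeric", nSharedRight = "numeric",
                   pctSharedLeft = "numeric", pctSharedRight = "numeric",
                   tpmShareNonsharedLeft = "numeric",
                   tpmShareNonsharedRight = "numeric",
                   annotFractionNonshared = "numeric",
                   annotSide = "character",
                   restrictedTo = "character", degenerate = "logical"))

setValidity("OverlapResult", function(object) {
    msg <- character()
    if (!object@degenerate) {
        if (object@nSharedLeft > object@nLeft ||
            object@nSharedRight > object@nRight)
            msg <- c(msg, "shared counts cannot exceed side totals")
        shares <- c(object@tpmShareNonsharedLeft,
                    object@tpmShareNonsharedRight)
        if (any(shares < -1e-9 | shares > 100 + 1e-9, na.rm = TRUE))
            msg <- c(msg, "TPM shares must lie in [0, 100]")
    }
    if (length(msg)) msg else TRUE
})

#' AssociationNetwork: filtered bipartite target-regulator graph
#'
#' @slot targetsName name of the target gene set ("transporters_pumps" or
#'   "channels").
#' @slot nodes \code{data.frame}: \code{symbol}, \code{role} (target or
#'   regulator), \code{regulator_class} (`NA` for targets), \code{tpm},
#'   \code{size_bin} (1, 2 or 3; `NA` before [assignNodeBins()]).
#' @slot edges \code{data.frame}: \code{target}, \code{regulator},
#'   \code{combined_score}.
#' @slot scoreInterval closed confidence interval the edges were filtered
#'   to.
#' @seealso [buildBipartiteNetwork()], [assignNodeBins()], [exportNetwork()]
#' @export
setClass("AssociationNetwork",
    representation(targetsName = "character", nodes = "data.frame",
                   edges = "data.frame", scoreInterval = "numeric"))

setValidity("AssociationNetwork", function(object) {
    msg <- character()
    nd <- object@nodes; ed <- object@edges
    if (!all(c("symbol", "role", "regulator_class", "tpm", "size_bin")
             %in% names(nd)))
        msg <- c(msg, "nodes must have symbol/role/regulator_class/tpm/size_bin")
    if (!all(c("target", "regulator", "combined_score") %in% names(ed)))
        msg <- c(msg, "edges must have target/regulator/combined_score")
    if (length(object@scoreInterval) != 2L ||
        object@scoreInterval[1] > object@scoreInterval[2] ||
        object@scoreInterval[1] < 0 || object@scoreInterval[2] > 1)
        msg <- c(msg, "scoreInterval must be a closed sub-interval of [0, 1]")
    if (!length(msg) && nrow(nd)) {
        tg <- nd$symbol[nd$role == "target"]
        # target endpoint must be a target node; the other endpoint a known
        # node (a regulator, or — under the opt-in target-target retention —
        # another target)
        if (!all(ed$target %in% tg) || !all(ed$regulator %in% nd$symbol))
            msg <- c(msg, "edge endpoints must be known nodes with a target on the target side")
        touched <- union(ed$target, ed$regulator)
        if (!all(nd$symbol %in% touched))
            msg <- c(msg, "isolated nodes are not permitted")
        sc <- ed$combined_score
        if (any(sc < object@scoreInterval[1] - 1e-12 |
                sc > object@scoreInterval[2] + 1e-12))
            msg <- c(msg, "edge scores must lie within scoreInterval")
    }
    if (length(msg)) msg else TRUE
})

#' SyntheticTruth: plan and planted ground truth for synthetic inputs
#'
#' Describes a fully self-contained synthetic study: sample sizes and
#' log-normal TPM parameters, the constructed (not sampled) shared fraction
#' between the two samples, planted category sizes, and the planted
#' association-network structure. All generation derived from it is
#' deterministic given \code{seed}.
#'
#' @slot seed integer RNG seed.
#' @slot samples list of two sample specs \code{list(sample_id, n_genes,
#'   meanlog, sdlog, n_subthreshold)}.
#' @slot sharedFraction planted left-perspective shared percentage.
#' @slot nOrthologBridges shared genes linked only through the ortholog map.
#' @slot categorySizes named integer vector over the eight categories.
#' @slot network list: \code{n_edges}, \code{score_range},
#'   \code{n_distractors_per_type}.
#' @slot cutoff TPM expression cutoff the construction guarantees against.
#' @seealso [syntheticTruth()], [generateExpressionSamples()]
#' @export
setClass("SyntheticTruth",
    representation(seed = "integer", samples = "list",
                   sharedFraction = "numeric", nOrthologBridges = "integer",
                   categorySizes = "integer", network = "list",
                   cutoff = "numeric"))

setValidity("SyntheticTruth", function(object) {
    msg <- character()
    if (length(object@samples) != 2L)
        msg <- c(msg, "exactly two sample specs are required")
    p <- object@sharedFraction
    if (length(p) != 1L || p < 0 || p > 100)
        msg <- c(msg, "sharedFraction must be a percentage in [0, 100]")
    if (length(msg)) msg else TRUE
})
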