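# Filtered bipartite transporter/channel <-> regulator association
# networks from STRING-format protein-link tables.

#' Load a STRING-style protein association edge table
#'
#' Reads a `protein.links.detailed`-style table (space- or tab-separated,
#' header required). The first two columns are taken as the protein pair;
#' a `combined_score` column is required and every remaining numeric
#' column is kept as an evidence channel. Symbols are uppercased, scores
#' on the 0-1000 scale are normalized to [0, 1], self-edges are dropped,
#' and duplicate undirected edges are collapsed keeping the row with the
#' maximum combined score.
#'
#' @param path file path.
#' @return data.frame with columns `protein_a`, `protein_b`,
#'   `combined_score` and one column per evidence channel, all scores in
#'   [0, 1].
#' @export
loadAssociationEdges <- function(path) {
    if (!file.exists(path))
        stop("edge table not found: ", path, call. = FALSE)
    raw <- utils::read.table(path, header = TRUE, sep = "",
                             comment.char = "#", check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(raw) < 3L)
        stop("format error in '", path,
             "': need two protein columns and combined_score",
             call. = FALSE)
    if (!"combined_score" %in% names(raw))
        stop("format error in '", path,
             "': missing column 'combined_score'", call. = FALSE)
    pa <- toupper(trimws(as.character(raw[[1]])))
    pb <- toupper(trimws(as.character(raw[[2]])))
    chan_cols <- setdiff(names(raw)[-(1:2)], "combined_score")
    norm <- function(x) {
        x <- as.numeric(x)
        if (any(is.na(x)))
            stop("format error in '", path, "': non-numeric score",
                 call. = FALSE)
        if (any(x > 1)) x / 1000 else x
    }
    ed <- data.frame(protein_a = pa, protein_b = pb,
                     combined_score = norm(raw$combined_score),
                     stringsAsFactors = FALSE)
    for (col in chan_cols) ed[[col]] <- norm(raw[[col]])
    ed <- ed[ed$protein_a != ed$protein_b, , drop = FALSE]
    # undirected key; keep the max combined_score representative
    key <- ifelse(ed$protein_a < ed$protein_b,
                  paste(ed$protein_a, ed$protein_b),
                  paste(ed$protein_b, ed$protein_a))
    ord <- order(key, -ed$combined_score)
    ed <- ed[ord, , drop = FALSE]
    ed <- ed[!duplicated(key[ord]), , drop = FALSE]
    rownames(ed) <- NULL
    ed
}

#' Filter association edges by evidence channel
#'
#' Keeps edges supported by at least one of the required evidence
#' channels (score > 0). The default requirement — `experiments` or
#' `databases` — keeps exactly the associations curated in a database or
#' demonstrated experimentally, discarding e.g. textmining-only links.
#'
#' @param edges edge data.frame from [loadAssociationEdges()].
#' @param required_channels channel column names; all must be present.
#' @return The filtered edge data.frame.
#' @export
filterEvidence <- function(edges,
                           required_channels = c("experiments",
                                                 "databases")) {
    missing <- setdiff(required_channels, names(edges))
    if (length(missing))
        stop("evidence channels absent from table: ",
             paste(missing, collapse = ", "), call. = FALSE)
    if (!nrow(edges)) return(edges)
    keep <- Reduce(`|`, lapply(required_channels,
                               function(ch) edges[[ch]] > 0))
    out <- edges[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Build a filtered bipartite target-regulator network
#'
#' Retains exactly the edges joining one target symbol (transporters and
#' pumps, or channels) with one regulator symbol, with combined score
#' inside the closed confidence interval; all regulator-regulator edges
#' are discarded, and target-target edges too unless
#' `keep_target_target`. Regulator nodes are tagged with the first
#' matching category in the order of `regulators` (default precedence:
#' GPCR > RTK > kinase > phosphatase > PDE > cyclase). Isolated nodes are
#' pruned. Genes appearing both as target and regulator are treated as
#' targets, with a warning.
#'
#' @param edges evidence-filtered edge data.frame.
#' @param targets character vector of target symbols (or a
#'   [GeneSet-class] of symbols).
#' @param regulators named list of regulator symbol vectors (or
#'   [GeneSet-class] objects), in category precedence order.
#' @param score_interval closed interval within [0, 1]; default
#'   `c(0.6, 1)`.
#' @param targets_name name recorded on the network.
#' @param keep_target_target also retain target-target edges (off by
#'   default, matching the stated bipartite restriction).
#' @return An [AssociationNetwork-class]; node TPM and size bins are `NA`
#'   until [assignNodeBins()].
#' @export
buildBipartiteNetwork <- function(edges, targets, regulators,
                                  score_interval = c(0.6, 1),
                                  targets_name = "transporters_pumps",
                                  keep_target_target = FALSE) {
    as_syms <- function(x) toupper(if (is(x, "GeneSet")) members(x)
                                   else as.character(x))
    tset <- unique(as_syms(targets))
    rlist <- lapply(regulators, as_syms)
    if (is.null(names(rlist)) || any(!nzchar(names(rlist))))
        stop("regulators must be a named list of categories", call. = FALSE)
    runion <- unique(unlist(rlist, use.names = FALSE))
    both <- intersect(tset, runion)
    if (length(both)) {
        warning("genes in both targets and regulators treated as targets: ",
                paste(utils::head(both, 10L), collapse = ", "))
        runion <- setdiff(runion, both)
    }
    if (length(score_interval) != 2L || score_interval[1] > score_interval[2] ||
        score_interval[1] < 0 || score_interval[2] > 1)
        stop("config error: score_interval must be a closed sub-interval of [0, 1]",
             call. = FALSE)
    a <- edges$protein_a; b <- edges$protein_b
    in_score <- edges$combined_score >= score_interval[1] &
        edges$combined_score <= score_interval[2]
    a_t <- a %in% tset; b_t <- b %in% tset
    a_r <- a %in% runion; b_r <- b %in% runion
    bip <- (a_t & b_r) | (a_r & b_t)
    tt <- a_t & b_t
    keep <- in_score & (bip | (keep_target_target & tt))
    ke <- edges[keep, , drop = FALSE]
    tgt <- ifelse(ke$protein_a %in% tset, ke$protein_a, ke$protein_b)
    reg <- ifelse(ke$protein_a %in% tset, ke$protein_b, ke$protein_a)
    ed <- data.frame(target = as.character(tgt),
                     regulator = as.character(reg),
                     combined_score = ke$combined_score,
                     stringsAsFactors = FALSE)
    ed <- ed[order(ed$target, ed$regulator), , drop = FALSE]
    rownames(ed) <- NULL
    reg_class <- function(s) {
        for (nm in names(rlist)) if (s %in% rlist[[nm]]) return(nm)
        NA_character_
    }
    tnodes <- sort(unique(c(ed$target,
                            if (keep_target_target)
                                ed$regulator[ed$regulator %in% tset])))
    rnodes <- sort(unique(ed$regulator[!ed$regulator %in% tset]))
    n_nodes <- length(tnodes) + length(rnodes)
    nodes <- data.frame(
        symbol = c(tnodes, rnodes),
        role = c(rep("target", length(tnodes)),
                 rep("regulator", length(rnodes))),
        regulator_class = c(rep(NA_character_, length(tnodes)),
                            vapply(rnodes, reg_class, "")),
        tpm = rep(NA_real_, n_nodes),
        size_bin = rep(NA_integer_, n_nodes), stringsAsFactors = FALSE)
    rownames(nodes) <- NULL
    net <- new("AssociationNetwork", targetsName = targets_name,
               nodes = nodes, edges = ed, scoreInterval = score_interval)
    net
}

#' Assign expression size bins to network nodes
#'
#' Bins each node's TPM into three display sizes with boundary values
#' assigned to the outer bins: bin 1 for TPM at or below the lower edge,
#' bin 3 for TPM at or above the upper edge, bin 2 between (e.g. edges
#' `c(10, 200)` encode "TPM <= 10, 10-200, >= 200"). Nodes absent from the
#' expression table get bin 1 with a warning.
#'
#' @param network an [AssociationNetwork-class].
#' @param expr an [ExpressionTable-class]; symbols matched
#'   case-insensitively.
#' @param bin_edges two strictly increasing thresholds.
#' @return The network with `tpm` and `size_bin` populated.
#' @export
assignNodeBins <- function(network, expr, bin_edges = c(10, 200)) {
    stopifnot(is(network, "AssociationNetwork"),
              is(expr, "ExpressionTable"))
    if (length(bin_edges) != 2L || !(bin_edges[1] < bin_edges[2]))
        stop("config error: bin edges must be two strictly increasing values",
             call. = FALSE)
    nd <- network@nodes
    sym <- toupper(expr@genes$symbol)
    idx <- match(nd$symbol, sym)
    if (anyNA(idx))
        warning("nodes absent from expression table get bin 1: ",
                paste(utils::head(nd$symbol[is.na(idx)], 10L),
                      collapse = ", "))
    nd$tpm <- expr@genes$tpm[idx]
    bin <- ifelse(nd$tpm <= bin_edges[1], 1L,
                  ifelse(nd$tpm >= bin_edges[2], 3L, 2L))
    bin[is.na(bin)] <- 1L
    nd$size_bin <- bin
    new("AssociationNetwork", targetsName = network@targetsName,
        nodes = nd, edges = network@edges,
        scoreInterval = network@scoreInterval)
}

# AssociationNetwork -> igraph with node/edge attributes
.asIgraph <- function(network) {
    nd <- network@nodes
    ed <- network@edges
    igraph::graph_from_data_frame(
        d = data.frame(from = ed$target, to = ed$regulator,
                       combined_score = ed$combined_score,
                       stringsAsFactors = FALSE),
        directed = FALSE,
        vertices = data.frame(name = nd$symbol, role = nd$role,
                              regulator_class = ifelse(
                                  is.na(nd$regulator_class), "",
                                  nd$regulator_class),
                              tpm = ifelse(is.na(nd$tpm), -1, nd$tpm),
                              size_bin = ifelse(is.na(nd$size_bin), 0L,
                                                nd$size_bin),
                              stringsAsFactors = FALSE))
}

#' Export an association network
#'
#' `graphml` is the primary, lossless format (node roles, regulator
#' classes, TPM, size bins and edge scores round-trip); `sif` and `tsv`
#' write the edge list (`target assoc regulator` for SIF) plus a sidecar
#' node-attribute table at `<path>.nodes.tsv`.
#'
#' @param network a non-empty [AssociationNetwork-class].
#' @param path output file path.
#' @param format `"graphml"`, `"sif"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
exportNetwork <- function(network, path,
                          format = c("graphml", "sif", "tsv")) {
    stopifnot(is(network, "AssociationNetwork"))
    if (length(format) == 1L &&
        !format %in% c("graphml", "sif", "tsv"))
        stop("config error: unknown export format '", format, "'",
             call. = FALSE)
    format <- match.arg(format)
    if (!nrow(network@edges))
        stop("cannot export an empty network", call. = FALSE)
    if (format == "graphml") {
        igraph::write_graph(.asIgraph(network), path, format = "graphml")
    } else {
        if (format == "sif") {
            writeLines(paste(network@edges$target, "assoc",
                             network@edges$regulator), path)
        } else {
            utils::write.table(network@edges, path, sep = "\t",
                               quote = FALSE, row.names = FALSE)
        }
        utils::write.table(network@nodes, paste0(path, ".nodes.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE,
                           na = "NA")
    }
    invisible(path)
}

#' Re-import a GraphML association network
#'
#' Inverse of [exportNetwork()] for the `graphml` format; used to verify
#' lossless round-trips.
#'
#' @param path GraphML file written by [exportNetwork()].
#' @param targets_name name to record on the reconstructed network.
#' @param score_interval interval to record; defaults to the score range
#'   found in the file.
#' @return An [AssociationNetwork-class].
#' @export
importNetworkGraphml <- function(path, targets_name = "targets",
                                 score_interval = NULL) {
    g <- igraph::read_graph(path, format = "graphml")
    vd <- igraph::as_data_frame(g, what = "vertices")
    edf <- igraph::as_data_frame(g, what = "edges")
    nodes <- data.frame(symbol = vd$name, role = vd$role,
                        regulator_class = ifelse(vd$regulator_class == "",
                                                 NA_character_,
                                                 vd$regulator_class),
                        tpm = ifelse(vd$tpm < 0, NA_real_, vd$tpm),
                        size_bin = ifelse(vd$size_bin == 0, NA_integer_,
                                          as.integer(vd$size_bin)),
                        stringsAsFactors = FALSE)
    role <- stats::setNames(nodes$role, nodes$symbol)
    tgt <- ifelse(role[edf$from] == "target", edf$from, edf$to)
    reg <- ifelse(role[edf$from] == "target", edf$to, edf$from)
    ed <- data.frame(target = unname(tgt), regulator = unname(reg),
                     combined_score = edf$combined_score,
                     stringsAsFactors = FALSE)
    ed <- ed[order(ed$target, ed$regulator), , drop = FALSE]
    nodes <- nodes[order(match(nodes$role, c("target", "regulator")),
                         nodes$symbol), , drop = FALSE]
    rownames(ed) <- rownames(nodes) <- NULL
    if (is.null(score_interval))
        score_interval <- c(min(ed$combined_score), max(ed$combined_score))
    new("AssociationNetwork", targetsName = targets_name, nodes = nodes,
        edges = ed, scoreInterval = score_interval)
}
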