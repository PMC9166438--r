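# TPM-ranked discovery tables per functional category and the
# cross-sample rank-concordance statistics.

#' Rank a category's genes by expression
#'
#' Restricts the (already cutoff-filtered) expression table to a gene set,
#' sorts by TPM descending with ties broken by ascending symbol, assigns
#' ranks 1..n and optionally truncates to the top `top_n`.
#'
#' @param table an [ExpressionTable-class], cutoff-filtered.
#' @param genes a [GeneSet-class] in the same gene_id space (or a character
#'   vector of gene_ids).
#' @param top_n positive integer, or `Inf` for the full ranking.
#' @param catalog optional [GeneCatalog-class] supplying the alias column.
#' @param category category name recorded on the result; defaults to the
#'   gene-set name.
#' @return A [DiscoveryTable-class]. An empty intersection yields an empty
#'   table plus a warning.
#' @export
rankGenes <- function(table, genes, top_n = Inf, catalog = NULL,
                      category = NULL) {
    stopifnot(is(table, "ExpressionTable"))
    memb <- if (is(genes, "GeneSet")) members(genes) else as.character(genes)
    if (is.null(category))
        category <- if (is(genes, "GeneSet")) setName(genes) else "genes"
    if (!is.infinite(top_n) && (top_n < 1 || top_n != round(top_n)))
        stop("domain error: top_n must be a positive integer or Inf",
             call. = FALSE)
    g <- table@genes[table@genes$gene_id %in% memb, , drop = FALSE]
    if (!nrow(g))
        warning("category '", category, "' has no genes in sample '",
                table@sampleId, "'")
    alias <- rep(NA_character_, nrow(g))
    if (!is.null(catalog)) {
        idx <- match(g$gene_id, catalog@entries$gene_id)
        alias <- catalog@entries$alias[idx]
    }
    ord <- order(-g$tpm, g$symbol)
    g <- g[ord, , drop = FALSE]
    alias <- alias[ord]
    n <- min(nrow(g), top_n)
    tb <- data.frame(gene_id = g$gene_id, symbol = g$symbol, alias = alias,
                     tpm = g$tpm, rank = seq_len(nrow(g)),
                     stringsAsFactors = FALSE)[seq_len(n), , drop = FALSE]
    rownames(tb) <- NULL
    new("DiscoveryTable", category = category, sampleId = table@sampleId,
        table = tb)
}

#' Add a cross-sample rank column to a discovery table
#'
#' Ranks the same category in another (cutoff-filtered) sample — the full,
#' untruncated ranking — and records each base-table gene's rank there as
#' column `rank.<label>`. A gene below the cutoff in the other sample gets
#' `NA` (the "N/A" convention of printed discovery tables). Base ordering
#' and TPM values are never altered.
#'
#' @param discovery a [DiscoveryTable-class].
#' @param other the other sample's [ExpressionTable-class], filtered with
#'   the same cutoff.
#' @param other_genes the category [GeneSet-class] resolved for `other`.
#' @param label cross-rank column label; must not collide with an existing
#'   one.
#' @return The augmented [DiscoveryTable-class].
#' @export
crossRank <- function(discovery, other, other_genes, label) {
    stopifnot(is(discovery, "DiscoveryTable"))
    col <- paste0("rank.", label)
    if (col %in% names(discovery@table))
        stop("label collision: cross-rank column '", label,
             "' already present", call. = FALSE)
    full <- suppressWarnings(
        rankGenes(other, other_genes, top_n = Inf,
                  category = discovery@category))
    idx <- match(discovery@table$gene_id, full@table$gene_id)
    tb <- discovery@table
    tb[[col]] <- full@table$rank[idx]
    new("DiscoveryTable", category = discovery@category,
        sampleId = discovery@sampleId, table = tb)
}

#' Containment of a top-n list within another sample's ranking
#'
#' For the first `n_top` rows of a discovery table, summarises the
#' cross-rank column `label`: the maximum rank the genes reach in the
#' other sample (over genes present there) and how many are absent
#' (below the cutoff, `NA` cross-rank). E.g. "the top 20 transporters were
#' all contained within the other sample's top 26" reads as
#' `max_cross_rank = 26`, `n_missing = 0`.
#'
#' @param discovery a [DiscoveryTable-class] carrying `rank.<label>`.
#' @param label cross-rank column label.
#' @param n_top number of leading rows to summarise; must not exceed the
#'   table length.
#' @return list with `n_top`, `reference_sample`, `max_cross_rank` (`NA`
#'   if every gene is missing) and `n_missing`.
#' @export
topNContainment <- function(discovery, label, n_top) {
    stopifnot(is(discovery, "DiscoveryTable"))
    col <- paste0("rank.", label)
    if (!col %in% names(discovery@table))
        stop("no cross-rank column for label '", label, "'", call. = FALSE)
    if (n_top > nrow(discovery@table))
        stop("domain error: n_top (", n_top, ") exceeds table length (",
             nrow(discovery@table), ")", call. = FALSE)
    cr <- discovery@table[[col]][seq_len(n_top)]
    list(n_top = as.integer(n_top), reference_sample = label,
         max_cross_rank = if (all(is.na(cr))) NA_integer_
                          else as.integer(max(cr, na.rm = TRUE)),
         n_missing = sum(is.na(cr)))
}

#' Write / read a discovery table as TSV
#'
#' The TSV mirrors the printed discovery-table layout: columns `Gene`,
#' `Alias`, `TPM`, `Rank` and one `<Label>_rank` column per cross-rank
#' (absent cross-ranks written as `NA`), so published tables can be
#' round-tripped as fixtures.
#'
#' @param discovery a [DiscoveryTable-class].
#' @param path output TSV path.
#' @return `writeDiscoveryTable`: `path`, invisibly.
#' @export
writeDiscoveryTable <- function(discovery, path) {
    tb <- discovery@table
    out <- data.frame(Gene = tb$symbol, Alias = tb$alias, TPM = tb$tpm,
                      Rank = tb$rank, check.names = FALSE,
                      stringsAsFactors = FALSE)
    for (col in grep("^rank\\.", names(tb), value = TRUE))
        out[[paste0(sub("^rank\\.", "", col), "_rank")]] <- tb[[col]]
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' @rdname writeDiscoveryTable
#' @param category,sample_id metadata for the reconstructed table.
#' @return `readDiscoveryTable`: a [DiscoveryTable-class]; gene_id is taken
#'   from the `Gene` column.
#' @export
readDiscoveryTable <- function(path, category, sample_id) {
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                             comment.char = "#", check.names = FALSE,
                             stringsAsFactors = FALSE)
    for (col in c("Gene", "TPM", "Rank"))
        if (!col %in% names(raw))
            stop("format error in '", path, "': missing column '", col, "'",
                 call. = FALSE)
    tb <- data.frame(gene_id = as.character(raw$Gene),
                     symbol = as.character(raw$Gene),
                     alias = if ("Alias" %in% names(raw))
                                 as.character(raw$Alias)
                             else NA_character_,
                     tpm = as.numeric(raw$TPM),
                     rank = as.integer(raw$Rank), stringsAsFactors = FALSE)
    for (col in grep("_rank$", names(raw), value = TRUE))
        tb[[paste0("rank.", sub("_rank$", "", col))]] <-
            suppressWarnings(as.integer(raw[[col]]))
    new("DiscoveryTable", category = category, sampleId = sample_id,
        table = tb)
}
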