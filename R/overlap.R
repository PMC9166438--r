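# Two-sample shared/non-shared gene statistics: cross-species,
# FACS-vs-tissue, sex and tissue comparisons rendered as Venn-style
# overlap reports.

#' Read an ortholog map
#'
#' Two-column tab-separated file (`left_symbol`, `right_symbol`), as
#' exported from a biomart-style query. Symbols are uppercased to the
#' canonical matching form; many-to-many pairs are permitted.
#'
#' @param path TSV path; a header line is required.
#' @return data.frame with columns `left`, `right` (uppercase symbols).
#' @export
readOrthologMap <- function(path) {
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                             comment.char = "#", colClasses = "character",
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(raw) < 2L)
        stop("format error in '", path,
             "': ortholog map needs two columns", call. = FALSE)
    out <- data.frame(left = toupper(trimws(raw[[1]])),
                      right = toupper(trimws(raw[[2]])),
                      stringsAsFactors = FALSE)
    unique(out[nzchar(out$left) & nzchar(out$right), , drop = FALSE])
}

#' Match genes between two samples by symbol or orthology
#'
#' A left gene is matched when its symbol (case-insensitive) equals a
#' right-side symbol, or an ortholog pair links it to a symbol present on
#' the right; symmetrically for right genes. Matching is computed on gene
#' sets — each gene counts once even under many-to-many orthology, by the
#' per-side "has at least one partner" rule.
#'
#' @param left,right cutoff-filtered [ExpressionTable-class] objects with
#'   symbols available.
#' @param orthologs optional data.frame with columns `left`, `right`
#'   (see [readOrthologMap()]), or `NULL` for symbol-only matching.
#' @return list with gene_id vectors `shared_left`, `left_only`,
#'   `shared_right`, `right_only`.
#' @examples
#' a <- ExpressionTable("a", c("1", "2", "3"), c(1, 1, 1),
#'                      symbol = c("A", "B", "C"))
#' b <- ExpressionTable("b", c("4", "5", "6"), c(1, 1, 1),
#'                      symbol = c("B", "C", "D"))
#' matchGenes(a, b)$shared_left  # genes B and C
#' @export
matchGenes <- function(left, right, orthologs = NULL) {
    stopifnot(is(left, "ExpressionTable"), is(right, "ExpressionTable"))
    ls <- toupper(left@genes$symbol)
    rs <- toupper(right@genes$symbol)
    lset <- unique(ls); rset <- unique(rs)
    l_hit <- ls %in% rset
    r_hit <- rs %in% lset
    if (!is.null(orthologs) && nrow(orthologs)) {
        ol <- toupper(orthologs$left); or <- toupper(orthologs$right)
        bridged_l <- unique(ol[or %in% rset])
        bridged_r <- unique(or[ol %in% lset])
        l_hit <- l_hit | ls %in% bridged_l
        r_hit <- r_hit | rs %in% bridged_r
    }
    list(shared_left = left@genes$gene_id[l_hit],
         left_only = left@genes$gene_id[!l_hit],
         shared_right = right@genes$gene_id[r_hit],
         right_only = right@genes$gene_id[!r_hit])
}

# restrict an ExpressionTable to a GeneSet's members
.restrictToSet <- function(table, gene_set) {
    g <- table@genes[table@genes$gene_id %in% members(gene_set), ,
                     drop = FALSE]
    rownames(g) <- NULL
    new("ExpressionTable", sampleId = table@sampleId, genes = g)
}

#' Two-sample overlap statistics
#'
#' Computes shared/non-shared gene counts and percentages from both
#' perspectives, the share of each side's total TPM carried by its
#' non-shared genes, and — over the non-shared genes of the designated
#' side — the percentage annotated with each queried GO label. "Total
#' transcripts" denominators are the TPM sums of the cutoff-filtered
#' tables of the relevant side. With `restrict`, both tables are first
#' intersected with the gene set (and the matching recomputed).
#'
#' @param left,right cutoff-filtered [ExpressionTable-class] objects.
#' @param matching optional result of [matchGenes()] on the same two
#'   tables; computed internally when `NULL` or when `restrict` is given.
#' @param catalog optional [GeneCatalog-class], required for
#'   `annot_terms`.
#' @param restrict optional [GeneSet-class] to intersect both sides with.
#' @param orthologs optional ortholog map forwarded to [matchGenes()].
#' @param annot_terms GO labels to profile over non-shared genes.
#' @param annot_side `"left"` or `"right"`: whose non-shared genes the
#'   annotation fractions describe.
#' @return An [OverlapResult-class]; if a side is empty (e.g. after
#'   restriction) the result is flagged degenerate and percentages are
#'   `NA`.
#' @export
overlapStats <- function(left, right, matching = NULL, catalog = NULL,
                         restrict = NULL, orthologs = NULL,
                         annot_terms = character(),
                         annot_side = c("right", "left")) {
    annot_side <- match.arg(annot_side)
    if (!is.null(restrict)) {
        left <- .restrictToSet(left, restrict)
        right <- .restrictToSet(right, restrict)
        matching <- NULL
    }
    if (is.null(matching))
        matching <- matchGenes(left, right, orthologs)
    nL <- nGenes(left); nR <- nGenes(right)
    restricted_to <- if (is.null(restrict)) NA_character_
                     else setName(restrict)
    if (nL == 0L || nR == 0L)
        return(new("OverlapResult", nLeft = nL, nRight = nR,
                   nSharedLeft = 0, nSharedRight = 0,
                   pctSharedLeft = NA_real_, pctSharedRight = NA_real_,
                   tpmShareNonsharedLeft = NA_real_,
                   tpmShareNonsharedRight = NA_real_,
                   annotFractionNonshared = stats::setNames(numeric(),
                                                            character()),
                   annotSide = annot_side, restrictedTo = restricted_to,
                   degenerate = TRUE))
    tpmL <- tpm(left); tpmR <- tpm(right)
    shareL <- 100 * sum(tpmL[matching$left_only]) / sum(tpmL)
    shareR <- 100 * sum(tpmR[matching$right_only]) / sum(tpmR)
    af <- stats::setNames(numeric(), character())
    if (length(annot_terms)) {
        if (is.null(catalog))
            stop("annot_terms requires a catalog", call. = FALSE)
        ns_ids <- if (annot_side == "right") matching$right_only
                  else matching$left_only
        go <- catalog@entries$go_terms[match(ns_ids,
                                             catalog@entries$gene_id)]
        go <- lapply(go, function(t) if (is.null(t)) character()
                                     else tolower(t))
        af <- vapply(annot_terms, function(term) {
            if (!length(ns_ids)) return(NA_real_)
            100 * mean(vapply(go, function(t) tolower(term) %in% t,
                              logical(1)))
        }, numeric(1))
    }
    new("OverlapResult", nLeft = nL, nRight = nR,
        nSharedLeft = length(matching$shared_left),
        nSharedRight = length(matching$shared_right),
        pctSharedLeft = 100 * length(matching$shared_left) / nL,
        pctSharedRight = 100 * length(matching$shared_right) / nR,
        tpmShareNonsharedLeft = shareL, tpmShareNonsharedRight = shareR,
        annotFractionNonshared = af, annotSide = annot_side,
        restrictedTo = restricted_to, degenerate = FALSE)
}

# display rounding: half away from zero, so 89.6 -> 90 and 0.5 -> 1
.roundHalfAway <- function(x, digits = 0) {
    m <- 10^digits
    sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Render an overlap result as a Venn-style report
#'
#' Emits the three Venn counts (left-only, shared from the left
#' perspective, right-only) and both perspective percentages, formatted
#' both as whole percents (figure style, rounded half away from zero) and
#' to one decimal (text style); the underlying [OverlapResult-class]
#' retains full precision.
#'
#' @param result a non-degenerate [OverlapResult-class].
#' @return list with `counts` (named integer vector `left_only`, `shared`,
#'   `right_only`), `disjoint` flag, `pct_shared` (full precision, both
#'   perspectives), `display_pct` (e.g. `"97%"`), `display_pct_1dp`, and
#'   `tpm_share_nonshared` (1-decimal strings per side).
#' @export
renderOverlapReport <- function(result) {
    stopifnot(is(result, "OverlapResult"))
    if (result@degenerate)
        stop("cannot render a degenerate overlap result", call. = FALSE)
    counts <- c(left_only = result@nLeft - result@nSharedLeft,
                shared = result@nSharedLeft,
                right_only = result@nRight - result@nSharedRight)
    fmt0 <- function(p) sprintf("%d%%", as.integer(.roundHalfAway(p)))
    fmt1 <- function(p) sprintf("%.1f%%", .roundHalfAway(p, 1))
    list(counts = counts,
         disjoint = result@nSharedLeft == 0 && result@nSharedRight == 0,
         pct_shared = c(left = result@pctSharedLeft,
                        right = result@pctSharedRight),
         display_pct = c(left = fmt0(result@pctSharedLeft),
                         right = fmt0(result@pctSharedRight)),
         display_pct_1dp = c(left = fmt1(result@pctSharedLeft),
                             right = fmt1(result@pctSharedRight)),
         tpm_share_nonshared = c(left = fmt1(result@tpmShareNonsharedLeft),
                                 right = fmt1(result@tpmShareNonsharedRight)))
}
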