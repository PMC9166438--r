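# Reading and normalizing gene-level expression tables, and the study-wide
# TPM expression cutoff.

# strict numeric parsing: no silent zeroing, no locale decimal commas
.parseNumeric <- function(x, column, path) {
    x <- trimws(x)
    suppressWarnings(v <- as.numeric(x))
    bad <- which(is.na(v))
    if (length(bad))
        stop("format error in '", path, "': column '", column,
             "' has non-numeric value '", x[bad[1]], "' (row ", bad[1], ")",
             call. = FALSE)
    v
}

#' Read an RSEM-style gene quantification table
#'
#' Reads a tab-separated gene-level quantification file into an
#' [ExpressionTable-class]. The full RSEM `*.genes.results` layout
#' (`gene_id`, `transcript_id(s)`, `length`, `effective_length`,
#' `expected_count`, `TPM`, `FPKM`) and a minimal two-column
#' `gene_id`/`TPM` file are both accepted; only `gene_id` and `TPM` are
#' required. Lines starting with `#` are ignored. TPM values are taken
#' verbatim; malformed numeric cells raise an error rather than being
#' silently zeroed.
#'
#' @param path path to a TSV file.
#' @param sample_id sample label for the resulting table.
#' @return An [ExpressionTable-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\tTPM", "g1\t5.0", "g2\t0.0"), f)
#' readQuantTable(f, "demo")
#' @export
readQuantTable <- function(path, sample_id) {
    if (!file.exists(path))
        stop("quantification file not found: ", path, call. = FALSE)
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                             comment.char = "#", colClasses = "character",
                             check.names = FALSE, stringsAsFactors = FALSE)
    names(raw) <- trimws(names(raw))
    for (col in c("gene_id", "TPM"))
        if (!col %in% names(raw))
            stop("format error in '", path, "': missing required column '",
                 col, "'", call. = FALSE)
    gene_id <- trimws(raw$gene_id)
    dup <- unique(gene_id[duplicated(gene_id)])
    if (length(dup))
        stop("integrity error in '", path, "': duplicate gene_id: ",
             paste(dup, collapse = ", "), call. = FALSE)
    tpmv <- .parseNumeric(raw$TPM, "TPM", path)
    opt <- function(col) {
        if (col %in% names(raw)) .parseNumeric(raw[[col]], col, path)
        else NA_real_
    }
    symbol <- if ("symbol" %in% names(raw)) trimws(raw$symbol) else gene_id
    ExpressionTable(sample_id, gene_id, tpmv, symbol = symbol,
                    expected_count = opt("expected_count"),
                    effective_length = opt("effective_length"))
}

#' TPM normalization from expected counts and effective lengths
#'
#' The standard transcripts-per-million definition: per-gene read rate
#' c_i / l_i, scaled so the sample sums to one million,
#' `1e6 * (c_i/l_i) / sum_j(c_j/l_j)`.
#'
#' @param expected_counts non-negative numeric vector.
#' @param effective_lengths positive numeric vector (bases), same length.
#' @return numeric vector of TPM values summing to 1e6 (relative tolerance
#'   1e-9).
#' @examples
#' computeTpm(c(10, 10), c(100, 200))  # 2:1 split of 1e6
#' @export
computeTpm <- function(expected_counts, effective_lengths) {
    if (length(expected_counts) < 1L ||
        length(expected_counts) != length(effective_lengths))
        stop("expected_counts and effective_lengths must have equal length >= 1",
             call. = FALSE)
    if (any(!is.finite(effective_lengths)) || any(effective_lengths <= 0))
        stop("domain error: effective lengths must be positive", call. = FALSE)
    if (any(!is.finite(expected_counts)) || any(expected_counts < 0))
        stop("domain error: expected counts must be non-negative",
             call. = FALSE)
    if (all(expected_counts == 0))
        stop("degenerate input: all expected counts are zero", call. = FALSE)
    rate <- expected_counts / effective_lengths
    1e6 * rate / sum(rate)
}

#' Attach catalog symbols to an expression table
#'
#' Quantification files carry stable gene_ids but usually no symbols;
#' this replaces the table's symbols with the catalog's (matched by
#' gene_id), leaving genes absent from the catalog untouched. Symbol- and
#' ortholog-based matching (and SLC family parsing) need this step.
#'
#' @param table an [ExpressionTable-class].
#' @param catalog a [GeneCatalog-class].
#' @return The annotated [ExpressionTable-class].
#' @export
annotateSymbols <- function(table, catalog) {
    stopifnot(is(table, "ExpressionTable"), is(catalog, "GeneCatalog"))
    g <- table@genes
    idx <- match(g$gene_id, catalog@entries$gene_id)
    hit <- !is.na(idx)
    g$symbol[hit] <- catalog@entries$symbol[idx[hit]]
    new("ExpressionTable", sampleId = table@sampleId, genes = g)
}

#' Restrict an expression table to a biotype/seqname-filtered gene universe
#'
#' Restricts a sample's gene universe using catalog annotation: keep only
#' the requested biotypes (e.g. `"protein_coding"` for cross-species
#' comparisons) and drop excluded seqnames (e.g. `"MT"` to remove
#' mitochondrial genes). With `renormalize = TRUE` and counts/lengths
#' present, TPM is recomputed on the restricted universe — equivalent to
#' rebuilding the reference without those genes before quantification.
#'
#' @param table an [ExpressionTable-class].
#' @param catalog a [GeneCatalog-class] resolving the table's genes.
#' @param biotypes character vector of biotypes to keep, or `"all"`.
#' @param exclude_seqnames seqnames to drop (character vector, may be
#'   empty).
#' @param renormalize logical; recompute TPM from `expected_count` /
#'   `effective_length` on the retained genes.
#' @return A restricted [ExpressionTable-class].
#' @examples
#' et <- ExpressionTable("s", c("g1", "gMT"), c(5e5, 5e5),
#'                       expected_count = c(10, 10),
#'                       effective_length = c(100, 100))
#' cat <- GeneCatalog(c("g1", "gMT"), c("G1", "MTX"),
#'                    biotype = "protein_coding", seqname = c("1", "MT"))
#' restrictUniverse(et, cat, exclude_seqnames = "MT", renormalize = TRUE)
#' @export
restrictUniverse <- function(table, catalog, biotypes = "all",
                             exclude_seqnames = character(),
                             renormalize = FALSE) {
    stopifnot(is(table, "ExpressionTable"), is(catalog, "GeneCatalog"))
    g <- table@genes
    filtering <- !identical(biotypes, "all") || length(exclude_seqnames) > 0L
    e <- catalog@entries
    idx <- match(g$gene_id, e$gene_id)
    if (filtering && anyNA(idx)) {
        missing <- g$gene_id[is.na(idx)]
        stop("annotation gap: genes absent from catalog: ",
             paste(utils::head(missing, 10L), collapse = ", "),
             if (length(missing) > 10L) ", ...", call. = FALSE)
    }
    keep <- rep(TRUE, nrow(g))
    if (!identical(biotypes, "all")) {
        bt <- e$biotype[idx]
        gap <- g$gene_id[is.na(bt)]
        if (length(gap))
            stop("annotation gap: catalog lacks biotype for: ",
                 paste(utils::head(gap, 10L), collapse = ", "),
                 if (length(gap) > 10L) ", ...", call. = FALSE)
        keep <- keep & bt %in% biotypes
    }
    if (length(exclude_seqnames))
        keep <- keep & !(e$seqname[idx] %in% exclude_seqnames)
    g <- g[keep, , drop = FALSE]
    rownames(g) <- NULL
    if (renormalize && nrow(g) &&
        !anyNA(g$expected_count) && !anyNA(g$effective_length))
        g$tpm <- computeTpm(g$expected_count, g$effective_length)
    new("ExpressionTable", sampleId = table@sampleId, genes = g)
}

#' Apply the study-wide TPM expression cutoff
#'
#' Retains exactly the genes transcribed at or above `cutoff` TPM; genes
#' strictly below are excluded (a gene at exactly the cutoff is kept, the
#' literal reading of excluding levels "below" it). Idempotent.
#'
#' @param table an [ExpressionTable-class].
#' @param cutoff non-negative TPM threshold (default 0.5).
#' @return The filtered [ExpressionTable-class].
#' @examples
#' et <- ExpressionTable("s", c("g1", "g2", "g3"), c(0.49, 0.5, 7.2))
#' geneIds(applyExpressionCutoff(et))  # g2, g3
#' @export
applyExpressionCutoff <- function(table, cutoff = 0.5) {
    stopifnot(is(table, "ExpressionTable"))
    if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) ||
        cutoff < 0)
        stop("domain error: cutoff must be a single non-negative number",
             call. = FALSE)
    g <- table@genes[table@genes$tpm >= cutoff, , drop = FALSE]
    rownames(g) <- NULL
    new("ExpressionTable", sampleId = table@sampleId, genes = g)
}
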