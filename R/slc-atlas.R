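# Solute-carrier (SLC) family parsing and aggregation of plasma-membrane
# SLC genes into substrate supercategories with accumulated TPM.

#' Parse the SLC family from a gene symbol
#'
#' Symbols of the form `SLC<number>...` (case-insensitive) return family
#' `"SLC<number>"`; symbols starting with `SLCO` return the organic-anion
#' transporter family `"SLCO"` (historically SLC21, named per Bioparadigms
#' convention); anything else returns `NA`.
#'
#' @param symbol character vector of gene symbols.
#' @return character vector of family ids or `NA`.
#' @examples
#' parseSlcFamily(c("SLC22A17", "SLCO1C1", "ATP1B1"))
#' @export
parseSlcFamily <- function(symbol) {
    s <- toupper(as.character(symbol))
    out <- rep(NA_character_, length(s))
    is_o <- grepl("^SLCO", s)
    out[is_o] <- "SLCO"
    is_num <- !is_o & grepl("^SLC[0-9]", s)
    out[is_num] <- paste0("SLC", sub("^SLC0*([0-9]+).*$", "\\1", s[is_num]))
    out
}

#' Read an SLC family-to-supercategory grouping
#'
#' Two-column tab-separated config (`family`, `supercategory`). The
#' package ships a reconstructed default grouping of the SLC families into
#' 11 substrate supercategories as
#' `system.file("extdata", "slc_supercategories.tsv", package =
#' "transportome")`; it is configuration data and can be replaced.
#'
#' @param path TSV path; defaults to the shipped reconstructed grouping.
#' @return named character vector: family id -> supercategory name.
#' @export
readSlcGrouping <- function(path = system.file("extdata",
                                               "slc_supercategories.tsv",
                                               package = "transportome")) {
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                             comment.char = "#", colClasses = "character",
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (!all(c("family", "supercategory") %in% names(raw)))
        stop("format error in '", path,
             "': need columns family, supercategory", call. = FALSE)
    stats::setNames(trimws(raw$supercategory), toupper(trimws(raw$family)))
}

#' Summarise plasma-membrane SLC expression by supercategory
#'
#' Restricts the expression table to the plasma-membrane SLC gene set,
#' applies the expression cutoff, derives each gene's family from its
#' symbol, maps families to supercategories and aggregates: detected
#' families (those with at least one gene at or above the cutoff), gene
#' counts and accumulated TPM, sorted by accumulated TPM descending.
#' Families without a grouping entry fall into an explicit `"ungrouped"`
#' bucket with a warning.
#'
#' @param table an [ExpressionTable-class].
#' @param pm_slc [GeneSet-class] of plasma-membrane SLC genes (gene_ids in
#'   the table's space).
#' @param grouping named character vector family -> supercategory, see
#'   [readSlcGrouping()].
#' @param cutoff TPM expression cutoff (default 0.5).
#' @return data.frame with columns `supercategory`, `n_families`,
#'   `families` (pipe-separated), `n_genes`, `accumulated_tpm`.
#' @export
summarizeSupercategories <- function(table, pm_slc,
                                     grouping = readSlcGrouping(),
                                     cutoff = 0.5) {
    stopifnot(is(table, "ExpressionTable"), is(pm_slc, "GeneSet"))
    et <- applyExpressionCutoff(table, cutoff)
    g <- et@genes[et@genes$gene_id %in% members(pm_slc), , drop = FALSE]
    fam <- parseSlcFamily(g$symbol)
    if (anyNA(fam)) {
        warning("dropping non-SLC symbols from supercategory summary: ",
                paste(utils::head(g$symbol[is.na(fam)], 10L),
                      collapse = ", "))
        g <- g[!is.na(fam), , drop = FALSE]
        fam <- fam[!is.na(fam)]
    }
    sc <- unname(grouping[fam])
    if (anyNA(sc)) {
        warning("families without supercategory grouping: ",
                paste(unique(fam[is.na(sc)]), collapse = ", "),
                " (assigned to 'ungrouped')")
        sc[is.na(sc)] <- "ungrouped"
    }
    if (!nrow(g))
        return(data.frame(supercategory = character(),
                          n_families = integer(), families = character(),
                          n_genes = integer(), accumulated_tpm = numeric(),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, lapply(split(seq_along(sc), sc), function(i) {
        fams <- sort(unique(fam[i]))
        data.frame(supercategory = sc[i[1]],
                   n_families = length(fams),
                   families = paste(fams, collapse = "|"),
                   n_genes = length(i),
                   accumulated_tpm = sum(g$tpm[i]),
                   stringsAsFactors = FALSE)
    }))
    out <- out[order(-out$accumulated_tpm, out$supercategory), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Bubble-plot layout for supercategory summaries
#'
#' Quantitative layout data for the supercategory bubble figure: circle
#' areas proportional to accumulated TPM, normalized to sum to 1, with
#' radii `sqrt(area / pi)`.
#'
#' @param summaries data.frame from [summarizeSupercategories()].
#' @return data.frame with `supercategory`, `accumulated_tpm`, `area`
#'   (sums to 1 within 1e-12) and `radius`.
#' @export
bubbleLayout <- function(summaries) {
    stopifnot(is.data.frame(summaries),
              all(c("supercategory", "accumulated_tpm") %in%
                  names(summaries)))
    tot <- sum(summaries$accumulated_tpm)
    if (!nrow(summaries) || tot <= 0)
        stop("degenerate layout: no supercategory with positive TPM",
             call. = FALSE)
    area <- summaries$accumulated_tpm / tot
    data.frame(supercategory = summaries$supercategory,
               accumulated_tpm = summaries$accumulated_tpm,
               area = area, radius = sqrt(area / pi),
               stringsAsFactors = FALSE)
}
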