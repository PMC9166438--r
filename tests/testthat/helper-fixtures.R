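# Shared in-code fixtures: tiny expression tables, catalogs and a small
# synthetic truth for the planted-recovery tests.

makeTable <- function(ids, tpms, sample_id = "s", symbols = toupper(ids),
                      counts = NA_real_, lengths = NA_real_) {
    ExpressionTable(sample_id, ids, tpms, symbol = symbols,
                    expected_count = counts, effective_length = lengths)
}

makeCatalog <- function(symbols, go = rep(list(character()),
                                          length(symbols)),
                        biotype = "protein_coding", seqname = "1",
                        alias = NA_character_,
                        ids = paste0("id_", symbols)) {
    GeneCatalog(ids, symbols, alias = alias, biotype = biotype,
                seqname = seqname, go_terms = go)
}

writeTsv <- function(df, path = tempfile(fileext = ".tsv")) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

# scaled-down synthetic study used across recovery tests
smallTruth <- function(seed = 7L) {
    syntheticTruth(seed = seed, n_left = 1000L, n_right = 950L,
                   shared_fraction = 89, n_subthreshold = 50L,
                   n_ortholog_bridges = 40L)
}

# map a GeneSet's members back to catalog symbols
setSymbols <- function(gene_set, catalog) {
    e <- catalogEntries(catalog)
    sort(e$symbol[match(members(gene_set), e$gene_id)])
}

# write the synthetic category sources and return default rules over them
rulesFromSources <- function(sources, dir = tempfile()) {
    dir.create(dir)
    paths <- list()
    for (nm in names(sources))
        paths[[nm]] <- writeTsv(sources[[nm]],
                                file.path(dir, paste0(nm, ".tsv")))
    defaultCategoryRules(paths)
}

fixturePath <- function(name)
    system.file("extdata", name, package = "transportome")
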