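# Shared fixtures: full pipeline runs are expensive, so each (seed, n_genes)
# combination is computed once per test session and cached.

.screen_cache <- new.env(parent = emptyenv())

cached_screen <- function(seed, n_genes = 27L) {
  key <- sprintf("s%d_g%d", seed, n_genes)
  if (is.null(.screen_cache[[key]]))
    .screen_cache[[key]] <- run_candidate_screen(scenario_spec(seed, n_genes))
  .screen_cache[[key]]
}

# normalize a planted truth set into the shape detect_variants() reports
normalized_truth <- function(res) {
  tr <- res$truth
  out <- do.call(rbind, lapply(seq_len(nrow(tr)), function(i)
    left_normalize(tr[i, c("contig", "pos", "ref", "alt")], res$reference)))
  out$genotype <- ifelse(tr$zygosity == "hom", "hom", "het")
  out[order(out$contig, out$pos), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

scenario_gene_ids_for <- function(spec, category) {
  sprintf("GENE%02d", which(spec$category_plan == category))
}

# independent translation oracle: Biostrings translation of the full CDS,
# truncated at the first stop by string inspection (never the package's own
# codon stepper)
oracle_translate <- function(cds) {
  n <- 3L * (nchar(cds) %/% 3L)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1L, n)), no.init.codon = TRUE))
  sub("\\*.*$", "", aa)
}
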