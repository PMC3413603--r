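make_pileup <- function(base_calls, events = NULL) {
  bc <- data.table::as.data.table(base_calls)
  data.table::setkey(bc, contig, pos)
  ev <- if (is.null(events))
    data.table::data.table(contig = character(0), pos = integer(0),
                           type = character(0), len = integer(0),
                           seq = character(0), count = integer(0))
  else data.table::as.data.table(events)
  structure(list(base_calls = bc, events = ev, regions = NULL),
            class = "pileup")
}

test_that("coverage census counts complete genes and reports uncovered intervals", {
  res <- cached_screen(3, n_genes = 3)
  # an empty pileup leaves every gene incomplete
  empty <- make_pileup(data.frame(contig = character(0), pos = integer(0),
                                  call = character(0), count = integer(0)))
  cen0 <- coverage_census(empty, res$models)
  expect_identical(sum(cen0$coverage_status == "complete"), 0L)

  # single gene with one exonic base at depth 0: a 1-base uncovered interval
  models <- gene_models(
    data.frame(gene_id = "G", contig = "c", strand = "+", start = 1L,
               end = 10L, utr5_len = 0L, cds_len = 9L, utr3_len = 1L),
    data.frame(gene_id = "G", exon_rank = 1L, start = 1L, end = 10L))
  bc <- data.frame(contig = "c", pos = setdiff(1:10, 6L), call = "A",
                   count = 1L)
  cen1 <- coverage_census(make_pileup(bc), models)
  expect_identical(cen1$coverage_status, "incomplete")
  unc <- attr(cen1, "uncovered")
  expect_identical(unc$start, 6L)
  expect_identical(unc$end, 6L)

  # a gene model without exons is a named error
  models_bad <- models
  models_bad$exons <- models_bad$exons[0L, ]
  expect_error(coverage_census(make_pileup(bc), models_bad), "no exons")
})

test_that("left-normalization shifts repeat indels, is idempotent, and matches enumeration", {
  unit <- "ACGTACGT"
  ref <- list(ctg = paste0("TTGCA", unit, unit, "GGTCCA"))
  # deletion of the 3' copy (bases 14..21), anchored at 13
  v <- data.frame(contig = "ctg", pos = 13L,
                  ref = substr(ref$ctg, 13L, 21L),
                  alt = substr(ref$ctg, 13L, 13L), stringsAsFactors = FALSE)
  n1 <- left_normalize(v, ref)
  expect_identical(n1$pos, 5L)    # anchor moves 8 bases left
  expect_identical(left_normalize(n1, ref), n1)   # idempotent

  # brute-force oracle: enumerate all placements of an 8 bp deletion that
  # give the same edited sequence; the normalized anchor must be leftmost
  apply_del <- function(seq, start, len)
    paste0(substr(seq, 1L, start - 1L), substr(seq, start + len, nchar(seq)))
  target <- apply_del(ref$ctg, 14L, 8L)
  equivalent <- which(vapply(1:(nchar(ref$ctg) - 8L), function(s)
    apply_del(ref$ctg, s, 8L) == target, TRUE))
  expect_identical(n1$pos + 1L, min(equivalent))

  # SNV and repeat-free deletion pass through unchanged
  snv <- data.frame(contig = "ctg", pos = 3L, ref = "G", alt = "T")
  expect_identical(left_normalize(snv, ref), snv)
  ref2 <- list(ctg = "TTGACGTACGCAGGTT")
  d2 <- data.frame(contig = "ctg", pos = 4L,
                   ref = substr(ref2$ctg, 4L, 7L), alt = "A")
  expect_identical(left_normalize(d2, ref2), d2)

  # allele/reference mismatch is a named error
  bad <- data.frame(contig = "ctg", pos = 3L, ref = "AAAA", alt = "A")
  expect_error(left_normalize(bad, ref), "mismatch")
})

test_that("variant detection applies depth and allele-fraction thresholds", {
  ref <- list(c = strrep("A", 60))
  # all-reference pileup: no calls
  bc_ref <- data.frame(contig = "c", pos = 1:50, call = "A", count = 30L)
  expect_identical(nrow(detect_variants(make_pileup(bc_ref), ref)), 0L)

  # 50/50 two-allele column at depth 30: heterozygous call
  bc_het <- rbind(bc_ref,
                  data.frame(contig = "c", pos = 25L, call = "G", count = 15L))
  bc_het$count[bc_het$pos == 25L & bc_het$call == "A"] <- 15L
  calls <- detect_variants(make_pileup(bc_het), ref)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$genotype, "het")
  expect_identical(calls$alt, "G")

  # sub-threshold evidence stays silent; full fraction is homozygous
  bc_low <- rbind(bc_ref,
                  data.frame(contig = "c", pos = 10L, call = "T", count = 3L))
  expect_identical(nrow(detect_variants(make_pileup(bc_low), ref)), 0L)
  bc_hom <- data.frame(contig = "c", pos = 5L, call = "C", count = 25L)
  callh <- detect_variants(make_pileup(bc_hom), ref)
  expect_identical(callh$genotype, "hom")
})

test_that("detection recovers the planted truth on clean simulations", {
  for (s in c(1, 2, 3, 4, 5, 6)) {
    res <- cached_screen(s, n_genes = 4)
    truth <- normalized_truth(res)
    calls <- res$calls[order(res$calls$contig, res$calls$pos),
                       c("contig", "pos", "ref", "alt", "genotype")]
    rownames(calls) <- rownames(truth) <- NULL
    expect_identical(calls, truth[, names(calls)],
                     label = sprintf("seed %d", s))
  }
})

test_that("coding annotation classifies effects via the codon table", {
  res <- cached_screen(3, n_genes = 3)
  calls <- res$calls
  tr <- res$truth
  # planted coding SNVs: emitted residue annotations match the truth
  for (i in which(tr$type == "snv" & !is.na(tr$codon_index))) {
    hit <- calls[calls$contig == tr$contig[i] & calls$pos == tr$pos[i], ]
    expect_identical(hit$codon_index, tr$codon_index[i])
    expect_identical(hit$ref_aa, tr$ref_aa[i])
    expect_identical(hit$alt_aa, tr$alt_aa[i])
    expect_identical(hit$hgvs_p,
                     sprintf("p.%s%d%s", tr$ref_aa[i], tr$codon_index[i],
                             tr$alt_aa[i]))
  }
  # the 8 bp CDS deletion is a frameshift
  del <- calls[calls$type == "del", ]
  expect_identical(del$effect, "frameshift")
  expect_identical(del$region, "cds")
  # synonymous SNVs are recognized as such
  syn <- calls[!is.na(calls$ref_aa) & calls$ref_aa == calls$alt_aa, ]
  expect_true(all(syn$effect == "synonymous"))
})

test_that("the filter cascade reproduces the study classification and is order-stable", {
  res <- cached_screen(1)   # full 27-gene study plan
  reports <- res$reports
  cc <- category_counts(reports, complete_only = TRUE)
  expect_identical(unname(cc[["candidate_causal"]]), 1L)
  cand <- reports$gene_id[reports$category == "candidate_causal"]
  cv <- res$calls[!is.na(res$calls$gene_id) & res$calls$gene_id == cand, ]
  expect_true(any(cv$type == "del" &
                    nchar(cv$ref) - nchar(cv$alt) == 8L &
                    cv$genotype == "hom"))
  # categories partition the gene set
  expect_identical(sum(category_counts(reports)), nrow(res$models$genes))

  # shuffling variant input order never changes a category
  set.seed(17)
  shuffled <- res$calls[sample(nrow(res$calls)), ]
  rep2 <- filter_cascade(shuffled, res$models, res$conservation, res$census)
  expect_identical(rep2$category[order(rep2$gene_id)],
                   reports$category[order(reports$gene_id)])

  # all genes variant-free -> all no_polymorphisms
  rep0 <- filter_cascade(res$calls[0L, ], res$models, res$conservation)
  expect_true(all(rep0$category == "no_polymorphisms"))

  # a variant in a gene missing from the models is a named error
  alien <- res$calls[1L, ]
  alien$gene_id <- "GENE99"
  expect_error(filter_cascade(alien, res$models, res$conservation),
               "absent from the gene models")
})

test_that("a missense whose alternate residue pervades the ortholog panel is excluded", {
  # hand-built conservation matrix: the alternate residue is present in all
  # five orthologs at codon 10 (the conserved-alternate situation)
  cons <- structure(list(panels = list(
    G1 = matrix(rep(strsplit("MKKKKKKKKQKKKKK", "")[[1L]], each = 5),
                nrow = 5)), n_orthologs = 5), class = "conservation_matrix")
  expect_true(residue_observed(cons, "G1", 10L, "Q"))
  expect_false(residue_observed(cons, "G1", 10L, "W"))

  models <- gene_models(
    data.frame(gene_id = "G1", contig = "c", strand = "+", start = 1L,
               end = 45L, utr5_len = 0L, cds_len = 45L, utr3_len = 0L),
    data.frame(gene_id = "G1", exon_rank = 1L, start = 1L, end = 45L))
  v <- data.frame(contig = "c", pos = 28L, ref = "A", alt = "C",
                  genotype = "hom", type = "snv", depth = 30L,
                  alt_count = 30L, gene_id = "G1", region = "cds",
                  effect = "missense", codon_index = 10L, ref_aa = "K",
                  alt_aa = "Q", hgvs_c = "c.28A>C", hgvs_p = "p.K10Q")
  rep <- filter_cascade(v, models, cons)
  expect_identical(rep$category, "excluded_nonsynonymous_tolerated")
  # a non-tolerated missense in the same spot is the causal candidate
  v2 <- v; v2$alt_aa <- "W"; v2$hgvs_p <- "p.K10W"
  expect_identical(filter_cascade(v2, models, cons)$category,
                   "candidate_causal")
})
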