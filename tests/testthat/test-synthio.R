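test_that("reference construction is seed-deterministic and structurally valid", {
  spec <- scenario_spec(seed = 1, n_genes = 27)
  b1 <- build_reference(spec)
  b2 <- build_reference(spec)
  td <- withr::local_tempdir()
  f1 <- file.path(td, "a.fa"); f2 <- file.path(td, "b.fa")
  write_fasta(b1$reference, f1); write_fasta(b2$reference, f2)
  g1 <- file.path(td, "a.gff3"); g2 <- file.path(td, "b.gff3")
  write_gff3(b1$models, g1); write_gff3(b2$models, g2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(g1), readLines(g2))

  expect_identical(nrow(b1$models$genes), 27L)
  for (g in b1$models$genes$gene_id) {
    gi <- b1$models$genes[b1$models$genes$gene_id == g, ]
    expect_identical(gi$cds_len %% 3L, 0L)
    cds <- gene_cds(b1$reference, b1$models, g)
    expect_identical(substr(cds, 1, 3), "ATG")
    # >= 2 exons per gene
    expect_gte(sum(b1$models$exons$gene_id == g), 2L)
  }
})

test_that("every CDS translates without an internal stop (independent oracle)", {
  b <- build_reference(scenario_spec(seed = 2, n_genes = 3))
  for (g in b$models$genes$gene_id) {
    cds <- gene_cds(b$reference, b$models, g)
    prot <- oracle_translate(cds)
    # the oracle truncates at the first stop; a clean CDS loses only the
    # terminal stop codon
    expect_identical(nchar(prot), nchar(cds) %/% 3L - 1L)
  }
})

test_that("the generator rejects read lengths longer than the shortest exon", {
  spec <- scenario_spec(seed = 1, n_genes = 2, read_length = 5000L)
  expect_error(build_reference(spec), "shortest exon")
})

test_that("planted truth sets honour the category plan", {
  spec <- scenario_spec(seed = 4)   # 27-gene study plan
  b <- build_reference(spec)
  p <- plant_variants(b$reference, b$models, spec)
  tr <- p$variants
  dels <- tr[tr$type == "del", ]
  expect_identical(nrow(dels), 1L)
  expect_identical(nchar(dels$ref) - nchar(dels$alt), 8L)
  expect_identical(dels$zygosity, "hom")
  expect_identical(dels$region, "exonic_cds")
  # the linked SNV sits exactly 18 bases downstream of the deleted sequence
  snv_linked <- tr[tr$gene_id == dels$gene_id & tr$type == "snv", ]
  expect_identical(snv_linked$pos, dels$del_end + 18L)
  expect_identical(snv_linked$zygosity, "hom")

  # tandem repeat: the 8 bases 5' of the deletion equal the deleted bases
  ctg <- p$reference[[dels$contig]]
  expect_identical(substr(ctg, dels$del_start - 8L, dels$del_start - 1L),
                   substr(ctg, dels$del_start, dels$del_end))

  # all-none plan yields an empty truth set
  spec0 <- scenario_spec(seed = 4, n_genes = 5,
                         category_plan = rep("none", 5),
                         coverage_plan = rep(TRUE, 5))
  b0 <- build_reference(spec0)
  expect_identical(nrow(plant_variants(b0$reference, b0$models,
                                       spec0)$variants), 0L)
})

test_that("planted synonymous SNVs leave the protein unchanged (codon-table oracle)", {
  spec <- scenario_spec(seed = 6)
  b <- build_reference(spec)
  p <- plant_variants(b$reference, b$models, spec)
  tr <- p$variants
  syn_genes <- scenario_gene_ids_for(spec, "synonymous_snv")
  syn <- tr[tr$gene_id %in% syn_genes, ]
  expect_identical(nrow(syn), 2L)
  for (k in seq_len(nrow(syn))) {
    g <- syn$gene_id[k]
    cds <- gene_cds(p$reference, b$models, g)
    cr <- recscreen:::cds_tx_range(b$models, g)
    cds_pos <- syn$tx_pos[k] - cr["start"] + 1L
    mut <- cds
    substr(mut, cds_pos, cds_pos) <- syn$alt[k]
    expect_identical(oracle_translate(mut), oracle_translate(cds))
  }
})

test_that("simulated reads are transcript substrings carrying planted alleles", {
  spec <- scenario_spec(seed = 9, n_genes = 2, mean_depth = 1)
  b <- build_reference(spec)
  p <- plant_variants(b$reference, b$models, spec)
  reads <- simulate_reads(p$reference, b$models, p$variants, spec)
  for (g in unique(reads$reads$gene_id)) {
    tx <- gene_transcript(p$reference, b$models, g)
    gv <- p$variants[p$variants$gene_id == g, , drop = FALSE]
    hapA <- recscreen:::apply_variants_tx(tx, gv[gv$zygosity == "hom", ,
                                                 drop = FALSE])
    hapB <- recscreen:::apply_variants_tx(tx, gv)
    r <- reads$reads[reads$reads$gene_id == g, ]
    for (i in seq_len(nrow(r))) {
      hap <- if (r$hap[i] == "A") hapA else hapB
      expect_true(grepl(r$seq1[i], hap, fixed = TRUE))
      expect_true(grepl(recscreen:::revcomp(r$seq2[i]), hap, fixed = TRUE))
    }
  }
})

test_that("zygosity is conserved in emitted reads", {
  # homozygous deletion: no read supports the undeleted allele
  spec <- scenario_spec(seed = 3, n_genes = 1,
                        category_plan = "causal_frameshift_deletion",
                        coverage_plan = TRUE)
  b <- build_reference(spec)
  p <- plant_variants(b$reference, b$models, spec)
  reads <- simulate_reads(p$reference, b$models, p$variants, spec)
  del <- p$variants[p$variants$type == "del", ]
  tx <- gene_transcript(p$reference, b$models, del$gene_id)
  undeleted <- substr(tx, del$tx_pos - 10L, del$tx_pos + nchar(del$ref) + 2L)
  for (s in c(reads$reads$seq1, recscreen:::revcomp(reads$reads$seq2)))
    expect_false(grepl(undeleted, s, fixed = TRUE))

  # heterozygous SNV: per-fragment allele draw converges to 0.5
  spec2 <- scenario_spec(seed = 8, n_genes = 1,
                         category_plan = "heterozygous_snv",
                         coverage_plan = TRUE, mean_depth = 1500)
  b2 <- build_reference(spec2)
  p2 <- plant_variants(b2$reference, b2$models, spec2)
  reads2 <- simulate_reads(p2$reference, b2$models, p2$variants, spec2)
  v <- p2$variants[1L, ]
  count_allele <- function(seqs, starts, allele) {
    covers <- starts <= v$tx_pos & starts + nchar(seqs) - 1L >= v$tx_pos
    base <- substr(seqs[covers], v$tx_pos - starts[covers] + 1L,
                   v$tx_pos - starts[covers] + 1L)
    sum(base == allele)
  }
  r <- reads2$reads
  s2_start <- r$start + r$frag_len - nchar(r$seq2)
  n_alt <- count_allele(r$seq1, r$start, v$alt) +
    count_allele(recscreen:::revcomp(r$seq2), s2_start, v$alt)
  n_ref <- count_allele(r$seq1, r$start, v$ref) +
    count_allele(recscreen:::revcomp(r$seq2), s2_start, v$ref)
  expect_gte(n_alt + n_ref, 1000L)
  bt <- stats::binom.test(n_alt, n_alt + n_ref, p = 0.5)
  expect_gte(bt$p.value, 0.001)
})

test_that("coverage plan is realized exactly in the emitted reads", {
  spec <- scenario_spec(seed = 12, n_genes = 4,
                        category_plan = rep("none", 4),
                        coverage_plan = c(TRUE, TRUE, FALSE, TRUE))
  b <- build_reference(spec)
  p <- plant_variants(b$reference, b$models, spec)
  reads <- simulate_reads(p$reference, b$models, p$variants, spec)
  # recount transcript coverage from the fragment coordinates themselves
  for (i in seq_len(4)) {
    g <- sprintf("GENE%02d", i)
    L <- nchar(gene_transcript(p$reference, b$models, g))
    cov <- logical(L)
    r <- reads$reads[reads$reads$gene_id == g, ]
    rl <- reads$read_length
    for (k in seq_len(nrow(r))) {
      cov[r$start[k]:(r$start[k] + rl - 1L)] <- TRUE
      e <- r$start[k] + r$frag_len[k] - 1L
      cov[(e - rl + 1L):e] <- TRUE
    }
    if (spec$coverage_plan[i]) {
      expect_true(all(cov), label = sprintf("%s fully covered", g))
    } else {
      win <- reads$uncovered_windows
      win <- win[win$gene_id == g, ]
      expect_false(any(cov[win$tx_start:win$tx_end]))
      expect_gte(win$tx_end - win$tx_start + 1L, rl)
    }
  }
})

test_that("fragment-analysis panels have the specified composition", {
  p145 <- simulate_panel(145, n_carriers = 8, seed = 7)
  expect_identical(nrow(p145), 145L)
  expect_identical(sum(!is.na(p145$peak2)), 8L)
  expect_identical(sum(p145$truth_genotype == "wt/del"), 8L)

  p1 <- simulate_panel(1, n_carriers = 1, size_noise_sd = 0, seed = 1)
  expect_identical(sort(c(p1$peak1, p1$peak2)), c(260, 268))

  p513 <- simulate_panel(513, n_carriers = 0, seed = 2)
  expect_true(all(is.na(p513$peak2)))
  expect_true(all(abs(p513$peak1 - 268) < 1))

  expect_error(simulate_panel(5, n_carriers = 6), "exceeds")
  expect_error(simulate_panel(5, 0, wt_size = 268, del_size = 250),
               "8 bp shorter")
})

test_that("simulated qPCR plates follow the efficiency model", {
  # true fold change 1, no noise: case and control Cts identical
  q1 <- simulate_qpcr(fold_change = 1, noise_sd = 0, seed = 1)
  ctl <- q1$plate[q1$plate$sample == "control", ]
  cse <- q1$plate[q1$plate$sample == "case", ]
  expect_equal(cse$ct, ctl$ct)

  # E = 1, fold 68: target dCt is exactly log2(68)
  q68 <- simulate_qpcr(fold_change = 68, efficiencies = c(t = 1, r = 1),
                       noise_sd = 0, seed = 1)
  agg <- stats::aggregate(ct ~ sample + assay, q68$plate, mean)
  dct <- function(a) agg$ct[agg$sample == "case" & agg$assay == a] -
    agg$ct[agg$sample == "control" & agg$assay == a]
  expect_equal(dct("t"), log2(68))
  expect_equal(dct("r"), 0)

  # dilution series at 100% efficiency: +1 Ct per twofold dilution
  dil <- q68$dilution[q68$dilution$assay == "t", ]
  expect_equal(diff(dil$ct[order(-dil$log2_quantity)]), rep(1, 6))
})

test_that("truth sets round-trip through VCF", {
  res <- cached_screen(3, n_genes = 3)
  tr <- res$truth
  vdf <- data.frame(contig = tr$contig, pos = tr$pos, ref = tr$ref,
                    alt = tr$alt,
                    genotype = ifelse(tr$zygosity == "hom", "hom", "het"),
                    stringsAsFactors = FALSE)
  f <- file.path(withr::local_tempdir(), "truth.vcf")
  write_vcf(vdf, f)
  expect_identical(read_vcf(f), vdf)
})
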