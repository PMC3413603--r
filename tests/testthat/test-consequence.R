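random_cds <- function(n_codons, seed) {
  set.seed(seed)
  sense <- recscreen:::sense_codons()
  paste0("ATG", paste(sample(sense, n_codons - 2L, TRUE), collapse = ""),
         "TAA")
}

test_that("no variants means identity: no aberrant run, no truncation", {
  cds <- random_cds(60, 1)
  rep <- apply_and_translate(cds, data.frame(pos = integer(0),
                                             ref = character(0),
                                             alt = character(0)))
  expect_identical(rep$mutant_protein, rep$wildtype_protein)
  expect_identical(rep$aberrant_run_length, 0L)
  expect_identical(rep$truncation_length, 0L)
  expect_false(rep$non_stop)
})

test_that("a downstream stop-destroying SNV lengthens the aberrant run of a frameshift", {
  # search a deterministic space of CDSs for the layered situation: an 8 bp
  # deletion creating a premature stop whose codon can be destroyed by a
  # later SNV, pushing termination further downstream
  found <- FALSE
  for (seed in 1:60) {
    cds <- random_cds(120, seed)
    del_start <- 100L
    del <- data.frame(pos = del_start - 1L,
                      ref = substr(cds, del_start - 1L, del_start + 7L),
                      alt = substr(cds, del_start - 1L, del_start - 1L))
    r1 <- apply_and_translate(cds, del)
    if (r1$non_stop || r1$aberrant_run_length < 1L) next
    # locate the premature stop codon of the shifted frame in wt coordinates
    mut_cds <- recscreen:::apply_variants_cds(cds, del)
    stop_m <- 3L * (nchar(r1$mutant_protein) + 1L) - 2L  # first stop base
    wt_pos <- stop_m + 8L   # downstream of the deletion: shift back by 8
    fixed <- FALSE
    for (off in 0:2) {
      for (alt in setdiff(c("A", "C", "G", "T"),
                          substr(cds, wt_pos + off, wt_pos + off))) {
        snv <- data.frame(pos = wt_pos + off,
                          ref = substr(cds, wt_pos + off, wt_pos + off),
                          alt = alt)
        mut2 <- recscreen:::apply_variants_cds(cds, rbind(del, snv))
        stop_codon <- substr(mut2, stop_m, stop_m + 2L)
        if (!stop_codon %in% c("TAA", "TAG", "TGA")) {
          r2 <- apply_and_translate(cds, rbind(del, snv))
          expect_gt(r2$aberrant_run_length, r1$aberrant_run_length)
          # both reports agree with the independent translation oracle
          expect_identical(r1$mutant_protein, oracle_translate(mut_cds))
          expect_identical(r2$mutant_protein, oracle_translate(mut2))
          expect_identical(
            nchar(r2$wildtype_protein),
            (r2$first_aberrant_residue_index - 1L) +
              r2$aberrant_run_length + r2$truncation_length)
          fixed <- TRUE
        }
        if (fixed) break
      }
      if (fixed) break
    }
    if (fixed) { found <- TRUE; break }
  }
  expect_true(found)
})

test_that("a deletion creating an immediate stop gives a zero-length aberrant run", {
  # CCC CCC ... ; deleting 2 bases ahead of TA A.. exposes a stop right away
  cds <- paste0("ATG", "AAAAAG", "TTAACC", "AAATAA")
  # delete "AG" (positions 8..9, anchored at 7): frame shifts so that codon 3
  # starts at T TA A...
  del <- data.frame(pos = 7L, ref = substr(cds, 7, 9), alt = substr(cds, 7, 7))
  rep <- apply_and_translate(cds, del)
  mut <- recscreen:::apply_variants_cds(cds, del)
  expect_identical(rep$mutant_protein, oracle_translate(mut))
  if (nchar(rep$mutant_protein) <= rep$first_aberrant_residue_index - 1L)
    expect_identical(rep$aberrant_run_length, 0L)
})

test_that("overlapping and out-of-range variants are named errors", {
  cds <- random_cds(30, 2)
  v1 <- data.frame(pos = c(10L, 12L), ref = c(substr(cds, 10, 14), "X"),
                   alt = c(substr(cds, 10, 10), "A"))
  v1$ref[2] <- substr(cds, 12, 12)
  expect_error(apply_and_translate(cds, v1), "overlapping")
  v2 <- data.frame(pos = 5000L, ref = "A", alt = "T")
  expect_error(apply_and_translate(cds, v2), "outside the CDS")
  expect_error(apply_and_translate("TTTAAA", v2[0L, ]), "ATG")
})

test_that("anchor-insertion notation parses, emits and converts to HGVS", {
  p <- parse_ins_notation("p.G1952insRDRGQGRPLLLMHRHGAGAACQEPLCS*")
  expect_identical(p$run_length, 27L)
  expect_true(p$terminated)
  expect_identical(p$anchor_aa, "G")
  expect_identical(p$anchor_index, 1952L)

  p0 <- parse_ins_notation("p.G1ins*")
  expect_identical(p0$run_length, 0L)
  expect_true(p0$terminated)

  expect_error(parse_ins_notation("p.G12fsTer3"), "malformed")

  # parse -> emit identity over random annotations
  set.seed(5)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  for (i in 1:25) {
    txt <- paste0("p.", sample(aa, 1), sample(1:5000, 1), "ins",
                  paste(sample(aa, sample(0:30, 1), TRUE), collapse = ""),
                  if (i %% 2) "*" else "")
    q <- parse_ins_notation(txt)
    expect_identical(emit_ins_notation(q$anchor_aa, q$anchor_index,
                                       q$peptide, q$terminated), txt)
  }

  expect_identical(ins_notation_to_hgvs("p.G1952insRDRGQGRPLLLMHRHGAGAACQEPLCS*"),
                   "p.R1953fsTer28")
})

test_that("in-silico PCR reports exact products and tracks deletion alleles", {
  fwd <- "TACTGGACACCACGGACAAGT"            # 21-mer
  rev <- "GGCCTCTATCTCTGCCTTGAT"            # 21-mer
  set.seed(3)
  spacer <- paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = "")
  tpl <- paste0(fwd, spacer, recscreen:::revcomp(rev))
  pr <- in_silico_pcr(tpl, fwd, rev)
  expect_identical(pr$size, 52L)

  # wild-type vs deletion templates: product sizes differ by exactly 8
  mid <- paste(sample(c("A", "C", "G", "T"), 226, TRUE), collapse = "")
  wt_tpl <- paste0(fwd, mid, recscreen:::revcomp(rev))    # 268 bp product
  del_tpl <- paste0(fwd, substr(mid, 1, 100), substr(mid, 109, 226),
                    recscreen:::revcomp(rev))
  s_wt <- in_silico_pcr(wt_tpl, fwd, rev)$size
  s_del <- in_silico_pcr(del_tpl, fwd, rev)$size
  expect_identical(s_wt, 268L)
  expect_identical(s_wt - s_del, 8L)

  # no binding: empty result, not an error
  expect_identical(nrow(in_silico_pcr(strrep("A", 100), fwd, rev)), 0L)
  expect_error(in_silico_pcr(tpl, "ACGT", rev), "15")
})

test_that("translation matches the oracle on random CDS+variant sets and in-frame indels stay in frame", {
  set.seed(77)
  for (i in 1:12) {
    cds <- random_cds(sample(50:300, 1), seed = 1000 + i)
    n <- nchar(cds)
    nv <- sample(0:3, 1)
    pos <- sort(sample(seq(10L, n - 30L, by = 25L), nv))
    vars <- do.call(rbind, lapply(pos, function(p) {
      kind <- sample(c("snv", "del", "ins"), 1)
      if (kind == "snv") {
        data.frame(pos = p, ref = substr(cds, p, p),
                   alt = sample(setdiff(c("A", "C", "G", "T"),
                                        substr(cds, p, p)), 1))
      } else if (kind == "del") {
        len <- sample(1:9, 1)
        data.frame(pos = p, ref = substr(cds, p, p + len),
                   alt = substr(cds, p, p))
      } else {
        ins <- paste(sample(c("A", "C", "G", "T"), sample(1:9, 1), TRUE),
                     collapse = "")
        data.frame(pos = p, ref = substr(cds, p, p),
                   alt = paste0(substr(cds, p, p), ins))
      }
    }))
    if (is.null(vars))
      vars <- data.frame(pos = integer(0), ref = character(0),
                         alt = character(0))
    rep <- apply_and_translate(cds, vars)
    mut <- recscreen:::apply_variants_cds(cds, vars)
    expect_identical(rep$mutant_protein, oracle_translate(mut))
  }

  # an in-frame deletion never changes the frame downstream
  cds <- random_cds(100, 42)
  v <- data.frame(pos = 50L, ref = substr(cds, 50, 56),
                  alt = substr(cds, 50, 50))   # 6 bp deletion
  rep <- apply_and_translate(cds, v)
  wt <- rep$wildtype_protein
  mut <- rep$mutant_protein
  expect_identical(nchar(wt) - nchar(mut), 2L)
  expect_identical(substr(mut, nchar(mut) - 20L, nchar(mut)),
                   substr(wt, nchar(wt) - 20L, nchar(wt)))
})
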